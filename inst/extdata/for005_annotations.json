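{
  "numbering": "1-based precursor light-chain numbering, first residue after the signal sequence",
  "A": {
    "conformation": "A",
    "fibril_protein_span": {"start": 2, "end": 116},
    "ordered_spans": {
      "start": [9, 60],
      "end": [49, 107],
      "label": ["N-terminal ordered core (Ala9-Arg49)", "C-terminal ordered core (Arg60-Val107)"]
    },
    "disordered_spans": {
      "start": [2, 50, 108],
      "end": [8, 59, 116],
      "label": ["N-terminus (Ser2-Pro8)", "internal disorder (Lys50-Asp59)", "C-terminus (Leu108-Ser116)"]
    },
    "strand_spans": {
      "start": [10, 17, 25, 28, 34, 43, 60, 64, 72, 79, 85, 88, 95, 103],
      "end":   [14, 23, 26, 31, 37, 47, 62, 65, 75, 82, 86, 91, 97, 106],
      "label": ["beta1", "beta2", "beta3", "beta4", "beta5", "beta6",
                "beta6p", "beta6pp",
                "beta7", "beta8", "beta9", "beta10", "beta11", "beta12"]
    }
  },
  "B": {
    "conformation": "B",
    "fibril_protein_span": {"start": 2, "end": 116},
    "ordered_spans": {
      "start": [9, 68],
      "end": [49, 107],
      "label": ["N-terminal ordered core (Ala9-Arg49)", "C-terminal ordered core (Asn68-Val107)"]
    },
    "disordered_spans": {
      "start": [2, 50, 108],
      "end": [8, 67, 116],
      "label": ["N-terminus (Ser2-Pro8)", "internal disorder (Lys50-Gly67)", "C-terminus (Leu108-Ser116)"]
    },
    "strand_spans": {
      "start": [10, 17, 25, 28, 34, 43, 72, 79, 85, 88, 95, 103],
      "end":   [14, 23, 26, 31, 37, 47, 75, 82, 86, 91, 97, 106],
      "label": ["beta1", "beta2", "beta3", "beta4", "beta5", "beta6",
                "beta7", "beta8", "beta9", "beta10", "beta11", "beta12"]
    }
  },
  "mutations": {
    "position": [31, 48, 49, 51, 94, 97, 135],
    "from_aa": ["Y", "Y", "G", "N", "G", "V", "V"],
    "to_aa":   ["S", "F", "R", "S", "A", "Q", "G"],
    "germline_segment": ["IGLV3-19", "IGLV3-19", "IGLV3-19", "IGLV3-19",
                         "IGLV3-19", "IGLJ2", "IGLC2"],
    "name": ["Tyr31Ser", "Tyr48Phe", "Gly49Arg", "Asn51Ser",
             "Gly94Ala", "Val97Gln", "Val135Gly"]
  }
}
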