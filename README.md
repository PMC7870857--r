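# fibrilbreaks

Segment-level analysis of conformational heterogeneity ("structural
breaks") along amyloid fibrils, for cryo-EM helical reconstruction data.

## The problem

Helical reconstruction classifies each boxed fibril *segment* into a 3D
class. When classification of a patient-derived immunoglobulin
light-chain fibril sample (FOR005, λ3 light chain, explanted heart)
resolved two fibril structures A and B, the question became whether they
are two separate fibril morphologies or whether single fibrils carry both
conformations at different axial positions — i.e. whether fibrils contain
structural breaks where the protein conformation switches between A and B
along one protofilament stack.

That question is answerable from the segment table alone. For each fibril
(identified by the *pair* micrograph + helical tube ID) the package
computes the fraction of segments classified as B and the run structure of
the axially ordered label sequence: a *run* is a maximal stretch of
identical labels, a *switch* a boundary between runs. Separate
morphologies predict per-fibril B fractions piled at 0 and 1; breaks
predict mixed fibrils whose labels are *clustered* into contiguous axial
regions. Clustering is tested against a within-fibril permutation null:

* statistic: total switches `S`, summed over fibrils;
* null: independent shuffling of each fibril's labeled sequence
  (preserves every fibril's `n_A`, `n_B`);
* one-sided p toward fewer switches, with add-one correction
  `p = (1 + #{S_null ≤ S_obs}) / (B + 1)`.

Supporting modules cover helical lattice bookkeeping
(`pitch = (360/twist) × rise`, `crossover = pitch/2`), STAR/TSV segment
table I/O, a seeded two-state Markov simulator of fibril label sequences
with classification noise (for calibration and power analysis), residue
span annotation of the 115-residue fibril protein (ordered cores,
disordered segments, β-strands, germline mutations), and the four-predictor
aggregation consensus score (TANGO, FoldAmyloid, PASTA 2.0, Aggrescan;
0–4 per residue).

## Worked example

```r
library(fibrilbreaks)

cfg <- synthetic_config(n_fibrils = 2000, seed = 7)   # study-scale defaults
g   <- generate_fibrils(cfg)
s   <- fibril_summaries(g$table)

fraction_histogram(s)$n_fibrils
#>  min_1  min_5 min_10 min_20
#>   2000   1238    696    226

mixture_report(s, min_segments = 5)
#> Fibril mixture report (>= 5 labeled segments): 1238 fibrils
#>   pure_A     488  (39.4%)
#>   pure_B     277  (22.4%)
#>   mixed      473  (38.2%)

permutation_test_clustering(g$table, n_permutations = 999, seed = 7)
#> Permutation test for axial clustering of conformation labels
#>   fibrils tested (>= 2 labeled segments): 1771
#>   observed total switches: 934
#>   null (within-fibril shuffle): mean 2145.04, sd 25.97, 999 permutations
#>   one-sided p (fewer switches): 0.001

helical_params(1.11, 4.79)
#> Helical parameters: twist 1.11 deg (left-handed), rise 4.79 A
#>   pitch     1553.5 A (155 nm)
#>   crossover 776.8 A
```

Reading: at the generator's defaults most fibrils with ≥5 classified
segments are mixtures of A and B, yet the observed 934 switches sit far
below the exchangeable-null mean of ~2145 — the labels are axially
clustered (p at the resolution floor of 999 permutations), which is the
structural-break signature. `estimate_switch_rate()` on the same table
returns 0.0586 per step; with 2% misclassification this overshoots the
generating 0.02 because an isolated flipped label creates two spurious
switches — the reason clustering is assessed by the permutation test
rather than raw switch counts.

Real data enter through `read_segment_table()`, e.g.

```r
tab <- read_segment_table("run_data.star",
                          class_map = c("3" = "A", "5" = "B"))
```

See the vignette (`vignettes/structural-breaks.Rmd`) for the model,
parameter meanings and limitations.

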