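---
title: "Detecting structural breaks along amyloid fibrils from segment classifications"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting structural breaks along amyloid fibrils from segment classifications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrilbreaks)
```

## The scientific question

Cryo-EM helical reconstruction of ex vivo amyloid fibrils proceeds by
cropping each picked fibril into overlapping segments (boxes) along its
axis and classifying the segments in 3D. When classification of a
patient-derived immunoglobulin light-chain (FOR005, a λ3 light chain
extracted from explanted heart tissue) fibril data set yielded two distinct
fibril structures, A and B, two explanations were possible: the sample
contains two separate fibril morphologies, or single fibrils carry both
conformations at different axial positions, implying *structural breaks* —
positions where the fibril protein conformation switches within one
protofilament stack.

The discriminating observation lives entirely at the level of the segment
table: if morphologies were separate, each fibril's segments should be
(almost) all A or all B; if breaks exist, fibrils should show mixtures of
A and B, with the labels clustered into contiguous axial regions rather
than interleaved at random. This package makes that argument quantitative
and testable.

## Data model

A **segment record** carries a micrograph identifier, a helical tube
identifier, an axial position (Å), optional picking coordinates, a class
label (`A`, `B`, `UNASSIGNED`) and a flag marking membership in the final
reconstruction subset. Fibril identity is always the *pair*
(micrograph, tube): tube numbering restarts on every micrograph, so a tube
ID alone never identifies a fibril. Axial positions within one fibril must
be pairwise distinct; on input the table is sorted by
(micrograph, tube, axial position), which makes downstream grouping
invariant under any permutation of input rows.

STAR particle tables in the helical convention
(`_rlnMicrographName`, `_rlnHelicalTubeID`, `_rlnClassNumber`, optional
`_rlnHelicalTrackLengthAngst`, coordinates) and plain TSV are supported.
Because the numbering of 3D classes is an artifact of each refinement run,
the mapping from class numbers to conformations is always user input
(`class_map = c("3" = "A", "5" = "B")`); unmapped classes become
`UNASSIGNED`. When a STAR file has no track-length column, axial positions
are synthesised as extraction order × the declared inter-box spacing.

## Per-fibril summaries, runs and switches

For each fibril, [summarize_fibril()] reports label counts, the B fraction
(`n_B / (n_A + n_B)`, i.e. over *classified* segments only), and the run
structure of the labeled subsequence: a **run** is a maximal stretch of
identical labels in axial order, a **switch** is a boundary between
adjacent runs (`n_switches = n_runs - 1` whenever at least one labeled
segment exists). Two deliberate choices:

* `UNASSIGNED` segments are excluded from both fractions and runs, and a
  run may span an unassigned gap. Final-reconstruction subsets cover
  fibrils sparsely, so breaking runs at every unclassified segment would
  manufacture spurious switches. For users who prefer a conservative
  reading, `break_at_gap` optionally terminates runs at axial gaps larger
  than a given distance; with it enabled, `n_runs` counts gap-split runs
  (two same-label runs separated by a large gap count twice) and
  `n_switches` remains `n_runs - 1`. The option is off by default.
* The B-fraction histogram ([fraction_histogram()]) stratifies fibrils by
  minimum classified-segment count with inclusive thresholds
  (defaults 1, 5, 10, 20) and normalises percentages within each
  category, retaining absolute counts. Bins are 10 equal-width intervals
  on [0, 1], left-closed with the last bin closed — the exact binning of
  the published histogram is not stated, so the package fixes this
  convention and documents it.

## The clustering permutation test

The qualitative claim "A and B segments occupy distinct regions along the
fibril axis" is formalised here — the original report states the
observation without a statistic, so the test below is this package's own
construction and is labelled as such in its output.

The statistic is the total switch count summed over fibrils. The null
hypothesis is exchangeability of labels within each fibril: the null
distribution is generated by independently shuffling each fibril's labeled
sequence, which preserves every fibril's composition (`n_A`, `n_B`) and
therefore tests *arrangement*, not *mixture*. The p-value is one-sided
toward fewer switches than expected (axial clustering) with the add-one
correction `p = (1 + #{null ≤ observed}) / (B + 1)`, so `p ≥ 1/(B+1)` and
the test is valid at any finite number of permutations. Shuffling runs in
compiled code against R's RNG stream, so a seed makes the whole test
reproducible. Per-fibril p-values are available behind a flag for
exploration, with Benjamini–Hochberg adjustment attached; the pooled
statistic is the primary inference.

Why not infer breaks from raw switch counts? Misclassification inflates
them: an isolated flipped label creates two observed switches. Under pure
noise (no true switching, flip rate ε) the expected observed switch rate
per adjacent pair is `2ε(1−ε)` — a property the simulator reproduces and
the test suite checks. The permutation test is immune to this because the
null preserves each fibril's observed composition, noise included.

## The synthetic generator

[generate_fibrils()] draws each fibril's true conformation sequence from a
two-state Markov chain (switch probability `p_switch` per inter-box step),
flips observed labels with probability `epsilon`, marks segments
`UNASSIGNED` with probability `p_unassigned`, and flags an `in_final`
subset. A two-state symmetric chain is the minimal model compatible with
both proposed break mechanisms (imperfect templating during growth, or
post-assembly conversion of initially disordered segments); the two are
indistinguishable at the label-sequence level, which is exactly the level
this package operates on. Asymmetric misclassification rates are left as a
configuration extension.

Defaults mirror the scale of the FOR005 data set: 11,194 fibrils,
geometric lengths of mean 9.05 segments (≈101,319 segments), initial B
probability 0.362 (the overall B share among classified segments), final
subset retention 0.228, inter-box spacing 33.6 Å. The switch probability
(0.02 per step) and misclassification rate (0.02) are **modelling
choices**, not measured quantities — they produce per-fibril B fractions
spanning [0, 1] almost continuously with mass at both pure endpoints, the
qualitative shape of the published histogram. At these defaults with
5,000 fibrils every decile bin of the B-fraction histogram is occupied.

What the generator does *not* emulate: image-level alignment errors that
correlate between neighbouring segments (overlapping boxes share signal),
polymorph contamination, protofilament number, polarity, or any spatial
correlation of classification noise. Passing tests on synthetic tables
therefore demonstrate correctness of the statistics under the stated
model, not robustness to correlated misclassification — on real data a
significant clustering p-value should be read together with the per-fibril
run overlays ([mixture_report()]).

`estimate_switch_rate()` is the pooled maximum-likelihood estimator of
`p_switch` (switches / adjacent labeled pairs) with a binomial standard
error; with ε = 0 it recovers generating rates across
`p_switch ∈ {0.02, 0.1, 0.3}` within Monte-Carlo error, and with noise it
is biased upward by the `2ε(1−ε)` term above — a caveat, not a defect,
documented here because it motivates the permutation test.

## Helical geometry

`pitch = (360 / twist) × rise`, `crossover = pitch / 2` for a C1 helix.
Twist is stored as a magnitude plus a handedness flag because fibril
handedness is commonly an assumption from the reconstruction; all derived
axial quantities are handedness-independent. Units are Å internally; nm
appears only at reporting boundaries, rounded to the nearest nm. The
refined FOR005 symmetry (twist 1.11°, rise 4.79 Å — the only unit reading
consistent with the reported 155 nm pitch and the 4.79 Å layer line) gives
pitch 1553.5 Å = 155 nm and crossover 776.8 Å, matching crossover
distances measurable on motion-corrected micrographs.

## Residue annotation

The fibril protein comprises residues 2–116 of the precursor light chain
(115 residues, numbered from the first residue after the signal peptide).
Both conformations share an N-terminal ordered core at residues 9–49 and
disordered termini (2–8, 108–116); they differ in where order resumes
after the internal disordered region: residue 60 in conformation A
(with two extra short strands at 60–62 and 64–65) versus residue 68 in
conformation B. [classify_position()] maps any precursor position to
`ordered-core` / `disordered` / `cleaved-or-absent`, and
[diff_annotations()] compares two annotations residue by residue (region
and strand membership), merging differences into maximal intervals — for
the built-in annotations the difference is exactly residues 60–67, inside
the reported 12-residue difference segment 60–71. (Positions 68–71 are
ordered in both conformations and carry the same strand membership at
this annotation's granularity, so the per-residue diff flags only 60–67;
the conformational rearrangement the structures describe extends to 71.)
The seven germline mutations ship with the package; their structural
region columns are always derived, never stored, so they cannot drift
from the span definitions.

## Aggregation consensus score

Four published per-residue predictors are consumed as numeric tracks
(TSV, contiguous from residue 1); the predictors themselves are not
reimplemented. Hit rules read the published thresholds literally and
strictly: TANGO > 5 (%), FoldAmyloid > 21.4 sustained for ≥ 5 consecutive
residues, PASTA < −2.8 (PASTA Energy Units, per-residue projection done
upstream by the predictor), Aggrescan > −0.02; boundary values are
non-hits. The consensus score is the per-residue count of agreeing
predictors (0–4). [max_scoring_window()] returns the contiguous region at
the track maximum — among maximal runs at the top score, the longest, with
ties broken toward the lower start index; "window maximizing summed
score" cannot mean an unrestricted sum over non-negative scores (the
whole track would always win), so the run-at-maximum reading is used and
fixed here.

## Numerical and testing choices

* Permutation shuffles use Fisher–Yates over R's uniform stream inside
  compiled code; `set.seed()` before the call reproduces results exactly.
* The generator draws in a fixed order (lengths, initial states, switches,
  flips, unassignment, retention), making tables byte-identical per seed.
* Test problem sizes: run counting is verified exhaustively against a
  brute-force counter on all 3^12 label sequences of length 12 (and all
  sequences up to length 7 with a second, scalar oracle); the single-fibril
  Monte-Carlo p-value is checked at 100,000 permutations against exhaustive
  enumeration over all 252 arrangements of five A and five B labels; type-I
  error and power use 2,000 simulated tables of 50 fibrils × 30 segments
  each at 199 permutations per test (type-I rejection ≤ 0.06 at α = 0.05
  under i.i.d. labels; power ≥ 0.95 at `p_switch = 0.02`, ε = 0.02);
  switch-rate recovery uses 2,000 fibrils × 50 segments; the FoldAmyloid
  run rule is enumerated over all 2^10 two-valued tracks.
* Thresholded histogram categories with zero fibrils are flagged, not
  errors; their percentages are `NA`.

## Known limitations

* The published per-threshold fibril counts (11,194 / 7,738 / 4,278 / 951)
  and map resolutions (3.2 / 3.4 Å) require the deposited micrograph data
  and a full reconstruction; they are kept in
  [study_reference_counts()] as reference metadata, with the one
  recomputable consistency check (64,652 + 36,667 = 101,319) asserted in
  the tests.
* Break positions are localised only to the inter-segment spacing; the
  package deliberately does not interpolate within unresolved distances,
  relate breaks to crossover phase, or touch density maps.
* The command-line workflows are exposed as R functions and scripts
  rather than a standalone executable; the functions are the interface.
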