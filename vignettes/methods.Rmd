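---
title: "Methods: sequence-window classification of RNA 5hmC sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence-window classification of RNA 5hmC sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the unit of prediction

5-hydroxymethylcytosine (5hmC) is an RNA cytosine modification produced by
TET-mediated oxidation of 5-methylcytosine.  Transcriptome-wide assays
(hMeRIP-seq) locate 5hmC-containing regions, but they are expensive; a
sequence-only predictor offers a cheap complementary screen.  The unit this
package classifies is a **site window**: a 41-nt RNA sequence with the
candidate cytosine at position 21 (1-based).  Benchmarks in this family use
662 experimentally supported positive windows and 662 subsampled negative
windows (cytosines not called by hMeRIP-seq); the loader tolerates
imbalance, and nothing downstream assumes balance except the interpretation
of accuracy.

## Feature encoding (244 dimensions)

Each window `S = R1 R2 ... R41` over `{A,C,G,U}` is encoded as the
concatenation of three descriptor blocks, in this fixed order:

1. **Positional binary code** (164 = 41 x 4): each position contributes a
   4-bit one-hot block with the codes `A = 0001`, `U = 0010`, `C = 0100`,
   `G = 1000` (most significant bit first), named `b1 ... b164`;
   position *p* occupies `b(4p-3) ... b(4p)`.
2. **2-mer spectrum** (16): occurrence frequency of each dimer, denominator
   `L - k + 1 = 40`, so the block sums to exactly 1.
3. **3-mer spectrum** (64): likewise with denominator 39.

Numerical choices worth stating:

* The k-mer denominator is the number of k-windows.  Any constant
  denominator is equivalent up to scale for the downstream ANOVA ranking
  and (standardized) SVM, but this one makes "the spectrum sums to 1" a
  testable invariant.
* The k-mer enumeration is lexicographic over `A < C < G < U`.  The printed
  dimer list in the source formulation (`f(AA), f(AC), ..., f(GG)`) cannot
  be a complete RNA enumeration, so the complete alphabetical order was
  adopted.
* Ambiguity codes (`N` etc.) are rejected, not imputed: the encoding has no
  defined column for them.  DNA-alphabet input is accepted with `T -> U`.

## Two-stage feature optimisation

**Stage 1 — ANOVA F ranking.**  Per feature, `F = MSB / MSW` with
`df_B = K - 1 = 1` and `df_w = N - K`.  For two classes this equals the
squared pooled-variance t statistic, which the tests exploit as an
independent identity.  Degenerate cases: a feature constant within each
class but differing between classes receives an `Inf` sentinel and ranks
first (it separates perfectly, which is the criterion's intent); a globally
constant feature receives 0.  Ties in the ranking break by ascending
original index, making the ranking deterministic.

**Stage 2 — sequential forward search.**  Nested prefixes of the ranking
are evaluated at sizes `step, 2*step, ..., d` (default `step = 10`,
"ten-by-ten"; the final prefix is always the full dimension), each scored
by mean 5-fold CV accuracy of the classifier.  Two choices remove noise
from the trajectory comparison:

* the fold partition is fixed (seeded) across all prefixes;
* the classifier's `cost` and `gamma` stay at their configured values
  (default `C = 1`, `gamma = 1/d_prefix`); no per-prefix grid search.

A reported optimum of 26 features is not expressible under a pure step-10
schedule, so `refine = TRUE` adds a step-1 scan across the +/- one-step
window around the coarse optimum.  Ties on the maximum accuracy resolve to
the smallest subset.

**Leakage.**  The historical protocol of this predictor family selects
features on the full dataset and then cross-validates — the selection sees
the evaluation data.  `cross_validate(..., nested = TRUE)` instead repeats
ranking + forward search inside every training fold; it is the
statistically sound estimate and the default for honesty-critical checks
(the null-calibration tests).  The default `nested = FALSE` replicates the
historical protocol.  On null data the replication-mode estimate is
upward-biased, which a tendency test asserts.

## Classifier

A C-SVC with RBF kernel (polynomial and sigmoid available for the kernel
comparison harness).  Because no SVM implementation is available among this
package's allowed dependencies, the dual problem is solved by an SMO solver
written for this package (second-order working-set selection, stopping at
`m(a) - M(a) < 1e-3`), validated against the KKT conditions and a duality
gap bound in the tests.  Design choices:

* **Standardization** (zero mean / unit variance, fitted on training data
  only) is on by default: the encoding mixes 0/1 binary features with
  frequencies bounded by 1, and an RBF kernel on unstandardized mixed
  scales is dominated by the binary block.  A flag disables it.
* **Scores.**  The 0.5 decision threshold implies probability-like scores,
  so Platt calibration is the default, fitted by the regularised Newton
  method on decision values from an internal seeded 5-fold CV (fitting on
  resubstitution margins would be optimistic).  With calibration off the
  raw margin is min-max mapped to `[0,1]` on the training margins — a
  documented fallback, not a probability.  Class calls use the
  strictly-greater-than rule; a score exactly at the threshold is negative.
* **Grid search** evaluates `cost = 2^i, i = -2..5` against
  `gamma = 2^j, j = -5..2` (8 x 8 = 64 cells) by mean CV accuracy on one
  seeded partition shared by all cells; ties prefer smaller `cost`, then
  smaller `gamma` (simpler models).  Only the ranges are inherited from the
  source protocol; integer-exponent resolution is this package's choice,
  and finer grids are available via the config.

Determinism: every partition and every solver path is a pure function of
the data and the seed, so repeated runs are bitwise identical.

## Evaluation

Sn, Sp, ACC and MCC are computed from the confusion counts in their
standard forms; a zero factor in the MCC denominator yields `MCC = 0`
(convention), and an Sn or Sp whose defining class is absent is reported as
`NA` rather than 0.  Cross-validation uses **stratified** folds (the source
protocol says only "randomly partitioned"; with balanced data
stratification reduces variance and cannot hurt comparability).  Per-fold
metrics are averaged arithmetically; held-out scores are pooled across
folds for the ROC and PR curves (vertical averaging is not implemented; the
pooled convention is stated in the report).  AUC is the trapezoidal
integral of the ROC with tied scores grouped into single sweep points,
which makes AUC equal the normalised Mann-Whitney U — asserted against
`wilcox.test` in the tests.

`position_enrichment()` is a numeric two-sample-logo analog: per position
and nucleotide it reports class frequencies, their difference, a
two-proportion z-test p-value and its Bonferroni correction across all
`41 x 4` tests (the graphical logo convention is not reproduced; the table
is the deliverable).

## The synthetic world

The generator emulates the benchmark's shape — balanced classes, 41-nt
windows, center C — with signal injected at the *generative* level
(nucleotide and trimer probabilities), never at the feature level, so that
recovery exercises the full encoder nontrivially.  Negatives are i.i.d.
from the background (default uniform; real transcript composition is not
uniform, and no attempt is made to match any real dataset's composition).
Positives apply, in order: a guanine boost (`g_boost` added to P(G), then
renormalised), an optional planted `GGG` trimer at a random non-center
position, and positional single-nucleotide enrichments.  The center is
excluded from planting because it is constitutively C.

Preset parameterization (chosen a priori from effect-size arithmetic, then
frozen):

* `strong_kmer` uses `g_boost = 0.4`, `ggg_insert_rate = 0.3`: the window
  G-count then differs between classes by d' ~ 2.9, putting even a
  single-feature classifier near 0.93 accuracy, before the spectrum and the
  planted trimer add signal — a scenario that is unambiguously "strong".
  (An initial sizing at `g_boost = 0.3` produced a marginal ~0.89 pipeline
  accuracy, i.e. failed to realize the strongly-separable scenario the
  preset is defined to be, and was revised once on the analytic grounds
  above.)
* `positional_only` enriches A at position 38 to probability 0.7 in
  positives — signal invisible to the spectra, visible to binary slots
  `b149..b152`, mirroring the position-38 adenine enrichment reported for
  the real data.
* `null` / `null_small` carry no label-dependent signal and calibrate the
  honesty of the nested protocol.

What a green synthetic test does **not** establish: real 5hmC windows are
not i.i.d. draws from a positionally independent model — they carry
long-range composition, shared transcripts between classes, and unknown
effect sizes.  The fixtures establish that the machinery recovers known
signal and reports chance for no signal, not that the real-data accuracies
are reproduced (those require the original externally hosted benchmark and
are documented as soft checks only).

## Known limitations

* Only binary classification; only the maximum-margin classifier family.
* Comparison descriptors from the wider literature (PCP, MMI, PseDNC,
  PseEIIP) are out of scope, as are alternative classifiers.
* The SMO solver has no shrinking heuristic; with the iteration cap
  (`max(20000, 200n)`) worst-case fits stop early with a warning-free
  approximate solution (adequate at the stopping tolerance used here).
* No transcriptome scanning: inputs must already be fixed-length windows.
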