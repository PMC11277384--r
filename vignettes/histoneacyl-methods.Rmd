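---
title: "histoneacyl: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{histoneacyl: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histoneacyl)
```

## The measurement model

Bottom-up histone PTM quantification derivatizes lysines before trypsin
digestion, restricting cleavage to arginine (ArgC-like specificity), and
then derivatizes peptide N-termini. `histoneacyl` models this chemistry
explicitly so that the consequences of each reagent choice can be computed
rather than assumed.

Everything is rooted in elemental compositions. Each amino-acid residue and
each modification is a signed vector of element counts over
`H, C, N, O, S` plus the heavy isotopes `2H, 13C, 15N` tracked as separate
symbols. A peptidoform's monoisotopic mass is the dot product of its total
composition with the monoisotopic element masses (CODATA/IUPAC values to at
least six decimals). Compositions, not printed delta masses, are the source
of truth: the commonly printed value for butyrylation (+70.0422 Da) exceeds
the compositional sum of C4H6O (+70.0419 Da) by ~0.0003 Da, and the printed
monomethyl+label combination masses carry the same small excess, so a mass
table assembled from printed values would not even be internally additive.
All printed values are still honored as cross-checks at 0.001 Da, enforced
at construction time of every `mod_spec()`.

### Derivatization rules

Chemical acylation occurs on unmodified and mono-methylated lysines. The
protocol model therefore applies its lysine label to every K whose
side-chain state is `free` or `me1` (me1 is retained alongside the label);
any endogenous acyl (ac, pr, bu, cr, fo, ma, su, gl, hib, la) or me2/me3
blocks the label. Every peptide N-terminus receives exactly one N-terminal
label. A protein N-terminus is treated like any other peptide N-terminus —
the rule is uniform so every enumerated form has a well-defined mass; if a
protein-level acetyl-N-terminus model is ever needed it can be expressed as
an endogenous modification.

The heavy (super-SILAC) channel adds the Arg10 label — ¹³C₆¹⁵N₄, a
+10.008269 Da substitution — to every arginine, so heavy − light mass is
exactly 10.008269 × (number of R) by construction.

### Ambiguity prediction

Two peptidoforms of the same window and channel are classified as:

* `indistinguishable` — masses within tolerance *and* isotope-blind
  compositions identical. Isotope-blind means `2H → H`, `13C → C`,
  `15N → N` before comparing: deuterated and light forms of the same acyl
  are chemically and chromatographically equivalent, so composition
  equality after this folding is the minimal co-elution predictor that
  reproduces the observed isobarization behavior. Positional isomers (same
  modification set on different lysines) are deliberately captured by this
  rule: they co-elute after label-induced homogenization of the peptide
  chemistry.
* `mass_only_distinct` — isotope-blind compositions identical but masses
  separated beyond tolerance. This is precisely the deuterated-label design
  working as intended: endogenous propionylation under D5PRO-PIC co-elutes
  with its labeled counterpart but sits 5.0314 Da away.
* `distinct` — anything else.

Classes are the transitive closure of `indistinguishable`, so chains of
pairwise-isobaric forms collapse together, mirroring what a chromatogram
would show. The mass tolerance defaults to 10 ppm of the peptidoform mass —
about twice a typical 4.5 ppm main-search precursor tolerance, so the
prediction errs toward flagging a collision — and is configurable.

### Digestion

`digest_argc()` cleaves C-terminal to arginine, suppressed before proline
by default. The proline rule is on because it reproduces the canonical
histone windows (H3 41–49 `YRPGTVALR` spans an internal R–P; with the rule
off that window never appears). Coordinates are 1-based inclusive protein
positions, matching the field's "H3 9–17" naming. Defaults: up to 2 missed
cleavages, minimum length 4. The implementation is validated against a
brute-force oracle that enumerates every substring and filters by cleavage
legality.

## Identification merging

Searching one acylation at a time keeps search spaces small, at the price
of spectra assigned differently across searches. `merge_searches()` keeps
the highest-scoring assignment per (raw file, scan) — deduplication is per
spectrum, not per (spectrum, charge), since the inputs in view carry no
charge column. Ties at exactly equal score break deterministically: fewer
modified residues first (the more parsimonious explanation), then
lexicographic modification string, then search id. Competitor assignments
are logged in a provenance column rather than dropped silently.

The confidence filter removes rows with score < 40 or localization
probability < 0.75 (both strict, so boundary values survive), plus decoy
and contaminant rows. Localization applies to modified peptides only — an
unmodified peptide has no site to localize and passes vacuously; a modified
peptide *without* a localization value fails, since its site placement is
unknowable. FDR control is consumed as an upstream fact (decoy flags), not
recomputed.

## Quantification

Percent relative abundance is computed within a peptide-window group per
channel per sample: `%RA_i = 100 a_i / Σ a_j` over the *observed* forms.
An absent record is missing data; an area of zero with a detected peak is a
true zero. An all-zero group is marked non-quantifiable rather than
divided.

The light/heavy ratio `%RA(light) / %RA(heavy)` is invariant to any
per-sample rescaling of intensities, which is the point of ratio-based
quantification against a constant spike-in; a heavy %RA of zero yields a
missing value, never an infinity.

The combinatorial reporting path (`sum_combinatorial()`) first rescales
each group to a fixed total area of 1e9, then credits each multiply
modified form's area to every single modification it carries. This path
feeds per-modification abundance displays only; the statistical path uses
per-form %RAs, as the ratio formula implies.

A peptidoform is quantifiable iff identified in at least 2 replicates,
identified in the spike-in, and marked as a clearly resolved peak. The
resolved-peak criterion is a manual-validation judgment in practice and is
modeled as a boolean input column (the simulator produces it with known
truth).

### Normalization, outliers, imputation

Ratios are log2-transformed and centered per row on the mean of the
reference samples — all samples (row means become exactly 0, and the
operation is idempotent) or the untreated samples. Tukey fences (Q3 +
1.5·IQR / Q1 − 1.5·IQR) then mask outliers. Two choices here were genuinely
open:

* **Quartile rule.** Linear interpolation between order statistics (R
  type 7), the common default; on `{1,2,3,4,100}` this gives Q1 = 2,
  Q3 = 4 and masks 100.
* **Scale and grouping.** Fences are computed on *normalized log2 ratios*,
  per row, across the **pooled** samples of a comparison. Computing fences
  within each small group separately was rejected empirically: with n = 4
  per group, per-group fences shrink the within-group variance estimate and
  inflate the t test's false-positive rate to ~0.10; pooled fences keep it
  at ~0.055, compatible with the nominal 0.05.

Mean imputation (row mean across conditions) exists only for consumers
that cannot tolerate missing values (PCA, discriminant analysis); the t
test path never imputes. Fully missing rows are dropped with a warning.

## Statistics

`two_sample_t()` is the classical pooled-variance Student t (df =
nA + nB − 2, two-sided), written from the closed form; `stats::t.test`
serves as an independent cross-check in the test suite. Welch's correction
is deliberately not used — the supported comparison is the plain Student t.
Degenerate inputs are explicit: zero pooled variance with equal means gives
t = 0, p = 1; zero pooled variance with unequal means is flagged degenerate
with p at the machine lower bound and a warning. Groups need at least two
values each ("insufficient replicates" otherwise). A paired mode is
available via `paired = TRUE`; the default is unpaired. No multiple-testing
correction gates the significance flag (raw p < 0.05), but a
Benjamini–Hochberg column is emitted for reference. z-scaling for
discriminant consumers uses the sample (n−1) standard deviation, and
constant rows are dropped because their z-score is undefined.

## The synthetic-data generator

`simulate_dataset()` emulates the experiment's three input tables with
known ground truth. What it models:

* true per-condition %RA profiles per peptide-window group (Dirichlet-like
  gamma draws normalized to 100), and one heavy spike-in profile over the
  covered subset of forms (coverage 0.7 by default, reproducing the
  observed ~30% of sites without a spike-in counterpart);
* XIC areas = per-sample group total × true %RA × multiplicative lognormal
  noise, mean-corrected so that expectation equals truth and CV = 0 gives
  exact recovery (lognormal is the standard model for XIC intensities);
* per-spectrum PSMs in the search of each form's own acylation, with
  truncated-normal scores (truth ~ N(120, 25), competitors ~ N(60, 20), at
  0) and Beta(12, 1) localization probabilities, placing mass on both
  sides of the 40 / 0.75 filters;
* same-spectrum competitor assignments injected into a *different* search
  at a configurable rate (default 0.2), drawn from the enumerable forms of
  the same window;
* record-level missingness, peptidoform-level resolved-peak failures, and
  a handful of decoy rows.

Defaults are the study conditions exercised throughout the test suite: 50
peptidoforms, 3 conditions × 4 replicates, CV 20%, coverage 0.7, ambiguity
rate 0.2. All randomness flows from the single mandatory seed; the same
seed reproduces byte-identical outputs.

What it does **not** model — and hence what passing tests do not show about
real data: chromatographic peak shapes and retention-time drift,
correlated (batch) noise across samples, intensity-dependent variance and
detector saturation, sequence-dependent ionization efficiency (the
stoichiometry bias of bottom-up %RA estimates), incomplete derivatization,
and real decoy score distributions. Recovery results on simulated data
bound what the arithmetic can do, not what an instrument will deliver.

## Problem sizes and budgets

The shipped test suite runs the chemistry checks over all enumerated forms
of the H3 9–17, 18–26, 27–40 and H4 4–17 windows (25–625 forms per window,
five side-chain states per lysine), validates digestion against the
brute-force oracle on 200 random sequences up to 60 aa at 0–2 missed
cleavages, and runs the simulator at the default study conditions plus a
1000-peptidoform null design for t-test calibration. These sizes were
chosen to exercise every code path with comfortable statistical resolution
(binomial SE ≈ 0.7% at 1000 null tests) while keeping a full test run
around a minute.

## Known limitations

* Co-elution prediction is composition equality only; it will not flag
  near-isobaric pairs of *different* composition that a low-resolution
  instrument could confuse, nor predict partial chromatographic separation
  of positional isomers.
* Replicate counting for the quantifiability rule is per raw file across
  the experiment; designs where the same sample is injected repeatedly
  need their raw files collapsed first.
* The moderated/correlated test used for matched clinical designs
  (limma-style duplicateCorrelation) is out of scope; the plain
  paired/unpaired t path is the supported comparison.
* Derivatization side reactions (over-acylation on S/T/Y) and MS2-level
  evidence are not modeled.
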