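---
title: "Methods: differential interactomics for quantitative TAP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential interactomics for quantitative TAP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtapdiff)
```

## The problem

Tandem affinity purification coupled to label-free quantitative mass
spectrometry (qTAP) asks which proteins change their association with a
tagged bait when a stimulus is applied.  Samples are purified in
replicate under two conditions ("mock" and "treatment"), quantified with
MaxQuant, and compared protein-by-protein.  Two features make this
harder than a generic two-group proteomics comparison:

1. **Left-censored missingness.**  A prey bound only under treatment has
   *no* quantification in the mock runs — not a value of zero, but an
   absence caused by abundance below the detection limit (missing not at
   random, MNAR).
2. **A degrading bait.**  When the stimulus triggers degradation of the
   bait itself, every prey captured through the bait tends to fall with
   it.  On the absolute intensity scale the volcano plot skews toward
   mock, and preys whose *relative* association with the bait increases
   can be hidden by the global loss of material.

`qtapdiff` implements the complete post-processing chain for this
situation: decoy/contaminant filtering, log2 transform, an optional
bait-level normalization, a valid-value filter, replicate QC,
left-censored imputation, and an S0-moderated two-sample test whose
significance threshold is set by a label-permutation estimate of the
false discovery rate.

## The analysis chain

Stages run in a fixed order (a configuration cannot reorder them):

1. `filter_flagged_rows()` — remove reverse-database hits, potential
   contaminants, and groups identified only by modified peptides.
2. `log2_transform()` — intensities to log2; missing stays missing.
3. `bait_normalize()` *(intensity arm only)* — subtract the bait's
   per-sample log2 intensity from every protein, i.e. analyze the log2
   prey/bait ratio.  Applied **before** imputation, so imputed values
   are drawn in bait-relative coordinates.
4. `filter_valid_values()` — keep rows with at least `min_valid`
   quantifications in the mock group *or* in the treatment group
   (default 4: a full group in a 4 + 4 design).  The one-sided rule is
   what lets a treatment-only prey — absent from every mock run —
   survive.
5. `replicate_qc()` — pairwise Pearson correlations per within-group
   sample pair, on pairwise-complete rows.  QC deliberately precedes
   imputation: imputed cells are drawn noise and would inflate apparent
   reproducibility.
6. `impute_missing()` — see below.
7. `diff_test()` / `permutation_fdr()` — see below.

A full qTAP study runs two arms over the same samples
(`run_pipeline(mode = "both")`): the **LFQ arm** (normalized LFQ
intensities, no bait normalization) and the **intensity arm** (raw
intensities, bait-normalized).  They answer different questions — change
in *absolute* co-purified amount versus change *relative to the bait* —
and with a degrading bait the second is the one that exposes recruited
machinery.

## Imputation model

Missing label-free values are overwhelmingly below-detection-limit
censoring, so they are replaced by draws from a normal distribution in
the lower tail of the observed intensities:

* `downshift_normal` (default): Normal(μ − d·σ, (w·σ)²) with μ, σ the
  observed mean and standard deviation of the imputation scope and the
  community-standard defaults d = 1.8, w = 0.3;
* `min_centered`: Normal(min, (w·σ)²), centring the draws on the lowest
  detected intensity of the scope.

The scope is per sample column by default (each run has its own
detection characteristics); `global` pools the matrix for very small
designs.  Whether a real study imputed per sample or globally is rarely
reported; both are provided and the choice is recorded in the saved
configuration.  Draws come from a position-indexed substream of a single
seed, so a cell's imputed value does not depend on which other cells
happen to be missing, and identical seed + input reproduces the matrix
bit for bit.  Observed cells are never modified.

## The moderated test and the permutation FDR

For each protein, with group means difference D = mean(mock) −
mean(treatment) and (pooled Student, default, or Welch) standard error
s, the test statistic is

    d* = D / (s + s0),        s0 = 0.1 by default.

s0 damps proteins whose tiny variance would otherwise make a negligible
difference "significant"; the unmoderated t and its two-sided p-value
are reported alongside (the volcano y-axis is −log10 p; the significance
*flag* comes from d*).  Degenerate inputs: zero variance in both groups
with D = 0 yields t = 0, p = 1, d* = 0; zero variance with D ≠ 0 is
regularized by s0 (t = ±Inf, p = 0) and is an error at s0 = 0.

Significance is a threshold c on |d*| chosen from a permutation null:
all relabellings of the samples into groups of the original sizes
(exhaustively when the number of distinct assignments is at most 10,000
— a 4 + 4 design has only choose(8,4) = 70 — otherwise `n_perm` seeded
draws without replacement; the identity labelling is excluded).  For
every candidate c taken from the sorted observed |d*|,

    FDR(c) = mean over permutations of #{|d*_perm| >= c}
             -----------------------------------------------
             max(1, #{|d*_obs| >= c})

capped at 1.  The curve is then made monotone non-increasing in c by a
running maximum from the largest threshold downward — a looser threshold
is never allowed to claim a lower FDR than a stricter one.  The selected
threshold is the smallest c with FDR(c) ≤ α (default 0.05); if none
qualifies nothing is flagged.  No π0 correction is applied; omitting it
is conservative.  On any instance small enough to enumerate, the
implementation agrees exactly with a brute-force oracle coded
independently in the test suite.

## The synthetic-data generator

`simulate_apms()` generates ground-truthed experiments at the scale of a
typical qTAP study: ~300 protein groups, 4 + 4 replicates, log-normal
abundances (log2 base levels N(25, 2²)), replicate noise σ = 0.3 on the
log2 scale, a bait at log2 ≈ 28 losing 1.5 log2 units under treatment,
and logistic left-censoring around a detection limit of 20 with a hard
floor 2 log2 units below it.  Class semantics (mock / treatment true
levels) are documented in `?sim_config`.  Three modelling choices
deserve justification:

* **Background binders are flat and bait-independent** (bead binders);
  **constitutive preys are flat in the mean but carry the bait's
  per-sample fluctuation**.  With a strongly overexpressed bait the
  bait remains in excess even after a 3-fold drop, so the captured
  amount of a constitutively bound prey is prey-limited: it does not
  follow the bait's condition-level drop.  This is exactly the class
  that is invisible in the LFQ arm (D ≈ 0) and shifts to D = −δ_bait
  after bait normalization — the mechanism by which bait normalization
  "finds" preys a bait-agnostic analysis misses.
* **Interactor classes are drawn detectable in their bound state**
  (base level at least 3 log2 units above the detection limit), and the
  **bait is never censored**.  A planted "interactor" that is below the
  detection limit in both conditions is unobservable by construction
  and would only measure the censoring model, not the analysis; the
  bait anchors the purification and is identified in every run.
* **Censoring steepness**: the logistic slope defaults to 2 per log2
  unit, concentrating the soft-censoring zone within about one log2
  unit of the detection limit, consistent with the sharp
  detection behaviour of LC-MS at fixed acquisition settings.

What the generator does **not** emulate: peptide-level quantification
and roll-up, match-between-runs artifacts, retention-time drift,
ratio-compression, batch structure, or real LFQ normalization (the
"LFQ" columns of simulated data are per-sample median-centered raw
intensities — a surrogate that shares LFQ's anchor-on-the-bulk
assumption but none of its pairwise-ratio machinery).  Passing tests on
simulated data therefore demonstrate the correctness and calibration of
the *post-processing chain*, not robustness to every artifact of real
acquisitions.

In the intensity arm the null hypothesis is *constant stoichiometry
with the bait*: when the bait degrades, any protein whose absolute
level does not fall with it is genuinely enriched relative to the bait
— including stable bead binders.  The candidate list of the
bait-normalized arm is therefore intentionally inclusive, mirrors how
relative-to-bait analyses behave on real degrading-bait data, and is
meant to be read together with the LFQ arm, not instead of it.

## Numerical and interface choices

* Raw-scale zeros and empty cells are parsed as missing (MaxQuant
  convention); the imputation step presupposes this.
* Bait identification is a substring match of the configured bait id
  against the protein-group id (groups concatenate accessions); an
  exact-match mode exists.  An ambiguous match is an error, never a
  silent pick.
* A bait missing in some sample is an error by default; an opt-in mode
  censors those samples instead.  (With the recommended overexpressed
  bait this should not occur in practice.)
* The bait row is retained through testing — after normalization its
  difference is exactly 0, serving as an internal control point.
* Results tables order rows by descending |difference|, ties by
  ascending p.
* Intensity values written by `write_protein_groups()` carry 17
  significant digits, so a write/read cycle reproduces the analysis
  byte for byte.
* Two-sided testing throughout: enrichment is biologically meaningful
  in both directions (recruited and released preys).
* The p-values plotted are from the unmoderated t; flags come from the
  moderated |d*| threshold.  Both are reported per row.

## Problem sizes used by the test suite

The packaged checks run at sizes chosen to finish in minutes on one
core while keeping Monte-Carlo error well inside the asserted margins:
200 pure-null simulations of 500 × 8 matrices for FDR calibration, 50
seeds each for the recovery and bait-normalization properties, 10,000
draws for imputation moments, and exhaustive 3 vs 3 enumeration (19
non-identity assignments) against the brute-force oracle.

## Known limitations

* The permutation null at 4 + 4 has 69 non-identity assignments; the
  smallest non-zero FDR estimate is 1/69 per observed exceedance, so
  very small candidate lists have coarse FDR granularity.
* No batch covariates: designs that pool different constructs into one
  group are analyzed without a batch term.
* No π0 estimation (conservative by design); no empirical-Bayes
  variance moderation — s0 plays that role in the simpler SAM-style
  form.
* Paired designs and more than two groups are out of scope.
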