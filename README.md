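# qtapdiff

Differential interactomics for quantitative tandem affinity purification
(qTAP): find the proteins whose association with a tagged bait changes
between a mock and a treatment condition, from MaxQuant-style
`proteinGroups.txt` label-free quantification output.

The package is aimed at AP-MS / TAP-MS practitioners analyzing
two-condition pulldown experiments — in particular the hard case where
the treatment triggers **degradation of the bait itself**, so that every
co-purified prey drops with it and conventionally normalized volcano
plots hide the biology.

## What it computes

For each protein group, with log2 group means and difference
`D = mean(mock) − mean(treatment)` and standard error `s` (pooled
Student, default, or Welch), the SAM-style moderated statistic

```
d* = D / (s + S0),    S0 = 0.1 by default
```

is thresholded on |d*| by a **permutation-based FDR** (default level
0.05): all relabellings of the samples into two groups of the original
sizes are enumerated (exhaustive for designs up to 10,000 assignments —
a 4 + 4 design has 70), the expected number of null exceedances is
compared to the observed count at every candidate threshold, and the
smallest threshold with estimated FDR ≤ α is selected.

Around that core, the pipeline implements the full qTAP post-processing
chain:

* decoy / contaminant / site-only row removal,
* log2 transform with explicit missingness (raw zero = not quantified),
* **bait-level normalization**: subtract the bait's per-sample log2
  intensity from every protein, turning the analysis into one of log2
  prey/bait ratios — the device that exposes preys recruited to a
  degrading bait,
* "≥ N valid values in at least one group" filtering (one-sided, so a
  prey absent from every mock run survives via its treatment profile),
* replicate QC (pairwise Pearson correlations, pre-imputation),
* left-censored imputation from a down-shifted normal distribution
  (Perseus-style defaults: downshift 1.8 σ, width 0.3 σ),
* volcano tables/plots of `log2(mock/treatment)` vs `−log10 p`.

A ground-truthed synthetic AP-MS generator (`simulate_apms()`) emulates
the whole setting — degrading bait, constitutively bound preys,
treatment-recruited and treatment-released interactors, stable
background, log-normal abundances, and intensity-dependent left-censored
missingness — so every stage is testable without raw MS data.  See the
methods vignette (`vignettes/qtap-methods.Rmd`) for the model and all
defaults.

## Worked example

A 20-row synthetic `proteinGroups` fixture ships with the package:

```r
library(qtapdiff)

design <- read_sample_design(
  system.file("extdata", "design_synthetic20.tsv", package = "qtapdiff"),
  bait_id = "AT2G29970")
tab <- read_protein_groups(
  system.file("extdata", "proteinGroups_synthetic20.txt", package = "qtapdiff"),
  "raw", design)
tab
#> protein_table: 20 protein groups x 8 samples (raw scale)
#>   missing cells: 21 (13.1%)
#>   flagged for removal: 4; bait: AT2G29970.1;AT2G29970.2

an <- analyze_table(tab, design, mode = "intensity",
                    impute = impute_params(seed = 1),
                    fdr = fdr_params(seed = 1))
an
#> qtap_analysis (intensity mode): 20 -> 16 -> 13 rows; 12 significant
an$qc
#> qc_report: within-group Pearson r in [0.883, 0.993]
#>   per-sample missingness: 0.0% to 7.7%

head(an$results[order(-abs(an$results$difference)),
                c("gene_label", "difference", "p_value", "d_star",
                  "significant")], 5)
#>  gene_label difference  p_value d_star significant
#>     PREY010      -3.60 3.54e-05  -8.37        TRUE
#>    MOCKONLY       2.65 2.20e-04   6.08        TRUE
#>   TREATSIDE      -2.55 2.01e-02  -2.79        TRUE
#>     PREY004      -2.02 6.37e-06  -8.48        TRUE
#>     PREY003      -1.88 4.89e-03  -3.52        TRUE
```

Reading the output: 4 of the 20 rows are decoy/contaminant/site-only
and are removed; 3 more fail the valid-value filter (≥ 4 quantifications
in at least one group).  In the bait-normalized ("intensity") arm the
difference column is the change in log2 prey/bait ratio, mock minus
treatment: `PREY010` at −3.60 is strongly treatment-enriched relative to
the bait, `MOCKONLY` (quantified in no treatment sample; its treatment
values were imputed at the detection limit) at +2.65 is mock-enriched.
The bait's own difference is exactly 0 by construction.  Negative
differences sit on the treatment side of the volcano.

End-to-end runs with artifact files (results tables, QC report,
imputation record, volcano PNGs, resolved JSON config) go through
`run_pipeline(pipeline_config(...))`, or from a shell via the thin CLI:

```sh
qtapdiff run --protein-groups proteinGroups.txt --design design.tsv \
             --bait AT2G29970 --mode both --out my_run
qtapdiff simulate --seed 7 --out sim_run
```

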