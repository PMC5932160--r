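# Row filters, log2 transform and replicate quality control.
# Stage order in the pipeline: flagged-row removal -> log2 ->
# [bait normalization] -> valid-value filter -> QC -> imputation.

#' Remove decoy, contaminant and site-only protein groups
#'
#' Drops every row flagged as a reverse-database hit, a potential
#' contaminant, or identified only by modified peptides.  Row order is
#' preserved.  The bait row must never carry a removal flag; if it does,
#' the design is mis-specified and an error is raised rather than the
#' bait silently discarded.
#'
#' @param table a [protein_table()] (raw or log2 scale).
#' @return The filtered `protein_table`.
#' @export
filter_flagged_rows <- function(table) {
  r <- table$records
  drop <- r$is_reverse | r$is_contaminant | r$only_by_site
  if (any(drop & r$is_bait)) {
    stop("the bait row carries a removal flag (reverse/contaminant/site); ",
         "check the bait id in the design")
  }
  subset_rows(table, !drop)
}

#' Log2-transform a raw-scale table
#'
#' Present cells become their log2; missing cells stay missing.
#'
#' @param table a raw-scale [protein_table()].
#' @return The table on the log2 scale.
#' @export
log2_transform <- function(table) {
  if (table$scale != "raw") stop("log2_transform expects a raw-scale table")
  v <- table$values
  if (any(v[!is.na(v)] <= 0)) stop("raw intensities must be > 0")
  protein_table(table$records, log2(v), scale = "log2")
}

#' Keep rows quantified in at least one full (or near-full) group
#'
#' Retains exactly the rows with at least `min_valid` non-missing values
#' in the mock group OR at least `min_valid` in the treatment group.  The
#' one-sided rule is essential for treatment-recruited interactors that
#' are absent from every mock sample: they keep a full treatment profile
#' and must survive the filter.
#'
#' @param table a log2-scale [protein_table()].
#' @param design a [sample_design()].
#' @param min_valid required count of valid values; the default (4)
#'   equals the replicate number of a 4 vs 4 qTAP design, i.e. a full
#'   group.  Must not exceed the size of the largest group.
#' @return The filtered `protein_table`.
#' @export
filter_valid_values <- function(table, design, min_valid = 4L) {
  if (table$scale != "log2") stop("filter_valid_values expects a log2 table")
  min_valid <- as.integer(min_valid)
  if (min_valid < 1L) stop("min_valid must be >= 1")
  idx <- design_indices(table, design)
  if (min_valid > max(length(idx$mock), length(idx$treatment))) {
    stop("min_valid (", min_valid, ") exceeds both group sizes")
  }
  ok_mock <- rowSums(!is.na(table$values[, idx$mock, drop = FALSE])) >= min_valid
  ok_trt <- rowSums(!is.na(table$values[, idx$treatment, drop = FALSE])) >= min_valid
  subset_rows(table, ok_mock | ok_trt)
}

#' Replicate quality control: pairwise Pearson correlations
#'
#' Computes the Pearson correlation of log2 intensities for every
#' within-group sample pair (optionally all pairs) on pairwise-complete
#' rows only.  QC runs before imputation by design: imputed values are
#' drawn noise and must not inflate the apparent reproducibility.
#'
#' @param table a log2-scale [protein_table()].
#' @param design a [sample_design()].
#' @param include_cross also report mock-vs-treatment pairs.
#' @return An object of class `qc_report`: list with `correlation`
#'   (sample x sample matrix, unit diagonal, `NA` where not computed),
#'   `n_shared` (pairwise-complete row counts), `pairs` (long-format data
#'   frame), `missing_frac` per sample, and `r_min`/`r_max` over the
#'   within-group pairs.  Pairs sharing fewer than 3 complete rows are
#'   reported as `NA` with a warning.
#' @export
replicate_qc <- function(table, design, include_cross = FALSE) {
  if (table$scale != "log2") stop("replicate_qc expects a log2 table")
  s <- design$samples
  idx <- match(s$sample, colnames(table$values))
  if (anyNA(idx)) {
    stop("design sample(s) not present in the table: ",
         paste(s$sample[is.na(idx)], collapse = ", "))
  }
  v <- table$values[, idx, drop = FALSE]
  k <- ncol(v)
  cm <- matrix(NA_real_, k, k, dimnames = list(s$sample, s$sample))
  ns <- matrix(0L, k, k, dimnames = list(s$sample, s$sample))
  diag(cm) <- 1
  diag(ns) <- as.integer(colSums(!is.na(v)))
  pairs <- NULL
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      within <- s$group[i] == s$group[j]
      if (!within && !include_cross) next
      both <- !is.na(v[, i]) & !is.na(v[, j])
      n <- sum(both)
      r <- if (n >= 3L) {
        stats::cor(v[both, i], v[both, j])
      } else {
        warning("samples ", s$sample[i], " and ", s$sample[j],
                " share only ", n, " complete rows; correlation undefined")
        NA_real_
      }
      cm[i, j] <- cm[j, i] <- r
      ns[i, j] <- ns[j, i] <- n
      pairs <- rbind(pairs, data.frame(
        sample1 = s$sample[i], sample2 = s$sample[j],
        group = if (within) s$group[i] else "cross",
        r = r, n_shared = n, stringsAsFactors = FALSE))
    }
  }
  wr <- pairs$r[pairs$group != "cross"]
  structure(list(correlation = cm, n_shared = ns, pairs = pairs,
                 missing_frac = colMeans(is.na(v)),
                 r_min = if (all(is.na(wr))) NA_real_ else min(wr, na.rm = TRUE),
                 r_max = if (all(is.na(wr))) NA_real_ else max(wr, na.rm = TRUE)),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: within-group Pearson r in [%.3f, %.3f]\n",
              x$r_min, x$r_max))
  cat(sprintf("  per-sample missingness: %.1f%% to %.1f%%\n",
              100 * min(x$missing_frac), 100 * max(x$missing_frac)))
  invisible(x)
}

#' Write a QC report as a tab-separated matrix plus a summary line
#' @param qc a `qc_report` from [replicate_qc()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(qc, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  df <- data.frame(sample = rownames(qc$correlation), qc$correlation,
                   missing_frac = qc$missing_frac, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(sprintf("# within-group Pearson r: min=%.6f max=%.6f",
                     qc$r_min, qc$r_max), con)
  invisible(path)
}
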