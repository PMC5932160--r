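# Bait-level normalization and a median-centering surrogate for LFQ.

#' Normalize every protein to the per-sample bait intensity
#'
#' Subtracts the bait's log2 intensity in each sample from every protein
#' in that sample, i.e. re-expresses each prey as the log2 ratio
#' prey/bait.  For a bait that degrades under treatment this is the key
#' device of the analysis: a prey whose absolute level does not fall with
#' the bait appears enriched *relative to the bait* under treatment,
#' while a prey bound at constant stoichiometry (tracking the bait
#' exactly) is normalized to a difference of zero.  The transformation is
#' applied before imputation, so imputed values are drawn in
#' bait-relative coordinates.
#'
#' The bait row itself is kept (its normalized value is exactly 0
#' wherever it was observed); downstream it therefore shows a mock vs
#' treatment difference of exactly 0.
#'
#' @param table a log2-scale [protein_table()] containing the bait row.
#' @param design a [sample_design()] (used to check sample coverage).
#' @param on_missing_bait what to do when the bait was not quantified in
#'   some sample: `"error"` (default) aborts listing those samples;
#'   `"censor"` marks every value in those samples missing, with a
#'   warning.
#' @return A list with `table` (the normalized `protein_table`) and
#'   `state`, a `bait_norm_state` recording the subtracted per-sample
#'   bait log2 intensities (adding them back restores the input exactly).
#' @export
bait_normalize <- function(table, design,
                           on_missing_bait = c("error", "censor")) {
  on_missing_bait <- match.arg(on_missing_bait)
  if (table$scale != "log2") stop("bait_normalize expects a log2 table")
  design_indices(table, design)  # validate coverage
  bi <- which(table$records$is_bait)
  if (length(bi) != 1L) stop("table does not contain a flagged bait row")
  bait_vals <- table$values[bi, ]
  missing_in <- colnames(table$values)[is.na(bait_vals)]
  if (length(missing_in) > 0L) {
    if (on_missing_bait == "error") {
      stop("bait not quantified in sample(s): ",
           paste(missing_in, collapse = ", "))
    }
    warning("bait missing in sample(s) ", paste(missing_in, collapse = ", "),
            "; all values in those samples are censored")
  }
  v <- sweep(table$values, 2L, bait_vals, "-")
  v[, is.na(bait_vals)] <- NA_real_
  state <- structure(list(bait_log2 = bait_vals,
                          censored_samples = missing_in,
                          bait_group_id = table$records$group_id[bi]),
                     class = "bait_norm_state")
  list(table = protein_table(table$records, v, scale = "log2"),
       state = state)
}

#' Undo a bait normalization
#' @param table a bait-normalized log2 [protein_table()].
#' @param state the `bait_norm_state` returned by [bait_normalize()].
#' @return The table on the original log2 coordinates (censored samples
#'   stay missing).
#' @export
bait_denormalize <- function(table, state) {
  v <- sweep(table$values, 2L, state$bait_log2, "+")
  protein_table(table$records, v, scale = "log2")
}

#' Write the bait-normalization state alongside results
#' @param state a `bait_norm_state`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bait_norm_state <- function(state, path) {
  df <- data.frame(sample = names(state$bait_log2),
                   bait_log2 = sprintf("%.10g", state$bait_log2),
                   subtracted = ifelse(is.na(state$bait_log2), "FALSE", "TRUE"),
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
  invisible(path)
}

#' Median-center the sample columns of a log2 table
#'
#' Shifts every sample column so that its median over present values
#' equals the grand median of the per-sample medians.  This is a simple
#' surrogate for between-run LFQ normalization, used by the simulator to
#' produce "LFQ-like" columns for synthetic data; real MaxQuant LFQ
#' columns arrive already normalized and are not re-centered.
#'
#' @param table a log2-scale [protein_table()].
#' @return The centered `protein_table`.
#' @export
median_center <- function(table) {
  if (table$scale != "log2") stop("median_center expects a log2 table")
  v <- table$values
  n_present <- colSums(!is.na(v))
  if (any(n_present == 0L)) {
    stop("sample(s) with no present values: ",
         paste(colnames(v)[n_present == 0L], collapse = ", "))
  }
  med <- apply(v, 2L, stats::median, na.rm = TRUE)
  target <- stats::median(med)
  protein_table(table$records, sweep(v, 2L, med - target, "-"),
                scale = "log2")
}
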