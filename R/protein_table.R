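# Core containers: protein_table and sample_design.

#' Construct a protein-group table
#'
#' The central data structure of the pipeline: one row per protein group,
#' one column per sample.  Missing quantifications are stored as `NA`
#' (a raw-scale zero in a MaxQuant export is read as missing, see
#' [read_protein_groups()]).  A table is either on the `"raw"` intensity
#' scale (all present values strictly positive) or on the `"log2"` scale
#' (all present values finite).
#'
#' @param records data frame with one row per protein group and columns
#'   `group_id` (unique identifier, typically the majority protein IDs),
#'   `gene_label`, `unique_peptides`, and the logical flags `is_reverse`,
#'   `is_contaminant`, `only_by_site`, `is_bait`.  At most one row may be
#'   flagged as the bait.
#' @param values numeric matrix of intensities, `nrow(records)` rows and
#'   one named column per sample; `NA` marks a missing value.
#' @param scale `"raw"` or `"log2"`.
#' @return An object of class `protein_table` with elements `records`,
#'   `values` and `scale`.
#' @seealso [read_protein_groups()], [log2_transform()]
#' @export
protein_table <- function(records, values, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  values <- as.matrix(values)
  storage.mode(values) <- "double"

  required <- c("group_id", "gene_label", "unique_peptides",
                "is_reverse", "is_contaminant", "only_by_site", "is_bait")
  miss <- setdiff(required, names(records))
  if (length(miss) > 0L) {
    stop("records is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(records) != nrow(values)) {
    stop("records and values disagree on the number of protein groups")
  }
  if (is.null(colnames(values)) || anyDuplicated(colnames(values))) {
    stop("values must have unique sample column names")
  }
  dup <- records$group_id[duplicated(records$group_id)]
  if (length(dup) > 0L) {
    stop("duplicate protein group identifier(s): ",
         paste(unique(dup), collapse = ", "))
  }
  for (fl in c("is_reverse", "is_contaminant", "only_by_site", "is_bait")) {
    records[[fl]] <- as.logical(records[[fl]])
    if (anyNA(records[[fl]])) stop("flag column ", fl, " contains NA")
  }
  if (sum(records$is_bait) > 1L) {
    stop("more than one protein group is flagged as the bait")
  }
  present <- values[!is.na(values)]
  if (scale == "raw" && any(present <= 0)) {
    stop("raw-scale intensities must be strictly positive")
  }
  if (scale == "log2" && any(!is.finite(present))) {
    stop("log2-scale intensities must be finite")
  }
  rownames(values) <- records$group_id
  structure(list(records = records, values = values, scale = scale),
            class = "protein_table")
}

#' @export
print.protein_table <- function(x, ...) {
  cat(sprintf("protein_table: %d protein groups x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat(sprintf("  missing cells: %d (%.1f%%)\n", sum(is.na(x$values)),
              100 * mean(is.na(x$values))))
  nflag <- sum(x$records$is_reverse | x$records$is_contaminant |
                 x$records$only_by_site)
  cat(sprintf("  flagged for removal: %d; bait: %s\n", nflag,
              if (any(x$records$is_bait))
                x$records$group_id[x$records$is_bait] else "<none>"))
  invisible(x)
}

#' @export
dim.protein_table <- function(x) dim(x$values)

#' Sample names of a protein table
#' @param table a [protein_table()].
#' @return Character vector of sample column names.
#' @export
sample_names <- function(table) colnames(table$values)

# Subset rows of a protein table, keeping records and values aligned.
subset_rows <- function(table, keep) {
  protein_table(table$records[keep, , drop = FALSE],
                table$values[keep, , drop = FALSE],
                scale = table$scale)
}

#' Describe the two-group sample layout of a qTAP experiment
#'
#' @param sample character vector of sample names, matching the intensity
#'   column suffixes of the proteinGroups table.
#' @param group group membership per sample, `"mock"` or `"treatment"`;
#'   both groups must be non-empty.
#' @param replicate replicate index per sample, unique within each group.
#'   Defaults to 1..n within each group in input order.
#' @param bait_id identifier of the bait protein; matched against the
#'   protein-group `group_id` field (see [read_protein_groups()]).
#' @return An object of class `sample_design`: a list with a `samples`
#'   data frame (`sample`, `group`, `replicate`) and `bait_id`.
#' @examples
#' sample_design(c("mock_r1", "mock_r2", "gr24_r1", "gr24_r2"),
#'               c("mock", "mock", "treatment", "treatment"),
#'               bait_id = "AT2G29970")
#' @export
sample_design <- function(sample, group, replicate = NULL, bait_id = NULL) {
  sample <- as.character(sample)
  group <- as.character(group)
  if (length(sample) != length(group)) {
    stop("sample and group must have the same length")
  }
  if (anyDuplicated(sample)) stop("sample names must be unique")
  bad <- setdiff(unique(group), c("mock", "treatment"))
  if (length(bad) > 0L) {
    stop("group must be 'mock' or 'treatment'; found: ",
         paste(bad, collapse = ", "))
  }
  if (!all(c("mock", "treatment") %in% group)) {
    stop("both a mock and a treatment group are required")
  }
  if (is.null(replicate)) {
    replicate <- stats::ave(seq_along(sample), group, FUN = seq_along)
  }
  replicate <- as.integer(replicate)
  for (g in c("mock", "treatment")) {
    if (anyDuplicated(replicate[group == g])) {
      stop("replicate indices must be unique within the ", g, " group")
    }
  }
  structure(list(samples = data.frame(sample = sample, group = group,
                                      replicate = replicate,
                                      stringsAsFactors = FALSE),
                 bait_id = bait_id),
            class = "sample_design")
}

#' @export
print.sample_design <- function(x, ...) {
  cat(sprintf("sample_design: %d mock + %d treatment samples; bait: %s\n",
              sum(x$samples$group == "mock"),
              sum(x$samples$group == "treatment"),
              if (is.null(x$bait_id)) "<unset>" else x$bait_id))
  invisible(x)
}

# Column indices of the mock / treatment samples within table$values,
# in design order.  Errors if a design sample is absent from the table.
design_indices <- function(table, design) {
  s <- design$samples
  idx <- match(s$sample, colnames(table$values))
  if (anyNA(idx)) {
    stop("design sample(s) not present in the table: ",
         paste(s$sample[is.na(idx)], collapse = ", "))
  }
  list(mock = idx[s$group == "mock"], treatment = idx[s$group == "treatment"])
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
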