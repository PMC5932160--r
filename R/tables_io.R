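# Reading and writing MaxQuant-style proteinGroups tables, sample-design
# files and result tables.  All files are UTF-8, tab-separated, "." decimal.

#' Read a MaxQuant-style proteinGroups table
#'
#' Parses the subset of a `proteinGroups.txt` export that the pipeline
#' needs: protein-group identifiers, gene names, unique-peptide counts,
#' the decoy/contaminant/site flags and one intensity column per design
#' sample.  Cells equal to `0` or empty are marked missing (`NA`): in
#' MaxQuant exports a zero intensity means the protein was not quantified
#' in that sample, not that its abundance was measured as zero.
#'
#' @param path path to the tab-separated file.
#' @param intensity_kind `"lfq"` to read the `"LFQ intensity <sample>"`
#'   columns, `"raw"` to read the `"Intensity <sample>"` columns (used for
#'   the bait-normalized analysis arm).
#' @param design a [sample_design()]; one intensity column per design
#'   sample must be present.
#' @param lfq_prefix,intensity_prefix column-name prefixes, configurable
#'   to absorb dialect drift between MaxQuant versions.
#' @param bait_match `"substring"` (default) flags as bait the single row
#'   whose `group_id` contains `design$bait_id`; protein groups
#'   concatenate accessions, so a substring test is the robust default.
#'   `"exact"` requires `group_id == bait_id`.
#' @param bait_required if `TRUE`, a missing bait row is an error;
#'   otherwise it is only a warning (bait normalization is then
#'   unavailable, but the LFQ-mode analysis still is).
#' @return A raw-scale [protein_table()].
#' @export
read_protein_groups <- function(path, intensity_kind = c("lfq", "raw"),
                                design,
                                lfq_prefix = "LFQ intensity",
                                intensity_prefix = "Intensity",
                                bait_match = c("substring", "exact"),
                                bait_required = FALSE) {
  intensity_kind <- match.arg(intensity_kind)
  bait_match <- match.arg(bait_match)
  raw <- utils::read.delim(path, check.names = FALSE, sep = "\t",
                           quote = "", stringsAsFactors = FALSE,
                           colClasses = "character", fileEncoding = "UTF-8")

  prefix <- if (intensity_kind == "lfq") lfq_prefix else intensity_prefix
  wanted <- paste(prefix, design$samples$sample)
  absent <- setdiff(wanted, names(raw))
  if (length(absent) > 0L) {
    stop("proteinGroups file lacks required column(s): ",
         paste(absent, collapse = ", "))
  }
  id_col <- first_present(raw, c("Majority protein IDs", "Protein IDs"),
                          required = TRUE)
  flag_cols <- c("Reverse", "Potential contaminant", "Only identified by site")
  absent <- setdiff(flag_cols, names(raw))
  if (length(absent) > 0L) {
    stop("proteinGroups file lacks required column(s): ",
         paste(absent, collapse = ", "))
  }

  group_id <- raw[[id_col]]
  if (anyDuplicated(group_id)) {
    stop("duplicate protein group identifier(s) in ", path, ": ",
         paste(unique(group_id[duplicated(group_id)]), collapse = ", "))
  }

  gene_col <- first_present(raw, c("Gene names", "Gene name"))
  pep_col <- first_present(raw, c("Unique peptides", "Razor + unique peptides"))

  is_bait <- rep(FALSE, nrow(raw))
  if (!is.null(design$bait_id)) {
    hit <- if (bait_match == "substring") {
      grepl(design$bait_id, group_id, fixed = TRUE)
    } else {
      group_id == design$bait_id
    }
    if (sum(hit) > 1L) {
      stop("bait id '", design$bait_id, "' matches ", sum(hit),
           " protein groups; use bait_match = \"exact\" or a longer id")
    }
    if (sum(hit) == 0L) {
      msg <- paste0("bait id '", design$bait_id, "' not found in ", path)
      if (bait_required) stop(msg) else warning(msg)
    }
    is_bait <- hit
  }

  records <- data.frame(
    group_id = group_id,
    gene_label = if (is.null(gene_col)) group_id else raw[[gene_col]],
    unique_peptides = if (is.null(pep_col)) NA_integer_
                      else suppressWarnings(as.integer(raw[[pep_col]])),
    is_reverse = raw[["Reverse"]] == "+",
    is_contaminant = raw[["Potential contaminant"]] == "+",
    only_by_site = raw[["Only identified by site"]] == "+",
    is_bait = is_bait,
    stringsAsFactors = FALSE
  )

  values <- vapply(wanted, function(cn) {
    v <- raw[[cn]]
    v[v == "" | is.na(v)] <- NA_character_
    suppressWarnings(as.numeric(v))
  }, numeric(nrow(raw)))
  values <- matrix(values, nrow = nrow(raw),
                   dimnames = list(NULL, design$samples$sample))
  values[!is.na(values) & values == 0] <- NA_real_

  protein_table(records, values, scale = "raw")
}

first_present <- function(df, candidates, required = FALSE) {
  hit <- candidates[candidates %in% names(df)]
  if (length(hit) == 0L) {
    if (required) stop("proteinGroups file lacks required column(s): ",
                       candidates[1L])
    return(NULL)
  }
  hit[1L]
}

#' Read a sample-design file
#'
#' Expects a tab-separated file with a header line and the columns
#' `sample`, `group` (`mock`/`treatment`) and `replicate`.
#'
#' @param path path to the design file.
#' @param bait_id bait protein identifier (a config key, not a file
#'   column); may be `NULL` for analyses without bait normalization.
#' @return A [sample_design()].
#' @export
read_sample_design <- function(path, bait_id = NULL) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  need <- c("sample", "group", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("design file lacks column(s): ", paste(miss, collapse = ", "))
  }
  sample_design(df$sample, df$group, df$replicate, bait_id = bait_id)
}

#' Write a protein table in the proteinGroups dialect
#'
#' Emits a tab-separated file that [read_protein_groups()] round-trips
#' exactly: numeric intensities are printed with 17 significant digits so
#' that re-parsing restores the identical doubles, and missing cells are
#' written as `0` (the MaxQuant convention).
#'
#' @param table a raw-scale [protein_table()]; its values populate the
#'   `"Intensity <sample>"` columns.
#' @param path output path.
#' @param lfq_values optional matrix of the same shape holding raw-scale
#'   normalized intensities for the `"LFQ intensity <sample>"` columns;
#'   defaults to `table$values`.
#' @return `path`, invisibly.
#' @export
write_protein_groups <- function(table, path, lfq_values = NULL) {
  if (table$scale != "raw") stop("write_protein_groups expects a raw-scale table")
  if (is.null(lfq_values)) lfq_values <- table$values
  if (!identical(dim(lfq_values), dim(table$values))) {
    stop("lfq_values must match the shape of table$values")
  }
  r <- table$records
  samples <- colnames(table$values)
  out <- data.frame(
    `Majority protein IDs` = r$group_id,
    `Gene names` = r$gene_label,
    `Unique peptides` = r$unique_peptides,
    Reverse = ifelse(r$is_reverse, "+", ""),
    `Potential contaminant` = ifelse(r$is_contaminant, "+", ""),
    `Only identified by site` = ifelse(r$only_by_site, "+", ""),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  for (s in samples) {
    out[[paste("LFQ intensity", s)]] <- fmt_intensity(lfq_values[, s])
  }
  for (s in samples) {
    out[[paste("Intensity", s)]] <- fmt_intensity(table$values[, s])
  }
  write_tsv(out, path)
  invisible(path)
}

fmt_intensity <- function(v) {
  out <- sprintf("%.17g", v)
  out[is.na(v)] <- "0"
  out
}

#' Write a sample design file
#' @param design a [sample_design()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_design <- function(design, path) {
  write_tsv(design$samples, path)
  invisible(path)
}

#' Write a differential-test result table
#'
#' Tab-separated, one row per protein group, ordered by descending
#' absolute log2 difference with ties broken by ascending p-value.
#'
#' @param results data frame as returned in `$results` by [diff_test()]
#'   or [analyze_table()]; must contain `group_id`, `gene_label`,
#'   `mean_mock`, `mean_treatment`, `difference`, `t_statistic`,
#'   `p_value`, `neg_log10_p` and `significant`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(results, path) {
  if (nrow(results) == 0L) stop("results table is empty")
  cols <- c("group_id", "gene_label", "mean_mock", "mean_treatment",
            "difference", "t_statistic", "p_value", "neg_log10_p",
            "significant")
  miss <- setdiff(cols, names(results))
  if (length(miss) > 0L) {
    stop("results is missing column(s): ", paste(miss, collapse = ", "))
  }
  ord <- order(-abs(results$difference), results$p_value)
  out <- results[ord, cols]
  for (cn in c("mean_mock", "mean_treatment", "difference", "t_statistic",
               "p_value", "neg_log10_p")) {
    out[[cn]] <- sprintf("%.10g", out[[cn]])
  }
  out$significant <- ifelse(results$significant[ord], "TRUE", "FALSE")
  write_tsv(out, path)
  invisible(path)
}

write_tsv <- function(df, path) {
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE,
                       fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write ", path, ": ", conditionMessage(ok))
  invisible(path)
}
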