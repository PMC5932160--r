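# End-to-end orchestration: configuration, the analysis chain applied to
# a table in memory, and the file-in/file-out runner with its artifacts.

#' Pipeline configuration
#'
#' Bundles every tunable of the analysis.  Defaults are the standard
#' qTAP settings: a full group of 4 replicates required by the
#' valid-value filter, FDR level 0.05, S0 = 0.1, Perseus-style
#' imputation (downshift 1.8, width 0.3).
#'
#' @param protein_groups path to a proteinGroups-style file (or `NULL`
#'   when simulating).
#' @param design path to a sample-design file, or a [sample_design()].
#' @param bait_id bait identifier (required for the intensity arm).
#' @param sim a [sim_config()] to run on simulated data instead of files.
#' @param mode `"both"` runs the two analysis arms of a qTAP study:
#'   `"lfq"` (LFQ intensities, no bait normalization) and `"intensity"`
#'   (raw intensities, bait-normalized).
#' @param min_valid see [filter_valid_values()].
#' @param impute an [impute_params()].
#' @param fdr an [fdr_params()].
#' @param bait_match,bait_required,on_missing_bait see
#'   [read_protein_groups()] and [bait_normalize()].
#' @param lfq_prefix,intensity_prefix intensity column prefixes.
#' @param out_dir output directory for [run_pipeline()] artifacts.
#' @param seed top-level seed; fills in the imputation / permutation /
#'   simulation seeds unless those were set explicitly.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(protein_groups = NULL, design = NULL,
                            bait_id = NULL, sim = NULL,
                            mode = c("both", "lfq", "intensity"),
                            min_valid = 4L,
                            impute = impute_params(),
                            fdr = fdr_params(),
                            bait_match = "substring",
                            bait_required = FALSE,
                            on_missing_bait = "error",
                            lfq_prefix = "LFQ intensity",
                            intensity_prefix = "Intensity",
                            out_dir = "qtap_run", seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) {
    impute$seed <- as.integer(seed)
    fdr$seed <- as.integer(seed)
    if (!is.null(sim)) sim$seed <- as.integer(seed)
  }
  structure(list(protein_groups = protein_groups, design = design,
                 bait_id = bait_id, sim = sim, mode = mode,
                 min_valid = as.integer(min_valid), impute = impute,
                 fdr = fdr, bait_match = bait_match,
                 bait_required = bait_required,
                 on_missing_bait = on_missing_bait,
                 lfq_prefix = lfq_prefix,
                 intensity_prefix = intensity_prefix,
                 out_dir = out_dir, seed = seed),
            class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Returns machine-readable findings instead of raising errors, so a
#' front end can show everything at once.
#'
#' @param config a [pipeline_config()].
#' @param replicates known replicates per group (e.g. `c(4, 4)`), used
#'   for checks that need the design size; taken from `config$sim` or a
#'   `sample_design` object when available.
#' @return Data frame with columns `level` (`"error"`/`"warning"`),
#'   `field`, `message`; zero rows when the configuration is clean.
#' @export
validate_config <- function(config, replicates = NULL) {
  findings <- data.frame(level = character(0), field = character(0),
                         message = character(0), stringsAsFactors = FALSE)
  add <- function(level, field, message) {
    findings[nrow(findings) + 1L, ] <<- list(level, field, message)
  }

  if (is.null(config$sim) && is.null(config$protein_groups)) {
    add("error", "input", "neither an input file nor a simulation is configured")
  }
  if (is.null(replicates)) {
    if (!is.null(config$sim)) {
      replicates <- rep(config$sim$replicates, 2L)
    } else if (inherits(config$design, "sample_design")) {
      replicates <- as.integer(table(config$design$samples$group))
    }
  }
  if (config$min_valid < 1L) {
    add("error", "min_valid", "min_valid must be >= 1")
  }
  if (!is.null(replicates) && config$min_valid > max(replicates)) {
    add("error", "min_valid",
        sprintf("min_valid (%d) exceeds both group sizes (%s)",
                config$min_valid, paste(replicates, collapse = " vs ")))
  }
  if (config$fdr$alpha <= 0 || config$fdr$alpha >= 1) {
    add("error", "fdr.alpha", "alpha must be in (0, 1)")
  }
  if (config$fdr$s0 < 0) {
    add("error", "fdr.s0", "s0 must be >= 0")
  }
  if (config$fdr$s0 == 0) {
    add("warning", "fdr.s0",
        "s0 = 0: zero-variance rows give undefined statistics")
  }
  if (!is.null(replicates) && identical(config$fdr$n_perm, "exhaustive")) {
    total <- choose(sum(replicates), replicates[1L])
    if (total > config$fdr$exhaustive_cap) {
      add("warning", "fdr.n_perm",
          sprintf("exhaustive enumeration infeasible: %.0f assignments exceed the cap (%d)",
                  total, config$fdr$exhaustive_cap))
    }
  }
  if (config$mode != "lfq" && is.null(config$bait_id) &&
      is.null(config$sim)) {
    add("error", "bait_id",
        "the intensity arm needs a bait_id for bait normalization")
  }
  if (config$impute$width <= 0) {
    add("error", "impute.width", "imputation width must be > 0")
  }
  findings
}

#' Run the analysis chain on an in-memory table
#'
#' Applies, in order: flagged-row removal, log2 transform, bait
#' normalization (intensity mode only), the valid-value filter,
#' replicate QC, left-censored imputation, the S0-moderated test and the
#' permutation FDR.
#'
#' @param table a raw-scale [protein_table()].
#' @param design a [sample_design()].
#' @param mode `"lfq"` (no bait normalization) or `"intensity"`
#'   (bait-normalized).
#' @param min_valid see [filter_valid_values()].
#' @param impute an [impute_params()].
#' @param fdr an [fdr_params()].
#' @param on_missing_bait see [bait_normalize()].
#' @param qc set `FALSE` to skip replicate QC.
#' @return A list of class `qtap_analysis`: `results` (see
#'   [diff_test()]), `volcano`, `qc`, `imputation`, `fdr`, `bait_norm`
#'   (state or `NULL`), `table` (the final complete log2 table), `mode`
#'   and `n_rows` (row counts per stage).
#' @export
analyze_table <- function(table, design, mode = c("lfq", "intensity"),
                          min_valid = 4L, impute = impute_params(),
                          fdr = fdr_params(),
                          on_missing_bait = "error", qc = TRUE) {
  mode <- match.arg(mode)
  n_rows <- c(input = nrow(table$values))

  t1 <- filter_flagged_rows(table)
  n_rows["flag_filter"] <- nrow(t1$values)
  t2 <- log2_transform(t1)

  state <- NULL
  if (mode == "intensity") {
    bn <- bait_normalize(t2, design, on_missing_bait = on_missing_bait)
    t2 <- bn$table
    state <- bn$state
  }

  t3 <- filter_valid_values(t2, design, min_valid = min_valid)
  n_rows["valid_filter"] <- nrow(t3$values)

  qc_report <- if (qc) replicate_qc(t3, design) else NULL
  imp <- impute_missing(t3, impute)
  dt <- diff_test(imp$table, design, fdr)

  structure(list(results = dt$results, volcano = volcano_table(dt$results),
                 qc = qc_report, imputation = imp$record, fdr = dt$fdr,
                 bait_norm = state, table = imp$table, mode = mode,
                 n_rows = n_rows),
            class = "qtap_analysis")
}

#' @export
print.qtap_analysis <- function(x, ...) {
  cat(sprintf("qtap_analysis (%s mode): %d -> %d -> %d rows; %d significant\n",
              x$mode, x$n_rows["input"], x$n_rows["flag_filter"],
              x$n_rows["valid_filter"], sum(x$results$significant)))
  invisible(x)
}

#' Run the full pipeline and write its artifacts
#'
#' Reads (or simulates) the input, runs the configured analysis arm(s)
#' and writes, per arm: the results table, the volcano plot (PNG), the
#' QC report, the imputation record and (intensity arm) the
#' bait-normalization state; plus the resolved configuration as JSON.
#' If any stage fails, an `INCOMPLETE` marker naming the stage is left
#' in the output directory and the error is re-raised.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with one `qtap_analysis` per arm, the
#'   output directory and the artifact paths.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  findings <- validate_config(config)
  if (any(findings$level == "error")) {
    stop("invalid configuration:\n  ",
         paste(findings$message[findings$level == "error"],
               collapse = "\n  "))
  }
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "setup"
  on_fail <- function(e) {
    writeLines(c(paste("failed at stage:", stage), conditionMessage(e)),
               file.path(out_dir, "INCOMPLETE"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  incomplete <- file.path(out_dir, "INCOMPLETE")
  if (file.exists(incomplete)) unlink(incomplete)

  arms <- if (config$mode == "both") c("lfq", "intensity") else config$mode
  artifacts <- character(0)
  analyses <- list()

  tryCatch({
    stage <- "input"
    if (!is.null(config$sim)) {
      sim <- simulate_apms(config$sim)
      design <- sim$design
      tables <- list(lfq = sim$lfq, intensity = sim$intensity)
      write_protein_groups(sim$intensity,
                           file.path(out_dir, "proteinGroups_synthetic.txt"),
                           lfq_values = sim$lfq$values)
      write_sample_design(design, file.path(out_dir, "design.tsv"))
      write_tsv(sim$truth, file.path(out_dir, "truth.tsv"))
      artifacts <- c(artifacts, "proteinGroups_synthetic.txt", "design.tsv",
                     "truth.tsv")
    } else {
      design <- if (inherits(config$design, "sample_design")) config$design
                else read_sample_design(config$design, bait_id = config$bait_id)
      if (!is.null(config$bait_id)) design$bait_id <- config$bait_id
      tables <- list()
      for (arm in arms) {
        tables[[arm]] <- read_protein_groups(
          config$protein_groups,
          intensity_kind = if (arm == "lfq") "lfq" else "raw",
          design = design, lfq_prefix = config$lfq_prefix,
          intensity_prefix = config$intensity_prefix,
          bait_match = config$bait_match,
          bait_required = config$bait_required || arm == "intensity")
      }
    }

    for (arm in arms) {
      stage <- paste0("analyze_", arm)
      message(sprintf("[%s] %d protein groups in", arm,
                      nrow(tables[[arm]]$values)))
      an <- analyze_table(tables[[arm]], design, mode = arm,
                          min_valid = config$min_valid,
                          impute = config$impute, fdr = config$fdr,
                          on_missing_bait = config$on_missing_bait)
      message(sprintf("[%s] %d after filters, %d significant", arm,
                      an$n_rows["valid_filter"], sum(an$results$significant)))
      analyses[[arm]] <- an

      stage <- paste0("write_", arm)
      write_results_table(an$results,
                          file.path(out_dir, paste0("results_", arm, ".tsv")))
      write_qc_report(an$qc, file.path(out_dir, paste0("qc_", arm, ".tsv")))
      write_imputation_record(
        an$imputation, file.path(out_dir, paste0("imputation_", arm, ".tsv")))
      grDevices::png(file.path(out_dir, paste0("volcano_", arm, ".png")),
                     width = 900, height = 700)
      plot_volcano(an$results, main = paste("qTAP volcano –", arm, "mode"))
      grDevices::dev.off()
      artifacts <- c(artifacts, paste0("results_", arm, ".tsv"),
                     paste0("qc_", arm, ".tsv"),
                     paste0("imputation_", arm, ".tsv"),
                     paste0("volcano_", arm, ".png"))
      if (!is.null(an$bait_norm)) {
        write_bait_norm_state(an$bait_norm,
                              file.path(out_dir, "bait_norm_state.tsv"))
        artifacts <- c(artifacts, "bait_norm_state.tsv")
      }
    }

    stage <- "write_config"
    cfg_out <- config
    cfg_out$design <- if (inherits(config$design, "sample_design"))
      config$design$samples else config$design
    jsonlite::write_json(unclass_deep(cfg_out),
                         file.path(out_dir, "config_resolved.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
    artifacts <- c(artifacts, "config_resolved.json")
  }, error = on_fail)

  invisible(list(analyses = analyses, out_dir = out_dir,
                 artifacts = file.path(out_dir, artifacts)))
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, unclass_deep)
  } else {
    x
  }
}
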