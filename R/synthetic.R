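# Ground-truthed AP-MS simulator: a degrading bait pulled down in mock
# vs treatment with replicate structure, log-normal abundances,
# replicate noise and intensity-dependent left-censored missingness.

#' Simulation configuration
#'
#' The generator emulates a two-condition qTAP pulldown of a bait that
#' is degraded under treatment.  Protein classes and their true log2
#' levels (mock, treatment), with `u` the protein's base level, `d` the
#' bait drop, `e` the interaction effect and `eta_s` a per-sample bait
#' fluctuation shared by every bait-bound prey:
#'
#' * `bait`:          `u + eta_s`  /  `u - d + eta_s`
#' * `background`:    `u` / `u` — stable bead binders, independent of the
#'   bait
#' * `constitutive`:  `u + eta_s` / `u + eta_s` — constitutively bound
#'   preys whose capture is prey-limited (the overexpressed bait stays in
#'   excess even after degradation), so their absolute level does not
#'   follow the bait's drop, only its replicate-to-replicate fluctuation
#' * `machinery`:     `u + eta_s` / `u + d*coupling + eta_s` —
#'   degradation machinery recruited as the bait is turned over
#'   (26S-proteasome-like), enriched under treatment
#' * `recruited`:     `u - e` / `u + eta_s` — treatment-recruited
#'   receptor-like preys; choose `e` large enough to push `u - e` below
#'   the detection floor to model a prey seen only under treatment
#' * `released`:      `u + eta_s` / `u - e` — preys released from the
#'   complex upon treatment (corepressor-like)
#'
#' Decoy and contaminant rows are background-like with the corresponding
#' flag set.  Observed values add Normal(0, noise_sd^2) replicate noise;
#' a value `x` is recorded missing with probability
#' `plogis(missing_slope * (detection_limit - x))`, and always when `x`
#' falls below `detection_limit - 2` (a hard floor).  Two classes are
#' exempt from unrestricted draws: interactor classes (constitutive,
#' machinery, recruited, released) have their base level floored at
#' `detection_limit + 3` — a prey below the detection limit in its bound
#' state would be unobservable and is not a meaningful planted effect —
#' and the bait, being the anchor of the purification, is never censored.
#'
#' @param n_background,n_constitutive,n_recruited,n_released,n_machinery
#'   class sizes; defaults give ~300 protein groups, the scale of a
#'   typical qTAP experiment.
#' @param n_decoy,n_contaminant counts of flagged rows.
#' @param replicates replicates per condition (default 4).
#' @param base_mean,base_sd log2 mean and sd of the per-protein base
#'   levels (log-normal raw abundances).
#' @param bait_mean log2 base level of the (overexpressed) bait.
#' @param bait_drop log2 units the bait loses under treatment (>= 0).
#' @param effect log2 effect size of recruited/released preys (>= 0).
#' @param noise_sd replicate noise sd on the log2 scale (> 0).
#' @param bait_noise_sd sd of the shared per-sample bait fluctuation
#'   `eta_s` inherited by bait-bound preys.
#' @param machinery_coupling multiplier linking machinery enrichment to
#'   the bait drop (default 1).
#' @param detection_limit log2 detection limit for the missingness model.
#' @param missing_slope steepness of the logistic censoring probability.
#' @param missingness set `FALSE` to disable censoring entirely.
#' @param bait_id accession used for the bait protein group (substring-
#'   matchable by the reader).
#' @param seed integer seed; the generator is deterministic given the
#'   seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_background = 280, n_constitutive = 5,
                       n_recruited = 2, n_released = 1, n_machinery = 10,
                       n_decoy = 5, n_contaminant = 5,
                       replicates = 4,
                       base_mean = 25, base_sd = 2, bait_mean = 28,
                       bait_drop = 1.5, effect = 2,
                       noise_sd = 0.3, bait_noise_sd = 0.3,
                       machinery_coupling = 1,
                       detection_limit = 20, missing_slope = 2,
                       missingness = TRUE,
                       bait_id = "AT2G29970", seed = 1L) {
  cfg <- list(n_background = n_background, n_constitutive = n_constitutive,
              n_recruited = n_recruited, n_released = n_released,
              n_machinery = n_machinery, n_decoy = n_decoy,
              n_contaminant = n_contaminant, replicates = as.integer(replicates),
              base_mean = base_mean, base_sd = base_sd, bait_mean = bait_mean,
              bait_drop = bait_drop, effect = effect, noise_sd = noise_sd,
              bait_noise_sd = bait_noise_sd,
              machinery_coupling = machinery_coupling,
              detection_limit = detection_limit,
              missing_slope = missing_slope, missingness = missingness,
              bait_id = bait_id, seed = as.integer(seed))
  counts <- unlist(cfg[grep("^n_", names(cfg))])
  if (any(counts < 0)) stop("class counts must be >= 0")
  if (cfg$replicates < 2L) stop("at least 2 replicates per condition")
  if (cfg$noise_sd <= 0) stop("noise_sd must be > 0")
  if (cfg$bait_noise_sd < 0) stop("bait_noise_sd must be >= 0")
  if (cfg$bait_drop < 0) stop("bait_drop must be >= 0 (class semantics fix the direction)")
  if (cfg$effect < 0) stop("effect must be >= 0 (class semantics fix the direction)")
  structure(cfg, class = "sim_config")
}

#' Simulate a qTAP AP-MS experiment with known ground truth
#'
#' See [sim_config()] for the generative model.  Two tables are
#' returned, built from the same underlying detections: `intensity`
#' (raw, un-normalized — the input of the bait-normalized analysis arm)
#' and `lfq` (the same values after per-sample median centering on the
#' log2 scale, a surrogate for between-run LFQ normalization of real
#' data).
#'
#' @param config a [sim_config()].
#' @return A list with `intensity` and `lfq` (raw-scale
#'   [protein_table()]s), `truth` (data frame: `group_id`, `class`,
#'   `effect` — the true mock-minus-treatment log2 difference on the
#'   absolute scale — and `effect_bait_relative`, the same after bait
#'   normalization), `design` (a [sample_design()]) and `config`.
#' @export
simulate_apms <- function(config = sim_config()) {
  cfg <- config
  reps <- cfg$replicates
  samples <- c(sprintf("mock_r%d", seq_len(reps)),
               sprintf("treat_r%d", seq_len(reps)))
  treat <- rep(c(0, 1), each = reps)
  design <- sample_design(samples,
                          rep(c("mock", "treatment"), each = reps),
                          bait_id = cfg$bait_id)

  classes <- c("bait",
               rep("background", cfg$n_background),
               rep("constitutive", cfg$n_constitutive),
               rep("recruited", cfg$n_recruited),
               rep("released", cfg$n_released),
               rep("machinery", cfg$n_machinery),
               rep("decoy", cfg$n_decoy),
               rep("contaminant", cfg$n_contaminant))
  nr <- length(classes)
  ns <- length(samples)

  out <- with_seed(cfg$seed, {
    u <- stats::rnorm(nr, cfg$base_mean, cfg$base_sd)
    u[1L] <- cfg$bait_mean
    # interactor classes are drawn detectable in their bound state: a prey
    # below the detection limit in both conditions is not an observable
    # interactor, so their base level is floored 3 log2 units above it
    planted <- classes %in% c("constitutive", "recruited", "released",
                              "machinery")
    u[planted] <- pmax(u[planted], cfg$detection_limit + 3)
    eta <- stats::rnorm(ns, 0, cfg$bait_noise_sd)

    level <- matrix(NA_real_, nr, ns)
    for (j in seq_len(ns)) {
      tj <- treat[j]
      level[, j] <- switch_levels(classes, u, eta[j], tj, cfg)
    }
    x <- level + matrix(stats::rnorm(nr * ns, 0, cfg$noise_sd), nr, ns)

    miss <- matrix(FALSE, nr, ns)
    if (cfg$missingness) {
      p_miss <- stats::plogis(cfg$missing_slope * (cfg$detection_limit - x))
      miss <- matrix(stats::runif(nr * ns) < p_miss, nr, ns)
      miss[x < cfg$detection_limit - 2] <- TRUE
      # the bait anchors the purification and is identified in every run
      miss[1L, ] <- FALSE
    }
    list(x = x, miss = miss)
  })
  x <- out$x
  miss <- out$miss

  ids <- sim_group_ids(classes, cfg$bait_id)
  records <- data.frame(
    group_id = ids$group_id,
    gene_label = ids$gene_label,
    unique_peptides = pmax(1L, as.integer(round((x[, 1L] - 15) / 2))),
    is_reverse = classes == "decoy",
    is_contaminant = classes == "contaminant",
    only_by_site = FALSE,
    is_bait = classes == "bait",
    stringsAsFactors = FALSE
  )

  raw <- 2^x
  raw[miss] <- NA_real_
  colnames(raw) <- samples
  intensity <- protein_table(records, raw, scale = "raw")

  lfq_log2 <- median_center(log2_transform(intensity))
  lfq <- protein_table(records, 2^lfq_log2$values, scale = "raw")

  effect <- effect_of(classes, cfg)
  truth <- data.frame(group_id = records$group_id, class = classes,
                      effect = effect,
                      effect_bait_relative = effect - cfg$bait_drop,
                      stringsAsFactors = FALSE)

  list(intensity = intensity, lfq = lfq, truth = truth,
       design = design, config = cfg)
}

# true log2 level of every row in one sample
switch_levels <- function(classes, u, eta_j, treated, cfg) {
  lev <- u  # background / decoy / contaminant: flat
  b <- classes == "bait"
  lev[b] <- u[b] + eta_j - cfg$bait_drop * treated
  k <- classes == "constitutive"
  lev[k] <- u[k] + eta_j
  k <- classes == "machinery"
  lev[k] <- u[k] + eta_j + cfg$bait_drop * cfg$machinery_coupling * treated
  k <- classes == "recruited"
  lev[k] <- if (treated) u[k] + eta_j else u[k] - cfg$effect
  k <- classes == "released"
  lev[k] <- if (treated) u[k] - cfg$effect else u[k] + eta_j
  lev
}

# planted mock - treatment log2 difference on the absolute scale
effect_of <- function(classes, cfg) {
  eff <- numeric(length(classes))
  eff[classes == "bait"] <- cfg$bait_drop
  eff[classes == "machinery"] <- -cfg$bait_drop * cfg$machinery_coupling
  eff[classes == "recruited"] <- -cfg$effect
  eff[classes == "released"] <- cfg$effect
  eff
}

sim_group_ids <- function(classes, bait_id) {
  n <- length(classes)
  idx <- stats::ave(seq_len(n), classes, FUN = seq_along)
  group_id <- sprintf("AT%dG%05d.1", (seq_len(n) %% 5) + 1L, 10L * seq_len(n))
  gene_label <- toupper(paste0(substr(classes, 1L, 4L),
                               sprintf("%03d", idx)))
  b <- classes == "bait"
  group_id[b] <- paste0(bait_id, ".1;", bait_id, ".2")
  gene_label[b] <- "SMXL7"
  group_id[classes == "decoy"] <- paste0("REV__", group_id[classes == "decoy"])
  group_id[classes == "contaminant"] <-
    paste0("CON__", group_id[classes == "contaminant"])
  list(group_id = group_id, gene_label = gene_label)
}

#' Evaluate significance calls against the simulation ground truth
#'
#' @param flags named logical vector of significance calls; its names
#'   must cover exactly the `group_id`s in `truth` (rows dropped by the
#'   filters should be entered as `FALSE`).
#' @param truth the `truth` data frame from [simulate_apms()].
#' @param relative_to_bait if `TRUE`, a "true effect" means a non-zero
#'   planted difference on the bait-relative scale (appropriate for the
#'   bait-normalized analysis arm); default uses the absolute scale.
#' @return A list with `sensitivity` (flagged true-effect rows over all
#'   true-effect rows; `NA` if there are none) and `fdp` (flagged
#'   zero-effect rows over `max(1, total flagged)`).
#' @export
truth_eval <- function(flags, truth, relative_to_bait = FALSE) {
  if (is.null(names(flags)) ||
      !setequal(names(flags), truth$group_id) ||
      length(flags) != nrow(truth)) {
    stop("flags must be named by group_id and cover exactly the truth rows")
  }
  flags <- flags[truth$group_id]
  eff <- if (relative_to_bait) truth$effect_bait_relative else truth$effect
  is_effect <- eff != 0
  sens <- if (any(is_effect)) sum(flags & is_effect) / sum(is_effect)
          else NA_real_
  fdp <- sum(flags & !is_effect) / max(1, sum(flags))
  list(sensitivity = sens, fdp = fdp)
}

#' Expand per-row significance calls to the full truth row set
#'
#' Convenience for [truth_eval()]: rows removed by the filters count as
#' not significant.
#'
#' @param results results data frame from [analyze_table()]/[diff_test()].
#' @param truth the `truth` data frame from [simulate_apms()].
#' @return Named logical vector over all truth rows.
#' @export
flags_from_results <- function(results, truth) {
  flags <- stats::setNames(rep(FALSE, nrow(truth)), truth$group_id)
  hit <- intersect(results$group_id, truth$group_id)
  flags[hit] <- results$significant[match(hit, results$group_id)]
  flags
}
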