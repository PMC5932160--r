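# Shared fixtures and independent oracles for the test suite.

make_design <- function(n_mock = 4, n_treat = 4, bait_id = "AT2G29970") {
  sample_design(c(sprintf("mock_r%d", seq_len(n_mock)),
                  sprintf("treat_r%d", seq_len(n_treat))),
                rep(c("mock", "treatment"), c(n_mock, n_treat)),
                bait_id = bait_id)
}

# protein_table from a bare matrix, with optional flags
make_table <- function(values, scale = "log2", bait_row = NA,
                       reverse_rows = integer(0), contam_rows = integer(0),
                       site_rows = integer(0)) {
  n <- nrow(values)
  if (is.null(colnames(values))) {
    colnames(values) <- c(sprintf("mock_r%d", seq_len(ncol(values) / 2)),
                          sprintf("treat_r%d", seq_len(ncol(values) / 2)))
  }
  rec <- data.frame(group_id = sprintf("AT1G%05d.1", 10L * seq_len(n)),
                    gene_label = sprintf("G%03d", seq_len(n)),
                    unique_peptides = 2L, is_reverse = FALSE,
                    is_contaminant = FALSE, only_by_site = FALSE,
                    is_bait = FALSE, stringsAsFactors = FALSE)
  rec$is_reverse[reverse_rows] <- TRUE
  rec$is_contaminant[contam_rows] <- TRUE
  rec$only_by_site[site_rows] <- TRUE
  if (!is.na(bait_row)) {
    rec$is_bait[bait_row] <- TRUE
    rec$group_id[bait_row] <- "AT2G29970.1"
  }
  protein_table(rec, values, scale = scale)
}

subset_rows_for_test <- function(table, keep) {
  protein_table(table$records[keep, , drop = FALSE],
                table$values[keep, , drop = FALSE], scale = table$scale)
}

fixture_path <- function(file) {
  system.file("extdata", file, package = "qtapdiff", mustWork = TRUE)
}

# ---- independent oracles -------------------------------------------------

# textbook two-sample p-value via stats::t.test (never used in R/)
oracle_student_p <- function(x, y, pooled = TRUE) {
  stats::t.test(x, y, var.equal = pooled)$p.value
}

# Brute-force permutation FDR: plain loops, scalar mean()/sd(), its own
# enumeration of label assignments and its own FDR curve.  Mirrors the
# documented estimator definition, independently of the implementation.
oracle_perm_fdr <- function(mat, n1, s0, alpha) {
  n <- ncol(mat)
  stat_for <- function(g1) {
    g2 <- setdiff(seq_len(n), g1)
    out <- numeric(nrow(mat))
    for (i in seq_len(nrow(mat))) {
      x <- mat[i, g1]; y <- mat[i, g2]
      sp <- sqrt(((length(x) - 1) * stats::sd(x)^2 +
                    (length(y) - 1) * stats::sd(y)^2) /
                   (length(x) + length(y) - 2))
      se <- sp * sqrt(1 / length(x) + 1 / length(y))
      out[i] <- (mean(x) - mean(y)) / (se + s0)
    }
    out
  }
  obs <- stat_for(seq_len(n1))
  combos <- utils::combn(n, n1)
  null_stats <- list()
  for (k in seq_len(ncol(combos))) {
    if (identical(combos[, k], seq_len(n1))) next
    null_stats[[length(null_stats) + 1L]] <- abs(stat_for(combos[, k]))
  }
  cands <- sort(unique(abs(obs)))
  fdr_raw <- numeric(length(cands))
  n_obs <- integer(length(cands))
  for (j in seq_along(cands)) {
    c0 <- cands[j]
    n_obs[j] <- sum(abs(obs) >= c0)
    exceed <- vapply(null_stats, function(v) sum(v >= c0), numeric(1))
    fdr_raw[j] <- min(1, mean(exceed) / max(1, n_obs[j]))
  }
  fdr <- fdr_raw
  for (j in rev(seq_along(fdr))[-1L]) fdr[j] <- max(fdr[j], fdr[j + 1L])
  qualifying <- cands[fdr <= alpha]
  threshold <- if (length(qualifying)) min(qualifying) else Inf
  list(d_star = obs, cands = cands, fdr = fdr, threshold = threshold,
       significant = abs(obs) >= threshold,
       n_assignments = length(null_stats))
}
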