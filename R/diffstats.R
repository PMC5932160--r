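# S0-moderated two-group testing with permutation-based FDR.
#
# The moderated statistic is d* = D / (s + s0): the ordinary two-sample
# difference-over-standard-error, with a constant s0 added to the
# denominator so that rows with tiny variance cannot reach significance
# on a biologically negligible difference.  Significance is decided by a
# threshold on |d*| chosen from a label-permutation null so that the
# estimated FDR stays below the requested level.

#' FDR / test parameters
#'
#' @param s0 non-negative moderation constant added to the standard
#'   error in the denominator of the test statistic (default 0.1).
#' @param alpha target false discovery rate in (0, 1) (default 0.05).
#' @param n_perm number of label permutations when exhaustive
#'   enumeration is infeasible (default 250), or `"exhaustive"` to force
#'   enumeration (only permitted when the number of distinct label
#'   assignments is at most `exhaustive_cap`).
#' @param seed integer seed for permutation sampling (unused when the
#'   null is exhaustive).
#' @param test_variant `"pooled_student"` (equal-variance two-sample
#'   test, the default) or `"welch"`.
#' @param exhaustive_cap assignment count up to which the null is
#'   enumerated exhaustively rather than sampled (default 10000).  A
#'   4 vs 4 design has choose(8, 4) = 70 assignments, so full
#'   enumeration is the default behaviour at that scale.
#' @return A list of class `fdr_params`.
#' @export
fdr_params <- function(s0 = 0.1, alpha = 0.05, n_perm = 250, seed = 1L,
                       test_variant = c("pooled_student", "welch"),
                       exhaustive_cap = 10000) {
  test_variant <- match.arg(test_variant)
  if (s0 < 0) stop("s0 must be >= 0")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (!identical(n_perm, "exhaustive")) {
    n_perm <- as.integer(n_perm)
    if (n_perm < 1L) stop("n_perm must be >= 1 or \"exhaustive\"")
  }
  structure(list(s0 = s0, alpha = alpha, n_perm = n_perm,
                 seed = as.integer(seed), test_variant = test_variant,
                 exhaustive_cap = exhaustive_cap),
            class = "fdr_params")
}

# Row-wise two-group statistics on a complete matrix.
# idx1/idx2: column indices of the two groups.  Returns means,
# difference D = mean1 - mean2, standard error s, t, p, df and
# d* = D / (s + s0).
row_group_stats <- function(mat, idx1, idx2, s0,
                            variant = c("pooled_student", "welch")) {
  variant <- match.arg(variant)
  x1 <- mat[, idx1, drop = FALSE]
  x2 <- mat[, idx2, drop = FALSE]
  n1 <- ncol(x1)
  n2 <- ncol(x2)
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  ss1 <- rowSums((x1 - m1)^2)
  ss2 <- rowSums((x2 - m2)^2)
  D <- m1 - m2
  if (variant == "pooled_student") {
    df <- rep.int(n1 + n2 - 2L, length(D))
    s <- sqrt((ss1 + ss2) / (n1 + n2 - 2L) * (1 / n1 + 1 / n2))
  } else {
    v1 <- ss1 / (n1 - 1L) / n1
    v2 <- ss2 / (n2 - 1L) / n2
    s <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1L) + v2^2 / (n2 - 1L))
  }
  if (s0 == 0 && any(s == 0 & D != 0)) {
    stop("zero within-group variance with a non-zero difference is ",
         "undefined at s0 = 0; use s0 > 0")
  }
  zero_s <- s == 0
  t <- ifelse(zero_s, ifelse(D == 0, 0, sign(D) * Inf), D / s)
  p <- numeric(length(D))
  ok <- !zero_s
  p[ok] <- 2 * stats::pt(-abs(D[ok] / s[ok]), df[ok])
  p[zero_s] <- ifelse(D[zero_s] == 0, 1, 0)
  d_star <- ifelse(zero_s & D == 0, 0, D / (s + s0))
  list(mean1 = m1, mean2 = m2, difference = D, se = s, df = df,
       t = t, p = p, d_star = d_star)
}

#' S0-moderated two-sample test for one protein
#'
#' @param values_mock,values_treatment numeric vectors of log2
#'   intensities, each of length >= 2, all finite (i.e. post-imputation).
#' @param s0 moderation constant; see [fdr_params()].
#' @param variant `"pooled_student"` or `"welch"`.
#' @return A list with `difference` (mock mean minus treatment mean),
#'   `se`, `d_star` (= difference / (se + s0)), `t_statistic`, `df` and
#'   `p_value` (two-sided, from the unmoderated t).  With zero variance
#'   in both groups the degenerate cases are: difference 0 gives t = 0,
#'   p = 1, d_star = 0; a non-zero difference requires s0 > 0 and gives
#'   an infinite t with p = 0 and d_star = difference / s0.
#' @examples
#' moderated_t(c(24.1, 24.9, 25.3, 24.6), c(22.0, 22.8, 23.1, 22.4))
#' @export
moderated_t <- function(values_mock, values_treatment, s0 = 0.1,
                        variant = c("pooled_student", "welch")) {
  variant <- match.arg(variant)
  x <- as.numeric(values_mock)
  y <- as.numeric(values_treatment)
  if (length(x) < 2L || length(y) < 2L) {
    stop("each group needs at least 2 values")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("values must be finite (impute missing values first)")
  }
  mat <- matrix(c(x, y), nrow = 1L)
  st <- row_group_stats(mat, seq_along(x), length(x) + seq_along(y),
                        s0 = s0, variant = variant)
  list(difference = st$difference, se = st$se, d_star = st$d_star,
       t_statistic = st$t, df = st$df, p_value = st$p)
}

# Enumerate or sample the group-label assignments for the permutation
# null.  Each assignment is the set of column positions (within the
# design-ordered sample columns) relabelled "mock".  The identity
# assignment is excluded; assignments are unique.
perm_assignments <- function(n, n1, identity, params) {
  total <- choose(n, n1)
  exhaustive <- identical(params$n_perm, "exhaustive") ||
    total <= params$exhaustive_cap
  if (identical(params$n_perm, "exhaustive") && total > params$exhaustive_cap) {
    stop("exhaustive enumeration requested but ", total,
         " assignments exceed the cap (", params$exhaustive_cap, ")")
  }
  if (exhaustive) {
    combos <- utils::combn(n, n1)
    keep <- colSums(combos == identity) < n1
    combos <- combos[, keep, drop = FALSE]
  } else {
    want <- params$n_perm
    combos <- with_seed(params$seed, {
      seen <- character(0)
      out <- matrix(0L, nrow = n1, ncol = 0L)
      tries <- 0L
      while (ncol(out) < want && tries < 100L * want) {
        cand <- sort(sample.int(n, n1))
        key <- paste(cand, collapse = ",")
        tries <- tries + 1L
        if (key %in% seen || identical(cand, identity)) next
        seen <- c(seen, key)
        out <- cbind(out, cand)
      }
      out
    })
    if (ncol(combos) < 2L) {
      stop("fewer than 2 distinct non-identity label assignments are ",
           "available; add replicates")
    }
  }
  if (ncol(combos) < 2L) {
    stop("fewer than 2 distinct non-identity label assignments are ",
         "available; add replicates")
  }
  unname(combos)
}

#' Permutation-based FDR thresholding of the moderated statistic
#'
#' Computes the observed moderated statistics d* for every row, rebuilds
#' them under every (or a sampled subset of) relabelling of the samples
#' into two groups of the original sizes, and estimates, for each
#' candidate threshold c taken from the sorted observed |d*|,
#'
#'   FDR(c) = mean over permutations of #\{|d*_perm| >= c\} /
#'            max(1, #\{|d*_obs| >= c\}),
#'
#' capped at 1.  The curve is then forced monotone non-increasing in c
#' (a looser threshold can never claim a lower FDR than a stricter one:
#' each FDR(c) is raised to the maximum raw estimate over thresholds
#' >= c).  The selected threshold is the smallest c with FDR(c) <=
#' alpha; rows with |d*_obs| >= c are flagged significant.  If no
#' threshold qualifies, nothing is flagged.
#'
#' @param table a complete (post-imputation) log2 [protein_table()].
#' @param design a [sample_design()] with >= 2 samples per group.
#' @param params an [fdr_params()].
#' @return A list of class `permutation_fdr`: `threshold` (on |d*|;
#'   `Inf` when nothing qualifies), `significant` (logical per row),
#'   `d_star` (observed), `fdr_table` (per-candidate-threshold
#'   estimates), `null` (list with the assignment matrix and the |d*|
#'   null matrix) and `n_assignments`.
#' @export
permutation_fdr <- function(table, design, params = fdr_params()) {
  if (table$scale != "log2") stop("permutation_fdr expects a log2 table")
  if (anyNA(table$values)) {
    stop("matrix contains missing values; run impute_missing() first")
  }
  idx <- design_indices(table, design)
  n1 <- length(idx$mock)
  n2 <- length(idx$treatment)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 samples")

  # work on the design-ordered submatrix: columns 1..n1 mock, rest treatment
  mat <- table$values[, c(idx$mock, idx$treatment), drop = FALSE]
  n <- n1 + n2
  obs <- row_group_stats(mat, seq_len(n1), n1 + seq_len(n2),
                         s0 = params$s0, variant = params$test_variant)
  a_obs <- abs(obs$d_star)

  combos <- perm_assignments(n, n1, identity = seq_len(n1), params = params)
  n_assign <- ncol(combos)
  null_mat <- matrix(NA_real_, nrow = nrow(mat), ncol = n_assign)
  all_cols <- seq_len(n)
  for (k in seq_len(n_assign)) {
    g1 <- combos[, k]
    st <- row_group_stats(mat, g1, setdiff(all_cols, g1),
                          s0 = params$s0, variant = params$test_variant)
    null_mat[, k] <- abs(st$d_star)
  }

  cands <- sort(unique(a_obs))
  null_sorted <- sort(as.vector(null_mat))
  obs_sorted <- sort(a_obs)
  n_obs_ge <- length(obs_sorted) -
    findInterval(cands, obs_sorted, left.open = TRUE)
  mean_null_ge <- (length(null_sorted) -
                     findInterval(cands, null_sorted, left.open = TRUE)) /
    n_assign
  fdr_raw <- pmin(1, mean_null_ge / pmax(1, n_obs_ge))
  # monotone non-increasing in c: running maximum from the largest
  # threshold downwards
  fdr <- rev(cummax(rev(fdr_raw)))

  ok <- which(fdr <= params$alpha)
  threshold <- if (length(ok) > 0L) cands[min(ok)] else Inf
  significant <- a_obs >= threshold

  structure(list(
    threshold = threshold,
    significant = significant,
    d_star = obs$d_star,
    fdr_table = data.frame(threshold = cands, n_obs = n_obs_ge,
                           mean_null = mean_null_ge, fdr_raw = fdr_raw,
                           fdr = fdr),
    null = list(assignments = combos, d_star_abs = null_mat),
    n_assignments = n_assign,
    params = params
  ), class = "permutation_fdr")
}

#' @export
print.permutation_fdr <- function(x, ...) {
  cat(sprintf(
    "permutation_fdr: %d rows, %d label assignments; |d*| threshold %s -> %d significant\n",
    length(x$significant), x$n_assignments,
    if (is.finite(x$threshold)) sprintf("%.4f", x$threshold) else "Inf",
    sum(x$significant)))
  invisible(x)
}

#' Full differential test of a complete table
#'
#' Per-row S0-moderated statistics plus the permutation-FDR significance
#' call, assembled into one results data frame.
#'
#' @param table a complete (post-imputation) log2 [protein_table()].
#' @param design a [sample_design()].
#' @param params an [fdr_params()].
#' @return A list with `results` (data frame: `group_id`, `gene_label`,
#'   `mean_mock`, `mean_treatment`, `difference` (mock - treatment, log2),
#'   `se`, `d_star`, `t_statistic`, `df`, `p_value`, `neg_log10_p`,
#'   `significant`) and `fdr` (the [permutation_fdr()] object).
#' @export
diff_test <- function(table, design, params = fdr_params()) {
  idx <- design_indices(table, design)
  if (anyNA(table$values)) {
    stop("matrix contains missing values; run impute_missing() first")
  }
  st <- row_group_stats(table$values, idx$mock, idx$treatment,
                        s0 = params$s0, variant = params$test_variant)
  fdr <- permutation_fdr(table, design, params)
  results <- data.frame(
    group_id = table$records$group_id,
    gene_label = table$records$gene_label,
    is_bait = table$records$is_bait,
    mean_mock = st$mean1,
    mean_treatment = st$mean2,
    difference = st$difference,
    se = st$se,
    d_star = st$d_star,
    t_statistic = st$t,
    df = st$df,
    p_value = st$p,
    neg_log10_p = -log10(st$p),
    significant = fdr$significant,
    stringsAsFactors = FALSE
  )
  list(results = results, fdr = fdr)
}

#' Volcano-plot table
#'
#' Reduces a results data frame to the volcano coordinates: x is the
#' log2 mock/treatment difference, y the negative log10 p-value, plus
#' the per-point significance flag.  Treatment-enriched proteins (higher
#' under treatment) have negative x and sit left of zero.
#'
#' @param results the `results` data frame from [diff_test()] or
#'   [analyze_table()].
#' @return A data frame with `group_id`, `gene_label`, `difference`,
#'   `neg_log10_p`, `significant`.
#' @export
volcano_table <- function(results) {
  data.frame(group_id = results$group_id,
             gene_label = results$gene_label,
             difference = results$difference,
             neg_log10_p = results$neg_log10_p,
             significant = results$significant,
             stringsAsFactors = FALSE)
}

#' Draw a volcano plot
#'
#' @param results results data frame (see [volcano_table()]).
#' @param main plot title.
#' @param label_significant annotate significant points with their gene
#'   labels.
#' @return The volcano table, invisibly.
#' @export
plot_volcano <- function(results, main = "qTAP volcano",
                         label_significant = TRUE) {
  vt <- volcano_table(results)
  y <- vt$neg_log10_p
  y[!is.finite(y)] <- max(y[is.finite(y)], 1) * 1.05
  graphics::plot(vt$difference, y,
                 pch = 16, cex = 0.6,
                 col = ifelse(vt$significant, "#c0392b", "#7f8c8d"),
                 xlab = "log2(mock/treatment)",
                 ylab = expression(-log[10] ~ italic(p)),
                 main = main)
  graphics::abline(v = 0, col = "grey70", lty = 2)
  if (label_significant && any(vt$significant)) {
    sel <- which(vt$significant)
    graphics::text(vt$difference[sel], y[sel], labels = vt$gene_label[sel],
                   pos = 3, cex = 0.6, col = "#c0392b")
  }
  invisible(vt)
}
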