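# The S0-moderated statistic and the permutation FDR.

test_that("identical groups give a null statistic", {
  out <- moderated_t(c(1, 2, 3, 4), c(1, 2, 3, 4), s0 = 0.1)
  expect_equal(out$difference, 0)
  expect_equal(out$t_statistic, 0)
  expect_equal(out$p_value, 1)
  expect_equal(out$d_star, 0)
})

test_that("with s0 = 0 the p-value is the textbook Student p-value", {
  set.seed(2024)
  for (i in 1:200) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- rnorm(n1, 0, runif(1, 0.5, 3))
    y <- rnorm(n2, runif(1, -2, 2), runif(1, 0.5, 3))
    out <- moderated_t(x, y, s0 = 0)
    expect_equal(out$p_value, oracle_student_p(x, y, pooled = TRUE),
                 tolerance = 1e-12)
    expect_equal(out$d_star, out$t_statistic)
    w <- moderated_t(x, y, s0 = 0, variant = "welch")
    expect_equal(w$p_value, oracle_student_p(x, y, pooled = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("zero within-group variance is regularized by s0", {
  out <- moderated_t(c(10, 10, 10), c(8, 8, 8), s0 = 0.1)
  expect_equal(out$difference, 2)
  expect_equal(out$se, 0)
  expect_equal(out$d_star, 20)
  expect_equal(out$t_statistic, Inf)
  expect_equal(out$p_value, 0)
  expect_error(moderated_t(c(10, 10, 10), c(8, 8, 8), s0 = 0), "s0")
})

test_that("exhaustive 3v3 permutation FDR matches the brute-force oracle", {
  set.seed(77)
  d <- make_design(3, 3)
  v <- matrix(rnorm(30 * 6, 22, 1), 30, 6,
              dimnames = list(NULL, d$samples$sample))
  v[1:3, 1:3] <- v[1:3, 1:3] + 4  # a few real effects
  tab <- make_table(v, scale = "log2")
  fit <- permutation_fdr(tab, d, fdr_params(s0 = 0.1, alpha = 0.05))
  oracle <- oracle_perm_fdr(v, 3, s0 = 0.1, alpha = 0.05)
  expect_equal(fit$n_assignments, choose(6, 3) - 1)
  expect_equal(oracle$n_assignments, choose(6, 3) - 1)
  expect_equal(unname(fit$d_star), oracle$d_star, tolerance = 1e-12)
  expect_equal(fit$fdr_table$threshold, oracle$cands, tolerance = 1e-12)
  expect_equal(fit$fdr_table$fdr, oracle$fdr, tolerance = 1e-12)
  expect_equal(fit$threshold, oracle$threshold, tolerance = 1e-12)
  expect_identical(unname(fit$significant), oracle$significant)
})

test_that("a strongly separated row among nulls is flagged", {
  set.seed(5)
  d <- make_design()
  v <- matrix(rnorm(500 * 8, 22, 0.3), 500, 8,
              dimnames = list(NULL, d$samples$sample))
  v[1, 1:4] <- v[1, 1:4] + 5 * 0.3  # planted effect of 5 noise-sd
  tab <- make_table(v, scale = "log2")
  fit <- permutation_fdr(tab, d, fdr_params())
  expect_true(fit$significant[1])
})

test_that("alpha and s0 act monotonically", {
  set.seed(11)
  d <- make_design()
  v <- matrix(rnorm(100 * 8, 22, 0.5), 100, 8,
              dimnames = list(NULL, d$samples$sample))
  v[1:10, 1:4] <- v[1:10, 1:4] + 2
  tab <- make_table(v, scale = "log2")
  sig_at <- function(alpha) {
    permutation_fdr(tab, d, fdr_params(alpha = alpha))$significant
  }
  s_lo <- sig_at(0.01); s_mid <- sig_at(0.05); s_hi <- sig_at(0.2)
  expect_true(all(s_lo <= s_mid))   # raising alpha never shrinks the set
  expect_true(all(s_mid <= s_hi))
  d0 <- permutation_fdr(tab, d, fdr_params(s0 = 0.05))$d_star
  d1 <- permutation_fdr(tab, d, fdr_params(s0 = 0.5))$d_star
  expect_true(all(abs(d1) <= abs(d0)))  # raising s0 never inflates |d*|
})

test_that("observed statistics are invariant to consistent relabelling", {
  set.seed(13)
  d <- make_design()
  v <- matrix(rnorm(50 * 8, 22, 1), 50, 8,
              dimnames = list(NULL, d$samples$sample))
  tab <- make_table(v, scale = "log2")
  fit1 <- permutation_fdr(tab, d, fdr_params())
  perm <- c(3, 1, 4, 2, 7, 5, 8, 6)  # shuffle within groups
  v2 <- v[, perm]
  tab2 <- make_table(v2, scale = "log2")
  d2 <- sample_design(colnames(v2), d$samples$group[perm],
                      bait_id = d$bait_id)
  fit2 <- permutation_fdr(tab2, d2, fdr_params())
  expect_equal(fit1$d_star, fit2$d_star)
  expect_identical(fit1$significant, fit2$significant)
})

test_that("sampled (non-exhaustive) nulls are seeded and reproducible", {
  set.seed(21)
  d <- make_design()
  v <- matrix(rnorm(40 * 8, 22, 1), 40, 8,
              dimnames = list(NULL, d$samples$sample))
  tab <- make_table(v, scale = "log2")
  p <- fdr_params(n_perm = 30, seed = 8, exhaustive_cap = 10)
  fit1 <- permutation_fdr(tab, d, p)
  fit2 <- permutation_fdr(tab, d, p)
  expect_equal(fit1$n_assignments, 30)
  expect_identical(fit1$null$assignments, fit2$null$assignments)
  expect_identical(fit1$significant, fit2$significant)
  expect_error(
    permutation_fdr(tab, d, fdr_params(n_perm = "exhaustive",
                                       exhaustive_cap = 10)),
    "exceed")
})

test_that("BH on s0 = 0 p-values controls FDR on null data (cross-check)", {
  set.seed(31)
  d <- make_design()
  fdp <- numeric(200)
  for (i in 1:200) {
    v <- matrix(rnorm(100 * 8), 100, 8,
                dimnames = list(NULL, d$samples$sample))
    st <- qtapdiff:::row_group_stats(v, 1:4, 5:8, s0 = 0,
                                     variant = "pooled_student")
    rej <- p.adjust(st$p, "BH") <= 0.05
    fdp[i] <- sum(rej) / max(1, sum(rej))
  }
  # global null: E[FDP] = P(any rejection) <= alpha, plus Monte-Carlo slack
  expect_lte(mean(fdp), 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("volcano coordinates and flags are consistent", {
  res <- data.frame(group_id = c("a", "b", "c"), gene_label = c("a", "b", "c"),
                    difference = c(-2, 0.5, 1),
                    neg_log10_p = c(3, 0, 1),
                    p_value = c(1e-3, 1, 0.1),
                    significant = c(TRUE, FALSE, FALSE),
                    stringsAsFactors = FALSE)
  vt <- volcano_table(res)
  expect_equal(vt$neg_log10_p[2], 0)  # p = 1 -> y = 0
  # a treatment-enriched significant row sits left of zero
  expect_lt(vt$difference[vt$significant], 0)
  # empty significant set: all flags false
  res$significant <- FALSE
  expect_false(any(volcano_table(res)$significant))
})
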