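# Row filters, log2 transform, valid-value filter, replicate QC.

test_that("flagged rows are removed once each and the bait is protected", {
  v <- matrix(2^rnorm(10 * 4, 20), 10, 4,
              dimnames = list(NULL, c("mock_r1", "mock_r2",
                                      "treat_r1", "treat_r2")))
  tab <- make_table(v, scale = "raw", reverse_rows = c(1, 2),
                    contam_rows = 3)
  out <- filter_flagged_rows(tab)
  expect_equal(nrow(out$values), 7L)
  expect_equal(out$records$group_id, tab$records$group_id[-(1:3)])

  # a row with two flags disappears exactly once
  tab2 <- make_table(v, scale = "raw", contam_rows = 4, site_rows = 4)
  out2 <- filter_flagged_rows(tab2)
  expect_equal(nrow(out2$values), 9L)
  expect_false(anyDuplicated(out2$records$group_id) > 0)

  tab3 <- make_table(v, scale = "raw", bait_row = 5, contam_rows = 5)
  expect_error(filter_flagged_rows(tab3), "bait")
})

test_that("generator flag counts drive the flag filter exactly", {
  sim <- simulate_apms(sim_config(n_background = 500, n_constitutive = 0,
                                  n_recruited = 0, n_released = 0,
                                  n_machinery = 0, n_decoy = 5,
                                  n_contaminant = 5, seed = 3))
  out <- filter_flagged_rows(sim$intensity)
  expect_equal(nrow(out$values), 501L)  # 500 background + bait
})

test_that("log2 transform maps present cells and preserves missingness", {
  v <- matrix(c(1024, 1, NA, 8), 2, 2,
              dimnames = list(NULL, c("mock_r1", "treat_r1")))
  tab <- make_table(v, scale = "raw")
  out <- log2_transform(tab)
  expect_equal(out$scale, "log2")
  expect_equal(unname(out$values), matrix(c(10, 0, NA, 3), 2, 2))
  expect_error(log2_transform(out), "raw-scale")
  # pointwise 2^x restores the raw table exactly on present cells
  expect_identical(2^out$values[!is.na(v)], v[!is.na(v)])
})

test_that("the valid-value filter keeps one-sided complete rows", {
  d <- make_design()
  v <- matrix(NA_real_, 4, 8,
              dimnames = list(NULL, d$samples$sample))
  v[1, ] <- 20                     # complete
  v[2, 1:4] <- 21                  # 4 mock / 0 treatment -> keep
  v[3, c(1:3, 5:7)] <- 22          # 3 / 3 -> drop at min_valid 4
  # row 4 all missing -> drop
  tab <- make_table(v, scale = "log2")
  out <- filter_valid_values(tab, d, min_valid = 4)
  expect_equal(out$records$group_id, tab$records$group_id[1:2])
  # limiting case: min_valid = 1 only removes the all-missing row
  out1 <- filter_valid_values(tab, d, min_valid = 1)
  expect_equal(out1$records$group_id, tab$records$group_id[1:3])
  expect_error(filter_valid_values(tab, d, min_valid = 5),
               "exceeds both group sizes")
})

test_that("both filters are idempotent on generated tables", {
  for (seed in c(1, 2, 3)) {
    sim <- simulate_apms(sim_config(n_background = 60, seed = seed))
    f1 <- filter_flagged_rows(sim$intensity)
    expect_identical(filter_flagged_rows(f1), f1)
    lg <- log2_transform(f1)
    v1 <- filter_valid_values(lg, sim$design, 4)
    expect_identical(filter_valid_values(v1, sim$design, 4), v1)
  }
})

test_that("replicate QC recovers exact correlations in designed cases", {
  d <- make_design(2, 2)
  x <- rnorm(50, 20, 2)
  v <- cbind(mock_r1 = x, mock_r2 = x,             # duplicated column
             treat_r1 = x, treat_r2 = 40 - x)      # anti-proportional
  qc <- replicate_qc(make_table(v, scale = "log2"), d)
  expect_equal(qc$correlation["mock_r1", "mock_r2"], 1.0)
  expect_equal(qc$correlation["treat_r1", "treat_r2"], -1.0)
  expect_equal(qc$r_min, -1.0)
  expect_equal(qc$r_max, 1.0)
  expect_true(all(qc$missing_frac == 0))
})

test_that("QC uses pairwise-complete observations and warns on tiny overlap", {
  d <- make_design(2, 2)
  x <- rnorm(30, 20, 2)
  v <- cbind(mock_r1 = x, mock_r2 = x, treat_r1 = x, treat_r2 = x)
  v[1:28, 4] <- NA  # only 2 shared rows for the treatment pair
  expect_warning(qc <- replicate_qc(make_table(v, scale = "log2"), d),
                 "2 complete rows")
  expect_true(is.na(qc$correlation["treat_r1", "treat_r2"]))
  expect_equal(qc$correlation["mock_r1", "mock_r2"], 1.0)
  expect_equal(qc$missing_frac[["treat_r2"]], 28 / 30)
})

test_that("replicate correlations match the variance-ratio expectation", {
  # abundance sd 2, replicate noise sd 0.3: expected r = 4 / 4.09 ~ 0.978
  r_all <- c()
  for (seed in 1:20) {
    sim <- simulate_apms(sim_config(n_background = 300, n_constitutive = 0,
                                    n_recruited = 0, n_released = 0,
                                    n_machinery = 0, n_decoy = 0,
                                    n_contaminant = 0, base_sd = 2,
                                    noise_sd = 0.3, missingness = FALSE,
                                    seed = seed))
    qc <- replicate_qc(log2_transform(sim$intensity), sim$design)
    r_all <- c(r_all, qc$r_min, qc$r_max)
  }
  expect_true(all(r_all > 0.95 & r_all < 0.99))
})
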