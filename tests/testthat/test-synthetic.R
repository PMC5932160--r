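# The ground-truthed AP-MS simulator.

test_that("the generator is deterministic and matches its configuration", {
  cfg <- sim_config(seed = 123)
  a <- simulate_apms(cfg)
  b <- simulate_apms(cfg)
  expect_identical(a$intensity$values, b$intensity$values)
  expect_identical(a$truth, b$truth)

  counts <- table(a$truth$class)
  expect_equal(unname(counts["background"]), cfg$n_background)
  expect_equal(unname(counts["constitutive"]), cfg$n_constitutive)
  expect_equal(unname(counts["recruited"]), cfg$n_recruited)
  expect_equal(unname(counts["released"]), cfg$n_released)
  expect_equal(unname(counts["machinery"]), cfg$n_machinery)
  expect_equal(unname(counts["decoy"]), cfg$n_decoy)
  expect_equal(unname(counts["contaminant"]), cfg$n_contaminant)
  expect_equal(unname(counts["bait"]), 1L)
  expect_equal(sum(a$intensity$records$is_reverse), cfg$n_decoy)
  expect_equal(sum(a$intensity$records$is_contaminant), cfg$n_contaminant)
  expect_true(all(a$intensity$values[!is.na(a$intensity$values)] > 0))
  # truth classes partition the rows; null classes carry zero effect
  expect_equal(nrow(a$truth), nrow(a$intensity$values))
  null_cls <- a$truth$class %in% c("background", "decoy", "contaminant",
                                   "constitutive")
  expect_true(all(a$truth$effect[null_cls] == 0))
})

test_that("a pure-null configuration lists only null classes", {
  sim <- simulate_apms(sim_config(n_constitutive = 0, n_recruited = 0,
                                  n_released = 0, n_machinery = 0,
                                  bait_drop = 0, seed = 2))
  expect_setequal(unique(sim$truth$class),
                  c("bait", "background", "decoy", "contaminant"))
  expect_true(all(sim$truth$effect == 0))
})

test_that("invalid effect directions are rejected", {
  expect_error(sim_config(bait_drop = -1), "bait_drop")
  expect_error(sim_config(effect = -0.5), "effect")
  expect_error(sim_config(noise_sd = 0), "noise_sd")
})

test_that("missingness is monotone non-increasing in true abundance", {
  args <- list(n_background = 4000, n_constitutive = 0, n_recruited = 0,
               n_released = 0, n_machinery = 0, n_decoy = 0,
               n_contaminant = 0, base_mean = 21, base_sd = 2.5,
               bait_drop = 0, seed = 6)
  sim_on <- simulate_apms(do.call(sim_config, c(args, missingness = TRUE)))
  # same seed with censoring off exposes every underlying measurement
  sim_off <- simulate_apms(do.call(sim_config, c(args, missingness = FALSE)))
  expect_false(anyNA(sim_off$intensity$values))
  x <- as.vector(log2(sim_off$intensity$values))
  miss <- as.vector(is.na(sim_on$intensity$values))
  bins <- cut(x, breaks = c(-Inf, 17, 18, 19, 20, 21, 22, 23, Inf))
  frac <- tapply(miss, bins, mean)
  expect_true(all(diff(frac) <= 0))  # non-increasing per intensity bin
  expect_equal(unname(frac[1]), 1)   # hard floor below L - 2
  expect_lt(frac[[length(frac)]], 0.05)
})

test_that("constitutive preys are invisible in LFQ mode but shift by the
           bait drop after bait normalization", {
  cfg <- sim_config(n_background = 200, n_constitutive = 10,
                    n_recruited = 0, n_released = 0, n_machinery = 0,
                    n_decoy = 0, n_contaminant = 0,
                    bait_drop = 1.5, noise_sd = 1e-4, bait_noise_sd = 0,
                    missingness = FALSE, seed = 14)
  sim <- simulate_apms(cfg)
  const <- sim$truth$class == "constitutive"

  lfq <- log2_transform(sim$lfq)
  D_lfq <- rowMeans(lfq$values[, 1:4]) - rowMeans(lfq$values[, 5:8])
  expect_true(all(abs(D_lfq[const]) < 0.01))

  raw <- log2_transform(sim$intensity)
  D_raw <- rowMeans(raw$values[, 1:4]) - rowMeans(raw$values[, 5:8])
  bn <- bait_normalize(raw, sim$design)
  D_bn <- rowMeans(bn$table$values[, 1:4]) - rowMeans(bn$table$values[, 5:8])
  # exact identity: the normalized difference is the raw difference minus
  # the bait's own difference ...
  expect_equal(unname(D_bn), unname(D_raw - D_raw[raw$records$is_bait]))
  # ... which at vanishing noise is exactly the bait drop
  expect_equal(unname(D_bn[const]), rep(-cfg$bait_drop, sum(const)),
               tolerance = 1e-3)
})

test_that("a hard-censored recruited prey survives the pipeline as a
           treatment-side hit (deterministic limit)", {
  cfg <- sim_config(n_background = 150, n_constitutive = 0, n_released = 0,
                    n_machinery = 0, n_decoy = 0, n_contaminant = 0,
                    n_recruited = 1, effect = 8,   # mock level far below L
                    bait_drop = 0, noise_sd = 0.05, bait_noise_sd = 0,
                    seed = 8)
  sim <- simulate_apms(cfg)
  rec_id <- sim$truth$group_id[sim$truth$class == "recruited"]
  # absent from every mock sample, present in treatment
  expect_true(all(is.na(sim$intensity$values[rec_id, 1:4])))
  an <- analyze_table(sim$lfq, sim$design, mode = "lfq", qc = FALSE)
  row <- an$results[an$results$group_id == rec_id, ]
  expect_lt(row$difference, 0)
  expect_true(row$significant)
})

test_that("truth_eval computes sensitivity and FDP as documented", {
  truth <- data.frame(group_id = c("a", "b", "c", "d"),
                      class = c("recruited", "released", "background",
                                "background"),
                      effect = c(-2, 2, 0, 0),
                      effect_bait_relative = c(-3.5, 0.5, -1.5, -1.5),
                      stringsAsFactors = FALSE)
  perfect <- c(a = TRUE, b = TRUE, c = FALSE, d = FALSE)
  expect_equal(truth_eval(perfect, truth),
               list(sensitivity = 1, fdp = 0))
  none <- c(a = FALSE, b = FALSE, c = FALSE, d = FALSE)
  expect_equal(truth_eval(none, truth), list(sensitivity = 0, fdp = 0))
  all_on <- c(a = TRUE, b = TRUE, c = TRUE, d = TRUE)
  expect_equal(truth_eval(all_on, truth), list(sensitivity = 1, fdp = 0.5))
  expect_error(truth_eval(perfect[1:3], truth), "cover")
  # bait-relative scale: c and d become true effects
  expect_equal(truth_eval(all_on, truth, relative_to_bait = TRUE)$fdp, 0)
})
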