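# OLS fits, the stage / SMG / methylation associations, oncogene group
# test, and the mutual-exclusivity screen.

test_that("ols_fit reproduces closed-form solutions", {
  x <- c(0, 1, 2, 3)
  f <- ols_fit(c(1, 2, 3, 4), data.frame(x = x))
  expect_equal(fit_term(f, "(Intercept)")$beta, 1, tolerance = 1e-12)
  expect_equal(fit_term(f, "x")$beta, 1, tolerance = 1e-12)

  f2 <- ols_fit(2 * x, data.frame(x = x))
  expect_equal(fit_term(f2, "x")$beta, 2, tolerance = 1e-12)
  expect_lt(max(abs(stats::residuals(f2$lm))), 1e-12)

  # orthogonal two-factor design recovered exactly
  d <- expand.grid(a = c(-1, 1), b = c(-1, 1))
  y <- 3 + 2 * d$a - 1.5 * d$b
  f3 <- ols_fit(y, d)
  expect_equal(fit_term(f3, "a")$beta, 2, tolerance = 1e-12)
  expect_equal(fit_term(f3, "b")$beta, -1.5, tolerance = 1e-12)
})

test_that("ols_fit errors on collinearity and handles NAs complete-case", {
  x <- rnorm(20)
  err <- tryCatch(ols_fit(rnorm(20), data.frame(x = x, x2 = 2 * x)),
                  condition = identity)
  expect_s3_class(err, "ctlnc_config_error")
  expect_match(conditionMessage(err), "x2")

  y <- c(rnorm(18), NA, 5); x2 <- c(NA, rnorm(19))
  f <- ols_fit(y, data.frame(x = x2))
  expect_equal(f$n_used, 18L)
})

test_that("ols_fit recovers a planted slope", {
  set.seed(1)
  stage <- sample(1:4, 400, replace = TRUE)
  y <- 2 + 1.0 * stage + rnorm(400, 0, 2)
  f <- ols_fit(y, data.frame(stage = stage))
  b <- fit_term(f, "stage")
  expect_lt(abs(b$beta - 1), 0.3)
  expect_lt(b$p, 0.01)
})

test_that("stage association encodes stage ordinally and errors degenerate input", {
  set.seed(2)
  n <- 300
  clin <- data.frame(sample_id = sprintf("s%03d", 1:n),
                     age = round(rnorm(n, 65, 8)),
                     gender = sample(c("male", "female"), n, TRUE),
                     stage = c("I", "II", "III", "IV")[sample(1:4, n, TRUE)],
                     cancer_type = sample(c("A", "B"), n, TRUE))
  stage_num <- c(I = 1, II = 2, III = 3, IV = 4)[clin$stage]
  counts <- data.frame(sample_id = clin$sample_id,
                       n_activated_eect = rpois(n, 2 + stage_num))
  f <- stage_association(counts, clin)
  b <- fit_term(f, "stage")
  expect_gt(b$beta, 0)
  expect_lt(b$p, 0.05)
  clin1 <- clin; clin1$stage <- "II"
  expect_error(stage_association(counts, clin1), class = "ctlnc_config_error")
})

test_that("SMG ratio association recovers sign in both orientations", {
  set.seed(3)
  n <- 300
  ratio <- pmin(pmax(rbeta(n, 2, 4), 0), 1)
  counts <- data.frame(sample_id = sprintf("s%d", 1:n),
                       n_activated_eect = pmax(0, round(6 - 6 * ratio +
                                                          rnorm(n, 0, 1.5))))
  f1 <- smg_ratio_association(ratio, counts)
  expect_lt(fit_term(f1, "smg_ratio")$beta, 0)
  expect_lt(fit_term(f1, "smg_ratio")$p, 0.05)
  f2 <- smg_ratio_association(ratio, counts, orientation = "ratio_on_count")
  expect_lt(fit_term(f2, "n_activated_eect")$beta, 0)
  expect_error(smg_ratio_association(rep(1.2, n), counts),
               class = "ctlnc_config_error")
  expect_error(smg_ratio_association(rep(0.4, n), counts),
               class = "ctlnc_config_error")  # constant predictor
})

test_that("methylation association recovers the negative coupling", {
  set.seed(4)
  n <- 400
  beta <- rbeta(n, 14, 6)
  counts <- data.frame(sample_id = sprintf("s%d", 1:n),
                       n_activated_eect = pmax(0, round(20 - 20 * beta +
                                                          rnorm(n, 0, 1.5))))
  f <- methylation_association(beta, counts,
                               cancer_type = sample(c("A", "B"), n, TRUE),
                               global_beta = rbeta(n, 10, 10))
  b <- fit_term(f, "mean_promoter_beta")
  expect_lt(b$beta, 0)
  expect_lt(b$p, 0.01)
  expect_error(methylation_association(rep(0.5, n), counts),
               class = "ctlnc_config_error")
})

test_that("oncogene group comparison is an exact rank-sum test", {
  r <- oncogene_group_test(c(0, 0, 0, 5, 6, 7),
                           c(rep("negative", 3), rep("positive", 3)))
  expect_equal(r$p.value, 0.1)
  same <- oncogene_group_test(rep(c(1, 2), 10),
                              rep(c("positive", "negative"), each = 10))
  expect_gt(same$p.value, 0.9)
  expect_error(oncogene_group_test(1:5, rep("positive", 5)),
               class = "ctlnc_config_error")
})

test_that("mutual-exclusivity screen flags never-co-occurring pairs", {
  samples <- sprintf("s%02d", 1:20)
  act <- matrix(c(rep(TRUE, 10), rep(FALSE, 10)), 1, 20,
                dimnames = list("lnc1", samples))
  mut <- matrix(c(rep(FALSE, 10), rep(TRUE, 10)), 20, 1,
                dimnames = list(samples, "DRV1"))
  scr <- mutual_exclusivity_screen(act, mut, include_aggregate = FALSE)
  row <- scr$results[1, ]
  expect_equal(row$p_raw, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(row$direction, "exclusive")
  expect_true(row$significant_exclusive)

  # zero-variance margins are skipped with a reason, not an error
  act2 <- rbind(act, lnc2 = rep(FALSE, 20))
  scr2 <- mutual_exclusivity_screen(act2, mut, include_aggregate = FALSE)
  expect_equal(nrow(scr2$results), 1L)
  expect_equal(scr2$skipped$lncrna, "lnc2")
  expect_match(scr2$skipped$reason, "activation")

  # mismatched sample universe
  mut_bad <- mut[c(2:20, 1), , drop = FALSE]
  expect_error(mutual_exclusivity_screen(act, mut_bad),
               class = "ctlnc_consistency_error")
})

test_that("exclusivity screen recovers planted pairs from the generator", {
  spec <- small_spec(seed = 31L, n_tumor_samples_per_type = 300L,
                     activation_frequency = 0.3, stage_effect = 0,
                     n_exclusive_pairs = 2L)
  np <- generate_normal_panel(spec)
  tc <- generate_tumor_cohorts(spec, np$truth)
  truth <- tc$truth
  type <- names(tc$cohorts)[1]
  act <- truth$tumor[[type]]$activated
  mut <- truth$tumor[[type]]$mutations
  scr <- mutual_exclusivity_screen(act, mut, alpha = 0.05,
                                   include_aggregate = FALSE)
  found <- scr$results[scr$results$significant_exclusive, ]
  for (i in seq_len(nrow(truth$exclusive_pairs))) {
    expect_true(any(found$lncrna == truth$exclusive_pairs$lncrna[i] &
                      found$driver == truth$exclusive_pairs$driver[i]))
  }
})
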