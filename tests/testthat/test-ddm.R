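test_that("the candidate model space has 15 distinct reductions of the full model", {
  space <- enumerate_model_space()
  expect_length(space, 15)
  sig <- vapply(space, function(s)
    paste(c(s$v, "|", s$a, "|", s$z, "|", s$t0), collapse = ","), character(1))
  expect_equal(anyDuplicated(sig), 0)
  n1 <- priomatch:::spec_n_cells(space[[1]])
  expect_equal(n1, 12 + 6 + 6 + 4)
  for (m in space[-1]) expect_lt(priomatch:::spec_n_cells(m), n1)
  expect_equal(space[[1]]$v, c("label", "match", "group"))
  # Model 7 drops the label dependence of boundary and starting point
  expect_equal(space[[7]]$a, "group")
  expect_equal(space[[7]]$z, "group")
  expect_equal(space[[7]]$v, c("label", "match", "group"))
})

test_that("hierarchical fits are seed-deterministic and respect parameter domains", {
  set.seed(101)
  truths <- lapply(1:4, function(i) make_fp_truth(sprintf("s%02d", i),
                                                  jitter = 0.1))
  trials <- sim_cohort_trials(truths, trials_per_condition = 12, seed = 102)
  fit1 <- suppressWarnings(fit_hddm(trials, ddm_spec(), n_samples = 150,
                                    burn_in = 50, seed = 103))
  fit2 <- suppressWarnings(fit_hddm(trials, ddm_spec(), n_samples = 150,
                                    burn_in = 50, seed = 103))
  expect_identical(fit1$draws, fit2$draws)
  td <- tidy(fit1)
  expect_true(all(td$estimate[td$parameter == "a"] > 0))
  z_est <- td$estimate[td$parameter == "z"]
  expect_true(all(z_est > 0 & z_est < 1))
  expect_true(all(td$estimate[td$parameter == "t0"] >= 0))
  expect_true(is.finite(fit1$dic$dic))
})

test_that("p_bayes equals a direct count over the stored draws", {
  set.seed(104)
  truths <- lapply(1:3, function(i) make_fp_truth(sprintf("s%02d", i),
                                                  jitter = 0.1))
  trials <- sim_cohort_trials(truths, trials_per_condition = 10, seed = 105)
  fit <- suppressWarnings(fit_hddm(trials, ddm_spec(), n_samples = 120,
                                   burn_in = 40, seed = 106))
  keep <- seq.int(41, 120)
  m <- fit$draws$mu$v[keep, ]
  direct <- mean(m[, "FP:friend_match"] > m[, "FP:self_match"])
  expect_equal(p_bayes(fit, "v", c("friend_match", "self_match"), "greater"),
               direct)
  expect_equal(p_bayes(fit, "v", c("friend_match", "friend_match"),
                       "greater"), 0)
  expect_error(p_bayes(fit, "v", c("nope", "self_match")), "unknown cell")
})

test_that("model comparison requires a shared dataset and ranks by DIC", {
  set.seed(107)
  truths <- lapply(1:3, function(i) make_fp_truth(sprintf("s%02d", i),
                                                  jitter = 0.1))
  trials <- sim_cohort_trials(truths, trials_per_condition = 10, seed = 108)
  space <- enumerate_model_space()
  f1 <- suppressWarnings(fit_hddm(trials, space[[1]], n_samples = 120,
                                  burn_in = 40, seed = 109))
  f2 <- suppressWarnings(fit_hddm(trials, space[[15]], n_samples = 120,
                                  burn_in = 40, seed = 110))
  cmp <- compare_models(list(f1, f2))
  expect_equal(cmp$dic, sort(cmp$dic))
  expect_equal(cmp$rank, 1:2)
  other <- sim_cohort_trials(truths, trials_per_condition = 8, seed = 111)
  f3 <- suppressWarnings(fit_hddm(other, space[[1]], n_samples = 120,
                                  burn_in = 40, seed = 112))
  expect_error(compare_models(list(f1, f3)), "different datasets")
})

test_that("trial-by-trial regression recovers the sign of a planted coupling", {
  set.seed(113)
  n_subj <- 6; n_tr <- 150
  trials <- purrr::map_dfr(seq_len(n_subj), function(s) {
    x <- rnorm(n_tr)
    v <- 1 + 0.5 * x
    sim <- priomatch:::simulate_ddm_cpp(n_tr, v, 1.8, 0.5, 0.25, 0.001, 30)
    tibble::tibble(subject = sprintf("s%02d", s),
                   response = ifelse(sim$upper == 1, "yes", "no"),
                   rt_ms = sim$rt * 1000, covar = x)
  })
  fit <- fit_neural_regression(trials, "covar", target = "v",
                               n_samples = 400, burn_in = 150, seed = 114)
  expect_gt(fit$p_beta_pos, 0.95)
  expect_gt(fit$beta_mean, 0)
  expect_error(
    fit_neural_regression(dplyr::mutate(trials, covar = 1), "covar"),
    "constant covariate")
})
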