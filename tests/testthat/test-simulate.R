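test_that("simulated choice proportions match the closed-form absorption probability", {
  set.seed(11)
  cases <- list(c(v = 0, a = 2, z = 0.5), c(v = 1, a = 2, z = 0.5),
                c(v = 1.5, a = 1.2, z = 0.35))
  n <- 1e5
  for (cs in cases) {
    sim <- priomatch:::simulate_ddm_cpp(n, cs["v"], cs["a"], cs["z"], 0,
                                        0.001, 60)
    p <- oracle_upper_prob(cs["v"], cs["a"], cs["z"])
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(sim$upper) - p), 3 * se + 1e-3)
  }
})

test_that("non-decision time is an additive RT floor when no outliers are drawn", {
  truth <- make_fp_truth()
  tr <- simulate_ddm_trials(truth, task_design(trials_per_condition = 30),
                            outlier_prob = 0, seed = 1)
  match_rts <- tr$rt_ms[!is.na(tr$rt_ms) & tr$match == "match"]
  nonmatch_rts <- tr$rt_ms[!is.na(tr$rt_ms) & tr$match == "nonmatch"]
  expect_gte(min(match_rts), truth$t0_map[["match"]] * 1000)
  expect_gte(min(nonmatch_rts), truth$t0_map[["nonmatch"]] * 1000)
})

test_that("trial counts, condition structure and determinism hold", {
  truth <- make_fp_truth()
  design <- task_design(trials_per_condition = 25)
  t1 <- simulate_ddm_trials(truth, design, seed = 7)
  t2 <- simulate_ddm_trials(truth, design, seed = 7)
  expect_identical(t1, t2)
  counts <- dplyr::count(t1, label, match)
  expect_equal(nrow(counts), 6)
  expect_true(all(counts$n == 25))
  expect_true(all(t1$accuracy[!is.na(t1$accuracy)] %in% c(0, 1)))
})

test_that("generated cohorts satisfy their group's defining drift inequality", {
  coh <- generate_cohort(10, 10, effect_size_v = 0.8, noise_sd = 0.1,
                         design = task_design(trials_per_condition = 2),
                         seed = 21)
  for (tr in coh$truths) {
    vm <- tr$v_map
    if (tr$latent_group == "FP") {
      expect_gt(vm[["friend_match"]], vm[["self_match"]])
    } else {
      expect_gt(vm[["self_match"]], vm[["friend_match"]])
    }
    expect_lt(vm[["stranger_match"]],
              max(vm[["self_match"]], vm[["friend_match"]]))
  }
  expect_error(generate_cohort(0, 5), "n_fp")
  coh2 <- generate_cohort(10, 10, effect_size_v = 0.8, noise_sd = 0.1,
                          design = task_design(trials_per_condition = 2),
                          seed = 21)
  expect_identical(coh$trials, coh2$trials)
})

test_that("synthesized epochs have the right shape and reconstruct templates noiselessly", {
  truth <- make_fp_truth()
  tr <- simulate_ddm_trials(truth, task_design(trials_per_condition = 2),
                            seed = 3)
  fs <- 500 # sample grid hits the P2 peak latency exactly
  ep <- synthesize_epochs(tr, osc = NULL, fs = fs,
                          epoch_window_ms = c(-500, 800), noise_sd = 0,
                          seed = 5)
  expect_equal(dim(ep$data), c(nrow(tr), 30, round(1300 * fs / 1000) + 1))
  # noiseless: peak at a template channel equals the template amplitude
  tpl <- erp_templates()
  p2 <- tpl[tpl$component == "P2", ]
  ci <- match(p2$channels[[1]][1], ep$channels)
  si <- which(ep$times == p2$peak_ms)
  expect_length(si, 1)
  expect_equal(mean(ep$data[, ci, si]), p2$amplitude_uv, tolerance = 1e-6)
})

test_that("the oscillation is non-phase-locked: it cancels in the ERP average", {
  trials <- tibble::tibble(subject = "s1", label = "self", match = "match")[
    rep(1, 200), ]
  mont <- default_montage()[1:4, ]
  ep <- synthesize_epochs(trials, templates = NULL,
                          osc = osc_spec(channels = c("F7", "F3")),
                          montage = mont, fs = 250, noise_sd = 0, seed = 9)
  erp <- apply(ep$data[, 3, ], 2, mean) # F3 average over 200 trials
  single <- ep$data[1, 3, ]
  # averaged power shrinks toward 1/n of single-trial power
  expect_lt(mean(erp^2), 0.05 * mean(single^2))
})

test_that("coupled oscillatory power decreases with the trial's drift", {
  truth <- make_fp_truth()
  tr <- simulate_ddm_trials(truth, task_design(trials_per_condition = 40),
                            seed = 13)
  tr <- tr[tr$match == "match", ]
  mont <- default_montage()[1:6, ]
  ep <- synthesize_epochs(tr, templates = NULL,
                          osc = osc_spec(channels = c("F3", "FZ"),
                                         coupling_gain = 0.8),
                          montage = mont, fs = 250, noise_sd = 0.2,
                          drift = condition_drift(truth, tr), seed = 15)
  fam <- build_wavelets(freqs = 8:12, fs = 250)
  tfr <- tf_power(subset_epochs(ep, channels = c("F3", "FZ")), fam,
                  keep_trials = TRUE)
  pw <- tfr_band_mean(tfr, c(8, 12), c(0, 600))
  expect_lt(cor(pw$power, condition_drift(truth, pw), method = "spearman"),
            -0.5)
})

test_that("trait and game tables respect endowment bounds and determinism", {
  coh <- generate_cohort(8, 8, design = task_design(trials_per_condition = 2),
                         seed = 31)
  tg1 <- generate_traits_and_games(coh, canonical_rho = 0.5, seed = 32)
  tg2 <- generate_traits_and_games(coh, canonical_rho = 0.5, seed = 32)
  expect_identical(tg1, tg2)
  expect_true(all(tg1$trust_send >= 0 & tg1$trust_send <= 10))
  expect_true(all(tg1$pgg_contribution >= 0 & tg1$pgg_contribution <= 80))
  expect_true(all(tg1$friend_closeness >= 1 & tg1$friend_closeness <= 7))
  expect_error(generate_traits_and_games(coh, canonical_rho = 1.2),
               "canonical_rho")
})
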