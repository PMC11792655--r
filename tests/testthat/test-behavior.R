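make_cell_trials <- function(subject, label, rts, accs,
                             match = "match") {
  tibble::tibble(
    subject = subject, label = label, match = match,
    response = ifelse(accs == 1,
                      ifelse(match == "match", "yes", "no"),
                      ifelse(match == "match", "no", "yes")),
    rt_ms = rts, accuracy = accs,
    trial_index = seq_along(rts)
  )
}

test_that("efficiency is mean correct RT over accuracy, with exact arithmetic", {
  tr <- dplyr::bind_rows(
    make_cell_trials("A", "self", c(rep(600, 9), 600), c(rep(1, 9), 0)),
    make_cell_trials("A", "friend", rep(650, 10), rep(1, 10)),
    make_cell_trials("A", "stranger", rep(700, 10), rep(1, 10))
  )
  eff <- response_efficiency(tr)
  self_row <- eff[eff$label == "self", ]
  expect_equal(self_row$efficiency, 600 / 0.9, tolerance = 1e-12)
  friend_row <- eff[eff$label == "friend", ]
  expect_equal(friend_row$efficiency, 650) # accuracy 1 -> E = mean RT
  expect_equal(unique(eff$diff_score), 600 / 0.9 - 650, tolerance = 1e-12)
})

test_that("zero-accuracy cells yield undefined efficiency and are excluded from classification", {
  tr <- dplyr::bind_rows(
    make_cell_trials("A", "self", rep(600, 4), rep(0, 4)),
    make_cell_trials("A", "friend", rep(650, 4), rep(1, 4)),
    make_cell_trials("B", "self", rep(700, 4), rep(1, 4)),
    make_cell_trials("B", "friend", rep(650, 4), rep(1, 4)),
    make_cell_trials("C", "self", rep(600, 4), rep(1, 4)),
    make_cell_trials("C", "friend", rep(650, 4), rep(1, 4))
  )
  eff <- response_efficiency(tr)
  expect_true(is.na(eff$efficiency[eff$subject == "A" & eff$label == "self"]))
  expect_true(all(is.na(eff$diff_score[eff$subject == "A"])))
  cl <- classify_groups(eff)
  expect_equal(as.character(cl$group[cl$subject == "A"]), "unassigned")
})

test_that("efficiency is monotone in RT and accuracy", {
  base <- make_cell_trials("A", "self", rep(600, 10), c(rep(1, 9), 0))
  slower <- base; slower$rt_ms <- slower$rt_ms + 50
  less_acc <- make_cell_trials("A", "self", rep(600, 10), c(rep(1, 8), 0, 0))
  e0 <- response_efficiency(dplyr::bind_rows(base,
    make_cell_trials("A", "friend", rep(1, 2) * 600, c(1, 1))))
  e1 <- response_efficiency(dplyr::bind_rows(slower,
    make_cell_trials("A", "friend", rep(1, 2) * 600, c(1, 1))))
  e2 <- response_efficiency(dplyr::bind_rows(less_acc,
    make_cell_trials("A", "friend", rep(1, 2) * 600, c(1, 1))))
  g <- function(e) e$efficiency[e$label == "self"]
  expect_gt(g(e1), g(e0))
  expect_gt(g(e2), g(e0))
})

test_that("group classification matches the hand-ranked selection rule", {
  eff <- tibble::tibble(subject = c("a", "b", "c", "d", "e"),
                        diff_score = c(10, 5, -1, -20, -30))
  cl <- classify_groups(eff)
  expect_setequal(cl$subject[cl$group == "FP"], c("a", "b"))
  expect_setequal(cl$subject[cl$group == "SP"], c("e", "d"))
  expect_equal(as.character(cl$group[cl$subject == "c"]), "unassigned")
  # invariance to row order; FP and SP disjoint by construction
  cl2 <- classify_groups(eff[sample.int(5), ])
  expect_identical(dplyr::arrange(cl, subject), dplyr::arrange(cl2, subject))
  # exact zero stays unassigned; all-negative scores are an error
  cl3 <- classify_groups(tibble::tibble(subject = c("a", "b", "c"),
                                        diff_score = c(0, 2, -3)))
  expect_equal(as.character(cl3$group[cl3$subject == "a"]), "unassigned")
  expect_error(classify_groups(tibble::tibble(subject = c("a", "b"),
                                              diff_score = c(-1, -2))),
               "FP group is empty")
  expect_error(classify_groups(tibble::tibble(subject = c("a", "b"),
                                              diff_score = c(3, 2))),
               "SP group")
})

test_that("bootstrap means are degenerate for constant data and consistent otherwise", {
  tr <- dplyr::bind_rows(lapply(c("A", "B", "C"), function(s)
    make_cell_trials(s, "self", rep(500, 6), rep(1, 6))))
  bo <- bootstrap_condition_means(tr, n_boot = 50, seed = 1)
  expect_true(all(bo$mean_accuracy == 1))
  expect_true(all(bo$mean_rt_ms == 500))
  # resampling consistency on variable data
  set.seed(2)
  tr2 <- dplyr::bind_rows(lapply(sprintf("s%02d", 1:12), function(s)
    make_cell_trials(s, "self", rnorm(20, 600, 40),
                     rbinom(20, 1, 0.9))))
  bo2 <- bootstrap_condition_means(tr2, n_boot = 400, seed = 3)
  per_subj <- tr2 |>
    dplyr::group_by(subject) |>
    dplyr::summarise(rt = mean(rt_ms[accuracy == 1]))
  expect_lt(abs(mean(bo2$mean_rt_ms) - mean(per_subj$rt)),
            3 * sd(bo2$mean_rt_ms))
  bo3 <- bootstrap_condition_means(tr2, n_boot = 400, seed = 3)
  expect_identical(bo2, bo3)
})

test_that("d-prime and beta match the quantile formulas and their symmetries", {
  n <- 200
  yes_m <- 168 # hit rate 0.84
  yes_n <- 100 # false-alarm rate 0.5
  tr <- dplyr::bind_rows(
    tibble::tibble(subject = "A", label = "self", match = "match",
                   response = rep(c("yes", "no"), c(yes_m, n - yes_m)),
                   rt_ms = 500, accuracy = NA, trial_index = 1:n),
    tibble::tibble(subject = "A", label = "self", match = "nonmatch",
                   response = rep(c("yes", "no"), c(yes_n, n - yes_n)),
                   rt_ms = 500, accuracy = NA, trial_index = 1:n)
  )
  out <- sdt_indices(tr)
  H <- yes_m / n; F <- yes_n / n
  expect_equal(out$d_prime, qnorm(H) - qnorm(F), tolerance = 1e-12)
  expect_equal(out$beta, exp((qnorm(F)^2 - qnorm(H)^2) / 2), tolerance = 1e-12)
  # H = F gives d' = 0, beta = 1
  tr_eq <- tr
  tr_eq$response[tr_eq$match == "match"] <-
    rep(c("yes", "no"), c(yes_n, n - yes_n))
  out_eq <- sdt_indices(tr_eq)
  expect_equal(out_eq$d_prime, 0)
  expect_equal(out_eq$beta, 1)
  # swapping H and F negates d' and inverts beta
  tr_sw <- tr
  tr_sw$match <- ifelse(tr$match == "match", "nonmatch", "match")
  out_sw <- sdt_indices(tr_sw)
  expect_equal(out_sw$d_prime, -out$d_prime, tolerance = 1e-12)
  expect_equal(out_sw$beta, 1 / out$beta, tolerance = 1e-12)
})

test_that("sdt indices equal brute-force counting on a synthetic cohort", {
  coh <- generate_cohort(3, 3, design = task_design(trials_per_condition = 40),
                         seed = 17)
  out <- sdt_indices(coh$trials)
  tr <- coh$trials[!is.na(coh$trials$response), ]
  for (i in seq_len(nrow(out))) {
    sub <- tr[tr$subject == out$subject[i] & tr$label == out$label[i], ]
    nm <- sum(sub$match == "match")
    nn <- sum(sub$match == "nonmatch")
    H <- sum(sub$match == "match" & sub$response == "yes") / nm
    F <- sum(sub$match == "nonmatch" & sub$response == "yes") / nn
    H <- min(max(H, 1 / (2 * nm)), 1 - 1 / (2 * nm))
    F <- min(max(F, 1 / (2 * nn)), 1 - 1 / (2 * nn))
    expect_equal(out$d_prime[i], qnorm(H) - qnorm(F), tolerance = 1e-12)
    expect_equal(out$beta[i], exp((qnorm(F)^2 - qnorm(H)^2) / 2),
                 tolerance = 1e-12)
    expect_gt(out$beta[i], 0)
  }
})

test_that("extreme hit/false-alarm rates are corrected before the quantile transform", {
  tr <- dplyr::bind_rows(
    tibble::tibble(subject = "A", label = "self", match = "match",
                   response = rep("yes", 20), rt_ms = 500, accuracy = NA,
                   trial_index = 1:20),
    tibble::tibble(subject = "A", label = "self", match = "nonmatch",
                   response = rep("no", 20), rt_ms = 500, accuracy = NA,
                   trial_index = 1:20)
  )
  out_half <- sdt_indices(tr, correction = "half")
  expect_equal(out_half$hit_rate, 1 - 1 / 40)
  expect_equal(out_half$fa_rate, 1 / 40)
  expect_true(is.finite(out_half$d_prime))
  out_ll <- sdt_indices(tr, correction = "loglinear")
  expect_equal(out_ll$hit_rate, 20.5 / 21)
  expect_true(is.finite(out_ll$d_prime))
})
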