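#' Ground-truth decision parameters for one simulated subject
#'
#' Bundles the drift-diffusion parameters that generate a subject's behavior:
#' a drift rate per label x match cell (evidence-acquisition speed, 1/s), a
#' boundary separation per label (response caution), a relative starting
#' point per label (prior response bias, in (0, 1)), a non-decision time per
#' match level (seconds), and a gain linking trial-level drift to the
#' amplitude of the synthesized alpha/low-beta oscillation.
#'
#' @param subject_id Subject identifier (coerced to character).
#' @param latent_group `"FP"` (friend-prioritizing), `"SP"`
#'   (self-prioritizing) or `"neutral"`.
#' @param v_map Named numeric of length 6, names `label_match` (e.g.
#'   `self_match`, `friend_nonmatch`).
#' @param a_map Named numeric of length 3 (per label), all positive.
#' @param z_map Named numeric of length 3 (per label), all in (0, 1).
#' @param t0_map Named numeric of length 2 (`match`, `nonmatch`), nonnegative,
#'   seconds.
#' @param coupling_gain Scalar; positive values make single-trial oscillatory
#'   power a decreasing function of the trial's condition drift.
#' @return An object of class `prio_truth`.
#' @examples
#' tr <- subject_truth("s01", "FP",
#'   v_map = c(self_match = 1.5, friend_match = 2.3, stranger_match = 1.2,
#'             self_nonmatch = -1.8, friend_nonmatch = -1.8,
#'             stranger_nonmatch = -1.8),
#'   a_map = c(self = 1.5, friend = 1.6, stranger = 1.6),
#'   z_map = c(self = 0.5, friend = 0.5, stranger = 0.5),
#'   t0_map = c(match = 0.25, nonmatch = 0.29))
#' @export
subject_truth <- function(subject_id, latent_group, v_map, a_map, z_map,
                          t0_map, coupling_gain = 0.6) {
  latent_group <- match.arg(latent_group, c("FP", "SP", "neutral"))
  labels <- c("self", "friend", "stranger")
  cells <- as.vector(outer(labels, c("match", "nonmatch"), paste, sep = "_"))
  if (!all(cells %in% names(v_map))) {
    abort(sprintf("v_map must be named with: %s", paste(cells, collapse = ", ")))
  }
  if (!all(labels %in% names(a_map)) || !all(labels %in% names(z_map))) {
    abort("a_map and z_map must be named self/friend/stranger")
  }
  if (!all(c("match", "nonmatch") %in% names(t0_map))) {
    abort("t0_map must be named match/nonmatch")
  }
  if (!all(is.finite(c(v_map, a_map, z_map, t0_map, coupling_gain)))) {
    abort("all decision parameters must be finite")
  }
  if (any(a_map <= 0)) abort("boundary separations must be positive")
  if (any(z_map <= 0 | z_map >= 1)) abort("starting points must lie in (0, 1)")
  if (any(t0_map < 0)) abort("non-decision times must be nonnegative")
  if (latent_group == "FP" &&
      v_map[["friend_match"]] <= v_map[["self_match"]]) {
    abort("FP subjects require v(friend, match) > v(self, match)")
  }
  if (latent_group == "SP" &&
      v_map[["self_match"]] <= v_map[["friend_match"]]) {
    abort("SP subjects require v(self, match) > v(friend, match)")
  }
  structure(
    list(subject_id = as.character(subject_id), latent_group = latent_group,
         v_map = v_map[cells], a_map = a_map[labels], z_map = z_map[labels],
         t0_map = t0_map[c("match", "nonmatch")],
         coupling_gain = coupling_gain),
    class = "prio_truth"
  )
}

#' @export
print.prio_truth <- function(x, ...) {
  cat(sprintf("<prio_truth> subject %s (%s)\n", x$subject_id, x$latent_group))
  cat("  v:", paste(sprintf("%s=%.2f", names(x$v_map), x$v_map), collapse = " "), "\n")
  cat("  a:", paste(sprintf("%s=%.2f", names(x$a_map), x$a_map), collapse = " "),
      " z:", paste(sprintf("%.2f", x$z_map), collapse = "/"),
      " t0:", paste(sprintf("%.2f", x$t0_map), collapse = "/"), "\n")
  invisible(x)
}

#' Simulate shape-label matching trials from one subject's truth
#'
#' Forward simulation of the diffusion process by Euler-Maruyama at `dt`
#' (default 1 ms) with unit diffusion coefficient; the upper boundary is a
#' "yes" (match) response, the lower a "no". RT = decision time + t0. A
#' fraction `outlier_prob` of trials is replaced by contaminants with uniform
#' RT on [t0, deadline] and a random response, mirroring the mixture assumed
#' at fitting time. Trials undecided at the response deadline are "slow":
#' response and accuracy are `NA`.
#'
#' @param truth A [subject_truth()].
#' @param design A [task_design()].
#' @param outlier_prob Proportion of contaminant trials, in [0, 0.5].
#' @param trial_drift_sd Within-subject trial-to-trial drift sd (default 0).
#' @param seed Optional integer seed.
#' @param dt Euler step, seconds.
#' @return A tibble with columns `subject`, `group_truth`, `label`, `match`,
#'   `response` ("yes"/"no"/NA), `rt_ms`, `accuracy`, `trial_index`.
#' @examples
#' tr <- generate_cohort(1, 1, seed = 1)$truths[[1]]
#' head(simulate_ddm_trials(tr, task_design(), seed = 2))
#' @export
simulate_ddm_trials <- function(truth, design = task_design(),
                                outlier_prob = 0.05, trial_drift_sd = 0,
                                seed = NULL, dt = 0.001) {
  if (!inherits(truth, "prio_truth")) abort("`truth` must be a prio_truth")
  if (!inherits(design, "prio_design")) abort("`design` must be a prio_design")
  assert_scalar_number(outlier_prob, "outlier_prob", 0, 0.5)
  assert_scalar_number(trial_drift_sd, "trial_drift_sd", 0)
  if (!is.null(seed)) set.seed(seed)

  n_cond <- design$trials_per_condition
  grid <- tidyr::expand_grid(label = design$labels,
                             match = design$match_levels)
  trials <- grid[rep(seq_len(nrow(grid)), each = n_cond), ]
  n <- nrow(trials)
  cell <- paste(trials$label, trials$match, sep = "_")
  v <- truth$v_map[cell]
  if (trial_drift_sd > 0) v <- v + rnorm(n, 0, trial_drift_sd)
  a <- truth$a_map[trials$label]
  z <- truth$z_map[trials$label]
  t0 <- truth$t0_map[trials$match]
  deadline_s <- design$response_deadline_ms / 1000

  sim <- simulate_ddm_cpp(n, v, a, z, t0, dt, deadline_s + 0.5)
  rt <- sim$rt
  response <- ifelse(sim$upper == 1L, "yes", "no")
  slow <- is.na(rt) | rt > deadline_s
  response[slow] <- NA
  rt[slow] <- NA

  if (outlier_prob > 0) {
    is_out <- runif(n) < outlier_prob
    n_out <- sum(is_out)
    if (n_out > 0) {
      rt[is_out] <- runif(n_out, t0[is_out], deadline_s)
      response[is_out] <- ifelse(runif(n_out) < 0.5, "yes", "no")
    }
  }

  accuracy <- ifelse(is.na(response), NA_integer_,
                     as.integer((trials$match == "match") == (response == "yes")))
  ord <- sample.int(n)
  tibble(
    subject = truth$subject_id,
    group_truth = truth$latent_group,
    label = trials$label[ord],
    match = trials$match[ord],
    response = response[ord],
    rt_ms = rt[ord] * 1000,
    accuracy = accuracy[ord],
    trial_index = seq_len(n)
  )
}

# population-level parameter maps for a latent group; the prioritized label's
# match drift exceeds the other's by effect_size_v, stranger drift is lowest
cohort_base_maps <- function(group, effect_size_v) {
  pri <- if (group == "FP") "friend" else "self"
  oth <- if (group == "FP") "self" else "friend"
  v <- c(self_match = NA, friend_match = NA, stranger_match = 1.2,
         self_nonmatch = -1.8, friend_nonmatch = -1.8, stranger_nonmatch = -1.8)
  v[paste0(pri, "_match")] <- 1.5 + effect_size_v
  v[paste0(oth, "_match")] <- 1.5
  z <- c(self = 0.5, friend = 0.5, stranger = 0.5)
  if (group == "SP") z["self"] <- 0.55 # prior bias toward "yes" for self
  list(v = v,
       a = c(self = 1.5, friend = 1.6, stranger = 1.6),
       z = z,
       t0 = c(match = 0.25, nonmatch = 0.29))
}

#' Generate a cohort of simulated subjects with known prioritization
#'
#' Draws `n_fp` friend-prioritizing and `n_sp` self-prioritizing subjects.
#' Population means put the prioritized label's match drift `effect_size_v`
#' above the non-prioritized one, with stranger drift lowest in both groups;
#' subject-level parameters add Normal between-subject noise. Noise on the
#' two defining match-drift cells is redrawn if it would flip the group's
#' defining inequality, so every generated truth satisfies its group's sign.
#'
#' @param n_fp,n_sp Number of subjects per latent group (both >= 1).
#' @param effect_size_v Drift-rate advantage of the prioritized label (> 0).
#' @param noise_sd Between-subject sd of the drift rates.
#' @param design A [task_design()].
#' @param outlier_prob Contaminant proportion passed to the trial simulator.
#' @param coupling_gain Drift-to-oscillation coupling stored in each truth.
#' @param seed Optional integer seed.
#' @return A list with `truths` (list of [subject_truth()]) and `trials`
#'   (pooled trial tibble).
#' @examples
#' coh <- generate_cohort(2, 2, seed = 1)
#' dplyr::count(coh$trials, subject)
#' @export
generate_cohort <- function(n_fp, n_sp, effect_size_v = 0.8, noise_sd = 0.1,
                            design = task_design(), outlier_prob = 0.05,
                            coupling_gain = 0.6, seed = NULL) {
  assert_scalar_number(n_fp, "n_fp", lower = 1)
  assert_scalar_number(n_sp, "n_sp", lower = 1)
  assert_scalar_number(effect_size_v, "effect_size_v", lower = 1e-12)
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  if (!is.null(seed)) set.seed(seed)

  groups <- c(rep("FP", n_fp), rep("SP", n_sp))
  n <- length(groups)
  ids <- sprintf("s%03d", seq_len(n))
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    g <- groups[i]
    base <- cohort_base_maps(g, effect_size_v)
    pri_cell <- if (g == "FP") "friend_match" else "self_match"
    oth_cell <- if (g == "FP") "self_match" else "friend_match"
    repeat {
      v <- base$v + rnorm(6, 0, noise_sd)
      names(v) <- names(base$v)
      if (v[[pri_cell]] > v[[oth_cell]]) break
    }
    a <- pmax(base$a + rnorm(3, 0, 0.08), 0.5)
    names(a) <- names(base$a)
    z <- pmin(pmax(base$z + rnorm(3, 0, 0.02), 0.2), 0.8)
    names(z) <- names(base$z)
    t0 <- pmax(base$t0 + rnorm(2, 0, 0.02), 0.05)
    names(t0) <- names(base$t0)
    truths[[i]] <- subject_truth(ids[i], g, v, a, z, t0, coupling_gain)
  }
  trials <- purrr::map_dfr(truths, simulate_ddm_trials, design = design,
                           outlier_prob = outlier_prob)
  list(truths = truths, trials = trials)
}
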