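#' Response efficiency per subject and label
#'
#' For the matching condition of each subject x label cell: the mean RT of
#' correct responses (ms), the response accuracy, and the response-efficiency
#' score E = mean RT / accuracy (ms; lower is better). "Slow" trials (no
#' response before the deadline, `response` NA) are excluded. The per-subject
#' difference score E(self) - E(friend) defines candidate friend-prioritizers
#' (positive) and self-prioritizers (negative). Cells with zero accuracy get
#' an undefined (NA) efficiency and an NA difference score; such subjects are
#' excluded from classification.
#'
#' @param trials Trial tibble with `subject`, `label`, `match`, `response`,
#'   `rt_ms`, `accuracy`.
#' @param trim Optional length-2 RT bounds (ms); correct trials outside them
#'   are dropped from the RT mean (default no trimming).
#' @return Tibble, one row per subject x label: `n_trials`, `mean_rt_ms`,
#'   `accuracy`, `efficiency`, plus the subject's `diff_score` (E_self -
#'   E_friend, ms) repeated across rows.
#' @examples
#' coh <- generate_cohort(2, 2, seed = 1)
#' response_efficiency(coh$trials)
#' @export
response_efficiency <- function(trials, trim = NULL) {
  assert_cols(trials, c("subject", "label", "match", "response", "rt_ms",
                        "accuracy"), "trials")
  trials$.rt_ok <- if (is.null(trim)) TRUE else {
    trials$rt_ms >= trim[1] & trials$rt_ms <= trim[2]
  }
  eff <- trials |>
    dplyr::filter(.data$match == "match", !is.na(.data$response)) |>
    dplyr::group_by(.data$subject, .data$label) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      mean_rt_ms = mean(.data$rt_ms[.data$accuracy == 1 & .data$.rt_ok]),
      accuracy = mean(.data$accuracy),
      .groups = "drop"
    ) |>
    dplyr::mutate(efficiency = ifelse(.data$accuracy > 0,
                                      .data$mean_rt_ms / .data$accuracy,
                                      NA_real_))
  diffs <- eff |>
    dplyr::filter(.data$label %in% c("self", "friend")) |>
    dplyr::select("subject", "label", "efficiency") |>
    tidyr::pivot_wider(names_from = "label", values_from = "efficiency") |>
    dplyr::mutate(diff_score = .data$self - .data$friend) |>
    dplyr::select("subject", "diff_score")
  dplyr::left_join(eff, diffs, by = "subject")
}

#' Classify friend- and self-prioritization groups
#'
#' Subjects with a positive efficiency difference score (E_self - E_friend
#' > 0) form the friend-prioritization (FP) group. As a size-matched control,
#' the same number of subjects with the most negative difference scores
#' (most prominent self-prioritization) form the SP group; everyone else —
#' including exact zeros and undefined scores — is unassigned. Ties at the SP
#' selection boundary are broken by subject id order.
#'
#' @param eff Output of [response_efficiency()], or any tibble with `subject`
#'   and `diff_score`.
#' @return Tibble, one row per subject: `subject`, `diff_score`, `group`
#'   (factor FP/SP/unassigned).
#' @export
classify_groups <- function(eff) {
  assert_cols(eff, c("subject", "diff_score"), "eff")
  d <- dplyr::distinct(eff, .data$subject, .data$diff_score) |>
    dplyr::arrange(.data$subject)
  if (anyDuplicated(d$subject)) abort("conflicting diff_score values per subject")
  if (sum(!is.na(d$diff_score)) < 2) {
    abort("need at least 2 subjects with defined diff_score")
  }
  fp <- d$subject[!is.na(d$diff_score) & d$diff_score > 0]
  if (length(fp) == 0) abort("no subject has diff_score > 0: FP group is empty")
  neg <- d |>
    dplyr::filter(!is.na(.data$diff_score), .data$diff_score < 0) |>
    dplyr::arrange(.data$diff_score, .data$subject)
  if (nrow(neg) < length(fp)) {
    abort(sprintf(
      "cannot select an SP group of size %d: only %d subjects have diff_score < 0",
      length(fp), nrow(neg)))
  }
  sp <- neg$subject[seq_along(fp)]
  d$group <- factor(ifelse(d$subject %in% fp, "FP",
                           ifelse(d$subject %in% sp, "SP", "unassigned")),
                    levels = c("FP", "SP", "unassigned"))
  d
}

#' Bootstrap distributions of condition means
#'
#' Resamples subjects with replacement within each condition cell (and group,
#' when a `group` column is present) and records the resampled mean accuracy
#' and mean correct-trial RT, suitable for a scatter display of the
#' population means.
#'
#' @param trials Trial tibble; per-subject condition means are the resampling
#'   unit.
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Optional integer seed.
#' @param match_only Keep only the matching condition (default TRUE).
#' @return A tibble of class `prio_boot`: group columns, `label`, `boot`,
#'   `mean_accuracy`, `mean_rt_ms`.
#' @export
bootstrap_condition_means <- function(trials, n_boot = 1000, seed = NULL,
                                      match_only = TRUE) {
  assert_cols(trials, c("subject", "label", "match", "rt_ms", "accuracy"),
              "trials")
  assert_scalar_number(n_boot, "n_boot", lower = 1)
  if (!is.null(seed)) set.seed(seed)
  df <- trials |> dplyr::filter(!is.na(.data$accuracy))
  if (match_only) df <- dplyr::filter(df, .data$match == "match")
  grp_cols <- intersect("group", names(df))
  per_subj <- df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grp_cols, "label", "subject")))) |>
    dplyr::summarise(acc = mean(.data$accuracy),
                     rt = mean(.data$rt_ms[.data$accuracy == 1]),
                     .groups = "drop")
  cells <- per_subj |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grp_cols, "label"))))
  if (any(dplyr::group_size(cells) == 0)) abort("empty condition cell")
  out <- cells |>
    dplyr::group_modify(function(cell, key) {
      n <- nrow(cell)
      purrr::map_dfr(seq_len(n_boot), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        tibble(boot = b, mean_accuracy = mean(cell$acc[idx]),
               mean_rt_ms = mean(cell$rt[idx]))
      })
    }) |>
    dplyr::ungroup()
  class(out) <- c("prio_boot", class(out))
  out
}

#' Signal detection theory indices per subject and label
#'
#' Hits are "yes" responses to matching pairs, false alarms "yes" responses
#' to nonmatching pairs. Sensitivity d' = qnorm(H) - qnorm(F); response bias
#' beta = exp((qnorm(F)^2 - qnorm(H)^2) / 2), where values below 1 indicate a
#' bias toward "yes". Extreme rates of 0 or 1 are corrected before the
#' quantile transform: by default replaced with 1/(2N) and 1 - 1/(2N); the
#' log-linear alternative adds 0.5 to both counts and 1 to both cell sizes.
#' Slow (no-response) trials are excluded.
#'
#' @param trials Trial tibble with `subject`, `label`, `match`, `response`.
#' @param correction `"half"` (1/(2N) rule, default) or `"loglinear"`.
#' @return Tibble per subject x label: `n_match`, `n_nonmatch`, `hit_rate`,
#'   `fa_rate` (corrected rates), `d_prime`, `beta`.
#' @export
sdt_indices <- function(trials, correction = c("half", "loglinear")) {
  correction <- match.arg(correction)
  assert_cols(trials, c("subject", "label", "match", "response"), "trials")
  counts <- trials |>
    dplyr::filter(!is.na(.data$response)) |>
    dplyr::group_by(.data$subject, .data$label, .data$match) |>
    dplyr::summarise(n = dplyr::n(), yes = sum(.data$response == "yes"),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "match", values_from = c("n", "yes"))
  need <- c("n_match", "n_nonmatch", "yes_match", "yes_nonmatch")
  if (!all(need %in% names(counts)) || anyNA(counts[need])) {
    abort("every subject x label cell needs both match and nonmatch trials")
  }
  rate <- function(yes, n) {
    if (correction == "loglinear") return((yes + 0.5) / (n + 1))
    r <- yes / n
    pmin(pmax(r, 1 / (2 * n)), 1 - 1 / (2 * n))
  }
  counts |>
    dplyr::mutate(
      hit_rate = rate(.data$yes_match, .data$n_match),
      fa_rate = rate(.data$yes_nonmatch, .data$n_nonmatch),
      d_prime = qnorm(.data$hit_rate) - qnorm(.data$fa_rate),
      beta = exp((qnorm(.data$fa_rate)^2 - qnorm(.data$hit_rate)^2) / 2)
    ) |>
    dplyr::select("subject", "label", "n_match", "n_nonmatch",
                  "hit_rate", "fa_rate", "d_prime", "beta")
}
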