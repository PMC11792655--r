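#' Trait and economic-game scores for a simulated cohort
#'
#' Generates interpersonal trait scores (four empathy subscales, two
#' self-construal scores, four friendship indices) and one-shot economic-game
#' contributions (trust-game send out of an endowment of 10 monetary units;
#' public-goods contribution out of 80) for each cohort subject. All
#' variables load on a latent interpersonal factor that is correlated with
#' the subject's friend-priority magnitude (the generative drift advantage
#' v(friend, match) - v(self, match)) at a level calibrated so the
#' population canonical correlation between the trait block and a
#' well-measured friend-priority criterion equals `canonical_rho`; empathic
#' concern, closeness and likability carry the largest loadings. With
#' `canonical_rho = 0` traits and games are independent of behavior.
#'
#' @param cohort A [generate_cohort()] result (or any list with `truths`).
#' @param canonical_rho Target canonical correlation in [0, 1); must not
#'   exceed the trait block's factor saturation (about 0.82 with the default
#'   loadings).
#' @param seed Optional integer seed.
#' @return Tibble, one row per subject: `subject`, `group_truth`,
#'   `friend_priority`, ten trait columns, `trust_send` (0-10),
#'   `pgg_contribution` (0-80).
#' @examples
#' coh <- generate_cohort(3, 3, seed = 1)
#' generate_traits_and_games(coh, canonical_rho = 0.33, seed = 2)
#' @export
generate_traits_and_games <- function(cohort, canonical_rho = 0.33,
                                      seed = NULL) {
  truths <- cohort$truths %||% cohort
  if (!all(vapply(truths, inherits, logical(1), "prio_truth"))) {
    abort("`cohort` must contain prio_truth subjects")
  }
  assert_scalar_number(canonical_rho, "canonical_rho", 0, 1 - 1e-9)
  if (!is.null(seed)) set.seed(seed)

  loadings <- c(
    empathic_concern = 0.8, perspective_taking = 0.3, fantasy = 0.2,
    personal_distress = 0.1, independent_sc = 0.1, interdependent_sc = 0.3,
    friend_time = 0.1, friend_closeness = 0.7, friend_likability = 0.7,
    friend_familiarity = 0.4
  )
  rho_x <- sqrt(sum(loadings^2) / (1 + sum(loadings^2)))
  if (canonical_rho >= rho_x) {
    abort(sprintf(
      "canonical_rho = %.2f exceeds the trait block's factor saturation (%.2f)",
      canonical_rho, rho_x))
  }
  cmix <- canonical_rho / rho_x

  n <- length(truths)
  m <- vapply(truths, function(tr) {
    tr$v_map[["friend_match"]] - tr$v_map[["self_match"]]
  }, numeric(1))
  m_std <- if (sd(m) > 0) as.numeric(scale(m)) else rep(0, n)
  xi <- cmix * m_std + sqrt(1 - cmix^2) * rnorm(n)

  clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  traits <- purrr::imap_dfc(as.list(loadings), function(lam, nm) {
    raw <- lam * xi + rnorm(n)
    out <- if (grepl("^friend_", nm)) {
      if (nm == "friend_time") clip(round(60 + 18 * raw), 1, 180) # months
      else clip(round(4.5 + 1.0 * raw), 1, 7)                     # Likert
    } else {
      clip(round(14 + 4 * raw), 0, 28)                            # IRI-like
    }
    tibble(!!nm := as.numeric(out))
  })

  trust <- clip(round(5 + 2 * (0.6 * xi + rnorm(n))), 0, 10)
  pgg <- clip(round(40 + 15 * (0.6 * xi + rnorm(n))), 0, 80)

  dplyr::bind_cols(
    tibble(
      subject = vapply(truths, `[[`, "", "subject_id"),
      group_truth = vapply(truths, `[[`, "", "latent_group"),
      friend_priority = m
    ),
    traits,
    tibble(trust_send = as.numeric(trust), pgg_contribution = as.numeric(pgg))
  )
}
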