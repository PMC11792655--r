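#' Trial-by-trial regression of a neural covariate onto a decision parameter
#'
#' Hierarchical linear link between a standardized single-trial covariate
#' (e.g. an ERP amplitude) and the drift rate, v_i = v0 + beta * x_i, or the
#' boundary separation on the log scale, a_i = exp(log a0 + beta * x_i).
#' Per-subject intercepts, slopes and nuisance parameters (boundary or
#' drift, starting point, non-decision time) are Normal around group means;
#' the trial likelihood is the same outlier-mixture Wiener density used by
#' [fit_hddm()]. The covariate is standardized (mean 0, sd 1) before
#' fitting, so the slope is per-sd of the covariate.
#'
#' @param trials Trial tibble with `subject`, `response`, `rt_ms`, and the
#'   covariate column.
#' @param covariate Name of the trial-wise covariate column.
#' @param target `"v"` (drift rate) or `"a"` (boundary separation).
#' @param condition Optional filter expression evaluated in `trials` (e.g.
#'   `label == "self" & match == "match"`).
#' @param n_samples,burn_in MCMC length (total / discarded).
#' @param outlier_prob Contaminant mixture proportion.
#' @param seed Optional integer seed.
#' @param eps Wiener density truncation tolerance.
#' @return Object of class `prio_neural`: group-level slope draws plus
#'   `p_beta_pos` / `p_beta_neg`, the posterior probabilities of a positive /
#'   negative coupling. `tidy()` summarises the group-level parameters.
#' @export
fit_neural_regression <- function(trials, covariate, target = c("v", "a"),
                                  condition = NULL, n_samples = 1500,
                                  burn_in = 500, outlier_prob = 0.05,
                                  seed = NULL, eps = 1e-7) {
  target <- match.arg(target)
  assert_cols(trials, c("subject", "response", "rt_ms", covariate), "trials")
  if (n_samples <= burn_in) abort("`n_samples` must exceed `burn_in`")
  df <- dplyr::filter(trials, !is.na(.data$response), !is.na(.data$rt_ms),
                      !is.na(.data[[covariate]]))
  cond <- rlang::enquo(condition)
  if (!rlang::quo_is_null(cond)) df <- dplyr::filter(df, !!cond)
  if (nrow(df) == 0) abort("no scoreable trials after filtering")
  x <- df[[covariate]]
  if (sd(x) == 0) abort("constant covariate: the slope is unidentifiable")
  x <- as.numeric(scale(x))

  subjects <- sort(unique(df$subject))
  rt <- df$rt_ms / 1000
  upper <- as.integer(df$response == "yes")
  subj_idx <- match(df$subject, subjects) - 1L
  rng <- range(rt)
  if (diff(rng) <= 0) abort("degenerate RT range")
  log_contam <- log(0.5) - log(diff(rng))

  # par0, beta, log a (or spare drift), logit z, log t0
  prior_mean <- if (target == "v") c(0, 0, log(1.5), 0, log(0.25))
  else c(log(1.5), 0, 0, 0, log(0.25))
  prior_mean[5] <- min(prior_mean[5], log(max(0.9 * rng[1], 1e-3)))
  prior_sd <- c(2, 1, 1, 1, 1)
  sigma_scale <- c(0.5, 0.3, 0.5, 0.5, 0.3)
  slice_w <- c(0.5, 0.3, 0.3, 0.5, 0.3)
  if (target == "a") { # par0 is log a0; nuisance slot 3 is the drift
    prior_sd <- c(1, 0.5, 2, 1, 1)
    slice_w <- c(0.3, 0.2, 0.5, 0.5, 0.3)
  }

  if (!is.null(seed)) set.seed(seed)
  raw <- neural_reg_sampler_cpp(rt, upper, subj_idx, x,
                                as.integer(target == "a"),
                                prior_mean, prior_sd, sigma_scale, slice_w,
                                outlier_prob, log_contam, eps,
                                as.integer(n_samples), as.integer(burn_in))
  par_names <- if (target == "v") {
    c("v0", "beta", "log_a", "logit_z", "log_t0")
  } else {
    c("log_a0", "beta", "v", "logit_z", "log_t0")
  }
  colnames(raw$mu) <- par_names
  colnames(raw$sigma) <- par_names
  keep <- seq.int(burn_in + 1, n_samples)
  beta <- raw$mu[keep, "beta"]
  structure(
    list(draws = raw, target = target, covariate = covariate,
         subjects = subjects, n_samples = n_samples, burn_in = burn_in,
         p_beta_pos = mean(beta > 0), p_beta_neg = mean(beta < 0),
         beta_mean = mean(beta)),
    class = "prio_neural"
  )
}

#' @export
print.prio_neural <- function(x, ...) {
  cat(sprintf("<prio_neural> %s ~ %s (%d subjects)\n",
              x$target, x$covariate, length(x$subjects)))
  cat(sprintf("  beta = %.3f; P(beta > 0) = %.3f, P(beta < 0) = %.3f\n",
              x$beta_mean, x$p_beta_pos, x$p_beta_neg))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.prio_neural <- function(x, ...) {
  keep <- seq.int(x$burn_in + 1, x$n_samples)
  m <- x$draws$mu[keep, , drop = FALSE]
  tibble(
    term = colnames(m),
    estimate = colMeans(m),
    std.error = apply(m, 2, sd),
    conf.low = apply(m, 2, quantile, 0.025),
    conf.high = apply(m, 2, quantile, 0.975)
  )
}

#' @exportS3Method generics::glance
glance.prio_neural <- function(x, ...) {
  tibble(target = x$target, covariate = x$covariate,
         beta = x$beta_mean, p_beta_pos = x$p_beta_pos,
         p_beta_neg = x$p_beta_neg, n_subjects = length(x$subjects))
}
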