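# transformed <-> natural scales used by the sampler (v, a, z, t0)
ddm_to_natural <- list(
  v = identity, a = exp, z = stats::plogis, t0 = exp
)

# cell labels implied by a spec for one parameter type (group excluded:
# group enters through the group dimension of the group-level means)
ddm_cell_levels <- function(factors) {
  labels <- c("self", "friend", "stranger")
  matches <- c("match", "nonmatch")
  has_l <- "label" %in% factors
  has_m <- "match" %in% factors
  if (has_l && has_m) as.vector(outer(labels, matches, paste, sep = "_"))
  else if (has_l) labels
  else if (has_m) matches
  else "all"
}

ddm_trial_cells <- function(trials, factors, group = NULL) {
  has_l <- "label" %in% factors
  has_m <- "match" %in% factors
  lev <- ddm_cell_levels(factors)
  key <- if (has_l && has_m) paste(trials$label, trials$match, sep = "_")
  else if (has_l) trials$label
  else if (has_m) trials$match
  else rep("all", nrow(trials))
  if (!is.null(group)) { # pooled fits: group becomes part of the cell
    lev <- as.vector(outer(levels(group), lev, paste, sep = "."))
    key <- paste(as.character(group), key, sep = ".")
  }
  idx <- match(key, lev)
  if (anyNA(idx)) abort("trial labels/match levels outside self/friend/stranger x match/nonmatch")
  list(index = idx - 1L, levels = lev)
}

#' Fit a hierarchical drift-diffusion model
#'
#' MCMC estimation of group- and subject-level DDM parameters under a
#' [ddm_spec()] dependency structure, with a "yes" response absorbed at the
#' upper and a "no" at the lower boundary. The per-trial likelihood is the
#' mixture (1 - p_out) x Wiener first-passage density + p_out x uniform
#' contaminant over the observed RT range. Sampling is component-wise slice
#' sampling within Gibbs on unconstrained scales (v, log a, logit z, log t0);
#' subject parameters are Normal around group means with Half-Normal
#' group sds. Slow (no-response) trials are dropped. The desk-scale default
#' is 2000 samples with 500 burn-in; the paper-scale preset of
#' [pipeline_config()] is 10000/1000.
#'
#' @param trials Trial tibble with `subject`, `label`, `match`, `response`,
#'   `rt_ms`, and — when the spec uses the group factor — a `group` or
#'   `group_truth` column.
#' @param spec A [ddm_spec()].
#' @param n_samples Total MCMC samples (including burn-in).
#' @param burn_in Samples discarded from the front of the chain.
#' @param seed Optional integer seed.
#' @param eps Wiener density truncation tolerance.
#' @return Object of class `prio_hddm` with posterior draws, DIC components
#'   (`dic$dic`, `$dbar`, `$pd`), split R-hat per group-level parameter, and
#'   a convergence flag. `tidy()` summarises group-level parameters on the
#'   natural scale; `glance()` reports the DIC.
#' @examples
#' \donttest{
#' coh <- generate_cohort(2, 2, seed = 1)
#' fit <- fit_hddm(coh$trials, ddm_spec(), n_samples = 300, burn_in = 100,
#'                 seed = 2)
#' glance(fit)
#' }
#' @export
fit_hddm <- function(trials, spec = ddm_spec(), n_samples = 2000,
                     burn_in = 500, seed = NULL, eps = 1e-7) {
  stopifnot(inherits(spec, "prio_ddm_spec"))
  assert_cols(trials, c("subject", "label", "match", "response", "rt_ms"),
              "trials")
  if (n_samples <= burn_in) abort("`n_samples` must exceed `burn_in`")
  df <- dplyr::filter(trials, !is.na(.data$response), !is.na(.data$rt_ms))
  if (nrow(df) == 0) abort("no scoreable trials")
  uses_group <- vapply(c("v", "a", "z", "t0"),
                       function(p) "group" %in% spec[[p]], logical(1))
  grp_col <- intersect(c("group", "group_truth"), names(df))[1]
  if (any(uses_group) && is.na(grp_col)) {
    abort("spec uses the group factor but trials have no group/group_truth column")
  }
  pooled <- !spec$hierarchical
  if (pooled) {
    # pooled estimation: all trials share one parameter set per likelihood
    # cell; the group factor is folded into the cell index so the dependency
    # structure enters the likelihood directly
    trial_group <- if (is.na(grp_col)) factor(rep("all", nrow(df)))
    else factor(as.character(df[[grp_col]]))
    df$subject <- "pooled"
  }
  subjects <- sort(unique(df$subject))
  if (spec$hierarchical && length(subjects) < 2) {
    abort("hierarchical estimation needs at least 2 subjects")
  }
  subj_group <- if (!pooled && !is.na(grp_col)) {
    g <- df[[grp_col]][match(subjects, df$subject)]
    factor(as.character(g))
  } else {
    factor(rep("all", length(subjects)))
  }
  groups <- levels(subj_group)

  rt <- df$rt_ms / 1000
  upper <- as.integer(df$response == "yes")
  subj_idx <- match(df$subject, subjects) - 1L
  cells <- lapply(seq_len(4), function(p) {
    nm <- c("v", "a", "z", "t0")[p]
    ddm_trial_cells(df, spec[[nm]],
                    group = if (pooled && uses_group[p]) trial_group)
  })
  K <- vapply(cells, function(cc) length(cc$levels), integer(1))
  if (pooled) uses_group <- rep(FALSE, 4)

  rng <- range(rt)
  if (diff(rng) <= 0) abort("degenerate RT range")
  log_contam <- log(0.5) - log(diff(rng))

  prior_mean <- c(0, log(1.5), 0, log(0.25))
  prior_sd <- c(2, 1, 1, 1)
  sigma_scale <- c(0.5, 0.5, 0.5, 0.3)
  slice_w <- c(0.5, 0.3, 0.5, 0.3)
  # keep the t0 starting value below the fastest response
  prior_mean[4] <- min(prior_mean[4], log(max(0.9 * rng[1], 1e-3)))

  init_mu <- purrr::map2(seq_len(4), K, function(p, k) {
    gp <- if (uses_group[p]) length(groups) else 1L
    matrix(prior_mean[p], gp, k)
  })

  if (!is.null(seed)) set.seed(seed)
  raw <- hddm_sampler_cpp(rt, upper, subj_idx,
                          as.integer(subj_group) - 1L,
                          lapply(cells, `[[`, "index"), K,
                          as.integer(uses_group), init_mu,
                          prior_mean, prior_sd, sigma_scale, slice_w,
                          spec$outlier_prob, log_contam, eps,
                          as.integer(n_samples), as.integer(burn_in),
                          as.integer(pooled))

  par_names <- c("v", "a", "z", "t0")
  mu <- setNames(vector("list", 4), par_names)
  sigma <- setNames(vector("list", 4), par_names)
  theta <- setNames(vector("list", 4), par_names)
  for (p in seq_len(4)) {
    gp <- if (uses_group[p]) groups else "all"
    cn <- as.vector(t(outer(gp, cells[[p]]$levels, paste, sep = ":")))
    m <- raw$mu[[p]]
    colnames(m) <- cn
    mu[[par_names[p]]] <- m
    s <- raw$sigma[[p]]
    colnames(s) <- cells[[p]]$levels
    sigma[[par_names[p]]] <- s
    th <- raw$theta[[p]]
    colnames(th) <- as.vector(t(outer(subjects, cells[[p]]$levels,
                                      paste, sep = ":")))
    theta[[par_names[p]]] <- th
    if (pooled) { # the sampled likelihood cells are the reported parameters
      m <- th
      colnames(m) <- paste("all", cells[[p]]$levels, sep = ":")
      mu[[par_names[p]]] <- m
    }
  }

  keep <- seq.int(burn_in + 1, n_samples)
  dbar <- mean(raw$deviance[keep])
  pd <- dbar - raw$dev_at_mean
  dic <- dbar + pd

  rhat <- purrr::map_dfr(par_names, function(p) {
    m <- mu[[p]][keep, , drop = FALSE]
    tibble(parameter = p, cell = colnames(m),
           rhat = apply(m, 2, split_rhat))
  })
  converged <- all(is.finite(rhat$rhat)) && max(rhat$rhat) <= 1.1
  if (!converged) {
    warn(sprintf("split R-hat above 1.1 for %d group-level parameter(s)",
                 sum(rhat$rhat > 1.1, na.rm = TRUE)))
  }

  structure(
    list(draws = list(mu = mu, sigma = sigma, theta = theta,
                      deviance = raw$deviance),
         spec = spec, subjects = subjects, groups = groups,
         uses_group = uses_group,
         cells = setNames(lapply(cells, `[[`, "levels"), par_names),
         n_samples = n_samples, burn_in = burn_in,
         priors = list(mean = prior_mean, sd = prior_sd,
                       sigma_scale = sigma_scale),
         dic = list(dic = dic, dbar = dbar, pd = pd,
                    dev_at_mean = raw$dev_at_mean),
         rhat = rhat, converged = converged,
         data_fingerprint = c(n = nrow(df), rt_sum = round(sum(rt), 6))),
    class = "prio_hddm"
  )
}

# split R-hat of a single chain (two half-chains)
split_rhat <- function(x) {
  n <- floor(length(x) / 2)
  ch <- cbind(x[seq_len(n)], x[seq.int(length(x) - n + 1, length(x))])
  m <- ncol(ch)
  means <- colMeans(ch)
  W <- mean(apply(ch, 2, var))
  B <- n * var(means)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' @export
print.prio_hddm <- function(x, ...) {
  cat(sprintf("<prio_hddm> %s: %d subjects, %d samples (%d burn-in)\n",
              x$spec$name, length(x$subjects), x$n_samples, x$burn_in))
  cat(sprintf("  DIC %.1f (Dbar %.1f, pD %.1f); max split R-hat %.3f%s\n",
              x$dic$dic, x$dic$dbar, x$dic$pd, max(x$rhat$rhat),
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.prio_hddm <- function(x, ...) {
  keep <- seq.int(x$burn_in + 1, x$n_samples)
  purrr::map_dfr(names(x$draws$mu), function(p) {
    m <- x$draws$mu[[p]][keep, , drop = FALSE]
    nat <- ddm_to_natural[[p]](m)
    parts <- strsplit(colnames(m), ":", fixed = TRUE)
    rh <- x$rhat[x$rhat$parameter == p, ]
    tibble(
      parameter = p,
      group = vapply(parts, `[[`, "", 1),
      cell = vapply(parts, `[[`, "", 2),
      estimate = colMeans(nat),
      std.error = apply(nat, 2, sd),
      conf.low = apply(nat, 2, quantile, 0.025),
      conf.high = apply(nat, 2, quantile, 0.975),
      rhat = rh$rhat[match(colnames(m), rh$cell)]
    )
  })
}

#' @exportS3Method generics::glance
glance.prio_hddm <- function(x, ...) {
  tibble(model = x$spec$name, dic = x$dic$dic, dbar = x$dic$dbar,
         pd = x$dic$pd, n_subjects = length(x$subjects),
         n_samples = x$n_samples, burn_in = x$burn_in,
         converged = x$converged)
}

#' Posterior probability of a directional parameter contrast
#'
#' Fraction of post-burn-in draws in which the group-level mean of one
#' parameter cell exceeds (or undershoots) another's — e.g. P(v_friend-match
#' > v_self-match). Contrasting a cell with itself under a strict inequality
#' gives 0.
#'
#' @param fit A [fit_hddm()] result.
#' @param parameter One of `"v"`, `"a"`, `"z"`, `"t0"`.
#' @param contrast Length-2 character: the two cell names (see
#'   `fit$cells[[parameter]]`).
#' @param direction `"greater"` tests cell1 > cell2, `"less"` cell1 < cell2.
#' @param group Group level the contrast refers to (required when the
#'   parameter is group-dependent and several groups were fit).
#' @return A proportion in [0, 1].
#' @export
p_bayes <- function(fit, parameter, contrast,
                    direction = c("greater", "less"), group = NULL) {
  stopifnot(inherits(fit, "prio_hddm"))
  direction <- match.arg(direction)
  parameter <- match.arg(parameter, c("v", "a", "z", "t0"))
  if (length(contrast) != 2) abort("`contrast` must name two cells")
  p_idx <- match(parameter, c("v", "a", "z", "t0"))
  g <- if (fit$uses_group[p_idx]) {
    if (length(fit$groups) > 1 && is.null(group)) {
      abort("`group` is required for a group-dependent parameter")
    }
    group %||% fit$groups[1]
  } else "all"
  cols <- paste(g, contrast, sep = ":")
  m <- fit$draws$mu[[parameter]]
  missing <- setdiff(cols, colnames(m))
  if (length(missing) > 0) {
    abort(sprintf("unknown cell(s): %s", paste(missing, collapse = ", ")))
  }
  keep <- seq.int(fit$burn_in + 1, fit$n_samples)
  d <- m[keep, cols[1]] - m[keep, cols[2]]
  if (direction == "greater") mean(d > 0) else mean(d < 0)
}

#' Rank fitted models by DIC
#'
#' @param fits A list of [fit_hddm()] results fitted to the same data.
#' @return Tibble ordered by ascending DIC (`delta_dic` relative to the
#'   winner).
#' @export
compare_models <- function(fits) {
  if (length(fits) < 2) abort("need at least two fitted models")
  ok <- vapply(fits, inherits, logical(1), "prio_hddm")
  if (!all(ok)) abort("all elements must be prio_hddm fits")
  fps <- vapply(fits, function(f) paste(f$data_fingerprint, collapse = "/"),
                character(1))
  if (length(unique(fps)) != 1) {
    abort("models were fitted to different datasets")
  }
  out <- purrr::map_dfr(fits, glance)
  out |>
    dplyr::arrange(.data$dic) |>
    dplyr::mutate(delta_dic = .data$dic - .data$dic[1], rank = dplyr::row_number())
}
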