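#' Cluster-based permutation test over time x electrode maps
#'
#' Paired design on per-subject condition-difference maps: a one-sample t is
#' computed at every (channel, time) point; points exceeding the two-sided
#' cluster-forming threshold (per-point alpha `alpha_forming`) are grouped
#' into signed clusters under channel adjacency x consecutive-time
#' connectivity; each observed cluster's mass (summed t) is compared to the
#' permutation distribution of the maximum absolute cluster mass under
#' random per-subject sign flips (positive and negative clusters pooled,
#' two-sided). Zero-variance points are excluded from clusters.
#'
#' @param diffs Numeric array, subjects x channels x time, of condition
#'   differences; `dimnames[[2]]` must name the channels.
#' @param adjacency Channel adjacency from [build_adjacency()].
#' @param alpha_forming Per-point two-sided cluster-forming alpha.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional integer seed.
#' @param times Optional time axis (ms) for reporting.
#' @return A tibble of class `prio_clusters`, one row per observed cluster
#'   (`cluster`, `sign`, `mass`, `n_points`, `p_perm`, time range, channel
#'   list), with the t map, cluster labels and null distribution attached as
#'   attributes `t_map`, `labels`, `null_max`.
#' @export
cluster_permutation <- function(diffs, adjacency, alpha_forming = 0.05,
                                n_perm = 1000, seed = NULL, times = NULL) {
  if (length(dim(diffs)) != 3) abort("`diffs` must be subjects x channels x time")
  S <- dim(diffs)[1]
  if (S < 2) abort("need at least 2 subjects")
  channels <- dimnames(diffs)[[2]]
  if (is.null(channels)) abort("`diffs` must carry channel dimnames")
  tcrit <- qt(1 - alpha_forming / 2, df = S - 1)
  adj_idx <- adjacency_index(adjacency, channels)
  if (!is.null(seed)) set.seed(seed)
  # engine expects channels-fastest ordering: pass (S, C, T) array directly
  res <- cluster_perm_cpp(aperm(diffs, c(1, 2, 3)), dim(diffs), adj_idx,
                          tcrit, as.integer(n_perm))
  nclu <- length(res$mass)
  times <- times %||% seq_len(dim(diffs)[3])
  out <- if (nclu == 0) {
    tibble(cluster = integer(0), sign = integer(0), mass = numeric(0),
           n_points = integer(0), p_perm = numeric(0),
           time_lo = numeric(0), time_hi = numeric(0), channels = list())
  } else {
    purrr::map_dfr(seq_len(nclu), function(i) {
      pts <- which(res$labels == i, arr.ind = TRUE)
      tibble(
        cluster = i, sign = res$sign[i], mass = res$mass[i],
        n_points = res$n_points[i],
        p_perm = (sum(res$null_max >= abs(res$mass[i])) + 1) / (n_perm + 1),
        time_lo = min(times[pts[, 2]]), time_hi = max(times[pts[, 2]]),
        channels = list(sort(unique(channels[pts[, 1]])))
      )
    }) |>
      dplyr::arrange(.data$p_perm, dplyr::desc(abs(.data$mass)))
  }
  class(out) <- c("prio_clusters", class(out))
  attr(out, "t_map") <- res$t
  attr(out, "labels") <- res$labels
  attr(out, "null_max") <- res$null_max
  attr(out, "tcrit") <- tcrit
  attr(out, "n_perm") <- n_perm
  out
}

#' Point-by-point correlation with a consecutive-run criterion
#'
#' Rank (Spearman) correlation, at every time point, between per-subject
#' differential signals and a per-subject scalar; reports maximal runs of at
#' least `run_length` consecutive points with uncorrected p below `alpha`.
#' At the native 1000 Hz sampling the default 100-point criterion spans
#' 100 ms.
#'
#' @param signals Numeric matrix, subjects x time.
#' @param scalar Numeric vector, one value per subject.
#' @param run_length Minimum run of consecutive significant points.
#' @param alpha Per-point significance level.
#' @param times Optional time axis (ms).
#' @return List of class `prio_runs`: `pointwise` tibble (`time`, `rho`,
#'   `p`) and `runs` tibble (`start`, `end`, `n_points`, `mean_rho`).
#' @export
pointwise_correlation <- function(signals, scalar, run_length = 100,
                                  alpha = 0.05, times = NULL) {
  if (!is.matrix(signals)) abort("`signals` must be a subjects x time matrix")
  n <- nrow(signals)
  if (n < 5) abort("need at least 5 subjects")
  if (length(scalar) != n) abort("`scalar` must have one value per subject")
  if (sd(scalar) == 0) abort("constant scalar: correlation undefined")
  times <- times %||% seq_len(ncol(signals))
  ry <- rank(scalar)
  rho <- apply(signals, 2, function(col) cor(rank(col), ry))
  # t approximation for the rank correlation p-value
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  sig <- p < alpha
  runs <- rle(as.vector(sig))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- which(runs$values & runs$lengths >= run_length)
  run_tbl <- purrr::map_dfr(keep, function(i) {
    idx <- seq.int(starts[i], ends[i])
    tibble(start = times[starts[i]], end = times[ends[i]],
           n_points = length(idx), mean_rho = mean(rho[idx]))
  })
  structure(list(pointwise = tibble(time = times, rho = rho, p = p),
                 runs = run_tbl, run_length = run_length, alpha = alpha),
            class = "prio_runs")
}

#' @export
print.prio_runs <- function(x, ...) {
  cat(sprintf("<prio_runs> %d time points; %d run(s) of >= %d consecutive p < %g\n",
              nrow(x$pointwise), nrow(x$runs), x$run_length, x$alpha))
  if (nrow(x$runs) > 0) print(as.data.frame(x$runs), row.names = FALSE)
  invisible(x)
}

#' Window-averaged brain-behavior correlation
#'
#' Spearman correlation between per-subject differential power (averaged
#' over a window) and per-subject differential drift rates.
#'
#' @param diff_power,diff_drift Paired numeric vectors (n >= 5).
#' @param method `"asymptotic"` (t approximation) or `"permutation"`.
#' @param n_perm Permutations when `method = "permutation"`.
#' @param seed Optional integer seed.
#' @return Tibble with `rho`, `p.value`, `n`, `method`.
#' @export
window_correlation <- function(diff_power, diff_drift,
                               method = c("asymptotic", "permutation"),
                               n_perm = 1000, seed = NULL) {
  method <- match.arg(method)
  n <- length(diff_power)
  if (length(diff_drift) != n) abort("inputs must be paired")
  if (n < 5) abort("need at least 5 pairs")
  if (length(unique(diff_power)) == 1 || length(unique(diff_drift)) == 1) {
    abort("ties-only input: rank correlation undefined")
  }
  rho <- cor(diff_power, diff_drift, method = "spearman")
  p <- if (method == "asymptotic") {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    2 * pt(-abs(tstat), df = n - 2)
  } else {
    if (!is.null(seed)) set.seed(seed)
    null <- replicate(n_perm, cor(diff_power, sample(diff_drift),
                                  method = "spearman"))
    (sum(abs(null) >= abs(rho)) + 1) / (n_perm + 1)
  }
  tibble(rho = rho, p.value = p, n = n, method = method)
}

#' Group moderation of the power-drift coupling
#'
#' Tests whether the slope of differential drift on differential power
#' differs between groups: linear model `diff_drift ~ diff_power * group`,
#' reporting the interaction F with partial eta squared and its 90% CI.
#'
#' @param diff_power,diff_drift Paired numeric vectors.
#' @param group Two-level factor (or coercible), each level n >= 3.
#' @param ci_level Confidence level of the partial eta squared CI.
#' @return Tibble: `df1`, `df2`, `statistic`, `p.value`, `pes`, `pes_lo`,
#'   `pes_hi`, per-group slopes.
#' @export
group_moderation <- function(diff_power, diff_drift, group,
                             ci_level = 0.90) {
  n <- length(diff_power)
  if (length(diff_drift) != n || length(group) != n) {
    abort("inputs must be paired vectors of one length")
  }
  group <- factor(group)
  if (nlevels(group) != 2) abort("`group` must have exactly two levels")
  if (any(table(group) < 3)) abort("each group needs at least 3 observations")
  if (any(tapply(diff_power, group, sd) == 0)) {
    abort("singular design: constant power within a group")
  }
  fit <- lm(diff_drift ~ diff_power * group)
  an <- anova(fit)
  i <- match("diff_power:group", rownames(an))
  Fv <- an[i, "F value"]
  df1 <- an[i, "Df"]
  df2 <- an["Residuals", "Df"]
  ci <- pes_ci(Fv, df1, df2, ci_level)
  slopes <- tapply(seq_len(n), group, function(ii) {
    unname(stats::coef(lm(diff_drift[ii] ~ diff_power[ii]))[2])
  })
  tibble(df1 = df1, df2 = df2, statistic = Fv, p.value = an[i, "Pr(>F)"],
         pes = (Fv * df1) / (Fv * df1 + df2), pes_lo = ci[1], pes_hi = ci[2],
         slope_1 = slopes[[1]], slope_2 = slopes[[2]])
}
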