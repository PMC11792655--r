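#' First canonical correlation between trait and behavior blocks
#'
#' Finds the linear combinations of the two standardized variable blocks
#' with maximal correlation (the first canonical pair), via the generalized
#' eigenproblem on the cross-covariance. Loadings are reported as structure
#' correlations (correlation of each variable with its block's canonical
#' variate). The overall sign is fixed by forcing the loading of
#' `anchor` — by default the first Y column, accuracy in the standard
#' behavioral block — to be nonnegative, so larger canonical scores mean
#' better performance.
#'
#' @param x Subjects x trait-variables data frame or matrix.
#' @param y Subjects x behavior-variables data frame or matrix.
#' @param anchor Column of `y` whose loading is forced nonnegative (name or
#'   index).
#' @return Object of class `prio_cca`: `rho`, `x_loadings`, `y_loadings`,
#'   `x_scores`, `y_scores`, `n`. `glance()` gives a one-row summary.
#' @examples
#' set.seed(1)
#' u <- rnorm(100)
#' x <- sapply(1:5, function(i) u + rnorm(100))
#' y <- sapply(1:3, function(i) u + rnorm(100))
#' canonical_correlation(x, y)$rho
#' @export
canonical_correlation <- function(x, y, anchor = 1) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  if (nrow(x) != nrow(y)) abort("`x` and `y` must have the same subjects")
  n <- nrow(x)
  if (n <= max(ncol(x), ncol(y))) {
    abort("need more subjects than variables in either block")
  }
  if (anyNA(x) || anyNA(y)) abort("missing values: drop incomplete rows first")
  const <- c(colnames2(x)[apply(x, 2, sd) == 0],
             colnames2(y)[apply(y, 2, sd) == 0])
  if (length(const) > 0) {
    abort(sprintf("constant column(s): %s", paste(const, collapse = ", ")))
  }
  xs <- scale(x)
  ys <- scale(y)
  for (blk in list(xs, ys)) {
    qrb <- qr(blk)
    if (qrb$rank < ncol(blk)) {
      bad <- colnames2(blk)[-qrb$pivot[seq_len(qrb$rank)]]
      abort(sprintf("rank-deficient block; collinear column(s): %s",
                    paste(bad, collapse = ", ")))
    }
  }
  cc <- stats::cancor(xs, ys)
  wx <- cc$xcoef[, 1]
  wy <- cc$ycoef[, 1]
  sx <- as.numeric(xs %*% wx)
  sy <- as.numeric(ys %*% wy)
  rho <- cor(sx, sy)
  if (rho < 0) { # orient the variates to correlate positively
    sy <- -sy
    wy <- -wy
    rho <- -rho
  }
  y_load <- as.numeric(cor(ys, sy))
  x_load <- as.numeric(cor(xs, sx))
  ai <- if (is.character(anchor)) match(anchor, colnames2(y)) else anchor
  if (is.na(ai) || ai < 1 || ai > ncol(y)) abort("`anchor` not found in `y`")
  if (y_load[ai] < 0) { # global sign flip keeps the variates aligned
    sx <- -sx; sy <- -sy
    x_load <- -x_load; y_load <- -y_load
  }
  structure(
    list(rho = rho,
         x_loadings = setNames(x_load, colnames2(x)),
         y_loadings = setNames(y_load, colnames2(y)),
         x_scores = sx, y_scores = sy, n = n),
    class = "prio_cca"
  )
}

colnames2 <- function(m) colnames(m) %||% paste0("V", seq_len(ncol(m)))

#' @export
print.prio_cca <- function(x, ...) {
  cat(sprintf("<prio_cca> first canonical correlation rho = %.3f (n = %d)\n",
              x$rho, x$n))
  if (!is.null(x$p_perm)) {
    cat(sprintf("  permutation p = %.4g (%d permutations)\n", x$p_perm, x$n_perm))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.prio_cca <- function(x, ...) {
  dplyr::bind_rows(
    tibble(block = "x", variable = names(x$x_loadings),
           loading = unname(x$x_loadings)),
    tibble(block = "y", variable = names(x$y_loadings),
           loading = unname(x$y_loadings))
  )
}

#' @exportS3Method generics::glance
glance.prio_cca <- function(x, ...) {
  tibble(rho = x$rho, n = x$n,
         p_perm = x$p_perm %||% NA_real_,
         n_perm = x$n_perm %||% NA_integer_)
}

#' Permutation p-value for the first canonical correlation
#'
#' Re-estimates the first canonical correlation after permuting the rows of
#' `y`, `n_perm` times; p = (#\{rho_perm >= rho_obs\} + 1) / (n_perm + 1).
#'
#' @inheritParams canonical_correlation
#' @param n_perm Number of permutations (a warning below 100).
#' @param seed Optional integer seed.
#' @return The `prio_cca` object with `p_perm`, `n_perm` and the null
#'   distribution (`null_rho`) attached.
#' @export
permutation_pvalue <- function(x, y, n_perm = 1000, seed = NULL, anchor = 1) {
  if (n_perm < 100) warn("fewer than 100 permutations: p-value is coarse")
  obs <- canonical_correlation(x, y, anchor = anchor)
  if (!is.null(seed)) set.seed(seed)
  y <- as.matrix(y)
  null_rho <- vapply(seq_len(n_perm), function(b) {
    canonical_correlation(x, y[sample.int(nrow(y)), , drop = FALSE],
                          anchor = anchor)$rho
  }, numeric(1))
  obs$p_perm <- (sum(null_rho >= obs$rho) + 1) / (n_perm + 1)
  obs$n_perm <- n_perm
  obs$null_rho <- null_rho
  obs
}

#' Correlations between friend-priority behavior and economic games
#'
#' Spearman correlation between the per-subject friend-minus-self accuracy
#' difference and each game's contribution, with a bootstrap 95% CI.
#'
#' @param diff_accuracy Per-subject friend-minus-self accuracy difference.
#' @param games Data frame of per-subject game contributions (e.g.
#'   `trust_send`, `pgg_contribution`).
#' @param n_boot Bootstrap replicates for the CI.
#' @param seed Optional integer seed.
#' @return Tibble per game: `game`, `rho`, `p.value`, `conf.low`,
#'   `conf.high`, `n`.
#' @export
game_correlations <- function(diff_accuracy, games, n_boot = 1000,
                              seed = NULL) {
  games <- as.data.frame(games)
  n <- length(diff_accuracy)
  if (nrow(games) != n) abort("inputs must be paired")
  if (length(unique(diff_accuracy)) == 1) abort("constant accuracy difference")
  if (!is.null(seed)) set.seed(seed)
  purrr::map_dfr(names(games), function(g) {
    yv <- games[[g]]
    if (length(unique(yv)) == 1) abort(sprintf("constant game column '%s'", g))
    ct <- suppressWarnings(cor.test(diff_accuracy, yv, method = "spearman"))
    boots <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      suppressWarnings(cor(diff_accuracy[idx], yv[idx], method = "spearman"))
    }, numeric(1))
    ci <- quantile(boots, c(0.025, 0.975), na.rm = TRUE)
    tibble(game = g, rho = unname(ct$estimate), p.value = ct$p.value,
           conf.low = ci[[1]], conf.high = ci[[2]], n = n)
  })
}
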