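#' Mixed-design ANOVA with partial eta squared
#'
#' Classic sums-of-squares decomposition for a balanced one-within
#' (e.g. Label) by one-between (e.g. Group) design on subject-level values:
#' between-subjects effect tested against subject variance, within and
#' interaction against the subject-by-within residual. Reports partial eta
#' squared with a 90% CI from inverting the noncentral-F distribution, plus
#' Bonferroni-corrected pairwise paired contrasts of the within-factor levels
#' inside each between group.
#'
#' @param data Tibble of subject-level values, one row per subject x
#'   within-level.
#' @param dv,within,between,subject Column names (strings).
#' @param ci_level Confidence level of the partial eta squared CI.
#' @return Object of class `prio_anova`; `tidy()` returns the effect table
#'   (`term`, `df1`, `df2`, `statistic`, `p.value`, `pes`, `pes_lo`,
#'   `pes_hi`), `$contrasts` the pairwise table.
#' @examples
#' coh <- generate_cohort(3, 3, seed = 1)
#' eff <- response_efficiency(coh$trials)
#' eff$group <- sub("s0.*", "", coh$trials$group_truth[
#'   match(eff$subject, coh$trials$subject)])
#' fit <- mixed_anova(eff, dv = "accuracy", within = "label",
#'                    between = "group", subject = "subject")
#' tidy(fit)
#' @export
mixed_anova <- function(data, dv, within, between, subject,
                        ci_level = 0.90) {
  assert_cols(data, c(dv, within, between, subject), "data")
  df <- tibble(
    y = data[[dv]],
    w = factor(data[[within]]),
    b = factor(data[[between]]),
    s = factor(data[[subject]])
  )
  if (nlevels(df$w) < 2) abort("within factor needs at least 2 levels")
  if (nlevels(df$b) < 2) abort("between factor needs at least 2 levels")
  if (anyNA(df$y)) abort("missing values in the dependent variable")
  counts <- table(df$s, df$w)
  if (any(counts != 1)) abort("design must be balanced: one value per subject x level")
  if (any(table(unique(df[c("s", "b")])$b) < 2)) {
    abort("each between group needs at least 2 subjects")
  }

  fit <- aov(y ~ w * b + Error(s / w), data = df)
  sm <- summary(fit)
  tab_s <- as.data.frame(sm[["Error: s"]][[1]])
  tab_w <- as.data.frame(sm[["Error: s:w"]][[1]])
  pick <- function(tab, name) {
    i <- match(name, trimws(rownames(tab)))
    tab[i, , drop = FALSE]
  }
  rows <- list(
    c(term = between, strat = "s", name = "b"),
    c(term = within, strat = "w", name = "w"),
    c(term = paste0(within, ":", between), strat = "w", name = "w:b")
  )
  eff <- purrr::map_dfr(rows, function(r) {
    tab <- if (r[["strat"]] == "s") tab_s else tab_w
    row <- pick(tab, r[["name"]])
    res <- pick(tab, "Residuals")
    Fv <- row[["F value"]]
    df1 <- row[["Df"]]
    df2 <- res[["Df"]]
    ci <- pes_ci(Fv, df1, df2, ci_level)
    tibble(term = r[["term"]], df1 = df1, df2 = df2, statistic = Fv,
           p.value = row[["Pr(>F)"]],
           pes = (Fv * df1) / (Fv * df1 + df2),
           pes_lo = ci[1], pes_hi = ci[2])
  })

  # Bonferroni-corrected pairwise paired contrasts within each between group
  lev <- levels(df$w)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  wide <- tidyr::pivot_wider(df, names_from = "w", values_from = "y")
  contrasts <- purrr::map_dfr(levels(df$b), function(g) {
    sub <- wide[wide$b == g, ]
    purrr::map_dfr(pairs, function(pr) {
      d <- sub[[pr[1]]] - sub[[pr[2]]]
      tt <- stats::t.test(d)
      tibble(group = g, contrast = paste(pr[1], "-", pr[2]),
             estimate = mean(d), df = unname(tt$parameter),
             statistic = unname(tt$statistic), p.value = tt$p.value)
    })
  }) |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(p.adj = pmin(1, .data$p.value * length(pairs))) |>
    dplyr::ungroup()

  structure(
    list(anova = eff, contrasts = contrasts, dv = dv, within = within,
         between = between, n_subjects = nlevels(df$s), ci_level = ci_level),
    class = "prio_anova"
  )
}

# CI for partial eta squared by inverting the noncentral-F cdf
pes_ci <- function(Fv, df1, df2, level = 0.90) {
  alpha <- (1 - level) / 2
  if (!is.finite(Fv) || Fv <= 0) return(c(0, 0))
  hi_ncp <- function(target) {
    f <- function(l) {
      p <- suppressWarnings(pf(Fv, df1, df2, ncp = l))
      if (!is.finite(p)) p <- 0 # huge ncp: cdf underflows to 0
      p - target
    }
    if (f(0) < 0) return(0)
    upper <- 10
    while (f(upper) > 0 && upper < 1e7) upper <- upper * 2
    if (f(upper) > 0) return(upper)
    uniroot(f, c(0, upper))$root
  }
  lam_lo <- hi_ncp(1 - alpha)
  lam_hi <- hi_ncp(alpha)
  lam <- sort(c(lam_lo, lam_hi))
  lam / (lam + df1 + df2 + 1)
}

#' @export
print.prio_anova <- function(x, ...) {
  cat(sprintf("<prio_anova> %s ~ %s * %s (%d subjects)\n",
              x$dv, x$within, x$between, x$n_subjects))
  print(as.data.frame(x$anova), digits = 4, row.names = FALSE)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.prio_anova <- function(x, ...) x$anova

#' @exportS3Method generics::glance
glance.prio_anova <- function(x, ...) {
  tibble(n_subjects = x$n_subjects, dv = x$dv,
         interaction_F = x$anova$statistic[3],
         interaction_p = x$anova$p.value[3])
}
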