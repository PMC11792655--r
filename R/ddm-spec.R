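#' Drift-diffusion model specification
#'
#' A factor-dependency map for the four decision parameters: which of the
#' design factors (`label`, `match`, between-subjects `group`) each parameter
#' is allowed to vary over. The hypothesized full model (Model 1) lets the
#' drift rate vary over label x match x group, boundary separation and
#' starting point over label x group, and non-decision time over match x
#' group.
#'
#' @param v,a,z,t0 Character vectors of factors, subsets of the allowed sets
#'   (`v`: label/match/group; `a`, `z`: label/group; `t0`: match/group).
#' @param outlier_prob Contaminant mixture proportion, in [0, 0.5].
#' @param hierarchical Hierarchical (subject-level) estimation flag.
#' @param name Optional model name.
#' @return Object of class `prio_ddm_spec`.
#' @examples
#' ddm_spec() # Model 1
#' @export
ddm_spec <- function(v = c("label", "match", "group"),
                     a = c("label", "group"),
                     z = c("label", "group"),
                     t0 = c("match", "group"),
                     outlier_prob = 0.05, hierarchical = TRUE,
                     name = NULL) {
  allowed <- list(v = c("label", "match", "group"), a = c("label", "group"),
                  z = c("label", "group"), t0 = c("match", "group"))
  deps <- list(v = v, a = a, z = z, t0 = t0)
  for (p in names(deps)) {
    bad <- setdiff(deps[[p]], allowed[[p]])
    if (length(bad) > 0) {
      abort(sprintf("factor(s) not allowed for %s: %s", p,
                    paste(bad, collapse = ", ")))
    }
    deps[[p]] <- intersect(allowed[[p]], deps[[p]]) # canonical order
  }
  assert_scalar_number(outlier_prob, "outlier_prob", 0, 0.5)
  structure(
    list(v = deps$v, a = deps$a, z = deps$z, t0 = deps$t0,
         outlier_prob = outlier_prob, hierarchical = isTRUE(hierarchical),
         name = name %||% "custom"),
    class = "prio_ddm_spec"
  )
}

#' @export
print.prio_ddm_spec <- function(x, ...) {
  fmt <- function(f) if (length(f) == 0) "~ 1" else paste("~", paste(f, collapse = " x "))
  cat(sprintf("<prio_ddm_spec> %s\n", x$name))
  cat(sprintf("  v %s | a %s | z %s | t0 %s\n",
              fmt(x$v), fmt(x$a), fmt(x$z), fmt(x$t0)))
  cat(sprintf("  outlier mixture %.3g, %s\n", x$outlier_prob,
              if (x$hierarchical) "hierarchical" else "pooled"))
  invisible(x)
}

# group-level cells implied by a spec (for parameter counting)
spec_n_cells <- function(spec) {
  sizes <- c(label = 3, match = 2, group = 2)
  sum(vapply(c("v", "a", "z", "t0"),
             function(p) prod(sizes[spec[[p]]], 1), numeric(1)))
}

#' Enumerate the candidate model space
#'
#' Model 1 is the full hypothesized dependency structure; Models 2-15 reduce
#' it by removing hypothesized factor dependencies, first one at a time
#' (Models 2-6 and 8-11), then jointly (7 and 12-15). Model 7 removes the
#' label dependence of both boundary separation and starting point — the
#' structure used by earlier work on self-prioritization — and Model 15
#' keeps condition dependence only on the drift rate. Which dependency each
#' reduced model drops is a package convention; every reduced model has
#' fewer group-level cells than Model 1 and all 15 are pairwise distinct.
#'
#' @param outlier_prob Passed to every [ddm_spec()].
#' @return A named list of 15 `prio_ddm_spec` objects.
#' @examples
#' length(enumerate_model_space())
#' @export
enumerate_model_space <- function(outlier_prob = 0.05) {
  full <- list(v = c("label", "match", "group"), a = c("label", "group"),
               z = c("label", "group"), t0 = c("match", "group"))
  red <- function(...) {
    drops <- list(...)
    deps <- full
    for (d in drops) deps[[d[1]]] <- setdiff(deps[[d[1]]], d[2])
    deps
  }
  defs <- list(
    red(),                                        # 1 full
    red(c("v", "label")),                         # 2
    red(c("v", "match")),                         # 3
    red(c("v", "group")),                         # 4
    red(c("a", "label")),                         # 5
    red(c("a", "group")),                         # 6
    red(c("a", "label"), c("z", "label")),        # 7 prior-study structure
    red(c("z", "label")),                         # 8
    red(c("z", "group")),                         # 9
    red(c("t0", "match")),                        # 10
    red(c("t0", "group")),                        # 11
    red(c("a", "label"), c("z", "label"), c("t0", "match")),   # 12
    red(c("a", "group"), c("z", "group"), c("t0", "group")),   # 13
    red(c("a", "label"), c("a", "group"),
        c("z", "label"), c("z", "group")),        # 14
    red(c("a", "label"), c("a", "group"), c("z", "label"),
        c("z", "group"), c("t0", "match"), c("t0", "group"))   # 15
  )
  out <- purrr::imap(defs, function(d, i) {
    ddm_spec(v = d$v, a = d$a, z = d$z, t0 = d$t0,
             outlier_prob = outlier_prob, name = sprintf("Model %d", i))
  })
  names(out) <- sprintf("model_%02d", seq_along(out))
  out
}
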