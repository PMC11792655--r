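#' Wiener first-passage-time log density
#'
#' Log density of a drift-diffusion response: boundary hit (upper = "yes",
#' lower = "no") at time `rt`, for drift rate `v`, boundary separation `a`,
#' relative starting point `z` in (0, 1) and non-decision time `t0` (all
#' times in seconds; diffusion coefficient 1). Evaluated with the
#' small-time/large-time series pair, switching automatically to whichever
#' needs fewer terms at truncation tolerance `eps`; the lower-boundary
#' density is obtained from the upper by the (v, z) -> (-v, 1 - z)
#' reflection. `rt <= t0` yields `-Inf` (zero likelihood), not an error.
#'
#' @param rt Response times, seconds.
#' @param boundary `"upper"`/`"lower"` (recycled), or a logical/0-1 vector
#'   where `TRUE`/1 means upper.
#' @param v,a,z,t0 Model parameters (recycled along `rt`).
#' @param eps Series truncation tolerance.
#' @return Numeric vector of log densities.
#' @examples
#' wfpt_logpdf(0.5, "upper", v = 1, a = 2, z = 0.5, t0 = 0.2)
#' @export
wfpt_logpdf <- function(rt, boundary, v, a, z, t0, eps = 1e-7) {
  upper <- if (is.character(boundary)) {
    if (!all(boundary %in% c("upper", "lower"))) {
      abort("`boundary` must be 'upper' or 'lower'")
    }
    as.integer(boundary == "upper")
  } else {
    as.integer(as.logical(boundary))
  }
  if (any(!is.finite(c(v, a, z, t0)))) abort("parameters must be finite")
  if (any(a <= 0)) abort("`a` must be positive")
  if (any(z <= 0 | z >= 1)) abort("`z` must lie in (0, 1)")
  if (any(t0 < 0)) abort("`t0` must be nonnegative")
  wfpt_logpdf_cpp(as.numeric(rt), upper, as.numeric(v), as.numeric(a),
                  as.numeric(z), as.numeric(t0), eps)
}

#' Closed-form boundary absorption probability
#'
#' Probability that the diffusion is absorbed at the upper boundary,
#' P = (1 - exp(-2 v z a)) / (1 - exp(-2 v a)) (unit diffusion), with the
#' v -> 0 limit equal to z.
#'
#' @inheritParams wfpt_logpdf
#' @return Probability of an upper-boundary ("yes") response.
#' @export
ddm_upper_prob <- function(v, a, z) {
  out <- ifelse(abs(v) < 1e-10, z,
                (1 - exp(-2 * v * z * a)) / (1 - exp(-2 * v * a)))
  as.numeric(out)
}
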