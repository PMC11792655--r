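#' Shape-label matching task design
#'
#' Constants of the shape-label matching paradigm: three person labels (self,
#' friend, stranger) crossed with match/nonmatch pairings, 110 trials per
#' condition, a 100 ms word-shape display, responses accepted within 1100 ms,
#' an inter-trial fixation jittered between 900 and 1700 ms, and 500 ms
#' feedback. The defaults are the conditions the analysis pipeline and the
#' synthetic-data generator assume.
#'
#' @param trials_per_condition Trials in each of the six label x match cells.
#' @param stim_duration_ms Word-shape pair display duration (ms).
#' @param response_deadline_ms Latest accepted response time (ms); slower
#'   trials receive "slow" feedback and carry no response.
#' @param fixation_range_ms Length-2 numeric, min/max fixation duration (ms).
#' @param feedback_duration_ms Feedback display duration (ms).
#'
#' @return An object of class `prio_design`: a list with the fields above plus
#'   `labels` (self, friend, stranger) and `match_levels` (match, nonmatch).
#' @examples
#' design <- task_design()
#' design$trials_per_condition
#' @export
task_design <- function(trials_per_condition = 110,
                        stim_duration_ms = 100,
                        response_deadline_ms = 1100,
                        fixation_range_ms = c(900, 1700),
                        feedback_duration_ms = 500) {
  assert_scalar_number(trials_per_condition, "trials_per_condition", lower = 1)
  assert_scalar_number(stim_duration_ms, "stim_duration_ms", lower = 0)
  assert_scalar_number(response_deadline_ms, "response_deadline_ms", lower = 0)
  if (length(fixation_range_ms) != 2 || fixation_range_ms[1] >= fixation_range_ms[2]) {
    abort("`fixation_range_ms` must be an increasing (min, max) pair")
  }
  if (response_deadline_ms <= stim_duration_ms) {
    abort("`response_deadline_ms` must exceed `stim_duration_ms`")
  }
  structure(
    list(
      labels = c("self", "friend", "stranger"),
      match_levels = c("match", "nonmatch"),
      trials_per_condition = as.integer(trials_per_condition),
      stim_duration_ms = stim_duration_ms,
      response_deadline_ms = response_deadline_ms,
      fixation_range_ms = fixation_range_ms,
      feedback_duration_ms = feedback_duration_ms
    ),
    class = "prio_design"
  )
}

#' @export
print.prio_design <- function(x, ...) {
  cat("<prio_design> shape-label matching task\n")
  cat(sprintf("  %d trials x %d conditions (%s x %s)\n",
              x$trials_per_condition,
              length(x$labels) * length(x$match_levels),
              paste(x$labels, collapse = "/"),
              paste(x$match_levels, collapse = "/")))
  cat(sprintf("  stimulus %g ms, deadline %g ms, fixation %g-%g ms, feedback %g ms\n",
              x$stim_duration_ms, x$response_deadline_ms,
              x$fixation_range_ms[1], x$fixation_range_ms[2],
              x$feedback_duration_ms))
  invisible(x)
}
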