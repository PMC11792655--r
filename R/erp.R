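#' ERP component registry
#'
#' The six analysis components with their measurement windows (ms, endpoints
#' inclusive at sample resolution), polarities, and electrode clusters:
#' frontal N1 (100-150, FCZ/FZ/CZ), posterior N1 (147-167, TP7/T5), P2
#' (180-240, frontocentral-to-centroparietal 9-channel cluster), N2 (240-300,
#' right central-temporal cluster), P3 (320-360, left parieto-temporo-
#' occipital cluster) and LPP (500-700, fronto-central-parietal cluster).
#' `peak_lo`/`peak_hi` give the peak-latency search window, which for the LPP
#' extends to 800 ms so late peaks near the window edge are measurable.
#'
#' @return Tibble with `component`, `window_lo`, `window_hi`, `peak_lo`,
#'   `peak_hi`, `polarity` (+1/-1) and a `channels` list-column.
#' @examples
#' erp_components()
#' @export
erp_components <- function() {
  tibble(
    component = c("N1", "posterior_N1", "P2", "N2", "P3", "LPP"),
    window_lo = c(100, 147, 180, 240, 320, 500),
    window_hi = c(150, 167, 240, 300, 360, 700),
    peak_lo = c(100, 147, 180, 240, 320, 500),
    peak_hi = c(150, 167, 240, 300, 360, 800),
    polarity = c(-1, -1, 1, -1, 1, 1),
    channels = list(
      c("FCZ", "FZ", "CZ"),
      c("TP7", "T5"),
      c("FC3", "FC4", "FCZ", "C3", "C4", "CZ", "CP3", "CP4", "CPZ"),
      c("P4", "PZ", "T4", "T6", "TP8", "C4", "CZ", "CP4", "CPZ"),
      c("P3", "PZ", "TP7", "T5", "CP3", "O1", "O2", "OZ"),
      c("FZ", "FC3", "FC4", "FCZ", "C3", "C4", "CZ", "CPZ")
    )
  )
}

#' Crop epochs and subtract the pre-stimulus baseline
#'
#' Restricts epochs to `window_ms` and subtracts, per trial and channel, the
#' mean amplitude over `baseline_ms` (default the 200 ms before stimulus
#' onset). Constant per-channel offsets therefore cancel exactly.
#'
#' @param epochs A [epoch_array()].
#' @param window_ms Length-2 epoch window to keep, ms.
#' @param baseline_ms Length-2 baseline window, ms; must lie inside
#'   `window_ms`.
#' @return A baseline-corrected `prio_epochs`.
#' @export
epoch_and_baseline <- function(epochs, window_ms = c(-200, 800),
                               baseline_ms = c(-200, 0)) {
  stopifnot(inherits(epochs, "prio_epochs"))
  if (baseline_ms[1] < window_ms[1] || baseline_ms[2] > window_ms[2]) {
    abort("`baseline_ms` must lie inside `window_ms`")
  }
  step <- 1000 / epochs$fs # endpoints may fall between samples
  if (window_ms[1] < min(epochs$times) - step ||
      window_ms[2] > max(epochs$times) + step) {
    abort("`window_ms` extends beyond the available epoch")
  }
  out <- subset_epochs(epochs, time_ms = window_ms)
  bi <- which(out$times >= baseline_ms[1] & out$times <= baseline_ms[2])
  if (length(bi) == 0) abort("`baseline_ms` selects no samples")
  bl <- apply(out$data[, , bi, drop = FALSE], c(1, 2), mean)
  out$data <- out$data - as.vector(bl) # recycled over the time dimension
  out
}

#' Reject trials with amplitudes exceeding a threshold
#'
#' Drops every trial whose absolute amplitude exceeds `threshold_uv` at any
#' channel and sample (muscle/movement artifacts); the default mirrors the
#' +/-70 microvolt criterion.
#'
#' @param epochs A [epoch_array()].
#' @param threshold_uv Positive rejection threshold, microvolts.
#' @param by Optional character vector of `info` columns for the per-condition
#'   survivor log.
#' @return The cleaned `prio_epochs`, with a `rejection_log` attribute: a
#'   tibble of retained/rejected counts (per condition when `by` is given).
#' @export
reject_artifacts <- function(epochs, threshold_uv = 70, by = NULL) {
  stopifnot(inherits(epochs, "prio_epochs"))
  if (!is.numeric(threshold_uv) || threshold_uv <= 0) {
    abort("`threshold_uv` must be positive")
  }
  peak <- apply(abs(epochs$data), 1, max)
  keep <- peak <= threshold_uv
  if (!any(keep)) {
    abort(sprintf(
      "all %d trials exceed +/-%g uV (peak range %.1f..%.1f uV)",
      length(keep), threshold_uv, min(peak), max(peak)))
  }
  log_df <- epochs$info
  log_df$.kept <- keep
  grp <- if (is.null(by)) character(0) else by
  log_tbl <- log_df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(n_total = dplyr::n(), n_kept = sum(.data$.kept),
                     n_rejected = sum(!.data$.kept), .groups = "drop")
  out <- subset_epochs(epochs, trials = which(keep))
  attr(out, "rejection_log") <- log_tbl
  out
}

resolve_component <- function(component) {
  if (is.character(component)) {
    defs <- erp_components()
    if (!component %in% defs$component) {
      abort(sprintf("unknown component '%s'; see erp_components()", component))
    }
    defs[defs$component == component, ]
  } else {
    component # caller-supplied one-row definition
  }
}

#' Mean component amplitude per subject and condition
#'
#' Averages over the component's electrode cluster, its time window
#' (endpoints inclusive) and the trials of each subject x condition cell.
#'
#' @param epochs Baseline-corrected [epoch_array()] whose `info` has a
#'   `subject` column.
#' @param component A component name from [erp_components()], or a one-row
#'   tibble with the same columns.
#' @param by Character vector of `info` columns defining conditions
#'   (default `c("label", "match")` intersected with available columns).
#' @return Tibble: subject, condition columns, `component`, `n_trials`,
#'   `amplitude_uv`.
#' @export
component_amplitude <- function(epochs, component,
                                by = c("label", "match")) {
  stopifnot(inherits(epochs, "prio_epochs"))
  cdef <- resolve_component(component)
  chans <- normalize_channels(cdef$channels[[1]])
  missing <- setdiff(chans, epochs$channels)
  if (length(missing) > 0) {
    abort(sprintf("epochs lack channel(s) required by %s: %s",
                  cdef$component, paste(missing, collapse = ", ")))
  }
  by <- intersect(by, names(epochs$info))
  si <- which(epochs$times >= cdef$window_lo - 1e-9 &
                epochs$times <= cdef$window_hi + 1e-9)
  if (length(si) == 0) abort("component window contains no samples")
  ci <- match(chans, epochs$channels)
  per_trial <- apply(epochs$data[, ci, si, drop = FALSE], 1, mean)
  df <- epochs$info
  df$.amp <- per_trial
  grp <- intersect(c("subject", by), names(df))
  df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(component = cdef$component, n_trials = dplyr::n(),
                     amplitude_uv = mean(.data$.amp), .groups = "drop")
}

#' Peak latency of a condition-average waveform
#'
#' Averages trials within each subject x condition cell over the component's
#' electrode cluster, then finds the extremum of the stated polarity within
#' the peak-search window. Ties go to the earliest sample; a flat waveform
#' returns the earliest sample with a warning.
#'
#' @inheritParams component_amplitude
#' @param window_ms Optional length-2 override of the peak-search window.
#' @return Tibble: subject, condition columns, `component`, `latency_ms`,
#'   `peak_uv`.
#' @export
peak_latency <- function(epochs, component, by = c("label", "match"),
                         window_ms = NULL) {
  stopifnot(inherits(epochs, "prio_epochs"))
  cdef <- resolve_component(component)
  chans <- normalize_channels(cdef$channels[[1]])
  missing <- setdiff(chans, epochs$channels)
  if (length(missing) > 0) {
    abort(sprintf("epochs lack channel(s) required by %s: %s",
                  cdef$component, paste(missing, collapse = ", ")))
  }
  win <- window_ms %||% c(cdef$peak_lo, cdef$peak_hi)
  si <- which(epochs$times >= win[1] - 1e-9 & epochs$times <= win[2] + 1e-9)
  if (length(si) == 0) abort("peak window contains no samples")
  ci <- match(chans, epochs$channels)
  by <- intersect(by, names(epochs$info))
  grp <- intersect(c("subject", by), names(epochs$info))
  cells <- if (length(grp) > 0) {
    split(seq_len(nrow(epochs$info)),
          lapply(grp, function(g) epochs$info[[g]]), drop = TRUE)
  } else list(all = seq_len(nrow(epochs$info)))
  purrr::map_dfr(cells, function(tr) {
    wave <- apply(epochs$data[tr, ci, si, drop = FALSE], 3, mean)
    signed <- cdef$polarity * wave
    if (diff(range(signed)) < .Machine$double.eps * 100) {
      warn("flat waveform in peak window; returning earliest sample")
    }
    pk <- which.max(signed) # which.max returns the earliest tie
    out <- epochs$info[tr[1], grp, drop = FALSE]
    out$component <- cdef$component
    out$latency_ms <- epochs$times[si][pk]
    out$peak_uv <- wave[pk]
    out
  })
}
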