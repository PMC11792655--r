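#' Stimulus-locked EEG epoch container
#'
#' Holds an epochs array (trials x channels x time, microvolts) with its
#' sampling rate, time axis in ms relative to stimulus onset, channel names
#' and per-trial metadata joinable to the behavioral trial table.
#'
#' @param data Numeric array, trials x channels x time.
#' @param fs Sampling rate, Hz.
#' @param tmin_ms Time of the first sample, ms relative to stimulus onset.
#' @param channels Character vector of unique channel names (dim 2).
#' @param info Tibble of per-trial metadata (one row per trial); at minimum a
#'   `subject` column for multi-subject containers.
#' @return An object of class `prio_epochs`.
#' @export
epoch_array <- function(data, fs, tmin_ms, channels, info = NULL) {
  if (length(dim(data)) != 3) abort("`data` must be trials x channels x time")
  if (!is.numeric(fs) || fs <= 0) abort("`fs` must be a positive sampling rate")
  if (length(channels) != dim(data)[2]) {
    abort("`channels` length must match dim(data)[2]")
  }
  if (anyDuplicated(channels)) abort("channel names must be unique")
  if (is.null(info)) info <- tibble(trial = seq_len(dim(data)[1]))
  if (nrow(info) != dim(data)[1]) abort("`info` must have one row per trial")
  times <- tmin_ms + (seq_len(dim(data)[3]) - 1) * 1000 / fs
  structure(
    list(data = data, fs = fs, times = times, channels = as.character(channels),
         info = as_tibble(info)),
    class = "prio_epochs"
  )
}

#' @export
print.prio_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<prio_epochs> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat(sprintf("  time %g..%g ms; channels: %s%s\n",
              min(x$times), max(x$times),
              paste(head(x$channels, 6), collapse = ", "),
              if (d[2] > 6) ", ..." else ""))
  invisible(x)
}

#' Subset an epoch container
#'
#' @param epochs A [epoch_array()].
#' @param trials Integer or logical index over trials (default all).
#' @param channels Character vector of channels to keep (default all).
#' @param time_ms Length-2 numeric window in ms, inclusive (default all).
#' @return A `prio_epochs` restricted to the selection.
#' @export
subset_epochs <- function(epochs, trials = NULL, channels = NULL,
                          time_ms = NULL) {
  stopifnot(inherits(epochs, "prio_epochs"))
  ti <- trials %||% seq_len(dim(epochs$data)[1])
  ch <- channels %||% epochs$channels
  missing <- setdiff(ch, epochs$channels)
  if (length(missing) > 0) {
    abort(sprintf("unknown channel(s): %s", paste(missing, collapse = ", ")))
  }
  ci <- match(ch, epochs$channels)
  si <- if (is.null(time_ms)) seq_along(epochs$times) else {
    which(epochs$times >= time_ms[1] & epochs$times <= time_ms[2])
  }
  if (length(si) == 0) abort("`time_ms` selects no samples")
  epoch_array(epochs$data[ti, ci, si, drop = FALSE], epochs$fs,
              epochs$times[si][1], ch, epochs$info[ti, , drop = FALSE])
}

#' Convert epochs to a long tibble
#'
#' @param x A `prio_epochs`.
#' @param ... Unused.
#' @return Tibble with `trial`, `channel`, `time_ms`, `value` plus the
#'   per-trial metadata columns.
#' @exportS3Method tibble::as_tibble
as_tibble.prio_epochs <- function(x, ...) {
  d <- dim(x$data)
  out <- tibble(
    trial = rep(seq_len(d[1]), times = d[2] * d[3]),
    channel = rep(rep(x$channels, each = d[1]), times = d[3]),
    time_ms = rep(x$times, each = d[1] * d[2]),
    value = as.vector(x$data)
  )
  info <- x$info
  info$trial <- seq_len(d[1])
  dplyr::left_join(out, info, by = "trial")
}
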