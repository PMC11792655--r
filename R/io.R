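trial_schema <- list(
  subject = "character", label = c("self", "friend", "stranger"),
  match = c("match", "nonmatch"), response = c("yes", "no", NA),
  rt_ms = "numeric", accuracy = c(0, 1, NA), trial_index = "numeric"
)

#' Validate a trial table against the package schema
#'
#' Checks column presence, level membership of `label`, `match`, `response`,
#' and numeric ranges of `rt_ms`/`accuracy`, naming the first violating row.
#'
#' @param trials Tibble to validate.
#' @return The tibble, invisibly, or an error.
#' @export
validate_trials <- function(trials) {
  assert_cols(trials, setdiff(names(trial_schema), "trial_index"), "trials")
  check_levels <- function(col, levels) {
    bad <- which(!trials[[col]] %in% levels)
    if (length(bad) > 0) {
      abort(sprintf("invalid %s value '%s' at row %d", col,
                    as.character(trials[[col]][bad[1]]), bad[1]))
    }
  }
  check_levels("label", trial_schema$label)
  check_levels("match", trial_schema$match)
  check_levels("response", trial_schema$response)
  bad_rt <- which(!is.na(trials$rt_ms) & trials$rt_ms < 0)
  if (length(bad_rt) > 0) {
    abort(sprintf("negative rt_ms at row %d", bad_rt[1]))
  }
  check_levels("accuracy", trial_schema$accuracy)
  invisible(trials)
}

#' Read and write trial tables as TSV
#'
#' @param trials Trial tibble.
#' @param path File path.
#' @return `read_trials()` returns a validated tibble; `write_trials()` the
#'   path, invisibly.
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  readr::write_tsv(trials, path)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  trials <- readr::read_tsv(path, show_col_types = FALSE,
                            progress = FALSE)
  trials$subject <- as.character(trials$subject)
  validate_trials(trials)
  trials
}

#' Read and write epoch containers
#'
#' Plain-text epoch storage: a directory holding `meta.json` (sampling rate,
#' epoch start, channel names), `info.tsv` (per-trial metadata) and
#' `data.tsv` (one row per trial x channel, one column per sample,
#' microvolts).
#'
#' @param epochs A [epoch_array()].
#' @param dir Directory path (created if needed).
#' @return `read_epochs()` returns a `prio_epochs`; `write_epochs()` the
#'   directory, invisibly.
#' @export
write_epochs <- function(epochs, dir) {
  stopifnot(inherits(epochs, "prio_epochs"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(epochs$data)
  meta <- list(fs = epochs$fs, tmin_ms = epochs$times[1],
               channels = epochs$channels, n_trials = d[1],
               n_samples = d[3])
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  readr::write_tsv(epochs$info, file.path(dir, "info.tsv"))
  flat <- matrix(aperm(epochs$data, c(2, 1, 3)), d[1] * d[2], d[3])
  readr::write_tsv(as.data.frame(flat), file.path(dir, "data.tsv"),
                   col_names = FALSE, progress = FALSE)
  invisible(dir)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  info <- readr::read_tsv(file.path(dir, "info.tsv"), show_col_types = FALSE,
                          progress = FALSE)
  flat <- as.matrix(readr::read_tsv(file.path(dir, "data.tsv"),
                                    col_names = FALSE, show_col_types = FALSE,
                                    progress = FALSE))
  n_ch <- length(meta$channels)
  data <- aperm(array(flat, dim = c(n_ch, meta$n_trials, meta$n_samples)),
                c(2, 1, 3))
  epoch_array(data, meta$fs, meta$tmin_ms, meta$channels, info)
}

#' Generic TSV table I/O with column checks
#'
#' @param x Data frame to write.
#' @param path File path.
#' @param required Character vector of columns that must be present on read.
#' @return `read_table_tsv()` returns a tibble; `write_table_tsv()` the
#'   path, invisibly.
#' @export
write_table_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path, required = NULL) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(required)) assert_cols(out, required, path)
  out
}
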