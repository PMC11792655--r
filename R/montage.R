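#' Default 30-channel 10/20 montage
#'
#' Schematic 2D (top view) electrode positions for the 30-channel Ag/AgCl cap
#' used in the shape-label matching recordings. Coordinates are unitless,
#' nose-up, on a unit head circle; they are used only to derive channel
#' adjacency and for topographic displays, not for source modelling.
#' Channel names follow the recording's (older) nomenclature, e.g. T3/T5; see
#' [channel_aliases()] for the modern equivalents.
#'
#' @return A tibble with columns `channel`, `x`, `y`.
#' @examples
#' default_montage()
#' @export
default_montage <- function() {
  tibble::tribble(
    ~channel,     ~x,     ~y,
    "FP1",     -0.31,   0.95,
    "FP2",      0.31,   0.95,
    "F7",      -0.81,   0.59,
    "F3",      -0.41,   0.58,
    "FZ",       0.00,   0.60,
    "F4",       0.41,   0.58,
    "F8",       0.81,   0.59,
    "FT7",     -0.95,   0.31,
    "FC3",     -0.45,   0.30,
    "FCZ",      0.00,   0.30,
    "FC4",      0.45,   0.30,
    "FT8",      0.95,   0.31,
    "T3",      -1.00,   0.00,
    "C3",      -0.50,   0.00,
    "CZ",       0.00,   0.00,
    "C4",       0.50,   0.00,
    "T4",       1.00,   0.00,
    "TP7",     -0.95,  -0.31,
    "CP3",     -0.45,  -0.30,
    "CPZ",      0.00,  -0.30,
    "CP4",      0.45,  -0.30,
    "TP8",      0.95,  -0.31,
    "T5",      -0.81,  -0.59,
    "P3",      -0.41,  -0.58,
    "PZ",       0.00,  -0.60,
    "P4",       0.41,  -0.58,
    "T6",       0.81,  -0.59,
    "O1",      -0.31,  -0.95,
    "OZ",       0.00,  -1.00,
    "O2",       0.31,  -0.95
  )
}

#' Old/new 10/20 electrode name aliases
#'
#' The temporal electrodes carry two generations of names (T3/T7, T5/P7,
#' T4/T8, T6/P8). [normalize_channels()] maps modern names onto the montage's
#' older convention so component definitions and external data interoperate.
#'
#' @return A named character vector, `modern name -> montage name`.
#' @export
channel_aliases <- function() {
  c(T7 = "T3", P7 = "T5", T8 = "T4", P8 = "T6")
}

#' @rdname channel_aliases
#' @param channels Character vector of channel names (any case).
#' @export
normalize_channels <- function(channels) {
  up <- toupper(channels)
  al <- channel_aliases()
  hit <- up %in% names(al)
  up[hit] <- al[up[hit]]
  up
}

#' Channel adjacency from 2D montage positions
#'
#' Two channels are neighbors when their planar distance is below `threshold`.
#' When `threshold` is `NULL` it is chosen as the smallest distance for which
#' every channel has at least one neighbor and the median neighbor count is at
#' least `target_median` (about 4 on the default cap).
#'
#' @param montage Tibble with `channel`, `x`, `y` (see [default_montage()]).
#' @param threshold Distance cutoff, or `NULL` to choose automatically.
#' @param target_median Median neighbor count targeted by the automatic rule.
#' @return A named list mapping each channel to a character vector of
#'   neighbors; symmetric and irreflexive. The chosen threshold is attached as
#'   attribute `"threshold"`.
#' @examples
#' adj <- build_adjacency(default_montage())
#' adj[["CZ"]]
#' @export
build_adjacency <- function(montage, threshold = NULL, target_median = 4) {
  assert_cols(montage, c("channel", "x", "y"), "montage")
  if (anyDuplicated(montage$channel)) abort("montage channel names must be unique")
  d <- as.matrix(stats::dist(cbind(montage$x, montage$y)))
  if (is.null(threshold)) {
    cand <- sort(unique(round(d[upper.tri(d)], 6)))
    for (th in cand) {
      nb <- rowSums(d <= th) - 1
      if (all(nb >= 1) && median(nb) >= target_median) {
        threshold <- th + 1e-9
        break
      }
    }
    if (is.null(threshold)) threshold <- max(d)
  }
  adj <- lapply(seq_len(nrow(montage)), function(i) {
    montage$channel[d[i, ] <= threshold & seq_len(nrow(montage)) != i]
  })
  names(adj) <- montage$channel
  if (any(lengths(adj) == 0)) abort("adjacency threshold leaves isolated channels")
  attr(adj, "threshold") <- threshold
  adj
}

# adjacency as 0-based integer index lists, in the order of `channels`
adjacency_index <- function(adjacency, channels) {
  missing <- setdiff(channels, names(adjacency))
  if (length(missing) > 0) {
    abort(sprintf("adjacency lacks channel(s): %s", paste(missing, collapse = ", ")))
  }
  lapply(channels, function(ch) {
    nb <- intersect(adjacency[[ch]], channels)
    as.integer(match(nb, channels) - 1L)
  })
}
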