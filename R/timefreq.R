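#' Complex Morlet wavelet family
#'
#' Gaussian-windowed complex exponentials w(t, f0) = A exp(-t^2 / (2 s_t^2))
#' exp(2 i pi f0 t) with the family constraint f0 / s_f = `ratio` (default 5)
#' and the spectral-temporal width relation s_t = 1 / (2 pi s_f). The
#' normalization A = (s_t sqrt(pi))^(-1/2) gives each kernel unit energy.
#' Kernels are discretized at 1/fs and truncated at +/-4 s_t.
#'
#' @param freqs Center frequencies, Hz (default 1-40 in 1 Hz steps).
#' @param ratio f0 / sigma_f (dimensionless).
#' @param fs Sampling rate, Hz; must satisfy fs >= 2 max(freqs).
#' @return Object of class `prio_wavelets`: a list with `freqs`, `sigma_t`
#'   (s), and `kernels` (list of complex vectors).
#' @examples
#' fam <- build_wavelets(freqs = 8:18, fs = 250)
#' fam$sigma_t[fam$freqs == 10]
#' @export
build_wavelets <- function(freqs = 1:40, ratio = 5, fs = 1000) {
  if (any(freqs <= 0)) abort("frequencies must be positive")
  assert_scalar_number(ratio, "ratio", lower = 1e-6)
  if (fs < 2 * max(freqs)) {
    abort(sprintf("fs = %g violates the Nyquist limit for %g Hz", fs, max(freqs)))
  }
  sigma_f <- freqs / ratio
  sigma_t <- 1 / (2 * pi * sigma_f)
  kernels <- purrr::map2(freqs, sigma_t, function(f0, st) {
    half <- ceiling(4 * st * fs)
    t <- (-half:half) / fs
    A <- (st * sqrt(pi))^(-1 / 2)
    A * exp(-t^2 / (2 * st^2)) * exp(2i * pi * f0 * t)
  })
  structure(list(freqs = freqs, ratio = ratio, fs = fs,
                 sigma_t = sigma_t, kernels = kernels),
            class = "prio_wavelets")
}

#' @export
print.prio_wavelets <- function(x, ...) {
  cat(sprintf("<prio_wavelets> %d kernels, %g-%g Hz, f0/sigma_f = %g @ %g Hz\n",
              length(x$freqs), min(x$freqs), max(x$freqs), x$ratio, x$fs))
  invisible(x)
}

#' Frequency bands used for oscillatory statistics
#'
#' @return Tibble with `band`, `fmin`, `fmax`: delta/theta 2-7 Hz,
#'   alpha/low-beta 8-18 Hz, beta 19-29 Hz.
#' @export
tf_bands <- function() {
  tibble(band = c("delta_theta", "alpha_low_beta", "beta"),
         fmin = c(2, 8, 19), fmax = c(7, 18, 29))
}

#' Remove phase-locked activity from epochs
#'
#' Subtracts each condition's mean waveform (the ERP) from every trial of
#' that condition, leaving only non-phase-locked (induced) activity. Output
#' condition means are numerically zero; singleton conditions produce a
#' warning since subtraction annihilates them.
#'
#' @param epochs A [epoch_array()].
#' @param by Character vector of `info` columns defining conditions.
#' @return A `prio_epochs` of induced activity.
#' @export
remove_phase_locked <- function(epochs, by = c("label", "match")) {
  stopifnot(inherits(epochs, "prio_epochs"))
  by <- intersect(by, names(epochs$info))
  key <- if (length(by) == 0) rep("all", nrow(epochs$info)) else {
    do.call(paste, c(epochs$info[by], sep = "\r"))
  }
  out <- epochs
  for (k in unique(key)) {
    tr <- which(key == k)
    if (length(tr) < 2) {
      warn("singleton condition: ERP subtraction leaves a zero epoch")
    }
    erp <- apply(epochs$data[tr, , , drop = FALSE], c(2, 3), mean)
    out$data[tr, , ] <- sweep(epochs$data[tr, , , drop = FALSE], c(2, 3), erp)
  }
  out
}

#' Time-frequency power via Morlet convolution
#'
#' Convolves each trial and channel with the complex wavelet family and
#' returns instantaneous power P(t) = Re[TF(t)]^2 + Im[TF(t)]^2. Samples
#' within 2 sigma_t of either epoch edge are flagged invalid (NA) rather
#' than padded, keeping power unbiased near the edges. Frequencies whose
#' valid region is empty are dropped with a warning; an error results only
#' if no requested frequency fits the epoch.
#'
#' @param epochs A [epoch_array()].
#' @param family A [build_wavelets()] (its `fs` must match the epochs).
#' @param keep_trials Keep single-trial power (memory scales with trials x
#'   channels x frequencies x time); otherwise average over trials.
#' @return Object of class `prio_tfr`: `power` array (trials x) channels x
#'   frequencies x time with NA outside the valid region, plus axes metadata.
#' @export
tf_power <- function(epochs, family = build_wavelets(fs = epochs$fs),
                     keep_trials = FALSE) {
  stopifnot(inherits(epochs, "prio_epochs"), inherits(family, "prio_wavelets"))
  if (abs(family$fs - epochs$fs) > 1e-9) {
    abort("wavelet family and epochs have different sampling rates")
  }
  nt <- length(epochs$times)
  edge <- ceiling(2 * family$sigma_t * epochs$fs)
  ok <- 2 * edge < nt
  if (!any(ok)) {
    abort("epoch shorter than every requested kernel's valid support")
  }
  if (!all(ok)) {
    warn(sprintf("dropping %d frequencies with no valid samples in this epoch",
                 sum(!ok)))
  }
  freqs <- family$freqs[ok]
  kernels <- family$kernels[ok]
  edge <- edge[ok]
  d <- dim(epochs$data)
  n_trials <- d[1]; n_ch <- d[2]
  nf <- length(freqs)

  # FFT-based linear convolution, centered (same-length output)
  nfft <- stats::nextn(nt + max(lengths(kernels)) - 1, 2)
  kfft <- lapply(kernels, function(k) fft(c(k, rep(0, nfft - length(k)))))
  klen <- lengths(kernels)

  pow <- array(NA_real_, dim = c(n_trials, n_ch, nf, nt))
  for (tr in seq_len(n_trials)) {
    for (ch in seq_len(n_ch)) {
      xf <- fft(c(epochs$data[tr, ch, ], rep(0, nfft - nt)))
      for (fi in seq_len(nf)) {
        conv <- fft(xf * kfft[[fi]], inverse = TRUE) / nfft
        half <- (klen[fi] - 1) / 2
        tf <- conv[half + seq_len(nt)]
        p <- Re(tf)^2 + Im(tf)^2
        lo <- edge[fi]; hi <- nt - edge[fi]
        p[seq_len(lo)] <- NA
        p[seq.int(hi + 1, nt)] <- NA
        pow[tr, ch, fi, ] <- p
      }
    }
  }
  if (!keep_trials) {
    pow <- apply(pow, c(2, 3, 4), mean)
  }
  structure(
    list(power = pow, freqs = freqs, times = epochs$times,
         channels = epochs$channels, fs = epochs$fs,
         keep_trials = keep_trials,
         info = if (keep_trials) epochs$info else NULL),
    class = "prio_tfr"
  )
}

#' @export
print.prio_tfr <- function(x, ...) {
  cat(sprintf("<prio_tfr> %s%d channels x %d freqs (%g-%g Hz) x %d samples\n",
              if (x$keep_trials) sprintf("%d trials x ", dim(x$power)[1]) else "",
              length(x$channels), length(x$freqs), min(x$freqs), max(x$freqs),
              length(x$times)))
  invisible(x)
}

#' ERS/ERD baseline normalization
#'
#' Normalizes power as the proportional change relative to the pre-stimulus
#' baseline, (P(t) - P0) / P0, with P0 the time-mean power over
#' `baseline_ms` (default -300 to -100 ms) per channel x frequency — and per
#' trial when single-trial power is present, so the normalization is
#' per-trial-then-average downstream. Values are bounded below by -1
#' (complete desynchronization).
#'
#' @param tfr A [tf_power()] result.
#' @param baseline_ms Length-2 baseline window, ms; its samples must be
#'   valid (outside the edge-flagged region) at every kept frequency.
#' @return A `prio_tfr` whose `power` holds ERS/ERD values.
#' @export
ers_erd <- function(tfr, baseline_ms = c(-300, -100)) {
  stopifnot(inherits(tfr, "prio_tfr"))
  bi <- which(tfr$times >= baseline_ms[1] & tfr$times <= baseline_ms[2])
  if (length(bi) == 0) abort("baseline window contains no samples")
  nd <- length(dim(tfr$power))
  base_slab <- if (nd == 4) tfr$power[, , , bi, drop = FALSE]
  else tfr$power[, , bi, drop = FALSE]
  if (anyNA(base_slab)) {
    abort("baseline window overlaps edge-invalid samples; shorten the kernel or the baseline")
  }
  p0 <- apply(base_slab, seq_len(nd - 1), mean)
  if (any(p0 <= 0)) abort("baseline power is zero: ERS/ERD undefined")
  out <- tfr
  out$power <- sweep(sweep(tfr$power, seq_len(nd - 1), p0, "-"),
                     seq_len(nd - 1), p0, "/")
  out$normalized <- TRUE
  out
}

#' Average TFR power over a band, window and channel set
#'
#' @param tfr A `prio_tfr` (raw or ERS/ERD-normalized).
#' @param band Length-2 frequency range (Hz), or a band name from
#'   [tf_bands()].
#' @param window_ms Length-2 time window, ms.
#' @param channels Channels to average (default all).
#' @return When single-trial power is kept, a tibble with one row per trial
#'   (metadata columns plus `power`); otherwise a single number.
#' @export
tfr_band_mean <- function(tfr, band, window_ms, channels = NULL) {
  stopifnot(inherits(tfr, "prio_tfr"))
  if (is.character(band)) {
    bd <- tf_bands()
    if (!band %in% bd$band) abort("unknown band name")
    band <- unlist(bd[bd$band == band, c("fmin", "fmax")])
  }
  fi <- which(tfr$freqs >= band[1] & tfr$freqs <= band[2])
  si <- which(tfr$times >= window_ms[1] & tfr$times <= window_ms[2])
  ci <- if (is.null(channels)) seq_along(tfr$channels) else {
    idx <- match(normalize_channels(channels), tfr$channels)
    if (anyNA(idx)) abort("unknown channel(s) in `channels`")
    idx
  }
  if (length(fi) == 0 || length(si) == 0) abort("empty band or window")
  if (tfr$keep_trials) {
    vals <- apply(tfr$power[, ci, fi, si, drop = FALSE], 1, mean, na.rm = TRUE)
    out <- tfr$info %||% tibble(trial = seq_along(vals))
    out$power <- vals
    out
  } else {
    mean(tfr$power[ci, fi, si], na.rm = TRUE)
  }
}
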