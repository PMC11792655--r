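#' ERP component templates for the epoch synthesizer
#'
#' Phenomenological single-component templates: a Gaussian bump per component
#' with a peak latency, temporal sd, polarity and peak amplitude, supported on
#' that component's electrode cluster (unit spatial weight on cluster
#' channels, zero elsewhere). Peaks sit inside the analysis windows of
#' [erp_components()].
#'
#' @return Tibble with `component`, `peak_ms`, `sd_ms`, `polarity` (+1/-1),
#'   `amplitude_uv`, and a `channels` list-column.
#' @examples
#' erp_templates()
#' @export
erp_templates <- function() {
  defs <- erp_components()
  amps <- c(N1 = 2, posterior_N1 = 1.5, P2 = 3, N2 = 2, P3 = 3, LPP = 2)
  sds <- c(N1 = 12, posterior_N1 = 6, P2 = 15, N2 = 15, P3 = 12, LPP = 60)
  tibble(
    component = defs$component,
    peak_ms = (defs$window_lo + defs$window_hi) / 2,
    sd_ms = unname(sds[defs$component]),
    polarity = defs$polarity,
    amplitude_uv = unname(amps[defs$component]),
    channels = defs$channels
  )
}

#' Oscillation specification for the epoch synthesizer
#'
#' A band-limited amplitude-modulated sinusoid with per-trial random phase,
#' so its power survives ERP subtraction (non-phase-locked). The post-stimulus
#' modulation window rescales the amplitude by `mod_factor` (power changes by
#' `mod_factor^2 - 1` relative to baseline); a positive `coupling_gain`
#' multiplies each trial's amplitude by `exp(-coupling_gain * drift / 2)`, so
#' single-trial power decreases with the trial's condition drift.
#'
#' @param freq_hz Oscillation frequency (default 10 Hz, inside the 8-18 Hz
#'   alpha/low-beta band).
#' @param amp_uv Baseline amplitude, microvolts.
#' @param channels Channels carrying the oscillation.
#' @param mod_window_ms Post-stimulus window of the amplitude modulation.
#' @param mod_factor Amplitude multiplier inside the window.
#' @param coupling_gain Drift-to-amplitude coupling (0 disables).
#' @param ramp_ms Gaussian ramp sd smoothing the window edges.
#' @return An object of class `prio_osc`.
#' @export
osc_spec <- function(freq_hz = 10, amp_uv = 3,
                     channels = c("F3", "FZ", "FC3", "FCZ", "C3", "CZ"),
                     mod_window_ms = c(200, 800), mod_factor = 1,
                     coupling_gain = 0, ramp_ms = 25) {
  assert_scalar_number(freq_hz, "freq_hz", lower = 1e-6)
  assert_scalar_number(amp_uv, "amp_uv", lower = 0)
  assert_scalar_number(mod_factor, "mod_factor", lower = 0)
  structure(
    list(freq_hz = freq_hz, amp_uv = amp_uv, channels = channels,
         mod_window_ms = mod_window_ms, mod_factor = mod_factor,
         coupling_gain = coupling_gain, ramp_ms = ramp_ms),
    class = "prio_osc"
  )
}

#' Condition drift rates for a trial table
#'
#' Looks up each trial's generative drift rate in a subject truth, for use as
#' the coupling variable when synthesizing epochs.
#'
#' @param truth A [subject_truth()].
#' @param trials Trial tibble with `label` and `match` columns.
#' @return Numeric vector of per-trial drift rates.
#' @export
condition_drift <- function(truth, trials) {
  stopifnot(inherits(truth, "prio_truth"))
  assert_cols(trials, c("label", "match"), "trials")
  unname(truth$v_map[paste(trials$label, trials$match, sep = "_")])
}

# 1/f-shaped noise via spectral shaping of white noise
pink_noise <- function(n, fs) {
  white <- rnorm(n)
  f <- seq(0, fs / 2, length.out = floor(n / 2) + 1)
  scale <- c(0, 1 / sqrt(f[-1]))
  spec <- fft(white)
  half <- seq_along(f)
  spec[half] <- spec[half] * scale
  if (n %% 2 == 0) {
    spec[(n / 2 + 2):n] <- Conj(spec[rev(seq(2, n / 2))])
  } else {
    spec[(floor(n / 2) + 2):n] <- Conj(spec[rev(seq(2, floor(n / 2) + 1))])
  }
  x <- Re(fft(spec, inverse = TRUE)) / n
  x / sd(x)
}

#' Synthesize multichannel EEG epochs for a trial table
#'
#' Each trial's signal is the sum of the Gaussian-windowed component
#' templates, an amplitude-modulated oscillation with per-trial random phase
#' (see [osc_spec()]), and white (or 1/f) Gaussian noise. With a positive
#' coupling gain and a `drift` vector, single-trial oscillatory power is a
#' decreasing function of the trial's condition drift.
#'
#' @param trials Trial tibble (one epoch per row).
#' @param templates Component templates, see [erp_templates()].
#' @param osc An [osc_spec()], or `NULL` for no oscillation.
#' @param montage Montage tibble; its channels define the epoch channels.
#' @param fs Sampling rate, Hz.
#' @param epoch_window_ms Length-2 epoch window (default -500..800 ms so the
#'   time-frequency baseline window exists).
#' @param noise_sd Noise sd, microvolts.
#' @param noise_model `"white"` or `"pink"`.
#' @param drift Optional per-trial drift rates (see [condition_drift()]);
#'   required when `osc$coupling_gain > 0`.
#' @param seed Optional integer seed.
#' @return A [epoch_array()] whose `info` carries the trial table columns.
#' @export
synthesize_epochs <- function(trials, templates = erp_templates(),
                              osc = osc_spec(), montage = default_montage(),
                              fs = 1000, epoch_window_ms = c(-500, 800),
                              noise_sd = 1, noise_model = c("white", "pink"),
                              drift = NULL, seed = NULL) {
  noise_model <- match.arg(noise_model)
  if (!is.null(seed)) set.seed(seed)
  n_trials <- nrow(trials)
  if (n_trials == 0) abort("`trials` is empty")
  channels <- montage$channel
  times <- seq(epoch_window_ms[1], epoch_window_ms[2], by = 1000 / fs)
  nt <- length(times)

  if (!is.null(templates) && nrow(templates) > 0) {
    bad <- templates$peak_ms < epoch_window_ms[1] |
      templates$peak_ms > epoch_window_ms[2]
    if (any(bad)) {
      abort(sprintf("template peak(s) outside the epoch window: %s",
                    paste(templates$component[bad], collapse = ", ")))
    }
    unknown <- setdiff(unique(unlist(templates$channels)), channels)
    if (length(unknown) > 0) {
      abort(sprintf("template channel(s) not in montage: %s",
                    paste(unknown, collapse = ", ")))
    }
  }
  if (!is.null(osc) && osc$coupling_gain != 0) {
    if (is.null(drift)) abort("`drift` is required when coupling_gain != 0")
    if (length(drift) != n_trials) abort("`drift` must have one value per trial")
  }

  # deterministic component layer, shared by all trials
  base <- matrix(0, length(channels), nt)
  if (!is.null(templates)) {
    for (i in seq_len(nrow(templates))) {
      bump <- templates$polarity[i] * templates$amplitude_uv[i] *
        exp(-(times - templates$peak_ms[i])^2 / (2 * templates$sd_ms[i]^2))
      ci <- match(templates$channels[[i]], channels)
      base[ci, ] <- base[ci, ] + rep(bump, each = length(ci))
    }
  }

  # oscillation envelope (trial-independent part)
  env <- NULL
  osc_ci <- integer(0)
  if (!is.null(osc) && osc$amp_uv > 0) {
    osc_ci <- match(normalize_channels(osc$channels), channels)
    if (anyNA(osc_ci)) abort("oscillation channels not all in montage")
    inwin <- as.numeric(times >= osc$mod_window_ms[1] &
                          times <= osc$mod_window_ms[2])
    if (osc$ramp_ms > 0) { # smooth the window edges
      k_t <- seq(-3 * osc$ramp_ms, 3 * osc$ramp_ms, by = 1000 / fs)
      k <- exp(-k_t^2 / (2 * osc$ramp_ms^2))
      k <- k / sum(k)
      inwin <- stats::filter(c(rep(inwin[1], length(k)), inwin,
                               rep(inwin[nt], length(k))), k, sides = 2)
      inwin <- as.numeric(inwin)[length(k) + seq_len(nt)]
    }
    env <- 1 + (osc$mod_factor - 1) * inwin
  }

  data <- array(0, dim = c(n_trials, length(channels), nt))
  t_s <- times / 1000
  for (tr in seq_len(n_trials)) {
    sig <- base
    if (!is.null(env)) {
      gain <- if (osc$coupling_gain != 0) {
        exp(-osc$coupling_gain * drift[tr] / 2)
      } else 1
      phase <- runif(1, 0, 2 * pi)
      wave <- osc$amp_uv * gain * env * sin(2 * pi * osc$freq_hz * t_s + phase)
      sig[osc_ci, ] <- sig[osc_ci, ] + rep(wave, each = length(osc_ci))
    }
    if (noise_sd > 0) {
      noise <- if (noise_model == "white") {
        matrix(rnorm(length(channels) * nt, 0, noise_sd), length(channels), nt)
      } else {
        t(vapply(seq_along(channels),
                 function(i) noise_sd * pink_noise(nt, fs), numeric(nt)))
      }
      sig <- sig + noise
    }
    data[tr, , ] <- sig
  }
  epoch_array(data, fs, epoch_window_ms[1], channels, info = trials)
}
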