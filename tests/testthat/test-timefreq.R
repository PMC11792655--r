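osc_epochs <- function(freq = 10, amp = 1, n_trials = 1, fs = 250,
                       window = c(-500, 800), phase = 0, envelope = NULL,
                       channels = "CZ") {
  times <- seq(window[1], window[2], by = 1000 / fs)
  env <- envelope %||% rep(1, length(times))
  data <- array(0, dim = c(n_trials, length(channels), length(times)))
  for (tr in seq_len(n_trials)) {
    ph <- if (is.na(phase)) runif(1, 0, 2 * pi) else phase
    wave <- amp * env * sin(2 * pi * freq * times / 1000 + ph)
    for (ch in seq_along(channels)) data[tr, ch, ] <- wave
  }
  epoch_array(data, fs, window[1], channels,
              info = tibble::tibble(subject = "s1", label = "self",
                                    match = "match")[rep(1, n_trials), ])
}

test_that("wavelet widths, energies and center frequencies follow the family definition", {
  fam <- build_wavelets(freqs = c(5, 10, 20), ratio = 5, fs = 1000)
  # f0/sigma_f = 5 and sigma_t = 1/(2 pi sigma_f): at 10 Hz, sigma_t ~ 79.6 ms
  expect_equal(fam$sigma_t[2], 1 / (2 * pi * 2), tolerance = 1e-12)
  expect_true(all(diff(fam$sigma_t) < 0))
  for (i in seq_along(fam$freqs)) {
    energy <- sum(Mod(fam$kernels[[i]])^2) / 1000
    expect_lt(abs(energy - 1), 1e-3)
    spec <- Mod(fft(fam$kernels[[i]]))^2
    faxis <- (seq_along(spec) - 1) * 1000 / length(spec)
    expect_lt(abs(faxis[which.max(spec)] - fam$freqs[i]),
              1000 / length(fam$kernels[[i]]) + 0.5)
  }
  expect_error(build_wavelets(freqs = 1:40, fs = 60), "Nyquist")
})

test_that("phase-locked removal zeroes identical trials and keeps induced power", {
  ep <- osc_epochs(n_trials = 5, phase = 0)
  out <- remove_phase_locked(ep)
  expect_lt(max(abs(out$data)), 1e-12)
  # random-phase oscillation: condition mean is zero by construction and
  # power survives subtraction
  set.seed(21)
  ep2 <- osc_epochs(n_trials = 120, phase = NA)
  out2 <- remove_phase_locked(ep2)
  expect_lt(max(abs(apply(out2$data, c(2, 3), mean))), 1e-9)
  pow_before <- mean(ep2$data^2)
  pow_after <- mean(out2$data^2)
  expect_gt(pow_after / pow_before, 0.95)
  ep3 <- osc_epochs(n_trials = 1)
  expect_warning(remove_phase_locked(ep3), "singleton")
})

test_that("time-frequency power peaks at the oscillation frequency and scales quadratically", {
  ep <- osc_epochs(freq = 10, amp = 1)
  fam <- build_wavelets(freqs = 5:20, fs = 250)
  tfr <- tf_power(ep, fam)
  prof <- apply(tfr$power[1, , ], 1, mean, na.rm = TRUE)
  expect_equal(tfr$freqs[which.max(prof)], 10)
  ep2 <- osc_epochs(freq = 10, amp = 2)
  tfr2 <- tf_power(ep2, fam)
  expect_equal(tfr2$power, 4 * tfr$power, tolerance = 1e-8)
  tiny <- subset_epochs(ep, time_ms = c(-20, 20))
  expect_error(tf_power(tiny, build_wavelets(freqs = 2, fs = 250)),
               "shorter")
})

test_that("white-noise power is stationary over the valid region", {
  set.seed(22)
  ep <- osc_epochs(amp = 0)
  ep$data[] <- rnorm(length(ep$data))
  fam <- build_wavelets(freqs = 10, fs = 250)
  tfr <- tf_power(ep, fam)
  p <- tfr$power[1, 1, ]
  p <- p[!is.na(p)]
  # single-trial wavelet power is exponentially distributed; the smoothed
  # series should show no trend
  half1 <- mean(p[seq_len(floor(length(p) / 2))])
  half2 <- mean(p[-seq_len(floor(length(p) / 2))])
  expect_lt(abs(half1 - half2) / mean(p), 0.5)
})

test_that("ERS/ERD is the proportional power change and is scale-invariant", {
  fake <- structure(list(
    power = array(2, dim = c(1, 1, 100)), freqs = 10,
    times = seq(-400, -5 + 95 * 4, by = 4), channels = "CZ", fs = 250,
    keep_trials = FALSE, info = NULL), class = "prio_tfr")
  fake$times <- seq(-400, by = 4, length.out = 100)
  out <- ers_erd(fake, baseline_ms = c(-300, -100))
  expect_true(all(out$power == 0))
  fake2 <- fake
  post <- fake2$times > 0
  fake2$power[, , post] <- 4 # doubled power -> ERS = +1
  out2 <- ers_erd(fake2, baseline_ms = c(-300, -100))
  expect_true(all(out2$power[, , post] == 1))
  expect_true(all(out2$power >= -1))
  # multiplying the raw signal by a constant leaves ERS/ERD unchanged
  set.seed(23)
  ep <- osc_epochs(freq = 10, amp = 1, envelope = NULL)
  ep$data <- ep$data + 0.1 * rnorm(length(ep$data))
  fam <- build_wavelets(freqs = 8:12, fs = 250)
  e1 <- ers_erd(tf_power(ep, fam))
  ep2 <- ep
  ep2$data <- 3 * ep2$data
  e2 <- ers_erd(tf_power(ep2, fam))
  expect_equal(e1$power, e2$power, tolerance = 1e-9)
})

test_that("a planted post-stimulus alpha power drop is recovered as ERD", {
  fs <- 250
  times <- seq(-500, 800, by = 1000 / fs)
  ramp <- 1 / (1 + exp(-(times - 150) / 10)) # smooth onset at ~150 ms
  env <- sqrt(1 - 0.3 * ramp)                # -30% power after onset
  set.seed(24)
  ep <- osc_epochs(freq = 10, amp = 2, n_trials = 30, phase = NA,
                   envelope = env)
  fam <- build_wavelets(freqs = 10, fs = fs)
  er <- ers_erd(tf_power(ep, fam, keep_trials = TRUE))
  erd <- mean(tfr_band_mean(er, c(10, 10), c(350, 650))$power)
  expect_lt(abs(erd - (-0.3)), 0.03)
})

test_that("the analysis bands partition 2-29 Hz as published", {
  bd <- tf_bands()
  expect_equal(bd$fmin, c(2, 8, 19))
  expect_equal(bd$fmax, c(7, 18, 29))
  grid <- 1:40
  alpha_idx <- grid[grid >= bd$fmin[2] & grid <= bd$fmax[2]]
  expect_equal(alpha_idx, 8:18)
})

test_that("total wavelet power tracks signal variance across frequencies", {
  fam <- build_wavelets(freqs = 5:30, fs = 250)
  ratio <- vapply(c(10, 15), function(f0) {
    ep <- osc_epochs(freq = f0, amp = 1)
    tfr <- tf_power(ep, fam)
    tot <- mean(apply(tfr$power[1, , ], 2, sum)[!is.na(tfr$power[1, 1, ])])
    tot / var(ep$data[1, 1, ])
  }, numeric(1))
  expect_lt(abs(ratio[1] - ratio[2]) / ratio[1], 0.1)
})
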