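flat_epochs <- function(n_trials = 4, channels = c("FZ", "CZ", "PZ"),
                        fs = 250, value = 0, info = NULL) {
  nt <- round(1000 * fs / 1000) + 1
  data <- array(value, dim = c(n_trials, length(channels), nt))
  epoch_array(data, fs, -200, channels, info = info)
}

test_that("the component registry reproduces the published windows and clusters", {
  defs <- erp_components()
  expected <- list(
    N1 = list(c(100, 150), c("FCZ", "FZ", "CZ")),
    posterior_N1 = list(c(147, 167), c("TP7", "T5")),
    P2 = list(c(180, 240), c("FC3", "FC4", "FCZ", "C3", "C4", "CZ",
                             "CP3", "CP4", "CPZ")),
    N2 = list(c(240, 300), c("P4", "PZ", "T4", "T6", "TP8", "C4", "CZ",
                             "CP4", "CPZ")),
    P3 = list(c(320, 360), c("P3", "PZ", "TP7", "T5", "CP3", "O1", "O2",
                             "OZ")),
    LPP = list(c(500, 700), c("FZ", "FC3", "FC4", "FCZ", "C3", "C4", "CZ",
                              "CPZ"))
  )
  for (nm in names(expected)) {
    row <- defs[defs$component == nm, ]
    expect_equal(c(row$window_lo, row$window_hi), expected[[nm]][[1]])
    expect_setequal(row$channels[[1]], expected[[nm]][[2]])
  }
  # the LPP peak-search window extends past the measurement window
  expect_equal(defs$peak_hi[defs$component == "LPP"], 800)
  expect_true(all(unlist(defs$channels) %in% default_montage()$channel))
})

test_that("baseline correction zeroes constants and is offset-invariant", {
  ep <- flat_epochs(value = 3)
  out <- epoch_and_baseline(ep)
  expect_true(all(out$data == 0))
  # per-channel offsets cancel exactly
  ep2 <- flat_epochs()
  ep2$data[, 1, ] <- ep2$data[, 1, ] + 7
  ep2$data[, 2, ] <- ep2$data[, 2, ] - 2
  sig <- sin(seq(-200, 800, by = 4) / 50)
  ep3 <- ep2
  ep3$data <- sweep(ep3$data, 3, sig, "+")
  out2 <- epoch_and_baseline(ep2)
  out3 <- epoch_and_baseline(ep3)
  expect_equal(out3$data - out2$data,
               sweep(array(0, dim(out2$data)), 3,
                     sig - mean(sig[seq_len(51)]), "+"),
               tolerance = 1e-12)
  expect_error(epoch_and_baseline(ep, baseline_ms = c(-400, 0)), "inside")
})

test_that("artifact rejection removes exactly the contaminated trials", {
  ep <- flat_epochs(n_trials = 10, info = tibble::tibble(
    subject = "s1", label = rep(c("self", "friend"), 5)))
  spiked <- c(2, 7, 9)
  for (i in spiked) ep$data[i, 1, 50] <- 100
  out <- reject_artifacts(ep, threshold_uv = 70, by = "label")
  expect_equal(dim(out$data)[1], 7)
  log <- attr(out, "rejection_log")
  expect_equal(sum(log$n_rejected), 3)
  # infinite threshold is the identity
  out_inf <- reject_artifacts(ep, threshold_uv = Inf)
  expect_equal(dim(out_inf$data)[1], 10)
  ep_bad <- flat_epochs(value = 200)
  expect_error(reject_artifacts(ep_bad, 70), "all .* trials exceed")
})

test_that("component amplitude averages cluster, window and trials exactly", {
  ep <- flat_epochs(channels = c("FCZ", "FZ", "CZ"),
                    info = tibble::tibble(subject = "s1", label = "self",
                                          match = "match")[rep(1, 4), ])
  ep$data[] <- 5
  amp <- component_amplitude(ep, "N1")
  expect_equal(amp$amplitude_uv, 5)
  # linear ramp 0 -> 10 over the window averages to 5
  ramp_def <- tibble::tibble(component = "ramp", window_lo = 100,
                             window_hi = 200, peak_lo = 100, peak_hi = 200,
                             polarity = 1, channels = list("FZ"))
  ep2 <- flat_epochs(channels = "FZ",
                     info = tibble::tibble(subject = "s1", label = "self",
                                           match = "match")[rep(1, 4), ])
  si <- which(ep2$times >= 100 & ep2$times <= 200)
  ep2$data[, 1, si] <- rep(seq(0, 10, length.out = length(si)),
                           each = dim(ep2$data)[1])
  amp2 <- component_amplitude(ep2, ramp_def)
  expect_equal(amp2$amplitude_uv, 5, tolerance = 1e-12)
  # extraction is linear in the data
  ep3 <- ep2
  ep3$data <- ep3$data * 3.5
  expect_equal(component_amplitude(ep3, ramp_def)$amplitude_uv,
               3.5 * amp2$amplitude_uv, tolerance = 1e-12)
  expect_error(component_amplitude(ep2, "P2"), "FC3")
})

test_that("peak latency finds the extremum, honors ties and warns on flat data", {
  fs <- 250
  times <- seq(-200, 800, by = 1000 / fs)
  bump <- exp(-(times - 652)^2 / (2 * 40^2)) # peak at nearest sample to 652
  lpp_def <- tibble::tibble(component = "LPP2", window_lo = 500,
                            window_hi = 700, peak_lo = 500, peak_hi = 800,
                            polarity = 1, channels = list("CZ"))
  ep <- flat_epochs(channels = "CZ", fs = fs,
                    info = tibble::tibble(subject = "s1", label = "self",
                                          match = "match")[rep(1, 4), ])
  ep$data <- sweep(ep$data, 3, bump, "+")
  out <- peak_latency(ep, lpp_def)
  expect_equal(out$latency_ms, 652)
  # two equal peaks: the earlier wins
  twin <- numeric(length(times))
  twin[times == 600] <- 1
  twin[times == 680] <- 1
  ep2 <- ep
  ep2$data <- sweep(array(0, dim(ep$data)), 3, twin, "+")
  expect_equal(peak_latency(ep2, lpp_def)$latency_ms, 600)
  ep3 <- flat_epochs(channels = "CZ", fs = fs,
                     info = tibble::tibble(subject = "s1", label = "self",
                                           match = "match")[rep(1, 4), ])
  expect_warning(peak_latency(ep3, lpp_def), "flat")
})

test_that("averaged peak latency is robust to noise at realistic trial counts", {
  set.seed(33)
  fs <- 250
  times <- seq(-200, 800, by = 1000 / fs)
  bump <- 2 * exp(-(times - 600)^2 / (2 * 50^2))
  data <- array(rnorm(100 * 1 * length(times), 0, 2),
                dim = c(100, 1, length(times)))
  data <- sweep(data, 3, bump, "+")
  ep <- epoch_array(data, fs, -200, "CZ",
                    info = tibble::tibble(subject = "s1", label = "self",
                                          match = "match")[rep(1, 100), ])
  cdef <- tibble::tibble(component = "LPP2", window_lo = 500, window_hi = 700,
                         peak_lo = 450, peak_hi = 750, polarity = 1,
                         channels = list("CZ"))
  out <- peak_latency(ep, cdef)
  expect_lt(abs(out$latency_ms - 600), 10)
})

test_that("rejection then averaging equals averaging the retained subset", {
  set.seed(34)
  ep <- flat_epochs(n_trials = 12, channels = c("FCZ", "FZ", "CZ"),
                    info = tibble::tibble(subject = "s1", label = "self",
                                          match = "match")[rep(1, 12), ])
  ep$data <- ep$data + array(rnorm(length(ep$data), 0, 10), dim(ep$data))
  clean <- reject_artifacts(ep, threshold_uv = 35)
  keep <- which(apply(abs(ep$data), 1, max) <= 35)
  manual <- apply(ep$data[keep, , , drop = FALSE], c(2, 3), mean)
  expect_equal(apply(clean$data, c(2, 3), mean), manual, tolerance = 1e-12)
})
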