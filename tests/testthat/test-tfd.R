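tt <- seq(-1000, 2000) / 1000  # seconds

make_tf <- function(power, freqs = 1:100, time_ms = seq(-500, 1000),
                    corrected = TRUE, cropped = TRUE) {
  structure(list(power = power, freq_hz = freqs, time_ms = time_ms,
                 baseline_corrected = corrected, cropped = cropped),
            class = "tf_map")
}

test_that("STFT concentrates power at the driving frequency", {
  ep <- signal_epochs(list(sin(2 * pi * 70 * tt)))
  tf <- stft_power(ep)
  p70 <- mean(tf$power[1, 1, 70, ])
  p20 <- mean(tf$power[1, 1, 20, ])
  expect_gt(p70 / p20, 100)
})

test_that("an impulse at t = 0 spreads no further than the window support", {
  x <- numeric(3001); x[1001] <- 1  # t = 0
  tf <- stft_power(signal_epochs(list(x)), crop = NULL)
  tot <- apply(tf$power[1, 1, , ], 2, sum)
  expect_true(all(tot[abs(tf$time_ms) > 100] < 1e-20))
  expect_gt(sum(tot[abs(tf$time_ms) <= 100]), 0)
})

test_that("chirp ridge frequency increases with time", {
  f0 <- 20; f1 <- 80
  inst <- f0 + (f1 - f0) * (tt - tt[1]) / 3  # linear 20 -> 80 Hz
  x <- sin(2 * pi * cumsum(inst) / 1000)
  tf <- stft_power(signal_epochs(list(x)))
  ridge <- apply(tf$power[1, 1, , ], 2, which.max)
  sm <- stats::filter(ridge, rep(1 / 101, 101))
  sm <- sm[!is.na(sm)]
  expect_true(all(diff(sm) >= -0.05))
  expect_gt(sm[length(sm)] - sm[1], 20)
})

test_that("baseline subtraction zeroes the baseline and constants", {
  set.seed(1)
  ep <- signal_epochs(lapply(1:3, function(i) rnorm(3001)), n_channels = 2)
  tf <- baseline_subtract(stft_power(ep))
  idx <- tf$time_ms >= -400 & tf$time_ms <= -100
  resid <- apply(tf$power[, , , idx, drop = FALSE], 1:3, mean)
  expect_lt(max(abs(resid)), 1e-6)
  # constant map -> all zero
  cm <- make_tf(array(5, dim = c(2, 1, 100, 1501)), corrected = FALSE)
  out <- baseline_subtract(cm)
  expect_equal(max(abs(out$power)), 0)
  expect_true(out$baseline_corrected)
  expect_error(baseline_subtract(cm, interval = c(5000, 6000)), "empty")
})

test_that("stationary noise has near-zero post-stimulus ROI after correction", {
  set.seed(2)
  ep <- signal_epochs(lapply(1:40, function(i) rnorm(3001)))
  tf <- baseline_subtract(stft_power(ep))
  v <- roi_power(tf)
  expect_lt(abs(mean(v)), 2 * sd(v) / sqrt(length(v)) + 1e-6)
})

test_that("roi_power averages the stated rectangle and guards cropping", {
  ones <- make_tf(array(1, dim = c(3, 2, 100, 1501)))
  expect_equal(roi_power(ones), rep(1, 3))
  blk <- array(0, dim = c(1, 1, 100, 1501))
  tm <- seq(-500, 1000)
  blk[1, 1, 55:90, tm >= 200 & tm <= 500] <- 2
  expect_equal(roi_power(make_tf(blk)), 2)
  uncropped <- make_tf(array(1, dim = c(1, 1, 100, 3001)),
                       time_ms = seq(-1000, 2000), cropped = FALSE)
  expect_error(roi_power(uncropped), "cropped")
  expect_error(roi_power(ones, f_band = c(300, 400)), "outside")
  expect_error(roi_power(ones, electrodes = "nope"), "nope")
})

test_that("summed STFT power scales with signal variance (Parseval-style)", {
  set.seed(3)
  x <- rnorm(3001)
  p1 <- sum(stft_power(signal_epochs(list(x)))$power)
  p2 <- sum(stft_power(signal_epochs(list(2 * x)))$power)
  expect_lt(abs(p2 / p1 - 4), 0.05 * 4)
})

test_that("LEP waveform recovers an injected half-cosine N2 closed-form", {
  # -60 uV half-cosine, center 325 ms, width 150 ms, support = the N2 ROI
  tm <- seq(-1000, 2000)
  u <- (tm - 250) / 150
  tmpl <- ifelse(u >= 0 & u <= 1, -60 * sin(pi * u), 0)
  data <- array(0, dim = c(1, 4, 3001))
  for (ch in 1:4) data[1, ch, ] <- tmpl
  ep <- make_epoch_set(data, labels = n2_electrodes())
  lw <- lep_waveform(ep)
  expected <- -60 * 2 / pi  # mean of sin(pi u) over its support
  expect_lt(abs(lw$n2_amplitude - expected), 0.75)
  expect_true(all(lw$time_ms >= -500 & lw$time_ms <= 1000))
  # zero signal -> zero amplitude
  z <- lep_waveform(make_epoch_set(array(0, dim = c(1, 4, 3001)),
                                   labels = n2_electrodes()))
  expect_equal(z$n2_amplitude, 0)
  expect_error(lep_waveform(ep, electrodes = c("FL2", "QQ")), "QQ")
  expect_error(lep_waveform(ep, lowpass = 600), "Nyquist")
})

test_that("synthetic awake trials show stronger N2 and gamma than moderate", {
  specs <- default_state_specs()
  mk <- function(sp) {
    sigs <- lapply(1:20, function(s) generate_epoch(sp, seed = 7000 + s))
    make_epoch_set(aperm(simplify2array(sigs), c(3, 1, 2)),
                   labels = default_montage())
  }
  ep_aw <- mk(specs$awake); ep_mod <- mk(specs$moderate)
  expect_lt(mean(lep_waveform(ep_aw)$n2_amplitude),
            mean(lep_waveform(ep_mod)$n2_amplitude))
  gbo <- function(ep) mean(roi_power(baseline_subtract(stft_power(ep)),
                                     electrodes = n2_electrodes()))
  expect_gt(gbo(ep_aw), gbo(ep_mod))
})

test_that("gamma ROI power is monotone in gbo_gain (rank correlation)", {
  gains <- c(0, 0.5, 1, 2)
  per_trial <- lapply(gains, function(g) {
    sp <- state_spec("shallow", n2_amplitude = 0, gbo_gain = g)
    sigs <- lapply(1:15, function(s) generate_epoch(sp, seed = 5000 + s))
    ep <- make_epoch_set(aperm(simplify2array(sigs), c(3, 1, 2)),
                         labels = default_montage())
    roi_power(baseline_subtract(stft_power(ep)), electrodes = n2_electrodes())
  })
  rho <- cor(rep(gains, each = 15), unlist(per_trial), method = "spearman")
  expect_gt(rho, 0.8)
})
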