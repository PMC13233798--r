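# Laser-evoked potentials and short-time Fourier time-frequency maps.
#
# The STFT uses a 200-ms Hanning window, 1-ms steps and 1-Hz bins (1-100 Hz),
# evaluated on the full -1000..2000 ms epoch and cropped to -500..1000 ms so
# window-edge artifacts never reach an ROI statistic (each retained value
# depends only on the samples inside its own window, so the crop can be
# applied at evaluation time without changing any retained value; epoch-edge
# windows are zero-padded and discarded by the crop anyway). Power is the
# squared magnitude of the windowed DFT (one-sided, linear units), computed
# as two real matrix products (cos/sin kernels x windowed segment matrix) so
# BLAS carries the hot loop.

#' Short-time Fourier power of an epoch set
#'
#' @param ep an `epoch_set`.
#' @param win_ms analysis window length, ms.
#' @param step_ms time step, ms (integer multiple of the sample step).
#' @param freqs frequency axis, Hz (integer bins).
#' @param crop interval retained after computation, ms (`NULL` keeps all).
#' @param trials trial indices to compute (default all; pass subsets to bound
#'   memory, the result array is trials x channels x freqs x times).
#' @return a `tf_map`: `power`, `freq_hz`, `time_ms`, flags
#'   `baseline_corrected`, `cropped`.
#' @export
stft_power <- function(ep, win_ms = 200, step_ms = 1, freqs = 1:100,
                       crop = c(-500, 1000), trials = NULL) {
  stopifnot(inherits(ep, "epoch_set"))
  d <- dim(ep$data)
  trials <- trials %||% seq_len(d[1])
  fs <- ep$fs
  L <- round(win_ms * fs / 1000)
  if (L >= d[3]) stop_bad_arg("STFT window must be shorter than the epoch")
  off <- L %/% 2
  n <- d[3]
  j <- 0:(L - 1)
  w <- 0.5 * (1 - cos(2 * pi * j / (L - 1)))  # Hanning
  kr <- t(vapply(freqs, function(f) w * cos(2 * pi * f * j / fs), numeric(L)))
  ki <- t(vapply(freqs, function(f) w * sin(2 * pi * f * j / fs), numeric(L)))
  t_keep <- seq(from = 1L, to = n, by = round(step_ms * fs / 1000))
  time_ms <- ep$time_ms[t_keep]
  if (!is.null(crop)) {
    sel <- time_ms >= crop[1] & time_ms <= crop[2]
    t_keep <- t_keep[sel]; time_ms <- time_ms[sel]
  }
  # window for epoch sample t covers x[t - off .. t + L - 1 - off]; the
  # edge overhang reads zero padding
  nt <- length(t_keep)
  npad <- n + L  # per-channel padded length
  idx1 <- outer(seq_len(L), t_keep, function(a, b) a + b - 1L)
  # all channels of one trial in a single segment matrix / BLAS call
  idx <- as.vector(outer(as.vector(idx1), (seq_len(d[2]) - 1L) * npad, `+`))
  power <- array(0, dim = c(length(trials), d[2], length(freqs), nt),
                 dimnames = list(NULL, dimnames(ep$data)[[2]], NULL, NULL))
  xp <- matrix(0, npad, d[2])
  for (ti in seq_along(trials)) {
    xp[off + seq_len(n), ] <- t(matrix(ep$data[trials[ti], , ], nrow = d[2]))
    S <- matrix(xp[idx], nrow = L)  # L x (nt * channels)
    p2 <- (kr %*% S)^2 + (ki %*% S)^2
    power[ti, , , ] <- aperm(array(p2, dim = c(length(freqs), nt, d[2])),
                             c(3, 1, 2))
  }
  structure(list(power = power, freq_hz = freqs, time_ms = time_ms,
                 baseline_corrected = FALSE, cropped = !is.null(crop)),
            class = "tf_map")
}

#' @export
print.tf_map <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf("<tf_map> %d trials x %d channels x %d freqs x %d times (%scorrected, %scropped)\n",
              d[1], d[2], d[3], d[4],
              if (x$baseline_corrected) "" else "un", if (x$cropped) "" else "un"))
  invisible(x)
}

#' Subtract a per-trial baseline from a time-frequency map
#'
#' For every (trial, channel, frequency), the mean power over the baseline
#' interval is subtracted (the single-trial subtraction procedure).
#'
#' @param tf a `tf_map`.
#' @param interval baseline interval, ms (default -400..-100).
#' @return the corrected `tf_map`.
#' @export
baseline_subtract <- function(tf, interval = c(-400, -100)) {
  stopifnot(inherits(tf, "tf_map"))
  idx <- ms_index(tf$time_ms, interval[1], interval[2])
  if (!length(idx)) stop_bad_arg("baseline interval is empty on this time axis")
  base <- rowMeans(tf$power[, , , idx, drop = FALSE], dims = 3)
  tf$power <- tf$power - as.vector(base)  # recycles over the time dimension
  tf$baseline_corrected <- TRUE
  tf
}

#' Mean power in a rectangular region of interest
#'
#' Structural guard: ROI statistics are only defined on the cropped
#' (-500..1000 ms) map, so uncropped maps are refused.
#'
#' @param tf a `tf_map` (cropped).
#' @param f_band frequency band, Hz, closed interval (default the gamma ROI
#'   55-90 Hz).
#' @param t_win time window, ms, closed interval (default 200-500 ms).
#' @param electrodes channel labels to average (default all).
#' @return per-trial scalar (mean over the ROI rectangle and channels).
#' @export
roi_power <- function(tf, f_band = c(55, 90), t_win = c(200, 500),
                      electrodes = NULL) {
  stopifnot(inherits(tf, "tf_map"))
  if (!tf$cropped) stop_bad_arg("ROI statistics require the cropped map")
  fi <- which(tf$freq_hz >= f_band[1] & tf$freq_hz <= f_band[2])
  ti <- ms_index(tf$time_ms, t_win[1], t_win[2])
  if (!length(fi) || !length(ti)) stop_bad_arg("ROI lies outside the map axes")
  ch <- if (is.null(electrodes)) seq_len(dim(tf$power)[2]) else {
    m <- match(electrodes, dimnames(tf$power)[[2]])
    if (anyNA(m)) stop_bad_arg(paste("unknown electrode:", electrodes[is.na(m)][1]))
    m
  }
  apply(tf$power[, ch, fi, ti, drop = FALSE], 1, mean)
}

#' Laser-evoked potential waveforms and N2 amplitude
#'
#' Low-pass filters each trial at `lowpass` Hz (zero-phase Butterworth), crops
#' to -500..1000 ms, averages the named electrodes, and summarizes the
#' N2 wave as the signed mean amplitude over 250-400 ms post-stimulus
#' (more negative = larger N2).
#'
#' @param ep an `epoch_set`.
#' @param lowpass cutoff, Hz (< fs/2).
#' @param electrodes electrode labels averaged into the waveform (default the
#'   central N2 set FL2, FR2, PL1, PR1).
#' @param crop retained interval, ms.
#' @param n2_win N2 region of interest, ms.
#' @return list with `waveform` (trials x times, microvolt), `time_ms`, and
#'   `n2_amplitude` (per-trial).
#' @export
lep_waveform <- function(ep, lowpass = 30, electrodes = n2_electrodes(),
                         crop = c(-500, 1000), n2_win = c(250, 400)) {
  stopifnot(inherits(ep, "epoch_set"))
  if (lowpass >= ep$fs / 2) stop_bad_arg("lowpass must be below Nyquist")
  ch <- match(electrodes, dimnames(ep$data)[[2]])
  if (anyNA(ch)) stop_bad_arg(paste("unknown electrode:", electrodes[is.na(ch)][1]))
  sos <- butter_sos(4, lowpass, ep$fs, "low")
  keep <- ms_index(ep$time_ms, crop[1], crop[2])
  ntr <- dim(ep$data)[1]
  wav <- matrix(0, ntr, length(keep))
  for (tr in seq_len(ntr)) {
    acc <- 0
    for (c0 in ch) acc <- acc + sos_filtfilt(ep$data[tr, c0, ], sos)
    wav[tr, ] <- (acc / length(ch))[keep]
  }
  tm <- ep$time_ms[keep]
  roi <- ms_index(tm, n2_win[1], n2_win[2])
  list(waveform = wav, time_ms = tm,
       n2_amplitude = rowMeans(wav[, roi, drop = FALSE]))
}
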