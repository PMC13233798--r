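# Continuous recordings -> artifact-screened, baseline-corrected epochs.
# Mirrors the conventional ECoG chain: zero-phase Butterworth band-pass
# (1-100 Hz) plus 49-51 Hz notch on the referenced signal (no re-referencing),
# segmentation into -1000..2000 ms epochs (inclusive endpoints, 3001 samples
# at 1000 Hz), pre-stimulus baseline subtraction, and 500 uV amplitude
# rejection. Rejected trials stay in the container with a reason code and are
# excluded from every downstream feature computation.

#' Band-pass and notch filter a continuous recording
#'
#' Zero-phase (forward-backward) Butterworth filtering, band-pass then
#' band-stop, applied per channel.
#'
#' @param rec an `ecog_recording` (fields `signal` channels x samples, `fs`,
#'   `channel_labels`, `subject_id`).
#' @param band pass band, Hz.
#' @param notch stop band, Hz (set `NULL` to skip).
#' @param order Butterworth prototype order (even).
#' @return the filtered recording, same shape.
#' @export
bandpass_notch <- function(rec, band = c(1, 100), notch = c(49, 51), order = 4) {
  stopifnot(inherits(rec, "ecog_recording"))
  if (band[1] <= 0 || band[2] >= rec$fs / 2)
    stop_bad_arg("pass band must lie strictly inside (0, fs/2)")
  if (!is.null(notch) && (notch[1] <= band[1] || notch[2] >= band[2]))
    stop_bad_arg("notch interval must lie inside the pass band")
  sos_bp <- butter_sos(order, band, rec$fs, "pass")
  sos_bs <- if (!is.null(notch)) butter_sos(order, notch, rec$fs, "stop")
  pad <- min(3L * rec$fs, ncol(rec$signal) - 2L)
  out <- rec
  for (ch in seq_len(nrow(rec$signal))) {
    y <- sos_filtfilt(rec$signal[ch, ], sos_bp, padlen = pad)
    if (!is.null(sos_bs)) y <- sos_filtfilt(y, sos_bs, padlen = pad)
    out$signal[ch, ] <- y
  }
  out
}

new_epoch_set <- function(data, time_ms, events, rejected, fs) {
  structure(list(data = data, time_ms = time_ms, events = events,
                 rejected = rejected, fs = fs), class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples (%g..%g ms), %d rejected\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              min(x$time_ms), max(x$time_ms), sum(!is.na(x$rejected$reason))))
  invisible(x)
}

#' Indices of retained (non-rejected) trials
#' @param ep an `epoch_set`.
#' @return integer vector.
#' @export
retained_trials <- function(ep) which(is.na(ep$rejected$reason))

#' Segment a recording into stimulus-locked baseline-corrected epochs
#'
#' Epochs are inclusive of both window endpoints at the native resolution
#' (3001 samples for -1000..2000 ms at 1000 Hz). Each trial and channel has
#' the mean over the baseline interval subtracted. Events whose window does
#' not fit inside the recording are kept but flagged rejected with reason
#' `"edge"`.
#'
#' @param rec filtered `ecog_recording`.
#' @param events event table with 0-based `onset_sample` (see
#'   [generate_cohort()]).
#' @param window epoch window, ms relative to stimulus.
#' @param baseline baseline interval, ms (default the full pre-stimulus
#'   interval).
#' @return an `epoch_set`: `data` trials x channels x samples, `time_ms`,
#'   `events`, `rejected` (trial, reason), `fs`.
#' @export
epoch_recording <- function(rec, events, window = c(-1000, 2000),
                            baseline = c(-1000, 0)) {
  stopifnot(inherits(rec, "ecog_recording"))
  fs <- rec$fs
  i0 <- round(window[1] * fs / 1000)
  i1 <- round(window[2] * fs / 1000)
  time_ms <- (i0:i1) * 1000 / fs
  nsamp <- length(time_ms)
  nch <- nrow(rec$signal)
  ntr <- nrow(events)
  data <- array(0, dim = c(ntr, nch, nsamp),
                dimnames = list(NULL, rec$channel_labels, NULL))
  reason <- rep(NA_character_, ntr)
  bidx <- ms_index(time_ms, baseline[1], baseline[2])
  for (tr in seq_len(ntr)) {
    onset <- events$onset_sample[tr] + 1L  # 0-based -> 1-based
    lo <- onset + i0; hi <- onset + i1
    if (lo < 1 || hi > ncol(rec$signal)) {
      reason[tr] <- "edge"
      next
    }
    seg <- rec$signal[, lo:hi, drop = FALSE]
    seg <- seg - rowMeans(seg[, bidx, drop = FALSE])
    data[tr, , ] <- seg
  }
  new_epoch_set(data, time_ms, events,
                data.frame(trial = seq_len(ntr), reason = reason,
                           stringsAsFactors = FALSE), fs)
}

#' Reject trials by absolute amplitude
#'
#' A trial is flagged with reason `"amplitude"` when any channel/sample
#' exceeds the threshold in absolute value. Purely per-trial, so rejection is
#' order-independent; already-rejected trials keep their first reason.
#'
#' @param ep an `epoch_set`.
#' @param threshold microvolt (> 0); default 500.
#' @return the `epoch_set` with an updated rejection log.
#' @export
reject_amplitude <- function(ep, threshold = 500) {
  stopifnot(inherits(ep, "epoch_set"))
  if (threshold <= 0) stop_bad_arg("threshold must be > 0")
  for (tr in seq_len(dim(ep$data)[1])) {
    if (!is.na(ep$rejected$reason[tr])) next
    if (max(abs(ep$data[tr, , ])) > threshold)
      ep$rejected$reason[tr] <- "amplitude"
  }
  ep
}

#' Preprocess a whole cohort
#'
#' Convenience chain: filter each subject's recording, epoch its events, and
#' apply amplitude rejection; epoch sets are concatenated across subjects in
#' event order.
#'
#' @param cohort a `syn_cohort` (or list with `recordings`, `events`, `fs`).
#' @param band,notch,order see [bandpass_notch()].
#' @param window,baseline see [epoch_recording()].
#' @param threshold see [reject_amplitude()].
#' @return an `epoch_set` covering all subjects.
#' @export
preprocess_cohort <- function(cohort, band = c(1, 100), notch = c(49, 51),
                              order = 4, window = c(-1000, 2000),
                              baseline = c(-1000, 0), threshold = 500) {
  sets <- lapply(cohort$recordings, function(rec) {
    ev <- cohort$events[cohort$events$subject_id == rec$subject_id, , drop = FALSE]
    filt <- bandpass_notch(rec, band, notch, order)
    reject_amplitude(epoch_recording(filt, ev, window, baseline), threshold)
  })
  data <- do.call(abind1, lapply(sets, `[[`, "data"))
  events <- do.call(rbind, lapply(sets, `[[`, "events"))
  rejected <- do.call(rbind, lapply(sets, `[[`, "rejected"))
  rejected$trial <- seq_len(nrow(rejected))
  rownames(events) <- rownames(rejected) <- NULL
  new_epoch_set(data, sets[[1]]$time_ms, events, rejected, cohort$fs)
}

# bind 3-D arrays along the first (trial) dimension
abind1 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  out <- array(0, dim = c(sum(vapply(arrs, function(a) dim(a)[1], 0L)), d[2], d[3]),
               dimnames = list(NULL, dimnames(arrs[[1]])[[2]], NULL))
  at <- 0L
  for (a in arrs) {
    n <- dim(a)[1]
    if (n > 0) out[at + seq_len(n), , ] <- a
    at <- at + n
  }
  out
}
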