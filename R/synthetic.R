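# Synthetic four-state ECoG generator.
#
# The generator emulates the stimulus-locked structure the downstream analysis
# assumes: a 1/f-colored background with a shared cross-channel source, a
# low-frequency evoked N2 deflection (250-400 ms), an evoked gamma burst
# (55-90 Hz, 200-500 ms), ordinal-diversity (entropy) control by mixing a fast
# colored process with a slowly varying one, and burst-suppression dynamics
# with stimulus-triggered bursts. Every trial carries a ground-truth state.

#' Specification of one latent anesthesia state
#'
#' @param name one of `"awake"`, `"shallow"`, `"moderate"`,
#'   `"burst_suppression"`.
#' @param n2_amplitude peak of the evoked low-frequency deflection, microvolt
#'   (negative = downward N2-like wave).
#' @param n2_latency deflection center, ms post-stimulus.
#' @param gbo_gain dimensionless multiplier on the evoked 55-90 Hz burst.
#' @param gbo_latency center of the evoked gamma burst envelope, ms
#'   (deeper-but-responsive states show diminished and delayed responses).
#' @param background_spectrum_slope 1/f^alpha exponent of the background.
#' @param entropy_level target ordinal-pattern diversity in `[0, 1]`; mixing
#'   weight between a fast colored process (1) and a slowly varying one (0).
#' @param coupling_strength shared-source mixing weight in `[0, 1]` across
#'   channels.
#' @param burst_rate spontaneous bursts per second (burst suppression only).
#' @param stim_triggered_burst_prob probability that a stimulus triggers a
#'   burst 50-150 ms after onset.
#' @param flick_prob probability a trial is labeled `"flick"`.
#' @param background_rms background amplitude, microvolt RMS (awake cortex is
#'   low-amplitude desynchronized; anesthesia raises slow-wave amplitude).
#' @return a `state_spec` object (validated list).
#' @export
state_spec <- function(name, n2_amplitude, n2_latency = 325, gbo_gain = 1,
                       gbo_latency = 350,
                       background_spectrum_slope = 1.5, entropy_level = 0.7,
                       coupling_strength = 0.3, burst_rate = 0,
                       stim_triggered_burst_prob = 0, flick_prob = 0.5,
                       background_rms = 35) {
  name <- match.arg(name, c("awake", "shallow", "moderate", "burst_suppression"))
  probs <- c(entropy_level, coupling_strength, stim_triggered_burst_prob, flick_prob)
  if (any(probs < 0 | probs > 1)) stop_bad_arg("probabilities/levels must lie in [0, 1]")
  if (burst_rate < 0) stop_bad_arg("burst_rate must be >= 0")
  if (gbo_gain < 0) stop_bad_arg("gbo_gain must be >= 0")
  if (background_rms <= 0) stop_bad_arg("background_rms must be positive")
  structure(list(name = name, n2_amplitude = n2_amplitude,
                 n2_latency = n2_latency, gbo_gain = gbo_gain,
                 gbo_latency = gbo_latency,
                 background_spectrum_slope = background_spectrum_slope,
                 entropy_level = entropy_level,
                 coupling_strength = coupling_strength, burst_rate = burst_rate,
                 stim_triggered_burst_prob = stim_triggered_burst_prob,
                 flick_prob = flick_prob, background_rms = background_rms),
            class = "state_spec")
}

#' Default state specifications for the four-state world
#'
#' Awake has the largest evoked N2 magnitude and gamma gain; burst suppression
#' has the strictly lowest entropy level and is the only state with bursts.
#'
#' @return named list of four [state_spec()] objects.
#' @export
default_state_specs <- function() {
  list(
    awake = state_spec("awake", n2_amplitude = -140, n2_latency = 315,
                       gbo_gain = 3.5, gbo_latency = 330,
                       background_spectrum_slope = 1,
                       entropy_level = 0.95, coupling_strength = 0.05,
                       flick_prob = 0.9, background_rms = 20),
    shallow = state_spec("shallow", n2_amplitude = -60, n2_latency = 380,
                         gbo_gain = 1.8, gbo_latency = 430,
                         background_spectrum_slope = 1.5,
                         entropy_level = 0.65, coupling_strength = 0.55,
                         flick_prob = 0.5, background_rms = 30),
    moderate = state_spec("moderate", n2_amplitude = -10, n2_latency = 350,
                          gbo_gain = 0.1, background_spectrum_slope = 2.2,
                          entropy_level = 0.45, coupling_strength = 0.7,
                          flick_prob = 0.05, background_rms = 38),
    burst_suppression = state_spec("burst_suppression", n2_amplitude = -5,
                                   n2_latency = 350, gbo_gain = 0.05,
                                   background_spectrum_slope = 2.2,
                                   entropy_level = 0.3,
                                   coupling_strength = 0.25, burst_rate = 0.15,
                                   stim_triggered_burst_prob = 0.95,
                                   flick_prob = 0, background_rms = 38))
}

# amplitude constants (microvolt), chosen so < 1% of default trials exceed the
# 500 uV rejection threshold
.gbo_base <- 35       # gamma burst amplitude at gain 1
.burst_gain <- 2.5    # background gain inside a burst
.suppress_gain <- 0.1 # background gain during suppression

# 1/f^alpha Gaussian noise by spectral shaping; optional extra Gaussian
# low-pass (sigma_hz) used for the slowly varying low-diversity process.
colored_noise <- function(n, alpha, sigma_hz = NULL, fs = 1000) {
  x <- rnorm(n)
  k <- seq_len(n) - 1
  f <- pmin(k, n - k) * fs / n
  amp <- ifelse(f > 0, f^(-alpha / 2), 0)
  if (!is.null(sigma_hz)) amp <- amp * exp(-(f / sigma_hz)^2 / 2)
  y <- Re(fft(fft(x) * amp, inverse = TRUE)) / n
  s <- sd(y)
  if (s > 0) y / s else y
}

# Unit-variance background: 1/f^alpha colored noise plus a 15%-variance
# broadband (white) floor, both shaped by a state-dependent Gaussian low-pass
# whose cutoff sigma_e = 50 * entropy_level^3 Hz sets the high-frequency
# share inside the recording band. At tau = 1 ordinal-pattern diversity is
# governed by millisecond-scale increments, i.e. by exactly this cutoff, so
# entropy_level maps monotonically onto realized permutation entropy (the
# slowly varying low-diversity process of deep states is the heavily
# low-passed background itself).
state_background <- function(n, spec, fs) {
  sig_e <- 50 * spec$entropy_level^3
  sqrt(0.85) * colored_noise(n, spec$background_spectrum_slope,
                             sigma_hz = sig_e, fs = fs) +
    sqrt(0.15) * colored_noise(n, 0, sigma_hz = sig_e, fs = fs)
}

half_cosine <- function(t_ms, center, width = 150) {
  u <- (t_ms - (center - width / 2)) / width
  ifelse(u >= 0 & u <= 1, sin(pi * u), 0)
}

gauss_env <- function(t_ms, center, sd_ms) exp(-((t_ms - center)^2) / (2 * sd_ms^2))

# raised-cosine burst envelope on gate vector (in place helper)
add_burst <- function(gate, onset, dur, n) {
  idx <- seq(from = max(1, onset), to = min(n, onset + dur - 1))
  if (!length(idx)) return(gate)
  u <- (idx - onset) / dur
  env <- 0.5 * (1 - cos(2 * pi * u))
  gate[idx] <- pmax(gate[idx], .suppress_gain + (.burst_gain - .suppress_gain) * env)
  gate
}

# Core segment generator: n samples, stimulus at sample `onset` (1-based,
# NA for no stimulus). Returns channels x samples matrix in microvolt.
# Consumes RNG; callers handle seeding.
gen_segment <- function(spec, n, onset, fs, labels) {
  nch <- length(labels)
  t_ms <- (seq_len(n) - ifelse(is.na(onset), 1, onset)) * 1000 / fs
  shared <- state_background(n, spec, fs)
  cw <- spec$coupling_strength
  sig <- matrix(0, nch, n)
  for (ch in seq_len(nch)) {
    own <- state_background(n, spec, fs)
    sig[ch, ] <- sqrt(1 - cw) * own + sqrt(cw) * shared
  }

  # burst-suppression gate (multiplicative on background)
  if (spec$burst_rate > 0 || spec$stim_triggered_burst_prob > 0) {
    gate <- rep(.suppress_gain, n)
    if (spec$burst_rate > 0) {
      t0 <- 0
      repeat {
        t0 <- t0 + rexp(1, rate = spec$burst_rate) * fs
        if (t0 > n) break
        gate <- add_burst(gate, round(t0), round(runif(1, 0.25, 0.45) * fs), n)
      }
    }
    if (!is.na(onset) && runif(1) < spec$stim_triggered_burst_prob) {
      start <- onset + round(runif(1, 0.06, 0.12) * fs)
      gate <- add_burst(gate, start, round(runif(1, 0.25, 0.45) * fs), n)
    }
    sig <- sweep(sig, 2, gate, `*`)
  }
  sig <- sig * spec$background_rms

  if (!is.na(onset)) {
    w_spatial <- ifelse(labels %in% n2_electrodes(), 1, 0.3)
    # evoked low-frequency complex: N2 deflection plus the opposite-polarity
    # P2 slow wave that follows it (about 60% of N2 size, ~230 ms later)
    n2 <- spec$n2_amplitude * half_cosine(t_ms, spec$n2_latency) -
      0.6 * spec$n2_amplitude * half_cosine(t_ms, spec$n2_latency + 230, 300)
    f_carrier <- 70 + runif(1, -10, 10)
    phase <- runif(1, 0, 2 * pi)
    gbo <- spec$gbo_gain * .gbo_base * gauss_env(t_ms, spec$gbo_latency, 60) *
      cos(2 * pi * f_carrier * t_ms / 1000 + phase)
    evoked <- n2 + gbo
    evoked[t_ms < 0] <- 0
    sig <- sig + outer(w_spatial, evoked)
  }
  sig
}

#' Generate one stimulus-locked multichannel epoch
#'
#' @param spec a [state_spec()].
#' @param seed integer; the same spec and seed give a bit-identical epoch.
#' @param fs sampling rate, Hz (>= 200).
#' @param window epoch window in ms relative to stimulus; must contain 0.
#' @param channel_labels channel names (length sets the channel count).
#' @param artifact if `TRUE`, plant a superthreshold (800 uV) artifact so
#'   amplitude-rejection paths can be exercised.
#' @return channels x samples numeric matrix (microvolt); sample at `t = 0`
#'   is the stimulus onset, endpoints inclusive at the native resolution.
#' @export
generate_epoch <- function(spec, seed, fs = 1000, window = c(-1000, 2000),
                           channel_labels = default_montage(),
                           artifact = FALSE) {
  stopifnot(inherits(spec, "state_spec"))
  if (fs < 200) stop_bad_arg("fs must be >= 200 Hz")
  if (window[1] > 0 || window[2] < 0)
    stop_bad_arg("epoch window must span the stimulus onset at t = 0")
  n <- round((window[2] - window[1]) * fs / 1000) + 1L
  onset <- round(-window[1] * fs / 1000) + 1L
  with_seed(seed, {
    sig <- gen_segment(spec, n, onset, fs, channel_labels)
    if (artifact) sig[1, onset + round(0.1 * fs)] <- 800
    rownames(sig) <- channel_labels
    sig
  })
}

# balanced per-subject state sequence: induction awake->shallow->moderate,
# emergence burst_suppression/moderate->shallow->awake
allocate_states <- function(n_trials) {
  if (n_trials < 8) stop_bad_arg("need at least 8 trials per subject for the four-state sequence")
  q <- rep(n_trials %/% 4, 4)
  extra <- n_trials %% 4
  if (extra > 0) q[seq_len(extra)] <- q[seq_len(extra)] + 1
  names(q) <- c("awake", "shallow", "moderate", "burst_suppression")
  n_ind <- n_trials %/% 2
  n_em <- n_trials - n_ind
  r <- n_em - q["burst_suppression"]
  a_e <- r %/% 3; s_e <- r %/% 3; m_e <- r - a_e - s_e
  a_i <- q["awake"] - a_e; s_i <- q["shallow"] - s_e; m_i <- q["moderate"] - m_e
  if (any(c(a_i, s_i, m_i) < 0)) stop_bad_arg("cannot balance states for this trial count")
  list(states = c(rep("awake", a_i), rep("shallow", s_i), rep("moderate", m_i),
                  rep("burst_suppression", q["burst_suppression"]),
                  rep("moderate", m_e), rep("shallow", s_e), rep("awake", a_e)),
       phase = c(rep("induction", n_ind), rep("emergence", n_em)))
}

#' Generate a synthetic multi-subject cohort
#'
#' Produces one continuous 14-channel recording per subject with embedded
#' stimulus epochs and an event table with ground-truth labels. Induction
#' sequences progress awake to shallow to moderate; emergence sequences
#' progress burst suppression / moderate to shallow to awake, so burst
#' suppression occurs only after anesthetic cessation.
#'
#' @param n_subjects number of subjects.
#' @param trials_per_subject stimuli per subject (>= 8).
#' @param seed master seed; same seed and parameters reproduce the cohort
#'   bit-identically.
#' @param specs named list with the four [state_spec()]s.
#' @param fs sampling rate, Hz.
#' @param isi_s inter-stimulus interval, seconds (>= 3.5 so each 3 s epoch
#'   plus margins fits; the experimental pacing of one stimulus per minute is
#'   compressed to keep simulations desk-scale).
#' @param channel_labels montage.
#' @param artifact_trials number of trials per subject to contaminate with a
#'   planted superthreshold artifact (for rejection tests).
#' @return a `syn_cohort`: list with `recordings` (list of `ecog_recording`),
#'   `events` (data.frame: subject_id, onset_sample (0-based), phase,
#'   behavior, true_state), `fs`, `specs`, `seed`.
#' @export
generate_cohort <- function(n_subjects = 6, trials_per_subject = 32, seed = 1,
                            specs = default_state_specs(), fs = 1000,
                            isi_s = 4, channel_labels = default_montage(),
                            artifact_trials = 0) {
  if (!all(c("awake", "shallow", "moderate", "burst_suppression") %in% names(specs)))
    stop_bad_arg("`specs` must name all four states")
  if (isi_s < 3.5) stop_bad_arg("isi_s must be >= 3.5 s")
  if (trials_per_subject < 1) stop_bad_arg("trials_per_subject must be >= 1")
  seg_len <- round(isi_s * fs)
  onset_local <- round(1.1 * fs)  # 1.1 s into each segment
  alloc <- allocate_states(trials_per_subject)
  recordings <- vector("list", n_subjects)
  events <- list()
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("S%02d", s)
    with_seed(derive_seed(seed, "cohort", s), {
      segs <- vector("list", trials_per_subject)
      for (tr in seq_len(trials_per_subject)) {
        sp <- specs[[alloc$states[tr]]]
        seg <- gen_segment(sp, seg_len, onset_local, fs, channel_labels)
        if (tr <= artifact_trials)
          seg[1, onset_local + round(0.1 * fs)] <- 800
        segs[[tr]] <- seg
        events[[length(events) + 1L]] <- data.frame(
          subject_id = sid,
          onset_sample = (tr - 1L) * seg_len + onset_local - 1L,  # 0-based
          phase = alloc$phase[tr],
          behavior = ifelse(runif(1) < sp$flick_prob, "flick", "non-flick"),
          true_state = sp$name, stringsAsFactors = FALSE)
      }
      sigmat <- do.call(cbind, segs)
      rownames(sigmat) <- channel_labels
      recordings[[s]] <- structure(
        list(signal = sigmat, fs = fs, channel_labels = channel_labels,
             subject_id = sid), class = "ecog_recording")
    })
  }
  structure(list(recordings = recordings,
                 events = do.call(rbind, events),
                 fs = fs, specs = specs, seed = seed,
                 channel_labels = channel_labels),
            class = "syn_cohort")
}

#' @export
print.syn_cohort <- function(x, ...) {
  cat(sprintf("<syn_cohort> %d subjects, %d events, fs = %g Hz\n",
              length(x$recordings), nrow(x$events), x$fs))
  print(table(x$events$true_state))
  invisible(x)
}

#' Write / read a continuous recording as TSV
#'
#' Plain-text stand-in for a binary container: one row per sample, one column
#' per channel, header row of channel labels, and a `# fs=<Hz>` comment line.
#'
#' @param rec an `ecog_recording`.
#' @param path output file.
#' @export
write_recording_tsv <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%g subject_id=%s", rec$fs, rec$subject_id), con)
  write.table(t(rec$signal), con, sep = "\t", row.names = FALSE,
              col.names = rec$channel_labels, quote = FALSE)
  invisible(path)
}

#' @rdname write_recording_tsv
#' @param path input file.
#' @export
read_recording_tsv <- function(path) {
  hdr <- readLines(path, n = 1)
  kv <- regmatches(hdr, gregexpr("[a-z_]+=[^ ]+", hdr))[[1]]
  kv <- strsplit(kv, "=")
  vals <- setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  m <- as.matrix(read.table(path, header = TRUE, sep = "\t", skip = 1,
                            check.names = FALSE))
  structure(list(signal = t(m), fs = as.numeric(vals[["fs"]]),
                 channel_labels = colnames(m),
                 subject_id = vals[["subject_id"]] %||% "unknown"),
            class = "ecog_recording")
}

#' Write / read a stimulus-event table as TSV
#' @param events event data.frame (see [generate_cohort()]).
#' @param path file path.
#' @export
write_events_tsv <- function(events, path) {
  write.table(events, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
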