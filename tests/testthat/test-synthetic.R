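specs <- default_state_specs()

test_that("state_spec validates fields and defaults satisfy the invariants", {
  expect_error(state_spec("awake", -80, entropy_level = 1.2), "\\[0, 1\\]")
  expect_error(state_spec("awake", -80, burst_rate = -1), ">= 0")
  n2 <- vapply(specs, function(s) abs(s$n2_amplitude), numeric(1))
  gbo <- vapply(specs, function(s) s$gbo_gain, numeric(1))
  ent <- vapply(specs, function(s) s$entropy_level, numeric(1))
  expect_equal(names(which.max(n2)), "awake")
  expect_equal(names(which.max(gbo)), "awake")
  expect_true(all(ent["burst_suppression"] < ent[names(ent) != "burst_suppression"]))
})

test_that("generate_epoch is deterministic, seed-sensitive, and validates the window", {
  e1 <- generate_epoch(specs$awake, seed = 5)
  e2 <- generate_epoch(specs$awake, seed = 5)
  e3 <- generate_epoch(specs$awake, seed = 6)
  expect_identical(e1, e2)
  expect_false(identical(e1, e3))
  expect_equal(dim(e1), c(14, 3001))
  expect_error(generate_epoch(specs$awake, seed = 1, window = c(100, 2000)),
               "onset")
  expect_error(generate_epoch(specs$awake, seed = 1, fs = 100), "200")
})

test_that("cohort bookkeeping: events, labels, shapes, determinism", {
  co <- generate_cohort(n_subjects = 6, trials_per_subject = 32, seed = 7)
  expect_equal(nrow(co$events), 192)
  expect_true(all(co$events$true_state %in% names(specs)))
  expect_true(all(co$events$behavior %in% c("flick", "non-flick")))
  expect_true(all(table(co$events$true_state) == 48))  # balanced quotas
  co2 <- generate_cohort(n_subjects = 6, trials_per_subject = 32, seed = 7)
  expect_identical(co$recordings[[3]]$signal, co2$recordings[[3]]$signal)
  co3 <- generate_cohort(n_subjects = 6, trials_per_subject = 32, seed = 8)
  expect_equal(dim(co3$recordings[[1]]$signal), dim(co$recordings[[1]]$signal))
  expect_false(identical(co$recordings[[1]]$signal, co3$recordings[[1]]$signal))
  expect_error(generate_cohort(specs = specs[1:3]), "four")
  expect_error(generate_cohort(isi_s = 2), "3.5")
})

test_that("burst suppression occurs only in the emergence phase", {
  co <- small_cohort()
  bs <- co$events$true_state == "burst_suppression"
  expect_true(any(bs))
  expect_true(all(co$events$phase[bs] == "emergence"))
  # and phase ordering progresses as stated
  ind <- co$events$true_state[co$events$phase == "induction" &
                                co$events$subject_id == "S01"]
  expect_equal(rle(ind)$values, c("awake", "shallow", "moderate"))
})

test_that("no evoked components means no post-stimulus deflection", {
  sp <- state_spec("moderate", n2_amplitude = 0, gbo_gain = 0)
  eps <- lapply(1:60, function(s) generate_epoch(sp, seed = s)[5, ])
  tm <- seq(-1000, 2000)
  roi <- tm >= 250 & tm <= 400
  base <- tm < 0
  d <- vapply(eps, function(e) mean(e[roi]) - mean(e[base]), numeric(1))
  expect_lt(abs(mean(d) / (sd(d) / sqrt(length(d)))), 3)  # |t| small
})


test_that("entropy_level and coupling_strength control PE and PCMI", {
  mk <- function(e, cw) {
    sp <- state_spec("moderate", n2_amplitude = 0, gbo_gain = 0,
                     entropy_level = e, coupling_strength = cw)
    sigs <- lapply(1:10, function(s) generate_epoch(sp, seed = 300 + s))
    make_epoch_set(aperm(simplify2array(sigs), c(3, 1, 2)),
                   labels = default_montage())
  }
  pe_lo <- mean(sliding_pe(mk(0.3, 0.3))$pe)
  pe_hi <- mean(sliding_pe(mk(0.9, 0.3))$pe)
  expect_lt(pe_lo, pe_hi)
  cs_lo <- suppressWarnings(windowed_pcmi(mk(0.6, 0.0),
                                          windows = list(c(0, 500))))
  cs_hi <- suppressWarnings(windowed_pcmi(mk(0.6, 0.8),
                                          windows = list(c(0, 500))))
  expect_lt(mean(cs_lo$pcmi), mean(cs_hi$pcmi))
})

test_that("default amplitudes stay under the rejection threshold; artifacts can be planted", {
  co <- small_cohort()
  ep <- preprocess_cohort(co)
  expect_lt(mean(!is.na(ep$rejected$reason)), 0.01)
  art <- generate_cohort(n_subjects = 1, trials_per_subject = 8, seed = 1,
                         artifact_trials = 3)
  epa <- reject_amplitude(epoch_recording(art$recordings[[1]], art$events))
  expect_equal(sum(epa$rejected$reason == "amplitude", na.rm = TRUE), 3)
})

test_that("recordings and event tables round-trip through TSV", {
  co <- generate_cohort(n_subjects = 1, trials_per_subject = 8, seed = 9,
                        isi_s = 3.5)
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  write_recording_tsv(co$recordings[[1]], f1)
  rec <- read_recording_tsv(f1)
  expect_equal(rec$fs, co$fs)
  expect_equal(rec$channel_labels, co$channel_labels)
  expect_equal(rec$signal, co$recordings[[1]]$signal, tolerance = 1e-6,
               ignore_attr = TRUE)
  write_events_tsv(co$events, f2)
  ev <- read_events_tsv(f2)
  expect_equal(ev$onset_sample, co$events$onset_sample)
  expect_equal(ev$true_state, co$events$true_state)
  unlink(c(f1, f2))
})
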