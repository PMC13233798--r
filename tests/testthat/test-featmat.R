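test_that("column counts match the stated feature arithmetic", {
  fm <- small_features()
  tab <- table(fm$columns$family)
  expect_equal(unname(tab["spectra"]), 504L)  # 14 * 6 * 6
  expect_equal(unname(tab["pe"]), 84L)        # 14 * 6
  expect_equal(unname(tab["pcmi"]), 546L)     # C(14,2) * 6
  expect_equal(ncol(fm$values), 1134L)
  expect_equal(nrow(electrode_pairs()), 91L)
})

test_that("the general E-electrode formula holds on a 5-channel montage", {
  set.seed(1)
  data <- array(rnorm(6 * 5 * 3001), dim = c(6, 5, 3001))
  ep <- make_epoch_set(data)
  fm <- build_feature_matrix(ep)
  E <- 5
  expect_equal(ncol(fm$values), E * 36 + E * 6 + choose(E, 2) * 6)  # 270
  tab <- table(fm$columns$family)
  expect_equal(unname(tab["spectra"]), E * 36L)
  expect_equal(unname(tab["pe"]), E * 6L)
  expect_equal(unname(tab["pcmi"]), choose(E, 2) * 6L)
})

test_that("column order is stable and survives a TSV round-trip", {
  fm <- small_features()
  expect_equal(fm$columns$family,
               rep(c("spectra", "pe", "pcmi"), c(504, 84, 546)))
  # spectra block is electrode-major in montage order
  first_block <- fm$columns[fm$columns$family == "spectra", ][1:36, ]
  expect_true(all(first_block$electrode == default_montage()[1]))
  expect_equal(first_block$bin, rep(1:6, 6))
  f <- tempfile(fileext = ".tsv")
  write_features_tsv(fm, f)
  back <- read_features_tsv(f)
  expect_equal(back$columns$name, fm$columns$name)
  expect_equal(unname(back$values), unname(fm$values), tolerance = 1e-9)
  expect_equal(back$events$true_state, fm$events$true_state)
  unlink(c(f, paste0(f, ".columns.tsv")))
})

test_that("bin_spectra obeys bin/band arithmetic on constructed maps", {
  mk_tf <- function(power) structure(
    list(power = power, freq_hz = 1:100, time_ms = seq(-500, 1000),
         baseline_corrected = TRUE, cropped = TRUE), class = "tf_map")
  ones <- mk_tf(array(1, dim = c(2, 14, 100, 1501)))
  dimnames(ones$power)[[2]] <- default_montage()
  blk <- bin_spectra(ones)
  expect_equal(dim(blk$values), c(2L, 504L))
  expect_lt(max(abs(blk$values - 1)), 1e-12)
  # power only at 70 Hz, 300 ms -> only (high_gamma, bin 4) columns
  pk <- array(0, dim = c(1, 14, 100, 1501))
  pk[1, , 70, 801] <- 1  # 300 ms
  tfp <- mk_tf(pk); dimnames(tfp$power)[[2]] <- default_montage()
  b2 <- bin_spectra(tfp)
  nz <- b2$columns[b2$values[1, ] != 0, ]
  expect_true(all(nz$band == "high_gamma"))
  expect_true(all(nz$bin == 4))  # 250..500 ms
  bad <- mk_tf(array(1, dim = c(1, 14, 30, 1501)))
  bad$freq_hz <- 1:30
  dimnames(bad$power)[[2]] <- default_montage()
  expect_error(bin_spectra(bad), "missing")
})

test_that("bin_pe averages per bin and enforces populated bins", {
  es <- structure(list(
    pe = array(2, dim = c(3, 2, 151)), time_ms = seq(-500, 1000, by = 10),
    params = ordinal_params(), step = 10, channel_labels = c("A", "B")),
    class = "entropy_series")
  blk <- bin_pe(es)
  expect_equal(dim(blk$values), c(3L, 12L))
  expect_true(all(blk$values == 2))
  sparse <- es; sparse$time_ms <- c(-400, 600); sparse$pe <- array(1, c(3, 2, 2))
  expect_error(bin_pe(sparse), "bin")
})

test_that("PCMI bin features equal PE on a duplicated-channel harness", {
  set.seed(2)
  x <- rnorm(3001)
  data <- array(0, dim = c(1, 2, 3001))
  data[1, 1, ] <- x; data[1, 2, ] <- x
  ep <- make_epoch_set(data)
  cs <- suppressWarnings(windowed_pcmi(ep, windows = pcmi_bin_windows(),
                                       allow_short = TRUE))
  tm <- ep$time_ms
  for (w in seq_along(cs$windows)) {
    win <- cs$windows[[w]]
    pe_bin <- permutation_entropy(x[tm >= win[1] & tm <= win[2]])
    expect_equal(cs$pcmi[1, 1, w], pe_bin, tolerance = 1e-12)
  }
})

test_that("z-scoring is exact, idempotent, and flags constants", {
  vals <- cbind(c(1, 2, 3), c(5, 5, 5), c(0, 1, 4))
  fm <- make_fm(vals)
  z <- zscore_features(fm)
  expect_equal(unname(z$values[, 1]), c(-1, 0, 1))  # sample SD
  expect_equal(z$zero_variance, 2L)
  expect_true(all(z$values[, 2] == 0))
  z2 <- zscore_features(make_fm(z$values[, c(1, 3)]))
  expect_equal(unname(z2$values), unname(z$values[, c(1, 3)]),
               tolerance = 1e-9)
  expect_error(zscore_features(make_fm(vals[1, , drop = FALSE])), "2 trials")
  fz <- small_features_z()
  expect_lt(max(abs(colMeans(fz$values))), 1e-9)
  expect_lt(max(abs(apply(fz$values, 2, sd) - 1)), 1e-9)
})

test_that("out-of-sample projection uses stored training scaling only", {
  set.seed(3)
  train <- make_fm(matrix(rnorm(40, mean = 10, sd = 4), 10, 4))
  z <- zscore_features(train)
  new <- matrix(rnorm(8, mean = 10, sd = 4), 2, 4)
  proj <- project_features(z$scaling, new)
  expect_equal(proj, sweep(sweep(new, 2, z$scaling$mean), 2, z$scaling$sd, "/"))
})

test_that("rejected trials never enter the feature matrix", {
  co <- generate_cohort(n_subjects = 1, trials_per_subject = 8, seed = 5,
                        artifact_trials = 2)
  ep <- reject_amplitude(epoch_recording(co$recordings[[1]], co$events))
  fm <- build_feature_matrix(ep)
  expect_equal(nrow(fm$values), 6)
  expect_equal(fm$trial_index, retained_trials(ep))
})
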