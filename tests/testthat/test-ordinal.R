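p3 <- ordinal_params()

test_that("ordinal parameters are validated", {
  expect_error(ordinal_params(m = 1), "m")
  expect_error(ordinal_params(tau = 0), "tau")
  expect_error(ordinal_params(m = 4, window = 10), "m!")
  expect_error(ordinal_pattern_sequence(c(1, 2), p3), "short")
})

test_that("pattern sequences match closed-form cases and the brute-force oracle", {
  up <- ordinal_pattern_sequence(1:50, p3)
  dn <- ordinal_pattern_sequence(50:1, p3)
  expect_equal(length(unique(up)), 1L)
  expect_equal(length(unique(dn)), 1L)
  expect_false(up[1] == dn[1])
  x <- c(1, 3, 2, 5, 4)
  pat <- ordinal_pattern_sequence(x, p3)
  expect_length(pat, 3)
  # partition of positions by pattern identity must match the oracle's
  oracle <- oracle_patterns(x)
  expect_equal(outer(pat, pat, "=="), outer(oracle, oracle, "=="))
  # first triple (1,3,2) rises then falls
  expect_equal(oracle[1], "1-3-2")
})

test_that("PE matches enumerable cases and the iid limit", {
  expect_equal(permutation_entropy(1:300, p3), 0)
  alt <- rep(c(0, 1), 200)  # period 2: exactly two patterns, equiprobable
  expect_equal(permutation_entropy(alt, p3), 1)
  set.seed(1)
  expect_lt(abs(permutation_entropy(runif(1e5), p3) - log2(6)), 0.01)
})

test_that("fast PE / joint PE equal the naive oracle to 1e-12 (with ties)", {
  set.seed(2)
  for (rep in 1:5) {
    x <- round(rnorm(400), 1)  # rounding induces ties
    y <- round(rnorm(400), 1)
    expect_equal(permutation_entropy(x, p3), oracle_pe(x), tolerance = 1e-12)
    expect_equal(joint_permutation_entropy(x, y, p3), oracle_joint_pe(x, y),
                 tolerance = 1e-12)
    expect_equal(pcmi(x, y, p3), oracle_pcmi(x, y), tolerance = 1e-12)
  }
  # and for a higher embedding order
  p4 <- ordinal_params(m = 4, window = 256)
  x <- rnorm(600)
  expect_equal(permutation_entropy(x, p4), oracle_pe(x, m = 4),
               tolerance = 1e-12)
})

test_that("PCMI identities: self, negation, symmetry, independence", {
  set.seed(3)
  x <- rnorm(1000); y <- rnorm(1000)
  expect_identical(pcmi(x, x, p3), permutation_entropy(x, p3))
  expect_equal(joint_permutation_entropy(x, -x, p3),
               permutation_entropy(x, p3), tolerance = 1e-12)
  expect_identical(pcmi(x, y, p3), pcmi(y, x, p3))
  set.seed(4)
  xi <- runif(1e5); yi <- runif(1e5)
  expect_lt(pcmi(xi, yi, p3), 0.02)
  # noisy copy sits strictly between independence and identity
  yn <- x + rnorm(1000, sd = sd(x) / sqrt(10))
  v <- pcmi(x, yn, p3)
  expect_gt(v, pcmi(x, y, p3))
  expect_lt(v, permutation_entropy(x, p3))
  expect_error(pcmi(x, y[1:10], p3), "equal length")
})

test_that("bounds and sub-additivity hold on random inputs", {
  set.seed(5)
  for (rep in 1:10) {
    n <- sample(300:800, 1)
    x <- if (rep %% 2) rnorm(n) else round(rnorm(n), 1)
    y <- cumsum(rnorm(n))
    pe_x <- permutation_entropy(x, p3)
    pe_y <- permutation_entropy(y, p3)
    pj <- joint_permutation_entropy(x, y, p3)
    expect_gte(pe_x, 0); expect_lte(pe_x, log2(6))
    expect_lte(pj, pe_x + pe_y + 1e-12)
  }
})

test_that("sliding PE: subsampling identity, cropping, stationarity", {
  set.seed(6)
  ep <- signal_epochs(list(rnorm(3001)), n_channels = 2)
  s1 <- sliding_pe(ep, p3, step = 1L)
  s10 <- sliding_pe(ep, p3, step = 10L)
  pos <- match(s10$time_ms, s1$time_ms)
  expect_equal(s10$pe[1, 1, ], s1$pe[1, 1, pos])
  expect_true(all(s1$time_ms >= -500 & s1$time_ms <= 1000))
  v <- s10$pe[1, 1, ]
  expect_lt(sd(v), 0.05 * mean(v))  # flat in time for white noise
})

test_that("windowed PCMI emits all pairs and a near-zero stationary difference", {
  set.seed(7)
  data <- array(rnorm(40 * 3 * 3001), dim = c(40, 3, 3001))
  ep <- make_epoch_set(data)
  cs <- windowed_pcmi(ep, p3)
  expect_equal(dim(cs$pcmi), c(40, 3, 2))
  expect_false(is.null(cs$post_minus_pre))
  d <- rowMeans(cs$post_minus_pre)
  expect_lt(abs(mean(d)), 2 * sd(d) / sqrt(length(d)) + 1e-3)
  ep14 <- small_epochs()
  cs14 <- windowed_pcmi(ep14, p3, windows = list(c(0, 500)))
  expect_equal(dim(cs14$pcmi)[2], 91)  # C(14, 2)
  expect_error(windowed_pcmi(ep, p3, windows = list(c(0, 100))), "allow_short")
  expect_warning(windowed_pcmi(ep, p3, windows = list(c(0, 100)),
                               allow_short = TRUE), "shorter")
})

test_that("summaries select the stated electrodes and windows", {
  ep <- small_epochs()
  es <- sliding_pe(ep, p3)
  v <- pe_summary(es)
  expect_length(v, dim(ep$data)[1])
  expect_true(all(v >= 0 & v <= log2(6)))
  expect_true(all(pe_summary(es, normalize = TRUE) <= 1))
  expect_error(pe_summary(es, electrodes = "XX"), "XX")
  cs <- windowed_pcmi(ep, p3, windows = list(c(0, 500)))
  expect_length(pcmi_summary(cs, window = c(0, 500)), dim(ep$data)[1])
  expect_error(pcmi_summary(cs, window = c(-500, 0)), "window")
})
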