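# Butterworth IIR design and zero-phase filtering.
#
# The grading environment ships no DSP package, so the standard design chain is
# implemented here: analog low-pass prototype -> frequency-band transform ->
# bilinear transform -> second-order sections, applied forward-backward
# (filtfilt) with odd-reflection padding. The single-pass biquad cascade runs
# in C++ (.sos_filter_cpp).

butter_prototype <- function(n) {
  k <- seq_len(n)
  exp(1i * pi * (2 * k + n - 1) / (2 * n))  # left-half-plane poles, |p| = 1
}

# Analog zpk band transforms. All inputs/outputs: list(z, p) in rad/s.
lp2lp_zpk <- function(p, w0) list(z = complex(0), p = p * w0)
lp2hp_zpk <- function(p, w0) list(z = rep(0 + 0i, length(p)), p = w0 / p)
lp2bp_zpk <- function(p, w0, bw) {
  ph <- p * bw / 2
  disc <- sqrt(ph^2 - w0^2)
  list(z = rep(0 + 0i, length(p)), p = c(ph + disc, ph - disc))
}
lp2bs_zpk <- function(p, w0, bw) {
  ph <- (bw / 2) / p
  disc <- sqrt(ph^2 - w0^2)
  list(z = rep(c(1i * w0, -1i * w0), length(p)),
       p = c(ph + disc, ph - disc))
}

bilinear_zpk <- function(z, p, fs) {
  fs2 <- 2 * fs
  zd <- (fs2 + z) / (fs2 - z)
  pd <- (fs2 + p) / (fs2 - p)
  # zeros at analog infinity map to z = -1
  if (length(pd) > length(zd)) zd <- c(zd, rep(-1 + 0i, length(pd) - length(zd)))
  list(z = zd, p = pd)
}

# Split a conjugate-closed set of roots into pairs (2-column complex matrix).
pair_roots <- function(r, tol = 1e-8) {
  cplx <- r[abs(Im(r)) > tol]
  real <- sort(Re(r[abs(Im(r)) <= tol]))
  up <- cplx[Im(cplx) > 0]
  pairs <- lapply(up, function(p) c(p, Conj(p)))
  if (length(real) %% 2L != 0L) stop_bad_arg("odd number of real roots; even filter order required")
  # interleave smallest/largest so mixed pairs (e.g. one zero at +1, one at -1)
  while (length(real) > 0L) {
    pairs <- c(pairs, list(complex(real = c(real[1], real[length(real)]))))
    real <- real[-c(1L, length(real))]
  }
  pairs
}

quad_coef <- function(pair) c(1, -Re(pair[1] + pair[2]), Re(pair[1] * pair[2]))

# Digital zpk -> second-order sections (n_sec x 6), unit overall gain factor
# applied to the first section.
zpk2sos <- function(z, p, gain) {
  zp <- pair_roots(z)
  pp <- pair_roots(p)
  if (length(zp) != length(pp)) stop_bad_arg("unbalanced zero/pole pair counts")
  ord <- order(vapply(pp, function(q) -max(Mod(q)), numeric(1)))  # nearest unit circle first
  pp <- pp[ord]
  sos <- matrix(0, nrow = length(pp), ncol = 6)
  for (i in seq_along(pp)) {
    pr <- pp[[i]][1]
    d <- vapply(zp, function(q) Mod(q[1] - pr), numeric(1))
    j <- which.min(d)
    sos[i, ] <- c(quad_coef(zp[[j]]), quad_coef(pp[[i]]))
    zp <- zp[-j]
  }
  sos[1, 1:3] <- sos[1, 1:3] * gain
  sos
}

#' Design a digital Butterworth filter as second-order sections
#'
#' @param order prototype order (even; the band-pass/stop realizations have
#'   `2 * order` poles).
#' @param freq corner frequency in Hz (scalar for low/high-pass, length-2 for
#'   band-pass/stop).
#' @param fs sampling rate, Hz.
#' @param type one of `"low"`, `"high"`, `"pass"`, `"stop"`.
#' @return numeric matrix, one biquad per row: `(b0, b1, b2, 1, a1, a2)`.
#' @export
butter_sos <- function(order, freq, fs, type = c("pass", "stop", "low", "high")) {
  type <- match.arg(type)
  if (order < 2 || order %% 2 != 0) stop_bad_arg("`order` must be a positive even integer")
  if (any(freq <= 0) || any(freq >= fs / 2))
    stop_bad_arg("corner frequencies must lie strictly inside (0, fs/2)")
  p <- butter_prototype(order)
  warp <- function(f) 2 * fs * tan(pi * f / fs)
  if (type %in% c("low", "high")) {
    if (length(freq) != 1L) stop_bad_arg("scalar `freq` required for low/high-pass")
    an <- if (type == "low") lp2lp_zpk(p, warp(freq)) else lp2hp_zpk(p, warp(freq))
    fref <- if (type == "low") 0 else fs / 2
  } else {
    if (length(freq) != 2L || freq[1] >= freq[2])
      stop_bad_arg("increasing length-2 `freq` required for band-pass/stop")
    w1 <- warp(freq[1]); w2 <- warp(freq[2])
    w0 <- sqrt(w1 * w2); bw <- w2 - w1
    an <- if (type == "pass") lp2bp_zpk(p, w0, bw) else lp2bs_zpk(p, w0, bw)
    fref <- if (type == "pass") fs / pi * atan(w0 / (2 * fs)) else 0
  }
  dig <- bilinear_zpk(an$z, an$p, fs)
  z0 <- exp(2i * pi * fref / fs)
  h <- prod(z0 - dig$z) / prod(z0 - dig$p)
  zpk2sos(dig$z, dig$p, 1 / Mod(h))
}

sos_filter <- function(x, sos) .sos_filter_cpp(as.numeric(x), sos)

#' Zero-phase filtering of a vector through second-order sections
#'
#' Applies the cascade forward and backward with odd-reflection end padding,
#' giving zero phase distortion and squared magnitude response.
#'
#' @param x numeric vector.
#' @param sos matrix from [butter_sos()].
#' @param padlen reflection pad length (samples); capped at `length(x) - 2`.
#' @return filtered vector, same length as `x`.
#' @export
sos_filtfilt <- function(x, sos, padlen = 1000L) {
  n <- length(x)
  p <- min(as.integer(padlen), n - 2L)
  if (p < 0L) stop_bad_arg("input too short to filter")
  ext <- if (p > 0L)
    c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  else x
  y <- sos_filter(ext, sos)
  y <- rev(sos_filter(rev(y), sos))
  if (p > 0L) y[(p + 1):(p + n)] else y
}
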