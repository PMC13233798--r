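# Ordinal-pattern analysis: permutation entropy (PE), joint ordinal-pattern
# entropy, and permutation cross-mutual information
# PCMI = PE_X + PE_Y - PE_XY. Patterns follow the Bandt-Pompe convention with
# ties broken by order of occurrence (earlier sample ranks lower). Entropies
# are Shannon entropies in bits, unnormalized; a normalization flag (divide by
# log2(m!)) is available where summaries are formed.

#' Ordinal analysis parameters
#'
#' @param m embedding order (>= 2; default 3).
#' @param tau embedding delay in samples (>= 1).
#' @param window window length in samples for windowed estimates (>= m!).
#' @return validated `ordinal_params` list.
#' @export
ordinal_params <- function(m = 3, tau = 1, window = 256) {
  if (m < 2) stop_bad_arg("m must be >= 2")
  if (tau < 1) stop_bad_arg("tau must be >= 1")
  if (window < factorial(m)) stop_bad_arg("window must be >= m! samples")
  structure(list(m = as.integer(m), tau = as.integer(tau),
                 window = as.integer(window)), class = "ordinal_params")
}

#' Ordinal pattern sequence of a signal
#'
#' One pattern per admissible start, indexed in `0..m!-1` by the Lehmer code
#' of the permutation that sorts the embedding vector ascending (ties: the
#' earlier sample ranks lower).
#'
#' @param x numeric vector, length >= `(m-1)*tau + 1`.
#' @param p an [ordinal_params()].
#' @return integer vector of pattern indices, length
#'   `length(x) - (m-1)*tau`.
#' @export
ordinal_pattern_sequence <- function(x, p = ordinal_params()) {
  m <- p$m; tau <- p$tau
  n_pat <- length(x) - (m - 1L) * tau
  if (n_pat < 1L) stop_bad_arg("input too short for the embedding")
  idx <- seq_len(n_pat)
  code <- integer(n_pat)
  for (j in seq_len(m - 1L)) {
    cj <- integer(n_pat)
    xj <- x[idx + (j - 1L) * tau]
    for (k in (j + 1L):m) cj <- cj + (x[idx + (k - 1L) * tau] < xj)
    code <- code + cj * factorial(m - j)
  }
  code
}

shannon_bits <- function(counts) {
  pr <- counts[counts > 0]
  pr <- pr / sum(pr)
  -sum(pr * log2(pr))
}

#' Permutation entropy of a signal
#'
#' Shannon entropy (base 2, unnormalized) of the empirical ordinal-pattern
#' distribution over the whole input.
#'
#' @inheritParams ordinal_pattern_sequence
#' @return entropy in bits, in `[0, log2(m!)]`.
#' @export
permutation_entropy <- function(x, p = ordinal_params()) {
  pat <- ordinal_pattern_sequence(x, p)
  shannon_bits(tabulate(pat + 1L, nbins = factorial(p$m)))
}

#' Joint ordinal-pattern entropy of two equal-length signals
#'
#' Entropy of the joint distribution of simultaneous pattern pairs
#' (`m! * m!` cells).
#'
#' @param x,y numeric vectors of equal length.
#' @inheritParams ordinal_pattern_sequence
#' @return entropy in bits.
#' @export
joint_permutation_entropy <- function(x, y, p = ordinal_params()) {
  if (length(x) != length(y)) stop_bad_arg("x and y must have equal length")
  mf <- factorial(p$m)
  px <- ordinal_pattern_sequence(x, p)
  py <- ordinal_pattern_sequence(y, p)
  shannon_bits(tabulate(px * mf + py + 1L, nbins = mf * mf))
}

#' Permutation cross-mutual information
#'
#' `PCMI = PE_X + PE_Y - PE_XY`. The raw value is reported: tiny negative
#' values can arise only through estimation noise and are not clamped.
#'
#' @inheritParams joint_permutation_entropy
#' @return PCMI in bits; `pcmi(x, x) == permutation_entropy(x)` exactly.
#' @export
pcmi <- function(x, y, p = ordinal_params()) {
  permutation_entropy(x, p) + permutation_entropy(y, p) -
    joint_permutation_entropy(x, y, p)
}

# cumulative per-pattern counts; column i+1 = counts among first i patterns
pattern_cumcounts <- function(pat, mf) {
  ind <- matrix(0L, mf, length(pat))
  ind[cbind(pat + 1L, seq_along(pat))] <- 1L
  cbind(0L, t(apply(ind, 1, cumsum)))
}

#' Sliding-window permutation entropy over an epoch set
#'
#' PE per `window`-sample window whose end slides in steps of `step` samples,
#' computed over the full epoch and then cropped to the analysis interval
#' (window-end timestamp convention).
#'
#' @param ep an `epoch_set`.
#' @param p an [ordinal_params()].
#' @param step slide step in samples (default 10 = 10 ms at 1000 Hz).
#' @param crop retained interval, ms.
#' @return an `entropy_series`: `pe` trials x channels x positions (bits),
#'   `time_ms` window-end timestamps, `params`.
#' @export
sliding_pe <- function(ep, p = ordinal_params(), step = 10L,
                       crop = c(-500, 1000)) {
  stopifnot(inherits(ep, "epoch_set"))
  if (step < 1) stop_bad_arg("step must be >= 1")
  d <- dim(ep$data)
  mf <- factorial(p$m)
  span <- (p$m - 1L) * p$tau
  ends <- seq(from = p$window, to = d[3], by = step)
  keep <- ep$time_ms[ends] >= crop[1] & ep$time_ms[ends] <= crop[2]
  ends <- ends[keep]
  pe <- array(NA_real_, dim = c(d[1], d[2], length(ends)))
  npat_w <- p$window - span  # patterns fully inside one window
  for (tr in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      pat <- ordinal_pattern_sequence(ep$data[tr, ch, ], p)
      cs <- pattern_cumcounts(pat, mf)
      s1 <- ends - p$window + 1L
      counts <- cs[, s1 + npat_w, drop = FALSE] - cs[, s1, drop = FALSE]
      pe[tr, ch, ] <- apply(counts, 2, shannon_bits)
    }
  }
  structure(list(pe = pe, time_ms = ep$time_ms[ends], params = p,
                 step = step, channel_labels = dimnames(ep$data)[[2]]),
            class = "entropy_series")
}

#' Windowed PCMI over all electrode pairs
#'
#' PCMI per unordered channel pair per analysis window, using every ordinal
#' pattern whose support lies fully inside the window. When both canonical
#' windows (-500..0 and 0..500 ms) are present, the post-minus-pre difference
#' is attached.
#'
#' @param ep an `epoch_set`.
#' @param p an [ordinal_params()].
#' @param windows list of ms pairs.
#' @param allow_short allow windows shorter than `p$window` samples (a single
#'   warning is emitted); otherwise such windows are an error.
#' @return a `coupling_series`: `pcmi` trials x pairs x windows (bits),
#'   `pairs` (from [electrode_pairs()]), `windows`, and optionally
#'   `post_minus_pre` (trials x pairs).
#' @export
windowed_pcmi <- function(ep, p = ordinal_params(),
                          windows = list(c(-500, 0), c(0, 500)),
                          allow_short = FALSE) {
  stopifnot(inherits(ep, "epoch_set"))
  d <- dim(ep$data)
  labels <- dimnames(ep$data)[[2]]
  pairs <- electrode_pairs(labels)
  mf <- factorial(p$m)
  span <- (p$m - 1L) * p$tau
  win_idx <- lapply(windows, function(w) ms_index(ep$time_ms, w[1], w[2]))
  short <- vapply(win_idx, length, 0L) < p$window
  if (any(short)) {
    if (!allow_short)
      stop_bad_arg("analysis window shorter than `p$window` samples; set allow_short = TRUE")
    warning("PCMI window(s) shorter than the nominal ", p$window,
            "-sample estimation window", call. = FALSE)
  }
  out <- array(NA_real_, dim = c(d[1], nrow(pairs), length(windows)))
  for (tr in seq_len(d[1])) {
    pats <- lapply(seq_len(d[2]),
                   function(ch) ordinal_pattern_sequence(ep$data[tr, ch, ], p))
    for (w in seq_along(windows)) {
      idx <- win_idx[[w]]
      starts <- idx[1]:(idx[length(idx)] - span)  # patterns fully inside
      sub <- lapply(pats, function(q) q[starts])
      pe_ch <- vapply(sub, function(q)
        shannon_bits(tabulate(q + 1L, nbins = mf)), numeric(1))
      for (pr in seq_len(nrow(pairs))) {
        ia <- pairs$ia[pr]; ib <- pairs$ib[pr]
        pj <- shannon_bits(tabulate(sub[[ia]] * mf + sub[[ib]] + 1L,
                                    nbins = mf * mf))
        out[tr, pr, w] <- pe_ch[ia] + pe_ch[ib] - pj
      }
    }
  }
  res <- structure(list(pcmi = out, pairs = pairs, windows = windows,
                        params = p), class = "coupling_series")
  is_pre <- vapply(windows, function(w) identical(as.numeric(w), c(-500, 0)), NA)
  is_post <- vapply(windows, function(w) identical(as.numeric(w), c(0, 500)), NA)
  if (any(is_pre) && any(is_post))
    res$post_minus_pre <- out[, , which(is_post)[1]] - out[, , which(is_pre)[1]]
  res
}

#' Scalar peri-stimulus PE summary
#'
#' Mean PE over all sliding windows whose full support lies inside `t_win`,
#' averaged over the given electrodes (default: the parietal set).
#'
#' @param es an `entropy_series` from [sliding_pe()].
#' @param t_win ms window (default 0..1000 post-stimulus).
#' @param electrodes channel labels to average.
#' @param normalize divide by `log2(m!)`.
#' @return per-trial numeric vector.
#' @export
pe_summary <- function(es, t_win = c(0, 1000), electrodes = pe_electrodes(),
                       normalize = FALSE) {
  stopifnot(inherits(es, "entropy_series"))
  ch <- match(electrodes, es$channel_labels)
  if (anyNA(ch)) stop_bad_arg(paste("unknown electrode:",
                                    electrodes[is.na(ch)][1]))
  win_ms <- (es$params$window - 1L)  # support length at 1 kHz
  keep <- (es$time_ms - win_ms) >= t_win[1] & es$time_ms <= t_win[2]
  if (!any(keep)) stop_bad_arg("no sliding window fully inside t_win")
  v <- apply(es$pe[, ch, keep, drop = FALSE], 1, mean)
  if (normalize) v <- v / log2(factorial(es$params$m))
  v
}

#' Scalar laser-evoked PCMI summary
#'
#' Mean PCMI across all pairs of the given electrodes (default: the four
#' frontal electrodes) in one analysis window of a `coupling_series`.
#'
#' @param cs a `coupling_series` from [windowed_pcmi()].
#' @param window ms pair naming which window of `cs` to summarize.
#' @param electrodes electrode set whose within-set pairs are averaged.
#' @return per-trial numeric vector.
#' @export
pcmi_summary <- function(cs, window = c(0, 500),
                         electrodes = frontal_electrodes()) {
  stopifnot(inherits(cs, "coupling_series"))
  w <- which(vapply(cs$windows, function(x)
    identical(as.numeric(x), as.numeric(window)), NA))
  if (!length(w)) stop_bad_arg("requested window not present in the series")
  sel <- cs$pairs$a %in% electrodes & cs$pairs$b %in% electrodes
  rowMeans(cs$pcmi[, sel, w[1], drop = FALSE])
}
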