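# Per-trial feature assembly: 504 spectral + 84 PE + 546 PCMI = 1134 columns
# for the default 14-electrode montage (general montage: E*36 + E*6 +
# choose(E,2)*6). Features live on six consecutive 250-ms time bins tiling
# -500..1000 ms and six frequency bands (delta 1-4, theta 4-7, alpha 7-13,
# beta 13-30, low gamma 30-45, high gamma 55-90 Hz; the 45-55 Hz gap guards
# the notch). Column order is fixed and documented: spectra electrode-major
# (electrode, band, bin), then PE (electrode, bin), then PCMI (pair, bin).

#' Canonical frequency bands
#' @return named list of Hz pairs.
#' @export
feature_bands <- function() {
  list(delta = c(1, 4), theta = c(4, 7), alpha = c(7, 13), beta = c(13, 30),
       low_gamma = c(30, 45), high_gamma = c(55, 90))
}

#' Canonical 250-ms time bins tiling -500..1000 ms
#' @return data.frame with `lo`, `hi` (ms); bins are half-open `[lo, hi)`
#'   except the last, which closes at +1000 ms.
#' @export
time_bins <- function() {
  data.frame(bin = 1:6, lo = seq(-500, 750, by = 250),
             hi = seq(-250, 1000, by = 250))
}

bin_of <- function(t_ms) {
  b <- floor((t_ms + 500) / 250) + 1
  b[t_ms == 1000] <- 6            # close the final bin
  b[b < 1 | b > 6] <- NA
  b
}

# select integer frequency bins of a band: half-open [lo, hi) except the last
# band, closed at 90 Hz
band_bins <- function(freq_hz, band, closed_hi = FALSE) {
  if (closed_hi) which(freq_hz >= band[1] & freq_hz <= band[2])
  else which(freq_hz >= band[1] & freq_hz < band[2])
}

#' Spectral feature block from a time-frequency map
#'
#' Mean baseline-corrected power per (electrode, band, time bin):
#' `E x 6 x 6` columns, electrode-major.
#'
#' @param tf a baseline-corrected, cropped `tf_map`.
#' @return list with `values` (trials x 36E matrix) and `columns`
#'   (provenance data.frame).
#' @export
bin_spectra <- function(tf) {
  stopifnot(inherits(tf, "tf_map"))
  if (!tf$baseline_corrected || !tf$cropped)
    stop_bad_arg("bin_spectra needs a baseline-corrected, cropped map")
  bands <- feature_bands()
  for (b in seq_along(bands)) {
    nb <- length(band_bins(tf$freq_hz, bands[[b]], b == length(bands)))
    if (nb == 0) stop_bad_arg(paste("band", names(bands)[b], "missing from the frequency axis"))
  }
  labels <- dimnames(tf$power)[[2]]
  bin_id <- bin_of(tf$time_ms)
  d <- dim(tf$power)
  # mean over time within each bin first (one matrix product), then over
  # frequencies within each band
  B <- vapply(1:6, function(bn) {
    sel <- !is.na(bin_id) & bin_id == bn
    sel / sum(sel)
  }, numeric(length(bin_id)))
  binmean <- array(matrix(tf$power, ncol = d[4]) %*% B,
                   dim = c(d[1], d[2], d[3], 6))
  cols <- list()
  out <- matrix(0, d[1], d[2] * 6 * 6)
  k <- 0L
  for (e in seq_len(d[2])) for (b in seq_along(bands)) {
    fi <- band_bins(tf$freq_hz, bands[[b]], b == length(bands))
    for (bn in 1:6) {
      k <- k + 1L
      out[, k] <- rowMeans(matrix(binmean[, e, fi, bn], nrow = d[1]))
      cols[[k]] <- data.frame(family = "spectra", electrode = labels[e],
                              pair = NA, band = names(bands)[b], bin = bn,
                              stringsAsFactors = FALSE)
    }
  }
  columns <- do.call(rbind, cols)
  columns$name <- sprintf("sp_%s_%s_b%d", columns$electrode, columns$band,
                          columns$bin)
  colnames(out) <- columns$name
  list(values = out, columns = columns)
}

#' Permutation-entropy feature block
#'
#' Mean sliding-window PE per (electrode, time bin): `E x 6` columns. Every
#' bin must contain at least one window position (forces step <= 250 ms).
#'
#' @param es an `entropy_series` cropped to -500..1000 ms.
#' @return list with `values` and `columns` as in [bin_spectra()].
#' @export
bin_pe <- function(es) {
  stopifnot(inherits(es, "entropy_series"))
  bin_id <- bin_of(es$time_ms)
  labels <- es$channel_labels
  d <- dim(es$pe)
  out <- matrix(0, d[1], d[2] * 6)
  cols <- list(); k <- 0L
  for (e in seq_len(d[2])) for (bn in 1:6) {
    ti <- which(bin_id == bn)
    if (!length(ti))
      stop_bad_arg(paste("no PE window positions fall in time bin", bn,
                         "- use a smaller sliding step"))
    k <- k + 1L
    out[, k] <- apply(es$pe[, e, ti, drop = FALSE], 1, mean)
    cols[[k]] <- data.frame(family = "pe", electrode = labels[e], pair = NA,
                            band = NA, bin = bn, stringsAsFactors = FALSE)
  }
  columns <- do.call(rbind, cols)
  columns$name <- sprintf("pe_%s_b%d", columns$electrode, columns$bin)
  colnames(out) <- columns$name
  list(values = out, columns = columns)
}

#' The six canonical PCMI bin windows
#'
#' 250 samples each at 1000 Hz: the closed ms intervals `[lo, lo + 249]` for
#' the six 250-ms bins tiling -500..1000 ms.
#'
#' @return list of six ms pairs, ready for [windowed_pcmi()].
#' @export
pcmi_bin_windows <- function() {
  tb <- time_bins()
  lapply(seq_len(nrow(tb)), function(i) c(tb$lo[i], tb$hi[i] - 1))
}

#' PCMI feature block
#'
#' PCMI per electrode pair per time bin, recomputed directly from the 250
#' samples of each bin (248 ordinal patterns at m = 3, tau = 1; the nominal
#' 256-sample estimation window cannot fit a 250-ms bin at 1000 Hz, so the
#' bin structure wins and the short-window path is used deliberately).
#'
#' @param cs a `coupling_series` evaluated on [pcmi_bin_windows()].
#' @return list with `values` (trials x 6*C(E,2)) and `columns`.
#' @export
bin_pcmi <- function(cs) {
  stopifnot(inherits(cs, "coupling_series"))
  if (length(cs$windows) != 6)
    stop_bad_arg("expected the six canonical bin windows")
  d <- dim(cs$pcmi)
  out <- matrix(0, d[1], d[2] * 6)
  cols <- list(); k <- 0L
  for (pr in seq_len(d[2])) for (bn in 1:6) {
    k <- k + 1L
    out[, k] <- cs$pcmi[, pr, bn]
    cols[[k]] <- data.frame(family = "pcmi", electrode = NA,
                            pair = cs$pairs$pair[pr], band = NA, bin = bn,
                            stringsAsFactors = FALSE)
  }
  columns <- do.call(rbind, cols)
  columns$name <- sprintf("pcmi_%s_b%d", columns$pair, columns$bin)
  colnames(out) <- columns$name
  list(values = out, columns = columns)
}

new_feature_matrix <- function(values, columns, events, trial_index,
                               scaling = NULL, zero_variance = integer(0)) {
  structure(list(values = values, columns = columns, events = events,
                 trial_index = trial_index, scaling = scaling,
                 zero_variance = zero_variance), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d trials x %d features (%s)%s\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s %d", names(table(x$columns$family)),
                            table(x$columns$family)), collapse = ", "),
              if (is.null(x$scaling)) "" else ", z-scored"))
  invisible(x)
}

#' Assemble the per-trial feature matrix from preprocessed epochs
#'
#' Runs the three feature stages (STFT power binned by band and time bin,
#' sliding permutation entropy binned by time, PCMI per electrode pair per
#' bin) on the retained trials of an epoch set and concatenates the blocks in
#' the documented column order. Trials flagged rejected never enter.
#'
#' @param ep an `epoch_set`.
#' @param p [ordinal_params()].
#' @param pe_step sliding-PE step, samples.
#' @param chunk trials per STFT batch (memory bound; results identical).
#' @return an unscaled `feature_matrix` (run [zscore_features()] before
#'   clustering).
#' @export
build_feature_matrix <- function(ep, p = ordinal_params(), pe_step = 10L,
                                 chunk = 16L) {
  stopifnot(inherits(ep, "epoch_set"))
  keep <- retained_trials(ep)
  if (!length(keep)) stop_bad_arg("no retained trials")
  # spectra, streamed over trial chunks to bound the TFD tensor
  sp_vals <- NULL; sp_cols <- NULL
  for (grp in split(keep, ceiling(seq_along(keep) / chunk))) {
    tf <- stft_power(ep, trials = grp)
    tf <- baseline_subtract(tf)
    blk <- bin_spectra(tf)
    sp_cols <- blk$columns
    sp_vals <- rbind(sp_vals, blk$values)
  }
  es <- sliding_pe(ep, p, step = pe_step)
  es$pe <- es$pe[keep, , , drop = FALSE]
  pe_blk <- bin_pe(es)
  cs <- suppressWarnings(windowed_pcmi(ep, p, pcmi_bin_windows(),
                                       allow_short = TRUE))
  cs$pcmi <- cs$pcmi[keep, , , drop = FALSE]
  pc_blk <- bin_pcmi(cs)
  values <- cbind(sp_vals, pe_blk$values, pc_blk$values)
  columns <- rbind(sp_cols, pe_blk$columns, pc_blk$columns)
  rownames(columns) <- NULL
  new_feature_matrix(values, columns,
                     events = ep$events[keep, , drop = FALSE],
                     trial_index = keep)
}

#' Z-score a feature matrix column-wise
#'
#' Centers and scales every column with its sample mean and sample SD
#' (`n - 1`), storing the scaling for out-of-sample projection.
#' Zero-variance columns are flagged, set to 0, and listed in
#' `$zero_variance`.
#'
#' @param fm a `feature_matrix` (>= 2 trials).
#' @return the scaled `feature_matrix`.
#' @export
zscore_features <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (nrow(fm$values) < 2) stop_bad_arg("z-scoring needs at least 2 trials")
  mu <- colMeans(fm$values)
  s <- apply(fm$values, 2, sd)
  zv <- unname(which(s == 0 | !is.finite(s)))
  s[zv] <- 1
  vals <- sweep(sweep(fm$values, 2, mu), 2, s, `/`)
  vals[, zv] <- 0
  fm$values <- vals
  fm$scaling <- list(mean = mu, sd = s)
  fm$zero_variance <- zv
  fm
}

#' Project raw feature rows with a stored training scaling
#'
#' @param scaling `$scaling` of a z-scored `feature_matrix`.
#' @param values raw feature rows (same columns).
#' @return scaled matrix; training statistics only, never test statistics.
#' @export
project_features <- function(scaling, values) {
  sweep(sweep(values, 2, scaling$mean), 2, scaling$sd, `/`)
}

#' Extract one feature-family block
#'
#' @param fm a `feature_matrix`.
#' @param family `"spectra"`, `"pe"` or `"pcmi"`.
#' @return matrix of that family's columns.
#' @export
family_block <- function(fm, family = c("spectra", "pe", "pcmi")) {
  family <- match.arg(family)
  fm$values[, fm$columns$family == family, drop = FALSE]
}

#' Write / read a feature matrix as TSV (values + provenance sidecar)
#'
#' @param fm a `feature_matrix`.
#' @param path values file; the sidecar goes to `<path>.columns.tsv`.
#' @export
write_features_tsv <- function(fm, path) {
  df <- cbind(fm$events, fm$values)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(fm$columns, paste0(path, ".columns.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features_tsv
#' @export
read_features_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  columns <- read.table(paste0(path, ".columns.tsv"), header = TRUE,
                        sep = "\t", stringsAsFactors = FALSE)
  meta <- setdiff(colnames(df), columns$name)
  new_feature_matrix(as.matrix(df[, columns$name, drop = FALSE]),
                     columns, events = df[, meta, drop = FALSE],
                     trial_index = seq_len(nrow(df)))
}
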