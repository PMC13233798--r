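# Shared fixtures, built in code and memoized per test session so the heavy
# synthetic cohort is only generated and featurized once.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# small default-spec cohort: 2 subjects x 12 trials
small_cohort <- function() memo("small_cohort", function()
  generate_cohort(n_subjects = 2, trials_per_subject = 12, seed = 42))

small_epochs <- function() memo("small_epochs", function()
  preprocess_cohort(small_cohort()))

small_features <- function() memo("small_features", function()
  build_feature_matrix(small_epochs()))

small_features_z <- function() memo("small_features_z", function()
  zscore_features(small_features()))

# build an epoch_set directly from a trials x channels x samples array
make_epoch_set <- function(data, fs = 1000, t0_ms = -1000,
                           labels = sprintf("C%02d", seq_len(dim(data)[2])),
                           events = NULL) {
  dimnames(data) <- list(NULL, labels, NULL)
  time_ms <- (seq_len(dim(data)[3]) - 1) * 1000 / fs + t0_ms
  structure(list(
    data = data, time_ms = time_ms,
    events = events %||% data.frame(subject_id = rep("S01", dim(data)[1]),
                                    onset_sample = 0L),
    rejected = data.frame(trial = seq_len(dim(data)[1]),
                          reason = NA_character_),
    fs = fs), class = "epoch_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# epoch set holding one signal per trial on every channel
signal_epochs <- function(signals, n_channels = 1, fs = 1000, t0_ms = -1000) {
  ntr <- length(signals)
  ns <- length(signals[[1]])
  data <- array(0, dim = c(ntr, n_channels, ns))
  for (tr in seq_len(ntr)) for (ch in seq_len(n_channels))
    data[tr, ch, ] <- signals[[tr]]
  make_epoch_set(data, fs = fs, t0_ms = t0_ms)
}

# feature_matrix wrapper around a plain matrix (for clustering-layer tests)
make_fm <- function(values, subjects = rep("S01", nrow(values)),
                    family = rep("spectra", ncol(values))) {
  colnames(values) <- sprintf("f%03d", seq_len(ncol(values)))
  structure(list(
    values = values,
    columns = data.frame(family = family, electrode = NA, pair = NA,
                         band = NA, bin = 1, name = colnames(values),
                         stringsAsFactors = FALSE),
    events = data.frame(subject_id = subjects, stringsAsFactors = FALSE),
    trial_index = seq_len(nrow(values)), scaling = NULL,
    zero_variance = integer(0)), class = "feature_matrix")
}

# k well-separated Gaussian blobs in d dimensions
make_blobs <- function(n_per = 20, k = 4, d = 6, sep = 10, sd = 1, seed = 1) {
  set.seed(seed)
  # orthogonal placement: all pairwise center distances equal sep * sqrt(2)
  centers <- matrix(0, k, d)
  for (i in seq_len(k)) centers[i, ((i - 1) %% d) + 1] <- sep
  x <- do.call(rbind, lapply(seq_len(k), function(i)
    sweep(matrix(rnorm(n_per * d, sd = sd), n_per, d), 2, centers[i, ], `+`)))
  list(x = x, labels = rep(seq_len(k), each = n_per), centers = centers)
}

# construct a family_embedding directly (for degenerate-input tests)
make_embedding <- function(pcs, family = "spectra") {
  structure(list(pcs = pcs, family = family,
                 explained_variance = rep(1 / 3, 3)),
            class = "family_embedding")
}
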