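# Clustering quality and reproducibility metrics, all computed in the
# z-scored Euclidean feature space used for clustering and invariant to
# cluster relabeling. Brute-force oracles in the test suite cross-check every
# metric on small instances.

label_groups <- function(labels) split(seq_along(labels), labels)

#' Davies-Bouldin index (lower is better)
#'
#' Mean over clusters of the worst pairwise `(s_i + s_j) / d(c_i, c_j)`,
#' where `s_i` is the mean distance of cluster members to their centroid and
#' `d` the centroid separation (Euclidean).
#'
#' @param x data matrix (rows = items) or `feature_matrix`.
#' @param labels integer cluster labels.
#' @return scalar; coincident centroids are an error (the index diverges).
#' @export
davies_bouldin <- function(x, labels) {
  x <- as_feature_values(x)
  g <- label_groups(labels)
  if (length(g) < 2) stop_bad_arg("need at least 2 clusters")
  if (all(lengths(g) == 1)) stop_bad_arg("all clusters are singletons")
  cent <- t(vapply(g, function(i) colMeans(x[i, , drop = FALSE]),
                   numeric(ncol(x))))
  scat <- vapply(seq_along(g), function(j)
    mean(sqrt(rowSums(sweep(x[g[[j]], , drop = FALSE], 2, cent[j, ])^2))),
    numeric(1))
  k <- length(g)
  r <- numeric(k)
  for (i in seq_len(k)) {
    ratio <- vapply(seq_len(k), function(j) {
      if (j == i) return(-Inf)
      d <- sqrt(sum((cent[i, ] - cent[j, ])^2))
      if (d == 0) stop_bad_arg("coincident cluster centroids: DBI undefined")
      (scat[i] + scat[j]) / d
    }, numeric(1))
    r[i] <- max(ratio)
  }
  mean(r)
}

#' Mean silhouette coefficient (higher is better)
#'
#' Per-point `(b - a) / max(a, b)` with Euclidean distances; points in
#' singleton clusters get silhouette 0 (documented convention).
#'
#' @param x data matrix or `feature_matrix`.
#' @param labels integer cluster labels.
#' @param dmat optional precomputed `dist` object over the rows.
#' @return mean silhouette in `[-1, 1]`.
#' @export
silhouette_mean <- function(x, labels, dmat = NULL) {
  x <- as_feature_values(x)
  n <- length(labels)
  dm <- as.matrix(dmat %||% dist(x))
  g <- label_groups(labels)
  if (length(g) < 2) stop_bad_arg("need at least 2 clusters")
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- g[[as.character(labels[i])]]
    if (length(own) == 1) { s[i] <- 0; next }
    a <- sum(dm[i, own]) / (length(own) - 1)
    b <- min(vapply(g, function(idx) {
      if (identical(idx, own)) return(Inf)
      mean(dm[i, idx])
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Dunn index (higher is better)
#'
#' Minimum single-linkage inter-cluster distance divided by the maximum
#' intra-cluster diameter. A zero diameter with separated clusters returns a
#' large finite sentinel (`1e12`) with an attribute flag.
#'
#' @inheritParams silhouette_mean
#' @return scalar (>= 0).
#' @export
dunn_index <- function(x, labels, dmat = NULL) {
  x <- as_feature_values(x)
  dm <- as.matrix(dmat %||% dist(x))
  g <- label_groups(labels)
  if (length(g) < 2) stop_bad_arg("need at least 2 clusters")
  diam <- max(vapply(g, function(idx) {
    if (length(idx) < 2) return(0)
    max(dm[idx, idx])
  }, numeric(1)))
  sep <- Inf
  ks <- seq_along(g)
  for (i in ks) for (j in ks[ks > i])
    sep <- min(sep, min(dm[g[[i]], g[[j]]]))
  if (diam == 0) return(structure(1e12, degenerate = TRUE))
  sep / diam
}

#' Adjusted Rand index between two partitions
#'
#' Permutation-invariant chance-corrected agreement: 1 for identical
#' partitions, about 0 for independent ones.
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @return scalar ARI.
#' @export
adjusted_rand <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop_bad_arg("partitions must cover the same items")
  tab <- table(labels_a, labels_b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / (max_idx - expected)
}

#' Per-run ARI against a reference partition
#'
#' @param sol a `cluster_solution`.
#' @return numeric vector: ARI of each run's partition vs the consensus.
#' @export
run_ari <- function(sol) {
  apply(sol$run_labels, 1, adjusted_rand, labels_b = sol$consensus_labels)
}

#' Quality report for one clustering solution
#'
#' @param x data matrix or z-scored `feature_matrix` used for clustering.
#' @param sol a `cluster_solution`.
#' @return a `quality_report` list: `dbi`, `silhouette_mean`, `dunn`,
#'   `ari_to_reference` (per run), `vote_fraction_median`,
#'   `vote_fraction_iqr`.
#' @export
quality_report <- function(x, sol) {
  vals <- as_feature_values(x)
  labels <- sol$consensus_labels
  dmat <- dist(vals)
  structure(list(
    dbi = davies_bouldin(vals, labels),
    silhouette_mean = silhouette_mean(vals, labels, dmat = dmat),
    dunn = dunn_index(vals, labels, dmat = dmat),
    ari_to_reference = run_ari(sol),
    vote_fraction_median = median(sol$vote_fraction),
    vote_fraction_iqr = unname(diff(quantile(sol$vote_fraction, c(0.25, 0.75))))),
    class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report> DBI %.3f | silhouette %.3f | Dunn %.3f | median run ARI %.3f | vote %.2f (IQR %.2f)\n",
              x$dbi, x$silhouette_mean, x$dunn, median(x$ari_to_reference),
              x$vote_fraction_median, x$vote_fraction_iqr))
  invisible(x)
}

#' Cluster-membership overlap between a reference and single-feature solutions
#'
#' For each reference cluster, finds the best-matching cluster (largest
#' membership intersection) in every comparison partition and tabulates the
#' Venn-style intersection counts.
#'
#' @param reference integer labels of the reference (all-features) partition.
#' @param solutions named list of comparison label vectors over the same
#'   trials.
#' @return data.frame: reference cluster, its size, and per solution the
#'   best-match cluster and intersection count.
#' @export
overlap_table <- function(reference, solutions) {
  stopifnot(is.list(solutions), length(names(solutions)) == length(solutions))
  for (s in solutions) if (length(s) != length(reference))
    stop_bad_arg("all partitions must cover the same trials")
  out <- list()
  for (cl in sort(unique(reference))) {
    members <- which(reference == cl)
    row <- data.frame(reference_cluster = cl, size = length(members))
    for (nm in names(solutions)) {
      tab <- table(solutions[[nm]][members])
      best <- names(tab)[which.max(tab)]
      row[[paste0(nm, "_best")]] <- best
      row[[paste0(nm, "_overlap")]] <- as.integer(max(tab))
    }
    out[[length(out) + 1L]] <- row
  }
  do.call(rbind, out)
}
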