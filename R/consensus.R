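# Consensus k-means: repeated randomized runs, Hungarian label alignment to
# the best-within-sum reference run, unweighted majority voting, leave-one-out
# subject validation, and subject-level bootstrap selection of the cluster
# number. Distances are Euclidean on z-scored features; initialization is
# k-means++ with run seeds derived from the master seed.

as_feature_values <- function(x) {
  if (inherits(x, "feature_matrix")) x$values else as.matrix(x)
}

# Greedy k-means++ (the scikit-learn default): at each step draw
# 2 + floor(log(k)) candidate seeds from the D^2 distribution and keep the
# one that most reduces the potential. Plain D^2 sampling double-seeds a
# well-separated cluster a few percent of the time; the greedy variant makes
# per-run recovery of separable structure essentially deterministic.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  n_cand <- 2L + as.integer(log(k))
  rn <- rowSums(x^2)  # squared distances via ||a-b||^2 = ||a||^2 - 2ab + ||b||^2
  d2_to <- function(i) pmax(rn - 2 * drop(x %*% x[i, ]) + rn[i], 0)
  chosen <- integer(k)
  chosen[1] <- sample.int(n, 1)
  d2 <- d2_to(chosen[1])
  for (j in seq_len(k - 1)) {
    pr <- if (sum(d2) > 0) d2 / sum(d2) else {
      u <- rep(0, n); u[-chosen[seq_len(j)]] <- 1; u / sum(u)  # k = n case
    }
    cand <- unique(sample.int(n, n_cand, replace = TRUE, prob = pr))
    pots <- vapply(cand, function(ci) sum(pmin(d2, d2_to(ci))), numeric(1))
    chosen[j + 1] <- cand[which.min(pots)]
    d2 <- pmin(d2, d2_to(chosen[j + 1]))
  }
  x[chosen, , drop = FALSE]
}

#' Repeated k-means with independent random initializations
#'
#' Each run is seeded from the master seed, initialized with k-means++, and
#' fitted by Lloyd iterations. Runs that converge with an empty cluster are
#' re-initialized (and counted).
#'
#' @param x feature matrix (`feature_matrix` or plain matrix; rows trials).
#' @param k number of clusters (>= 2, < trials).
#' @param runs number of runs.
#' @param seed master seed.
#' @param iter_max Lloyd iteration cap.
#' @return list with `labels` (runs x trials), `centroids` (list of k x d),
#'   `withinss` (per-run within-cluster sum of squared distances), `seeds`,
#'   `reinits`.
#' @export
kmeans_repeated <- function(x, k, runs = 100, seed = 1, iter_max = 50) {
  x <- as_feature_values(x)
  n <- nrow(x)
  if (k < 2) stop_bad_arg("k must be >= 2")
  if (n < k) stop_bad_arg("need at least as many trials as clusters")
  # Euclidean geometry is invariant under orthogonal rotation: when there are
  # more features than trials, run Lloyd in the (exact) n-dimensional SVD
  # basis and map centroids back afterwards.
  if (ncol(x) > n) {
    v <- svd(x, nu = 0, nv = min(dim(x)))$v
    xw <- x %*% v
  } else xw <- x
  labels <- matrix(0L, runs, n)
  centroids <- vector("list", runs)
  withinss <- numeric(runs)
  seeds <- vapply(seq_len(runs), function(r) derive_seed(seed, "kmeans", r), 0L)
  reinits <- 0L
  for (r in seq_len(runs)) {
    attempt <- 0L
    repeat {
      km <- with_seed(seeds[r] + attempt * 997L, {
        centers <- kmeanspp_init(xw, k)
        suppressWarnings(tryCatch(
          kmeans(xw, centers, iter.max = iter_max, algorithm = "Lloyd"),
          error = function(e) NULL))
      })
      ok <- !is.null(km) && all(km$size > 0)
      if (ok || attempt >= 20L) break
      attempt <- attempt + 1L
      reinits <- reinits + 1L
    }
    if (is.null(km)) stop("k-means failed to produce a valid run")
    labels[r, ] <- km$cluster
    centroids[[r]] <- rowsum(x, km$cluster) / as.vector(table(km$cluster))
    withinss[r] <- km$tot.withinss
  }
  list(labels = labels, centroids = centroids, withinss = withinss,
       seeds = seeds, reinits = reinits, k = k)
}

#' Reference run: best within-cluster sum of distances
#'
#' @param rr result of [kmeans_repeated()].
#' @return list with `index` and `centroids` (ties go to the lowest run index).
#' @export
choose_reference <- function(rr) {
  i <- which.min(rr$withinss)
  list(index = i, centroids = rr$centroids[[i]])
}

#' Majority-vote consensus over aligned run labels
#'
#' @param aligned runs x trials integer matrix.
#' @return list with `labels` (per-trial mode; ties resolved to the smaller
#'   cluster index and reported in `ties`), `vote_fraction` (per-trial share
#'   of runs agreeing with the consensus).
#' @export
consensus_vote <- function(aligned) {
  if (!is.matrix(aligned)) aligned <- matrix(aligned, nrow = 1)
  runs <- nrow(aligned)
  kmax <- max(aligned)
  labels <- integer(ncol(aligned))
  vote <- numeric(ncol(aligned))
  ties <- integer(0)
  for (i in seq_len(ncol(aligned))) {
    cnt <- tabulate(aligned[, i], nbins = kmax)
    best <- which(cnt == max(cnt))
    if (length(best) > 1) ties <- c(ties, i)
    labels[i] <- best[1]  # smallest index on ties
    vote[i] <- cnt[best[1]] / runs
  }
  list(labels = labels, vote_fraction = vote, ties = ties)
}

#' Consensus k-means clustering
#'
#' Runs [kmeans_repeated()], aligns every run to the best-within-sum
#' reference with the Hungarian algorithm, and takes the per-trial majority
#' vote.
#'
#' @inheritParams kmeans_repeated
#' @param align_method `"hungarian"` or `"greedy"` (see [align_labels()]).
#' @return a `cluster_solution`: `run_labels`, `aligned_labels`,
#'   `consensus_labels`, `vote_fraction`, `centroids` (reference-ordered),
#'   `k`, `seeds`, `reference_run`, `ties`, `reinits`.
#' @export
consensus_kmeans <- function(x, k, runs = 100, seed = 1,
                             align_method = "hungarian", iter_max = 50) {
  vals <- as_feature_values(x)
  rr <- kmeans_repeated(vals, k, runs, seed, iter_max)
  ref <- choose_reference(rr)
  aligned <- rr$labels
  for (r in seq_len(runs)) {
    perm <- align_labels(rr$centroids[[r]], ref$centroids, align_method)
    aligned[r, ] <- perm[rr$labels[r, ]]
  }
  cv <- consensus_vote(aligned)
  structure(list(run_labels = rr$labels, aligned_labels = aligned,
                 consensus_labels = cv$labels,
                 vote_fraction = cv$vote_fraction,
                 centroids = ref$centroids, k = k, seeds = rr$seeds,
                 reference_run = ref$index, ties = cv$ties,
                 reinits = rr$reinits, withinss = rr$withinss),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("<cluster_solution> k = %d, %d trials, %d runs; median vote fraction %.2f\n",
              x$k, length(x$consensus_labels), nrow(x$run_labels),
              median(x$vote_fraction)))
  print(table(x$consensus_labels))
  invisible(x)
}

#' Agglomerative (Ward) dendrogram as an auxiliary k selector
#'
#' @param x feature matrix.
#' @return `hclust` object (Ward linkage on Euclidean distances).
#' @export
ward_tree <- function(x) {
  stats::hclust(dist(as_feature_values(x)), method = "ward.D2")
}

#' Leave-one-subject-out stability validation
#'
#' For each subject: z-score and cluster the remaining subjects' trials,
#' project the held-out trials with the training scaling, assign them to the
#' nearest consensus centroid, and report the adjusted Rand index against the
#' full-data consensus restricted to that subject.
#'
#' @param fm an unscaled `feature_matrix` with `events$subject_id`.
#' @param k clusters.
#' @param runs k-means runs per fit.
#' @param seed master seed.
#' @return list with `per_subject` (data.frame subject, n_trials, ari) and
#'   `full_solution`.
#' @export
loo_validate <- function(fm, k = 4, runs = 100, seed = 1) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (!is.null(fm$scaling))
    stop_bad_arg("loo_validate needs the unscaled feature matrix")
  subjects <- unique(fm$events$subject_id)
  if (length(subjects) < 3) stop_bad_arg("need at least 3 subjects")
  full <- consensus_kmeans(zscore_features(fm), k, runs,
                           derive_seed(seed, "loo_full"))
  rows <- list()
  for (s in subjects) {
    test_idx <- which(fm$events$subject_id == s)
    train_idx <- setdiff(seq_len(nrow(fm$values)), test_idx)
    if (!length(test_idx)) next
    train <- new_feature_matrix(fm$values[train_idx, , drop = FALSE],
                                fm$columns,
                                fm$events[train_idx, , drop = FALSE],
                                train_idx)
    train_z <- zscore_features(train)
    sol <- consensus_kmeans(train_z, k, runs, derive_seed(seed, "loo", match(s, subjects)))
    present <- sort(unique(sol$consensus_labels))  # consensus may leave a cluster empty
    cent <- t(vapply(present, function(cl)
      colMeans(train_z$values[sol$consensus_labels == cl, , drop = FALSE]),
      numeric(ncol(train_z$values))))
    test_z <- project_features(train_z$scaling,
                               fm$values[test_idx, , drop = FALSE])
    test_z[, train_z$zero_variance] <- 0
    d2 <- vapply(seq_along(present), function(ci)
      rowSums(sweep(test_z, 2, cent[ci, ])^2), numeric(length(test_idx)))
    pred <- present[max.col(-matrix(d2, nrow = length(test_idx)))]
    rows[[s]] <- data.frame(subject = s, n_trials = length(test_idx),
                            ari = adjusted_rand(pred,
                                                full$consensus_labels[test_idx]),
                            stringsAsFactors = FALSE)
  }
  list(per_subject = do.call(rbind, rows), full_solution = full)
}

#' Subject-level bootstrap validation of the cluster number
#'
#' Resamples subjects with replacement (each resample reuses all trials of a
#' drawn subject, duplicates included); for each replicate and each candidate
#' k runs consensus k-means and scores the consensus partition with the
#' Davies-Bouldin index, mean silhouette, Dunn index, and the median vote
#' fraction. Replicates where a k's consensus leaves an empty cluster are
#' flagged and excluded from the paired comparisons.
#'
#' @param fm z-scored `feature_matrix` with `events$subject_id`.
#' @param k_grid candidate cluster numbers.
#' @param n_boot number of bootstrap replicates.
#' @param runs k-means runs per replicate per k.
#' @param seed master seed.
#' @return a `bootstrap_report`: `per_replicate`, `summary` (2.5/50/97.5
#'   percentiles per metric per k), `paired` (k = 4 minus the others, same
#'   replicate), `n_flagged`, `selected_k` (best median silhouette, Dunn as
#'   tiebreak).
#' @export
bootstrap_k <- function(fm, k_grid = c(3, 4, 5), n_boot = 1000, runs = 100,
                        seed = 1) {
  stopifnot(inherits(fm, "feature_matrix"))
  subjects <- unique(fm$events$subject_id)
  if (length(subjects) < 2) stop_bad_arg("need at least 2 subjects")
  per <- list()
  for (b in seq_len(n_boot)) {
    draw <- with_seed(derive_seed(seed, "boot", b),
                      sample(subjects, length(subjects), replace = TRUE))
    rows <- unlist(lapply(draw, function(s) which(fm$events$subject_id == s)))
    vals <- fm$values[rows, , drop = FALSE]
    dmat <- dist(vals)
    for (k in k_grid) {
      sol <- consensus_kmeans(vals, k, runs,
                              derive_seed(seed, "bootk", b * 100L + k))
      valid <- length(unique(sol$consensus_labels)) == k
      per[[length(per) + 1L]] <- data.frame(
        boot = b, k = k, valid = valid,
        dbi = if (valid) davies_bouldin(vals, sol$consensus_labels) else NA,
        silhouette = if (valid) silhouette_mean(vals, sol$consensus_labels,
                                                dmat = dmat) else NA,
        dunn = if (valid) dunn_index(vals, sol$consensus_labels,
                                     dmat = dmat) else NA,
        vote = median(sol$vote_fraction))
    }
  }
  per <- do.call(rbind, per)
  metrics <- c("dbi", "silhouette", "dunn", "vote")
  summ <- do.call(rbind, lapply(split(per, per$k), function(df) {
    do.call(rbind, lapply(metrics, function(m) data.frame(
      k = df$k[1], metric = m,
      p2.5 = quantile(df[[m]], 0.025, na.rm = TRUE),
      median = median(df[[m]], na.rm = TRUE),
      p97.5 = quantile(df[[m]], 0.975, na.rm = TRUE), row.names = NULL)))
  }))
  rownames(summ) <- NULL
  paired <- NULL
  if (4 %in% k_grid) {
    ok_boot <- unlist(lapply(split(per, per$boot),
                             function(df) if (all(df$valid)) df$boot[1]))
    if (length(ok_boot)) {
      base <- per[per$k == 4 & per$boot %in% ok_boot, ]
      paired <- do.call(rbind, lapply(setdiff(k_grid, 4), function(k2) {
        other <- per[per$k == k2 & per$boot %in% ok_boot, ]
        do.call(rbind, lapply(metrics, function(m) data.frame(
          comparison = sprintf("k4_minus_k%d", k2), metric = m,
          median_diff = median(base[[m]] - other[[m]]),
          p2.5 = quantile(base[[m]] - other[[m]], 0.025),
          p97.5 = quantile(base[[m]] - other[[m]], 0.975), row.names = NULL)))
      }))
      rownames(paired) <- NULL
    }
  }
  # selector: best median silhouette, Dunn as tiebreak; a k whose replicates
  # were all flagged (NA medians) is never selected
  med <- summ[summ$metric == "silhouette", ]
  best <- med$k[order(-med$median, na.last = TRUE)]
  top <- med$median[!is.na(med$median)]
  if (length(top) && sum(med$median == max(top), na.rm = TRUE) > 1) {
    dn <- summ[summ$metric == "dunn", ]
    tied <- med$k[!is.na(med$median) & med$median == max(top)]
    best <- tied[order(-dn$median[match(tied, dn$k)], na.last = TRUE)]
  }
  structure(list(per_replicate = per, summary = summ, paired = paired,
                 n_flagged = sum(!per$valid), selected_k = best[1],
                 k_grid = k_grid),
            class = "bootstrap_report")
}

#' @export
print.bootstrap_report <- function(x, ...) {
  cat(sprintf("<bootstrap_report> %d replicates x k in {%s}; selected k = %d (%d flagged)\n",
              max(x$per_replicate$boot), paste(x$k_grid, collapse = ", "),
              x$selected_k, x$n_flagged))
  print(x$summary[x$summary$metric %in% c("silhouette", "dunn"), ])
  invisible(x)
}
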