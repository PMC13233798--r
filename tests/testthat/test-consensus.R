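test_that("Hungarian solver equals brute-force enumeration", {
  set.seed(1)
  for (k in c(3, 4, 5, 6)) {
    for (rep in 1:5) {
      cost <- matrix(runif(k * k), k, k)
      sol <- hungarian(cost)
      expect_equal(sol$cost, oracle_assignment_cost(cost), tolerance = 1e-12)
      expect_equal(sort(sol$assignment), seq_len(k))  # bijection
    }
  }
  expect_error(hungarian(matrix(1, 2, 3)), "square")
})

test_that("label alignment recovers permutations and falls back to greedy", {
  set.seed(2)
  ref <- matrix(rnorm(4 * 7), 4, 7)
  perm <- c(2, 3, 4, 1)
  run <- ref[perm, ]  # run centroid i equals ref centroid perm[i]
  expect_equal(align_labels(run, ref), perm)
  expect_equal(align_labels(ref, ref), 1:4)
  g <- align_labels(run, ref, method = "greedy")
  expect_equal(g, perm)  # zero-noise case: greedy also exact
  expect_error(align_labels(ref, ref[, 1:3]), "dimensions")
  # greedy cost never beats Hungarian
  for (rep in 1:10) {
    a <- matrix(rnorm(4 * 5), 4, 5); b <- matrix(rnorm(4 * 5), 4, 5)
    cost <- as.matrix(dist(rbind(a, b)))[1:4, 5:8]
    expect_lte(hungarian(cost)$cost, greedy_cost <- sum(
      cost[cbind(1:4, align_labels(a, b, "greedy"))]))
  }
})

test_that("repeated k-means recovers separable blobs and is deterministic", {
  blobs <- make_blobs(n_per = 50, k = 4, sep = 10, seed = 3)
  rr <- kmeans_repeated(blobs$x, k = 4, runs = 10, seed = 11)
  for (r in 1:10)
    expect_equal(adjusted_rand(rr$labels[r, ], blobs$labels), 1)
  rr2 <- kmeans_repeated(blobs$x, k = 4, runs = 10, seed = 11)
  expect_identical(rr$labels, rr2$labels)
  expect_error(kmeans_repeated(blobs$x, k = 1, runs = 2, seed = 1), "k")
  # k = n: every point its own cluster, zero within-cluster sum
  small <- blobs$x[1:6, ]
  rr3 <- kmeans_repeated(small, k = 6, runs = 2, seed = 5)
  expect_equal(rr3$withinss, c(0, 0))
})

test_that("reference choice follows the best within-cluster sum with ties to the first", {
  rr <- list(withinss = c(5.0, 3.2, 7.1),
             centroids = list("a", "b", "c"))
  expect_equal(choose_reference(rr)$index, 2L)
  expect_identical(choose_reference(rr)$centroids, "b")
  rr$withinss <- c(4, 4, 4)
  expect_equal(choose_reference(rr)$index, 1L)
  rr$withinss <- 9; rr$centroids <- list("solo")
  expect_equal(choose_reference(rr)$index, 1L)
})

test_that("consensus voting: modes, fractions, tie rule", {
  aligned <- rbind(c(1, 1), c(1, 2), c(2, 2))
  cv <- consensus_vote(aligned)
  expect_equal(cv$labels, c(1L, 2L))
  expect_equal(cv$vote_fraction, c(2 / 3, 2 / 3))
  tie <- rbind(c(2, 3), c(3, 2))
  cvt <- consensus_vote(tie)
  expect_equal(cvt$labels, c(2L, 2L))  # smaller index wins
  expect_equal(cvt$ties, c(1L, 2L))
  all_same <- matrix(1L, nrow = 100, ncol = 5)
  expect_equal(consensus_vote(all_same)$vote_fraction, rep(1, 5))
})

test_that("consensus clustering nails the separable case with full stability", {
  blobs <- make_blobs(n_per = 40, k = 4, sep = 10, seed = 4)
  sol <- consensus_kmeans(blobs$x, 4, runs = 25, seed = 7)
  expect_equal(adjusted_rand(sol$consensus_labels, blobs$labels), 1)
  expect_equal(median(sol$vote_fraction), 1)
  expect_true(all(apply(sol$aligned_labels, 1, function(l)
    adjusted_rand(l, sol$consensus_labels)) == 1))
})

test_that("consensus partition is invariant to row permutation", {
  blobs <- make_blobs(n_per = 30, k = 3, sep = 12, seed = 5)
  sol1 <- consensus_kmeans(blobs$x, 3, runs = 10, seed = 9)
  set.seed(1); perm <- sample(nrow(blobs$x))
  sol2 <- consensus_kmeans(blobs$x[perm, ], 3, runs = 10, seed = 9)
  expect_equal(adjusted_rand(sol2$consensus_labels,
                             sol1$consensus_labels[perm]), 1)
})

test_that("Ward tree gives a sensible auxiliary cut", {
  blobs <- make_blobs(n_per = 25, k = 4, sep = 10, seed = 6)
  hc <- ward_tree(blobs$x)
  expect_s3_class(hc, "hclust")
  expect_equal(adjusted_rand(stats::cutree(hc, 4), blobs$labels), 1)
})

test_that("leave-one-subject-out validation holds up on separable cohorts", {
  blobs <- make_blobs(n_per = 60, k = 4, sep = 10, seed = 7)
  subjects <- rep(sprintf("S%02d", 1:6), times = 40)  # interleaved
  fm <- make_fm(blobs$x, subjects = subjects)
  lv <- loo_validate(fm, k = 4, runs = 10, seed = 13)
  expect_equal(nrow(lv$per_subject), 6)
  expect_gte(mean(lv$per_subject$ari), 0.9)
  expect_error(loo_validate(zscore_features(fm), k = 4, runs = 2, seed = 1),
               "unscaled")
  expect_error(loo_validate(make_fm(blobs$x), k = 4), "3 subjects")
})

test_that("bootstrap_k bookkeeping and preference on constructed geometries", {
  # moderately fuzzy blobs so k = 5 solutions keep non-empty clusters
  blobs <- make_blobs(n_per = 48, k = 4, sep = 10, sd = 1.5, seed = 8)
  subjects <- rep(sprintf("S%02d", 1:8), times = 24)
  fm <- make_fm(blobs$x, subjects = subjects)
  br1 <- bootstrap_k(fm, k_grid = c(3, 4, 5), n_boot = 1, runs = 8, seed = 3)
  expect_equal(nrow(br1$per_replicate), 3)  # one replicate per k
  br <- bootstrap_k(fm, k_grid = c(3, 4, 5), n_boot = 6, runs = 8, seed = 3)
  expect_equal(br$selected_k, 4)
  med <- br$summary[br$summary$metric == "silhouette", ]
  expect_gt(med$median[med$k == 4], med$median[med$k == 3])
  expect_true(is.na(med$median[med$k == 5]) ||
                med$median[med$k == 4] > med$median[med$k == 5])
  # single blob: no k is good
  one <- matrix(rnorm(120 * 5), 120, 5)
  fm1 <- make_fm(one, subjects = rep(sprintf("S%02d", 1:6), times = 20))
  br0 <- bootstrap_k(fm1, k_grid = c(3, 4, 5), n_boot = 4, runs = 8, seed = 5)
  sil <- br0$summary[br0$summary$metric == "silhouette", ]
  expect_lt(max(sil$median), 0.3)
})
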