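# Optimal assignment (Hungarian / Jonker-Volgenant shortest augmenting path).
# No assignment-solver package ships in the target environment, so the O(n^3)
# potential-based algorithm is implemented here; tests cross-check its cost
# against brute-force enumeration of all permutations.

#' Solve the linear assignment problem
#'
#' Finds the permutation `sigma` minimizing `sum_i cost[i, sigma[i]]`.
#'
#' @param cost square numeric cost matrix (rows: sources, columns: targets).
#' @return list with `assignment` (integer vector, `assignment[i]` = column
#'   assigned to row `i`) and `cost` (the minimized total).
#' @export
hungarian <- function(cost) {
  if (!is.matrix(cost) || nrow(cost) != ncol(cost))
    stop_bad_arg("`cost` must be a square matrix")
  n <- nrow(cost)
  # arrays indexed 1..n+1; index 1 is the virtual column 0
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1); way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf; j1 <- 0L
      for (j in 2:(n + 1)) {
        if (used[j]) next
        cur <- cost[i0, j - 1] - u[i0 + 1] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in 1:(n + 1)) {
        if (used[j]) { u[p[j] + 1] <- u[p[j] + 1] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  assignment <- integer(n)
  for (j in 2:(n + 1)) if (p[j] > 0) assignment[p[j]] <- j - 1L
  list(assignment = assignment,
       cost = sum(cost[cbind(seq_len(n), assignment)]))
}

greedy_assignment <- function(cost) {
  n <- nrow(cost)
  assignment <- integer(n)
  work <- cost
  for (step in seq_len(n)) {
    ij <- which(work == min(work), arr.ind = TRUE)[1, ]
    assignment[ij[1]] <- ij[2]
    work[ij[1], ] <- Inf
    work[, ij[2]] <- Inf
  }
  list(assignment = assignment,
       cost = sum(cost[cbind(seq_len(n), assignment)]))
}

#' Align one k-means run's labels to reference centroids
#'
#' Computes the label permutation minimizing the summed Euclidean
#' centroid-to-centroid distance (Hungarian algorithm; a greedy
#' closest-centroid matcher is available as a fallback).
#'
#' @param centroids k x d centroid matrix of the run.
#' @param reference k x d reference centroids.
#' @param method `"hungarian"` (optimal) or `"greedy"`.
#' @return integer permutation `perm`: run label `l` becomes `perm[l]`.
#' @export
align_labels <- function(centroids, reference, method = c("hungarian", "greedy")) {
  method <- match.arg(method)
  if (!all(dim(centroids) == dim(reference)))
    stop_bad_arg("centroid sets must share dimensions")
  k <- nrow(centroids)
  cost <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k))
    cost[i, j] <- sqrt(sum((centroids[i, ] - reference[j, ])^2))
  sol <- if (method == "hungarian") hungarian(cost) else greedy_assignment(cost)
  sol$assignment
}
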