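# Independent brute-force oracles. These stay deliberately naive (argsort +
# table, double loops over point pairs, explicit permutation enumeration) so
# they share no code path with the implementations they check.

# ordinal pattern of one embedding vector as a canonical string; ties broken
# by order of occurrence (stable order())
pattern_string <- function(v) paste(order(v), collapse = "-")

oracle_patterns <- function(x, m = 3, tau = 1) {
  n_pat <- length(x) - (m - 1) * tau
  vapply(seq_len(n_pat), function(i)
    pattern_string(x[i + (0:(m - 1)) * tau]), character(1))
}

entropy_bits <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

oracle_pe <- function(x, m = 3, tau = 1)
  entropy_bits(table(oracle_patterns(x, m, tau)))

oracle_joint_pe <- function(x, y, m = 3, tau = 1)
  entropy_bits(table(paste(oracle_patterns(x, m, tau),
                           oracle_patterns(y, m, tau), sep = "|")))

oracle_pcmi <- function(x, y, m = 3, tau = 1)
  oracle_pe(x, m, tau) + oracle_pe(y, m, tau) - oracle_joint_pe(x, y, m, tau)

# all permutations of 1..n (n <= 6)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1)) for (i in seq_len(n)) {
    out[[length(out) + 1L]] <- append(p, n, after = i - 1)
  }
  out
}

oracle_assignment_cost <- function(cost) {
  min(vapply(all_perms(nrow(cost)),
             function(p) sum(cost[cbind(seq_len(nrow(cost)), p)]),
             numeric(1)))
}

# naive clustering metrics (double loops)
oracle_dbi <- function(x, labels) {
  cl <- sort(unique(labels))
  cent <- lapply(cl, function(c0) colMeans(x[labels == c0, , drop = FALSE]))
  s <- vapply(seq_along(cl), function(i) {
    pts <- x[labels == cl[i], , drop = FALSE]
    mean(apply(pts, 1, function(p) sqrt(sum((p - cent[[i]])^2))))
  }, numeric(1))
  mean(vapply(seq_along(cl), function(i) {
    max(vapply(seq_along(cl), function(j) {
      if (i == j) return(-Inf)
      (s[i] + s[j]) / sqrt(sum((cent[[i]] - cent[[j]])^2))
    }, numeric(1)))
  }, numeric(1)))
}

oracle_silhouette <- function(x, labels) {
  n <- nrow(x)
  d <- function(i, j) sqrt(sum((x[i, ] - x[j, ])^2))
  mean(vapply(seq_len(n), function(i) {
    own <- setdiff(which(labels == labels[i]), i)
    if (!length(own)) return(0)
    a <- mean(vapply(own, d, numeric(1), i = i))
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(c0)
      mean(vapply(which(labels == c0), d, numeric(1), i = i)), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1)))
}

oracle_dunn <- function(x, labels) {
  d <- function(i, j) sqrt(sum((x[i, ] - x[j, ])^2))
  cl <- sort(unique(labels))
  diam <- 0
  for (c0 in cl) {
    idx <- which(labels == c0)
    if (length(idx) > 1)
      for (i in idx) for (j in idx[idx > i]) diam <- max(diam, d(i, j))
  }
  sep <- Inf
  for (a in seq_along(cl)) for (b in seq_along(cl)[-seq_len(a)])
    for (i in which(labels == cl[a])) for (j in which(labels == cl[b]))
      sep <- min(sep, d(i, j))
  sep / diam
}

oracle_ari <- function(a, b) {
  n <- length(a)
  s_same <- 0; s_a <- 0; s_b <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ai <- a[i] == a[j]; bi <- b[i] == b[j]
    if (ai && bi) s_same <- s_same + 1
    if (ai) s_a <- s_a + 1
    if (bi) s_b <- s_b + 1
  }
  tot <- choose(n, 2)
  exp_idx <- s_a * s_b / tot
  (s_same - exp_idx) / ((s_a + s_b) / 2 - exp_idx)
}
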