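# Cross-feature-family redundancy: per-family PCA embedding, Kraskov (KSG)
# k-nearest-neighbor mutual information, and the asymmetric relative
# information sharing matrix R[i, j] = I(i, j) / I(i, i), where I(i, i) is
# the within-family coupling between the overlapping [PC1, PC2] and
# [PC2, PC3] subspaces. Units: nats internally (natural KSG form); R itself
# is unit-free. By construction diag(R) = 1.

#' Three-component PCA embedding of one feature family
#'
#' PCA of the family's z-scored block; the first three PCs are retained with
#' a deterministic sign convention (the largest-magnitude loading of each
#' component is positive).
#'
#' @param fm a z-scored `feature_matrix`.
#' @param family `"spectra"`, `"pe"` or `"pcmi"`.
#' @return a `family_embedding`: `pcs` (trials x 3), `family`,
#'   `explained_variance` (fractions, per retained PC).
#' @export
family_pca <- function(fm, family = c("spectra", "pe", "pcmi")) {
  family <- match.arg(family)
  block <- family_block(fm, family)
  if (ncol(block) < 4 || nrow(block) < 5)
    stop_bad_arg("family block needs >= 4 columns and >= 5 trials")
  pc <- prcomp(block, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-9)
  if (rank < 3)
    stop_bad_arg(sprintf("family block has rank %d (< 3): PCA embedding undefined", rank))
  pcs <- pc$x[, 1:3, drop = FALSE]
  for (j in 1:3) {
    load <- pc$rotation[, j]
    if (load[which.max(abs(load))] < 0) pcs[, j] <- -pcs[, j]
  }
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(pcs = pcs, family = family, explained_variance = ev[1:3]),
            class = "family_embedding")
}

#' Kraskov k-nearest-neighbor mutual information (KSG variant 1)
#'
#' Max-norm neighborhoods in the joint space; returns nats. Duplicate points
#' (zero joint distances) are broken with a deterministic jitter of
#' `1e-10 * column SD`, logged via a warning.
#'
#' @param x,y numeric matrices (or vectors) with one row per observation.
#' @param k neighbor count (default 5; `k < n`).
#' @param jitter_seed seed for the deterministic tie-break jitter.
#' @return MI estimate in nats (can be slightly negative for independent
#'   data; no clamping here).
#' @export
ksg_mi <- function(x, y, k = 5, jitter_seed = 1) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y)) stop_bad_arg("x and y need equal observation counts")
  if (k >= nrow(x)) stop_bad_arg("k must be smaller than the number of observations")
  if (anyDuplicated(cbind(x, y))) {
    warning("duplicate joint points: applying deterministic jitter", call. = FALSE)
    sds <- pmax(apply(cbind(x, y), 2, sd), 1e-12)
    noise <- with_seed(jitter_seed,
                       matrix(rnorm(nrow(x) * (ncol(x) + ncol(y))),
                              nrow = nrow(x)))
    noise <- sweep(noise, 2, 1e-10 * sds, `*`)
    x <- x + noise[, seq_len(ncol(x)), drop = FALSE]
    y <- y + noise[, ncol(x) + seq_len(ncol(y)), drop = FALSE]
  }
  .ksg_mi_cpp(x, y, as.integer(k))
}

#' Within-family information coupling I(i, i)
#'
#' KSG mutual information between the overlapping `[PC1, PC2]` and
#' `[PC2, PC3]` subspaces of a family's 3-D embedding: an internal reference
#' scale (information coupling, not self-information).
#'
#' @param emb a `family_embedding`.
#' @param k KSG neighbor count.
#' @return scalar, nats.
#' @export
internal_coupling <- function(emb, k = 5) {
  stopifnot(inherits(emb, "family_embedding"))
  ksg_mi(emb$pcs[, c(1, 2)], emb$pcs[, c(2, 3)], k)
}

#' Relative information sharing matrix over three feature families
#'
#' Cross-family MI on the 3-D embeddings, normalized per row by the family's
#' internal coupling: `R[i, j] = I(i, j) / I(i, i)`, `diag(R) = 1` by
#' construction, asymmetric in general. Negative MI estimates are clamped to
#' 0 for R (raw values are kept in `I_cross`); rows whose internal coupling
#' is not positive are flagged invalid rather than divided.
#'
#' @param embs named list of three `family_embedding`s.
#' @param k KSG neighbor count.
#' @return a `sharing_matrix`: `R` (3 x 3), `I_cross` (raw nats), `I_self`,
#'   `invalid_rows`, `n_clamped`.
#' @export
sharing_matrix <- function(embs, k = 5) {
  stopifnot(length(embs) == 3, !is.null(names(embs)))
  n <- unique(vapply(embs, function(e) nrow(e$pcs), 0L))
  if (length(n) != 1) stop_bad_arg("families must share the same trials")
  fams <- names(embs)
  I_cross <- matrix(NA_real_, 3, 3, dimnames = list(fams, fams))
  I_self <- setNames(vapply(embs, internal_coupling, numeric(1), k = k), fams)
  n_clamped <- 0L
  for (i in 1:3) for (j in 1:3) {
    if (i == j) next
    I_cross[i, j] <- ksg_mi(embs[[i]]$pcs, embs[[j]]$pcs, k)
  }
  R <- matrix(NA_real_, 3, 3, dimnames = list(fams, fams))
  diag(R) <- 1
  invalid <- character(0)
  for (i in 1:3) {
    if (I_self[i] <= 0) { invalid <- c(invalid, fams[i]); next }
    for (j in setdiff(1:3, i)) {
      v <- I_cross[i, j]
      if (v < 0) { v <- 0; n_clamped <- n_clamped + 1L }
      R[i, j] <- v / I_self[i]
    }
  }
  structure(list(R = R, I_cross = I_cross, I_self = I_self,
                 invalid_rows = invalid, n_clamped = n_clamped, k = k),
            class = "sharing_matrix")
}

#' @export
print.sharing_matrix <- function(x, ...) {
  cat("<sharing_matrix> R (row family -> column family):\n")
  print(round(x$R, 3))
  if (length(x$invalid_rows))
    cat("invalid rows (non-positive internal coupling):",
        paste(x$invalid_rows, collapse = ", "), "\n")
  invisible(x)
}

#' Long-format export of a sharing matrix
#'
#' @param sm a `sharing_matrix`.
#' @return data.frame (family_i, family_j, I, R) ready for TSV / heat maps.
#' @export
sharing_long <- function(sm) {
  fams <- rownames(sm$R)
  out <- expand.grid(family_i = fams, family_j = fams,
                     stringsAsFactors = FALSE)
  out$I <- mapply(function(i, j) if (i == j) sm$I_self[i] else sm$I_cross[i, j],
                  out$family_i, out$family_j)
  out$R <- mapply(function(i, j) sm$R[i, j], out$family_i, out$family_j)
  out
}
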