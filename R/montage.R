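#' Default 14-electrode epidural montage
#'
#' Frontal (FL1, FR1, FL2, FR2), parietal (PL1, PR1, PL2, PR2), occipital
#' (OL, OR), and four temporal/central screws (TL, TR, CL, CR). The canonical
#' analysis sets are exposed as attributes-free helper vectors:
#' `n2_electrodes()` (central set used for the laser-evoked N2 wave),
#' `pe_electrodes()` (parietal set for entropy summaries) and
#' `frontal_electrodes()` (PCMI summaries).
#'
#' @return character vector of 14 channel labels.
#' @export
default_montage <- function() {
  c("FL1", "FR1", "FL2", "FR2", "PL1", "PR1", "PL2", "PR2",
    "OL", "OR", "TL", "TR", "CL", "CR")
}

#' @rdname default_montage
#' @export
n2_electrodes <- function() c("FL2", "FR2", "PL1", "PR1")

#' @rdname default_montage
#' @export
pe_electrodes <- function() c("PL1", "PR1", "PL2", "PR2")

#' @rdname default_montage
#' @export
frontal_electrodes <- function() c("FL1", "FR1", "FL2", "FR2")

#' All unordered electrode pairs of a montage
#'
#' @param labels channel labels.
#' @return data.frame with columns `a`, `b` and a `pair` label `"A-B"`;
#'   `C(n, 2)` rows (91 for the default 14-channel montage), ordered
#'   first-electrode-major following the montage order.
#' @export
electrode_pairs <- function(labels = default_montage()) {
  n <- length(labels)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  data.frame(a = labels[idx[, "row"]], b = labels[idx[, "col"]],
             ia = idx[, "row"], ib = idx[, "col"],
             pair = paste(labels[idx[, "row"]], labels[idx[, "col"]], sep = "-"),
             stringsAsFactors = FALSE)
}
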