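#' Principal coordinate analysis
#'
#' Classical metric multidimensional scaling of a distance matrix
#' (Gower double-centering via [stats::cmdscale()]). Eigenvalues are
#' returned non-increasing; coordinates of Euclidean inputs reproduce the
#' distances exactly up to rigid motion.
#'
#' @param d symmetric distance matrix with zero diagonal (distances, not
#'   squared distances).
#' @param k number of axes to keep (default all with positive eigenvalue).
#' @return list with `points` (n x k coordinate matrix), `eig`
#'   (all eigenvalues, decreasing) and `var_explained` (fraction of the
#'   positive-eigenvalue sum per kept axis).
#' @export
pcoa <- function(d, k = NULL) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8))
    stop_input("`d` must be a symmetric matrix")
  if (any(abs(diag(d)) > 1e-12)) stop_input("`d` must have a zero diagonal")
  n <- nrow(d)
  if (all(d == 0)) {
    kk <- k %||% 1L
    return(list(points = matrix(0, n, kk), eig = rep(0, n),
                var_explained = rep(0, kk)))
  }
  # cmdscale warns when fewer than k eigenvalues are positive; the
  # positive subspace is selected explicitly below
  fit <- suppressWarnings(cmdscale(d, k = n - 1L, eig = TRUE))
  eig <- fit$eig
  pos <- sum(eig > 1e-8 * max(eig))
  kk <- min(k %||% pos, pos)
  pts <- fit$points[, seq_len(kk), drop = FALSE]
  list(points = pts, eig = eig,
       var_explained = eig[seq_len(kk)] / sum(eig[eig > 0]))
}
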