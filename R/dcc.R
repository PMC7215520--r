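#' Dynamic cross-correlation matrix
#'
#' Normalized cross-correlation of selected-atom displacements over the
#' trajectory:
#' `C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2> <|dr_j|^2>)`,
#' where `dr_i(t) = r_i(t) - <r_i>` is atom i's displacement from its
#' time-average position and `< >` averages over frames. `C_ij = 1` means
#' fully correlated motion, `-1` fully anti-correlated, `0` uncorrelated.
#' When `superpose = TRUE` (default) frames are first fitted to the
#' iterated mean structure (the same procedure as [rmsf_profile()]), so
#' global rigid-body drift does not masquerade as correlation.
#'
#' @param traj A [trajectory()].
#' @param selection Selection mode or resolved selection (default `"CA"`).
#' @param superpose Fit frames to the mean structure first (default
#'   `TRUE`).
#' @param normalized If `FALSE`, return the raw displacement covariances
#'   `<dr_i . dr_j>` instead of the Pearson-normalized matrix.
#' @return A `correlation_matrix`: list with `labels` and the symmetric
#'   `values` matrix (unit diagonal, entries in `[-1, 1]` when
#'   normalized). Residues with zero fluctuation get `NA` rows/columns
#'   with a warning.
#' @export
dcc_matrix <- function(traj, selection = "CA", superpose = TRUE,
                       normalized = TRUE) {
  xyz <- coordinates_for(traj, selection)
  nf <- dim(xyz)[1]
  if (nf < 2) stop("cross-correlation needs at least 2 frames")
  if (superpose) xyz <- fit_to_mean(xyz)$coords
  nres <- dim(xyz)[2]
  labels <- dimnames(xyz)[[2]]
  mean_xyz <- apply(xyz, c(2, 3), mean)
  # covariance = sum over axes of per-axis frame-centred cross products
  cov <- matrix(0, nres, nres)
  for (ax in 1:3) {
    D <- xyz[, , ax] - matrix(mean_xyz[, ax], nf, nres, byrow = TRUE)
    cov <- cov + crossprod(D) / nf
  }
  if (!normalized) {
    return(structure(list(labels = labels, values = cov, normalized = FALSE),
                     class = "correlation_matrix"))
  }
  v <- diag(cov)
  zero <- v <= 0
  if (any(zero)) {
    warning("zero-fluctuation residue(s), set to NA: ",
            paste(labels[zero], collapse = ", "))
    v[zero] <- NA_real_
  }
  s <- sqrt(v)
  vals <- cov / outer(s, s)
  vals <- pmin(pmax(vals, -1), 1)  # clamp rounding spill at +-1
  d <- rep(NA_real_, nres)
  d[!zero] <- 1
  diag(vals) <- d
  dimnames(vals) <- list(labels, labels)
  structure(list(labels = labels, values = vals, normalized = TRUE),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("<correlation_matrix> %d x %d%s\n", nrow(x$values),
              ncol(x$values), if (x$normalized) "" else " (unnormalized)"))
  invisible(x)
}

#' Classify pairwise motion
#'
#' Bins the off-diagonal entries of a cross-correlation matrix into
#' anti-correlated / uncorrelated / correlated motion and reports the
#' fraction of residue pairs in each category (a descriptive summary of
#' whether motion is, e.g., predominately anti-correlated). A pair is
#' `anti` when `C <= thresholds[1]`, `correlated` when
#' `C >= thresholds[2]`, otherwise `none` (the middle bin is open at the
#' cut points).
#'
#' @param mat A `correlation_matrix` from [dcc_matrix()].
#' @param thresholds Increasing length-2 numeric cut points (default
#'   `c(-0.25, 0.25)`).
#' @return A list with `fractions` (named: anti, none, correlated),
#'   `counts`, `n_pairs` and the `thresholds`.
#' @export
classify_motion <- function(mat, thresholds = c(-0.25, 0.25)) {
  stopifnot(inherits(mat, "correlation_matrix"), mat$normalized)
  if (length(thresholds) != 2 || diff(thresholds) <= 0) {
    stop("thresholds must be two increasing values")
  }
  v <- mat$values[upper.tri(mat$values)]
  v <- v[!is.na(v)]
  counts <- c(anti = sum(v <= thresholds[1]),
              none = sum(v > thresholds[1] & v < thresholds[2]),
              correlated = sum(v >= thresholds[2]))
  list(fractions = counts / length(v), counts = counts,
       n_pairs = length(v), thresholds = thresholds)
}
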