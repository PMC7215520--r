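#' Kabsch superposition
#'
#' Least-squares rigid-body fit of a mobile point set onto a reference:
#' the returned RMSD is the minimum over all proper rotations and
#' translations (reflections excluded), obtained in closed form from the
#' SVD of the cross-covariance of the centred coordinates.
#'
#' @param mobile,reference Numeric `n x 3` matrices, `n >= 3`,
#'   non-degenerate (not all collinear).
#' @return A list with `coords` (the transformed mobile set), `rmsd`
#'   (Angstrom), and the fitted `rotation` and `translation`
#'   (`coords = mobile %*% t(rotation) + translation`).
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3, ncol(reference) == 3,
            nrow(mobile) == nrow(reference))
  n <- nrow(mobile)
  if (n < 3) stop("need at least 3 points to superpose")
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm)
  B <- sweep(reference, 2, cr)
  # collinearity check: centred point sets of rank < 2 have no unique fit
  if (sum(svd(A)$d > 1e-8) < 2 || sum(svd(B)$d > 1e-8) < 2) {
    stop("degenerate geometry: points are collinear")
  }
  s <- svd(crossprod(A, B))              # A^T B = U D V^T
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- A %*% t(R) + matrix(cr, n, 3, byrow = TRUE)
  list(coords = fitted,
       rmsd = sqrt(sum((fitted - reference)^2) / n),
       rotation = R,
       translation = as.numeric(cr - cm %*% t(R)))
}

# Iteratively superpose all frames of a coords array (frames x n x 3) onto
# the mean structure: fit to the running mean, recompute the mean, repeat
# until the mean moves < tol (A) or max_iter passes. Returns the fitted
# array and the converged mean.
fit_to_mean <- function(coords, tol = 1e-6, max_iter = 10L) {
  nf <- dim(coords)[1]
  mean_xyz <- coords[1, , ]
  for (iter in seq_len(max_iter)) {
    for (t in seq_len(nf)) {
      coords[t, , ] <- kabsch_superpose(coords[t, , ], mean_xyz)$coords
    }
    new_mean <- apply(coords, c(2, 3), mean)
    shift <- sqrt(max(rowSums((new_mean - mean_xyz)^2)))
    mean_xyz <- new_mean
    if (shift < tol) break
  }
  list(coords = coords, mean = mean_xyz)
}

new_metric_series <- function(values, metric, label, reference = NULL,
                              time_ps = NULL) {
  structure(list(label = label, metric = metric, values = values,
                 reference = reference, time_ps = time_ps),
            class = "metric_series")
}

#' @export
print.metric_series <- function(x, ...) {
  cat(sprintf("<metric_series> %s %s: %d frames, mean %.3f A\n",
              x$label, x$metric, length(x$values), mean(x$values)))
  invisible(x)
}

#' Per-frame best-fit RMSD series
#'
#' Root mean square deviation of each frame's selected atoms from a
#' reference frame, after Kabsch superposition (so global rototranslation
#' contributes nothing).
#'
#' @param traj A [trajectory()].
#' @param selection Selection mode or resolved selection (default `"CA"`,
#'   the alpha-carbons).
#' @param reference Index of the reference frame (default 1, the first
#'   frame).
#' @return A `metric_series` with `metric = "RMSD"`, values in Angstrom.
#' @export
rmsd_series <- function(traj, selection = "CA", reference = 1L) {
  xyz <- coordinates_for(traj, selection)
  ref <- xyz[reference, , ]
  vals <- vapply(seq_len(dim(xyz)[1]), function(t) {
    kabsch_superpose(xyz[t, , ], ref)$rmsd
  }, numeric(1))
  new_metric_series(vals, "RMSD", traj$label, reference = reference,
                    time_ps = frame_times(traj))
}

#' Per-frame radius of gyration series
#'
#' Unweighted radius of gyration of the selected atoms:
#' `sqrt(mean(|r_i - centroid|^2))`, a compactness measure. Translation-
#' and rotation-invariant, so no superposition is involved.
#'
#' @inheritParams rmsd_series
#' @return A `metric_series` with `metric = "Rg"`, values in Angstrom.
#' @export
rg_series <- function(traj, selection = "CA") {
  xyz <- coordinates_for(traj, selection)
  vals <- vapply(seq_len(dim(xyz)[1]), function(t) {
    fr <- xyz[t, , , drop = TRUE]
    if (is.null(dim(fr))) fr <- matrix(fr, 1, 3)
    ctr <- colMeans(fr)
    sqrt(mean(rowSums(sweep(fr, 2, ctr)^2)))
  }, numeric(1))
  new_metric_series(vals, "Rg", traj$label, time_ps = frame_times(traj))
}

new_residue_profile <- function(labels, values, metric, label = "") {
  structure(list(labels = labels, values = unname(values), metric = metric,
                 label = label),
            class = "residue_profile")
}

#' @export
print.residue_profile <- function(x, ...) {
  cat(sprintf("<residue_profile> %s %s: %d residues\n",
              x$label, x$metric, length(x$values)))
  invisible(x)
}

#' @export
as.data.frame.residue_profile <- function(x, ...) {
  data.frame(residue_label = x$labels, value = x$values,
             stringsAsFactors = FALSE)
}

#' Per-residue RMSF profile
#'
#' Root mean square fluctuation of each selected atom about its mean
#' position, a per-residue flexibility measure. Frames are first
#' superposed onto the iterated mean structure (fit to the mean, recompute
#' the mean, repeat until the mean shifts by less than 1e-6 Angstrom or
#' 10 iterations), then `RMSF_i = sqrt(mean_t |r_i(t) - <r_i>|^2)`.
#'
#' @inheritParams rmsd_series
#' @return A `residue_profile` with `metric = "RMSF"`.
#' @export
rmsf_profile <- function(traj, selection = "CA") {
  xyz <- coordinates_for(traj, selection)
  if (dim(xyz)[1] < 2) stop("RMSF needs at least 2 frames")
  fitted <- fit_to_mean(xyz)
  dev2 <- sweep(fitted$coords, c(2, 3), fitted$mean)^2
  vals <- sqrt(apply(dev2, 2, mean) * 3)  # mean over frames & axes, x3
  new_residue_profile(dimnames(xyz)[[2]], vals, "RMSF", traj$label)
}

#' WT-minus-variant difference profile
#'
#' Elementwise `wt - variant` of two per-residue profiles over an
#' identical residue ordering. Sign conventions follow the comparative
#' analysis this supports: a negative delta-RMSF means the variant residue
#' is more flexible; a positive delta-L means the variant residue is more
#' accessible; a positive delta-BC means the variant residue's
#' communication is reduced.
#'
#' @param wt,variant `residue_profile`s with identical residue labels and
#'   the same metric.
#' @return A `residue_profile` whose metric is `"delta<metric>"`.
#' @export
delta_profile <- function(wt, variant) {
  stopifnot(inherits(wt, "residue_profile"), inherits(variant, "residue_profile"))
  if (length(wt$labels) != length(variant$labels) ||
      any(wt$labels != variant$labels)) {
    bad <- which(wt$labels != variant$labels)[1]
    if (is.na(bad)) bad <- min(length(wt$labels), length(variant$labels)) + 1L
    stop("residue label mismatch at position ", bad, ": '",
         wt$labels[bad], "' vs '", variant$labels[bad], "'")
  }
  new_residue_profile(wt$labels, wt$values - variant$values,
                      paste0("delta", wt$metric),
                      paste0(wt$label, "-", variant$label))
}

#' Kernel density estimate of a metric series
#'
#' Gaussian-kernel density of the per-frame values on a 512-point grid
#' spanning `[min - 3h, max + 3h]`, with bandwidth `h` from Scott's rule
#' unless overridden; the smooth analogue of a histogram of conformational
#' sampling (peak location = most sampled conformation, width = breadth of
#' sampling).
#'
#' @param series A `metric_series` (or bare numeric vector).
#' @param bandwidth Optional bandwidth override (Angstrom).
#' @return A `density_estimate` with `grid`, `density` and `bandwidth`;
#'   the trapezoidal integral over the grid is 1 within 1e-3.
#' @export
kde_distribution <- function(series, bandwidth = NULL) {
  x <- if (inherits(series, "metric_series")) series$values else series
  if (length(unique(x)) < 2) {
    stop("all values identical; KDE needs variation ",
         "(is the trajectory static?)")
  }
  h <- if (is.null(bandwidth)) stats::bw.nrd(x) else bandwidth
  d <- stats::density(x, bw = h, kernel = "gaussian", n = 512,
                      from = min(x) - 3 * h, to = max(x) + 3 * h)
  structure(list(grid = d$x, density = d$y, bandwidth = h,
                 label = if (inherits(series, "metric_series")) series$label else "",
                 metric = if (inherits(series, "metric_series")) series$metric else ""),
            class = "density_estimate")
}

#' @export
print.density_estimate <- function(x, ...) {
  cat(sprintf("<density_estimate> %s %s: bw %.4f, peak at %.3f\n",
              x$label, x$metric, x$bandwidth, x$grid[which.max(x$density)]))
  invisible(x)
}

# Local maxima of a density estimate (interior grid points).
density_modes <- function(dens) {
  y <- dens$density
  n <- length(y)
  i <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  dens$grid[i]
}

#' Summary table of metric means and percent differences
#'
#' Per-protein metric means with the average percentage difference from
#' the wild type, `100 * (mean_WT - mean_variant) / mean_WT` (so a variant
#' with a smaller mean shows a positive percent difference). Means print
#' at 3 decimals and percents at 2, half-up; the returned columns are
#' unrounded.
#'
#' @param series_list List of `metric_series`, one per protein (all the
#'   same metric), or a named numeric vector of precomputed means.
#' @param wt_label Label of the wild-type entry.
#' @param metric Metric name, required when `series_list` is a bare vector.
#' @param frames Optional frame-index filter applied to every series
#'   before averaging (e.g. an equilibrated tail).
#' @return A data.frame of class `summary_table` with columns `label`,
#'   `metric`, `mean` and `pct_diff_from_wt` (0 for the WT row).
#' @export
summary_table <- function(series_list, wt_label = "WT", metric = NULL,
                          frames = NULL) {
  if (is.numeric(series_list)) {
    means <- series_list
    if (is.null(names(means))) stop("precomputed means must be named")
    if (is.null(metric)) metric <- ""
    labels <- names(means)
  } else {
    labels <- vapply(series_list, function(s) s$label, "")
    metrics <- unique(vapply(series_list, function(s) s$metric, ""))
    if (length(metrics) != 1) stop("mixed metrics in series_list")
    metric <- metrics
    means <- vapply(series_list, function(s) {
      v <- if (is.null(frames)) s$values else s$values[frames]
      mean(v)
    }, numeric(1))
  }
  if (!wt_label %in% labels) stop("wild-type label '", wt_label, "' missing")
  wt_mean <- means[match(wt_label, labels)]
  out <- data.frame(
    label = labels,
    metric = metric,
    mean = unname(means),
    pct_diff_from_wt = unname(100 * (wt_mean - means) / wt_mean),
    stringsAsFactors = FALSE
  )
  class(out) <- c("summary_table", "data.frame")
  out
}

#' @export
print.summary_table <- function(x, ...) {
  y <- data.frame(
    label = x$label, metric = x$metric,
    mean = sprintf("%.3f", round_half_up(x$mean, 3)),
    `pct_diff` = sprintf("%.2f", round_half_up(x$pct_diff_from_wt, 2))
  )
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
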