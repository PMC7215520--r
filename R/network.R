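#' Residue contact network of one frame
#'
#' Builds the undirected, unweighted residue graph of a single frame: one
#' node per residue, an edge whenever the Euclidean distance between the
#' two residues' selected atoms (beta-carbons, alpha-carbon for glycine)
#' is within the cutoff. All residue pairs are considered; the boundary is
#' inclusive (`d <= cutoff` forms an edge) unless `inclusive = FALSE`.
#'
#' @param coords Numeric `n x 3` matrix of one frame's per-residue
#'   coordinates (e.g. one slice of [coordinates_for()] under
#'   `"CB_GLY_CA"`), rows named by residue label.
#' @param cutoff Contact distance cutoff in Angstrom (default 6.7).
#' @param inclusive Include pairs at exactly the cutoff (default `TRUE`).
#' @param frame_index Bookkeeping index stored on the result.
#' @return A `contact_network`: list with the logical symmetric
#'   `adjacency` matrix (no self-edges), `n`, `labels` and `frame_index`.
#' @export
contact_network <- function(coords, cutoff = 6.7, inclusive = TRUE,
                            frame_index = NA_integer_) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3)
  if (nrow(coords) < 2) stop("a contact network needs at least 2 residues")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  d <- as.matrix(stats::dist(coords))
  adj <- if (inclusive) d <= cutoff else d < cutoff
  diag(adj) <- FALSE
  labels <- rownames(coords)
  dimnames(adj) <- list(labels, labels)
  structure(list(adjacency = adj, n = nrow(coords), labels = labels,
                 frame_index = frame_index),
            class = "contact_network")
}

#' @export
print.contact_network <- function(x, ...) {
  cat(sprintf("<contact_network> %d residues, %d contacts\n", x$n,
              sum(x$adjacency) / 2))
  invisible(x)
}

as_igraph <- function(network) {
  igraph::graph_from_adjacency_matrix(network$adjacency, mode = "undirected")
}

#' Per-residue average shortest path (L)
#'
#' For each residue node v, the mean unweighted (BFS) graph distance from
#' v to every other reachable node: the total shortest-path length to the
#' node divided by the number of reachable partners. Lower L marks a more
#' accessible, more central residue. Residues with no reachable partner
#' get `NA` (with a warning); unreachable pairs are excluded from the
#' average.
#'
#' @param network A [contact_network()].
#' @return Named numeric vector of L values (>= 1 where defined).
#' @export
shortest_path_profile <- function(network) {
  d <- igraph::distances(as_igraph(network))
  diag(d) <- NA
  d[is.infinite(d)] <- NA
  out <- rowMeans(d, na.rm = TRUE)
  isolated <- !apply(!is.na(d), 1, any)
  if (any(isolated)) {
    out[isolated] <- NA_real_
    warning("residue(s) with no reachable partner: ",
            paste(network$labels[isolated], collapse = ", "))
  }
  names(out) <- network$labels
  out
}

#' Graph-global mean shortest path length
#'
#' The average of the finite pairwise distances over all ordered node
#' pairs (the network-level characteristic path length); the per-residue
#' quantity that comparative delta-L profiles need is
#' [shortest_path_profile()].
#'
#' @param network A [contact_network()].
#' @return A single number.
#' @export
global_mean_path_length <- function(network) {
  d <- igraph::distances(as_igraph(network))
  diag(d) <- NA
  d[is.infinite(d)] <- NA
  mean(d, na.rm = TRUE)
}

#' Per-residue betweenness centrality (raw)
#'
#' `BC(v) = sum over unordered pairs {s,t}, s,t != v, of
#' sigma(s,t|v)/sigma(s,t)`: the fraction-weighted count of shortest paths
#' passing through v, endpoints excluded (Brandes accumulation, via
#' igraph). Disconnected pairs contribute 0. High BC marks a residue
#' important for communication within the protein.
#'
#' @param network A [contact_network()].
#' @return Named numeric vector of raw betweenness values, each within
#'   `[0, (n-1)(n-2)/2]`.
#' @export
betweenness_profile <- function(network) {
  b <- igraph::betweenness(as_igraph(network), directed = FALSE,
                           weights = NA)
  names(b) <- network$labels
  b
}

#' Dynamic residue network time series
#'
#' Builds the contact network of every sampled frame and computes both
#' per-residue profiles (L and raw BC) on each. Frames are sampled at a
#' fixed stride; when the analysis interval is given in picoseconds the
#' stride is `round(interval_ps / timestep_ps)`.
#'
#' @param traj A [trajectory()].
#' @param cutoff Contact cutoff in Angstrom (default 6.7).
#' @param stride Sample every `stride`-th frame (default 1).
#' @param interval_ps Alternative to `stride`: sampling interval in ps
#'   (requires the trajectory's `timestep_ps`).
#' @param selection Selection mode (default `"CB_GLY_CA"`).
#' @param inclusive Contact boundary handling, see [contact_network()].
#' @return A `network_timeseries`: list with `labels`, `frames_used`, and
#'   matrices `L` and `BC_raw` (`length(frames_used) x n_residues`).
#' @export
network_timeseries <- function(traj, cutoff = 6.7, stride = 1L,
                               interval_ps = NULL,
                               selection = "CB_GLY_CA", inclusive = TRUE) {
  if (!is.null(interval_ps)) {
    if (is.null(traj$timestep_ps)) {
      stop("interval_ps given but the trajectory has no timestep_ps")
    }
    stride <- max(1L, as.integer(round(interval_ps / traj$timestep_ps)))
  }
  frames <- seq(1L, n_frames(traj), by = stride)
  xyz <- coordinates_for(traj, selection)
  labels <- dimnames(xyz)[[2]]
  L <- matrix(NA_real_, length(frames), length(labels))
  BC <- matrix(NA_real_, length(frames), length(labels))
  for (i in seq_along(frames)) {
    fr <- xyz[frames[i], , ]
    rownames(fr) <- labels
    net <- contact_network(fr, cutoff = cutoff, inclusive = inclusive,
                           frame_index = frames[i])
    L[i, ] <- suppressWarnings(shortest_path_profile(net))
    BC[i, ] <- betweenness_profile(net)
  }
  colnames(L) <- colnames(BC) <- labels
  structure(list(labels = labels, frames_used = frames, L = L, BC_raw = BC,
                 cutoff = cutoff, stride = stride, label = traj$label),
            class = "network_timeseries")
}

#' @export
print.network_timeseries <- function(x, ...) {
  cat(sprintf("<network_timeseries> %s: %d sampled frames x %d residues (cutoff %.1f A)\n",
              x$label, length(x$frames_used), length(x$labels), x$cutoff))
  invisible(x)
}

# Min-max normalize one frame's profile across residues; a frame where
# max == min maps to all zeros (with the caller warning once).
minmax01 <- function(v) {
  r <- range(v, na.rm = TRUE)
  if (!is.finite(r[1])) return(v)
  if (r[2] == r[1]) return(ifelse(is.na(v), NA_real_, 0))
  (v - r[1]) / (r[2] - r[1])
}

#' Average network profiles over frames
#'
#' Per-frame profiles are min-max normalized to `[0, 1]` across residues
#' (missing values excluded) and then averaged arithmetically over frames,
#' giving the averaged L and BC profiles used for delta comparisons. The
#' raw (non-normalized) BC average is always reported as well. With
#' `normalization = "none"` the plain per-residue means are returned in
#' the normalized slots.
#'
#' @param ts A `network_timeseries`.
#' @param normalization `"minmax_per_frame"` (default) or `"none"`.
#' @return An `averaged_network_profile`: list with `labels`,
#'   `avg_L_normalized`, `avg_BC_normalized`, `avg_BC_raw`, `avg_L_raw`
#'   and per-residue `missing_counts`.
#' @export
average_profiles <- function(ts, normalization = c("minmax_per_frame", "none")) {
  normalization <- match.arg(normalization)
  norm_rows <- function(M) {
    if (normalization == "none") return(M)
    flat <- apply(M, 1, function(v) {
      r <- range(v, na.rm = TRUE)
      is.finite(r[1]) && r[1] == r[2]
    })
    if (any(flat)) {
      warning(sum(flat), " frame(s) with constant profile normalized to 0")
    }
    t(apply(M, 1, minmax01))
  }
  Ln <- norm_rows(ts$L)
  Bn <- norm_rows(ts$BC_raw)
  res <- list(
    labels = ts$labels,
    avg_L_normalized = colMeans(Ln, na.rm = TRUE),
    avg_BC_normalized = colMeans(Bn, na.rm = TRUE),
    avg_L_raw = colMeans(ts$L, na.rm = TRUE),
    avg_BC_raw = colMeans(ts$BC_raw, na.rm = TRUE),
    missing_counts = colSums(is.na(ts$L)),
    normalization = normalization,
    label = ts$label
  )
  structure(res, class = "averaged_network_profile")
}

#' Extract a residue profile from averaged network results
#'
#' @param avg An `averaged_network_profile`.
#' @param metric One of `"avgL"`, `"avgBC"`, `"avgBC_raw"`.
#' @return A `residue_profile` suitable for [delta_profile()].
#' @export
network_profile <- function(avg, metric = c("avgL", "avgBC", "avgBC_raw")) {
  metric <- match.arg(metric)
  vals <- switch(metric,
                 avgL = avg$avg_L_normalized,
                 avgBC = avg$avg_BC_normalized,
                 avgBC_raw = avg$avg_BC_raw)
  new_residue_profile(avg$labels, vals, metric, avg$label)
}

#' Two-standard-deviation outlier selection on a delta profile
#'
#' Flags residues whose WT-minus-variant delta lies more than `k`
#' population standard deviations from the mean of the delta
#' distribution: `delta > mean + k*SD` (increase list) or
#' `delta < mean - k*SD` (decrease list). For delta-L, the increase list
#' reads as residues whose accessibility increased in the variant; for
#' delta-BC, as residues whose communication was reduced in the variant.
#'
#' @param delta A `residue_profile` with a `delta*` metric.
#' @param k Threshold multiplier (default 2).
#' @return An `outlier_report`: lists `increase` and `decrease` of residue
#'   labels, the distribution `mean` and `sd`, `k`, the `metric`, a
#'   `semantics` note, and `note` when SD is 0.
#' @export
select_outliers <- function(delta, k = 2.0) {
  stopifnot(inherits(delta, "residue_profile"))
  v <- delta$values
  if (length(v) < 2) stop("need at least 2 residues")
  ok <- !is.na(v)
  m <- mean(v[ok])
  s <- sqrt(mean((v[ok] - m)^2))  # population SD
  semantics <- switch(delta$metric,
    deltaL = c(increase = "accessibility increase (positive delta-L)",
               decrease = "accessibility decrease (negative delta-L)"),
    deltaBC = c(increase = "communication reduction (positive delta-BC)",
                decrease = "communication increase (negative delta-BC)"),
    deltaRMSF = c(increase = "flexibility reduction (positive delta-RMSF)",
                  decrease = "flexibility increase (negative delta-RMSF)"),
    c(increase = "above threshold", decrease = "below threshold"))
  if (s == 0) {
    return(structure(list(metric = delta$metric, increase = character(0),
                          decrease = character(0), mean = m, sd = 0, k = k,
                          semantics = semantics,
                          note = "zero spread in delta values; no outliers defined",
                          label = delta$label),
                     class = "outlier_report"))
  }
  structure(list(
    metric = delta$metric,
    increase = delta$labels[ok & v > m + k * s],
    decrease = delta$labels[ok & v < m - k * s],
    mean = m, sd = s, k = k, semantics = semantics, note = NULL,
    label = delta$label
  ), class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("<outlier_report> %s %s (mean %.4g, SD %.4g, k = %g)\n",
              x$label, x$metric, x$mean, x$sd, x$k))
  if (!is.null(x$note)) cat("  note: ", x$note, "\n", sep = "")
  cat("  ", x$semantics["increase"], ": ",
      if (length(x$increase)) paste(x$increase, collapse = " ") else "-",
      "\n", sep = "")
  cat("  ", x$semantics["decrease"], ": ",
      if (length(x$decrease)) paste(x$decrease, collapse = " ") else "-",
      "\n", sep = "")
  invisible(x)
}
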