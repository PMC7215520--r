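# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid igraph and the package's own code paths.

# All-pairs shortest-path distances by Floyd-Warshall on a logical
# adjacency matrix (Inf where unreachable).
oracle_floyd_warshall <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# Per-node average shortest path from the Floyd-Warshall distances.
oracle_L <- function(adj) {
  d <- oracle_floyd_warshall(adj)
  diag(d) <- NA
  d[is.infinite(d)] <- NA
  suppressWarnings(rowMeans(d, na.rm = TRUE))
}

# Exhaustive betweenness: sigma(s,t) is the number of walks of minimal
# length (walks of the shortest length are exactly the shortest paths),
# counted from powers of the adjacency matrix; sigma(s,t|v) =
# sigma(s,v) * sigma(v,t) when d(s,v) + d(v,t) = d(s,t).
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- oracle_floyd_warshall(adj)
  A <- 1 * adj
  maxd <- max(d[is.finite(d)])
  pow <- vector("list", maxd)
  P <- diag(n)
  for (k in seq_len(maxd)) {
    P <- P %*% A
    pow[[k]] <- P
  }
  sigma <- function(i, j) {
    if (i == j) return(1)
    if (!is.finite(d[i, j])) return(0)
    pow[[d[i, j]]][i, j]
  }
  bc <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) {
      for (t in (s + 1):n) {
        if (s == v || t == v || !is.finite(d[s, t])) next
        if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
            d[s, v] + d[v, t] == d[s, t]) {
          bc[v] <- bc[v] + sigma(s, v) * sigma(v, t) / sigma(s, t)
        }
      }
    }
  }
  bc
}

# Random Erdos-Renyi adjacency matrix (symmetric, no self-edges).
random_adjacency <- function(n, p) {
  adj <- matrix(FALSE, n, n)
  up <- upper.tri(adj)
  adj[up] <- stats::runif(sum(up)) < p
  adj | t(adj)
}

# Wrap an adjacency matrix as a contact_network without going through
# coordinates: embed nothing, patch the structure directly.
adjacency_network <- function(adj) {
  labels <- paste0("Ala", seq_len(nrow(adj)) + 22L)
  dimnames(adj) <- list(labels, labels)
  structure(list(adjacency = adj, n = nrow(adj), labels = labels,
                 frame_index = NA_integer_),
            class = "contact_network")
}

# Brute-force rigid-body fit: optimal translation is the centroid match,
# rotations searched on a coarse-to-fine Euler-angle grid.
oracle_grid_rmsd <- function(mobile, reference) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(reference, 2, colMeans(reference))
  rot <- function(a, b, c) {
    Rz1 <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
                  byrow = TRUE)
    Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3,
                 byrow = TRUE)
    Rz2 <- matrix(c(cos(c), -sin(c), 0, sin(c), cos(c), 0, 0, 0, 1), 3, 3,
                  byrow = TRUE)
    Rz1 %*% Ry %*% Rz2
  }
  eval_rmsd <- function(a, b, c) {
    sqrt(sum((A %*% t(rot(a, b, c)) - B)^2) / nrow(A))
  }
  best <- c(0, 0, 0)
  best_val <- Inf
  step <- pi / 18  # 10 degrees
  grid_a <- seq(0, 2 * pi, by = step)
  grid_b <- seq(0, pi, by = step)
  for (a in grid_a) for (b in grid_b) for (c in grid_a) {
    v <- eval_rmsd(a, b, c)
    if (v < best_val) { best_val <- v; best <- c(a, b, c) }
  }
  for (refine in 1:4) {
    step <- step / 5
    ga <- seq(best[1] - 5 * step, best[1] + 5 * step, by = step)
    gb <- seq(best[2] - 5 * step, best[2] + 5 * step, by = step)
    gc <- seq(best[3] - 5 * step, best[3] + 5 * step, by = step)
    for (a in ga) for (b in gb) for (c in gc) {
      v <- eval_rmsd(a, b, c)
      if (v < best_val) { best_val <- v; best <- c(a, b, c) }
    }
  }
  best_val
}

# Build a trajectory directly from a frames x residues x 3 coordinate
# array of alpha-carbons (toy fixtures for metric tests).
toy_trajectory <- function(coords, label = "toy", resno = NULL) {
  nr <- dim(coords)[2]
  if (is.null(resno)) resno <- seq_len(nr) + 22L
  atoms <- data.frame(
    atom_name = "CA",
    residue_name = "ALA",
    residue_number = resno,
    chain_id = "A",
    stringsAsFactors = FALSE
  )
  trajectory(atoms, coords, label = label)
}
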