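path3 <- adjacency_network(rbind(c(FALSE, TRUE, FALSE),
                                 c(TRUE, FALSE, TRUE),
                                 c(FALSE, TRUE, FALSE)))

test_that("contact edges follow the inclusive 6.7 A cutoff", {
  coords <- rbind(c(0, 0, 0), c(6.0, 0, 0))
  rownames(coords) <- c("Ala23", "Ala24")
  expect_true(contact_network(coords)$adjacency[1, 2])
  coords[2, 1] <- 7.0
  expect_false(contact_network(coords)$adjacency[1, 2])
  coords[2, 1] <- 6.7
  expect_true(contact_network(coords)$adjacency[1, 2])
  expect_false(contact_network(coords, inclusive = FALSE)$adjacency[1, 2])
  expect_false(any(diag(contact_network(coords)$adjacency)))
})

test_that("average shortest path matches hand enumeration on small graphs", {
  expect_equal(unname(shortest_path_profile(path3)), c(1.5, 1, 1.5))
  complete5 <- adjacency_network(matrix(TRUE, 5, 5) & !diag(5))
  expect_equal(unname(shortest_path_profile(complete5)), rep(1, 5))
  # graph-global mean over ordered pairs, for the complete graph, is 1
  expect_equal(global_mean_path_length(complete5), 1)
})

test_that("betweenness matches closed forms on path and star graphs", {
  expect_equal(unname(betweenness_profile(path3)), c(0, 1, 0))
  star6 <- matrix(FALSE, 6, 6)
  star6[1, 2:6] <- star6[2:6, 1] <- TRUE
  expect_equal(unname(betweenness_profile(adjacency_network(star6))),
               c(10, 0, 0, 0, 0, 0))
})

test_that("L and BC match brute-force oracles on random graphs", {
  set.seed(2024)
  for (rep in 1:30) {
    n <- sample(4:12, 1)
    adj <- random_adjacency(n, stats::runif(1, 0.2, 0.7))
    net <- adjacency_network(adj)
    L <- suppressWarnings(shortest_path_profile(net))
    L_oracle <- oracle_L(adj)
    L_oracle[is.nan(L_oracle)] <- NA_real_
    expect_equal(unname(L), unname(L_oracle), tolerance = 1e-12)
    bc <- betweenness_profile(net)
    expect_equal(unname(bc), oracle_betweenness(adj), tolerance = 1e-12)
    expect_true(all(bc <= (n - 1) * (n - 2) / 2 + 1e-9))
  }
})

test_that("L and BC are invariant under node relabeling", {
  set.seed(7)
  adj <- random_adjacency(9, 0.4)
  perm <- sample(9)
  net1 <- adjacency_network(adj)
  net2 <- adjacency_network(adj[perm, perm])
  expect_equal(unname(betweenness_profile(net2)),
               unname(betweenness_profile(net1))[perm], tolerance = 1e-12)
  expect_equal(unname(suppressWarnings(shortest_path_profile(net2))),
               unname(suppressWarnings(shortest_path_profile(net1)))[perm],
               tolerance = 1e-12)
})

test_that("adding an edge never increases shortest-path averages", {
  set.seed(11)
  for (rep in 1:10) {
    adj <- random_adjacency(8, 0.35)
    missing_edges <- which(!adj & upper.tri(adj), arr.ind = TRUE)
    if (nrow(missing_edges) == 0) next
    e <- missing_edges[sample(nrow(missing_edges), 1), ]
    adj2 <- adj
    adj2[e[1], e[2]] <- adj2[e[2], e[1]] <- TRUE
    d1 <- oracle_floyd_warshall(adj)
    d2 <- oracle_floyd_warshall(adj2)
    expect_true(all(d2 <= d1))
    L1 <- suppressWarnings(shortest_path_profile(adjacency_network(adj)))
    L2 <- suppressWarnings(shortest_path_profile(adjacency_network(adj2)))
    both <- !is.na(L1) & !is.na(L2) &
      rowSums(adj) > 0  # nodes connected before stay comparable
    # L may rise for a node that gains reachable far-away partners, so
    # restrict to graphs staying fully connected
    if (all(is.finite(d1)) && all(is.finite(d2))) {
      expect_true(all(L2[both] <= L1[both] + 1e-12))
    }
  }
})

test_that("the network time series samples frames at the requested stride", {
  cfg <- generator_config(n_residues = 12, n_frames = 10, seed = 4,
                          fluctuation_sigma = 0, timestep_ps = 100)
  tr <- generate_trajectory(cfg)
  ts <- network_timeseries(tr, stride = 1)
  # static trajectory: identical profiles every frame
  expect_equal(max(apply(ts$L, 2, function(v) diff(range(v)))), 0)
  expect_equal(max(apply(ts$BC_raw, 2, function(v) diff(range(v)))), 0)
  # stride = total frames keeps a single sampled frame
  expect_equal(length(network_timeseries(tr, stride = 10)$frames_used), 1L)
  # a 100 ps interval at a 100 ps timestep is stride 1; 500 ps is stride 5
  expect_equal(network_timeseries(tr, interval_ps = 500)$stride, 5L)
})

test_that("a residue leaving contact range changes its per-frame L", {
  # two frames: residue 4 within range, then pushed away
  base <- rbind(c(0, 0, 0), c(4, 0, 0), c(8, 0, 0), c(12, 0, 0))
  far <- base; far[4, 1] <- 40
  coords <- array(NA_real_, c(2, 4, 3))
  coords[1, , ] <- base
  coords[2, , ] <- far
  tr <- toy_trajectory(coords)
  ts <- suppressWarnings(network_timeseries(tr, selection = "CA"))
  expect_false(isTRUE(all.equal(ts$L[1, 4], ts$L[2, 4])))
  expect_true(is.na(ts$L[2, 4]))
})

test_that("profile averaging normalizes per frame then averages", {
  ts <- structure(list(labels = paste0("Ala", 23:25),
                       frames_used = 1:2,
                       L = rbind(c(1, 2, 3), c(1, 2, 3)),
                       BC_raw = rbind(c(0, 5, 10), c(10, 5, 0)),
                       cutoff = 6.7, stride = 1L, label = "toy"),
                  class = "network_timeseries")
  avg <- average_profiles(ts)
  expect_equal(unname(avg$avg_L_normalized), c(0, 0.5, 1))
  expect_equal(unname(avg$avg_BC_normalized), c(0.5, 0.5, 0.5))
  expect_equal(unname(avg$avg_BC_raw), c(5, 5, 5))
  # spreadsheet-checked mixed fixture
  ts$L <- rbind(c(2, 4, 6), c(1, 5, NA))
  avg2 <- average_profiles(ts)
  expect_equal(unname(avg2$avg_L_normalized), c(0, 0.75, 1),
               tolerance = 1e-12)  # frame 2 normalizes over {1,5} -> {0,1}
  expect_equal(unname(avg2$missing_counts), c(0, 0, 1))
  # a constant frame normalizes to zero with a warning
  ts$L <- rbind(c(2, 2, 2), c(1, 2, 3))
  expect_warning(avg3 <- average_profiles(ts), "constant")
  expect_equal(unname(avg3$avg_L_normalized), c(0, 0.25, 0.5))
})

test_that("two-SD outlier selection flags extremes with correct semantics", {
  labels <- paste0("Ala", 23:73)
  vals <- c(10, rep(0, 50))
  d <- trajnet:::new_residue_profile(labels, vals, "deltaL", "WT-V")
  rep1 <- select_outliers(d)
  expect_equal(rep1$increase, "Ala23")
  expect_length(rep1$decrease, 0)
  expect_match(rep1$semantics[["increase"]], "accessibility increase")
  # direct mean/SD check
  expect_equal(rep1$mean, mean(vals))
  expect_equal(rep1$sd, sqrt(mean((vals - mean(vals))^2)))
  # negation swaps the lists exactly
  d2 <- trajnet:::new_residue_profile(labels, -vals, "deltaL", "WT-V")
  rep2 <- select_outliers(d2)
  expect_equal(rep2$decrease, rep1$increase)
  expect_equal(rep2$increase, rep1$decrease)
  # all-equal deltas: zero SD, empty report with note
  d3 <- trajnet:::new_residue_profile(labels, rep(0.3, 51), "deltaBC", "WT-V")
  rep3 <- select_outliers(d3)
  expect_length(rep3$increase, 0)
  expect_length(rep3$decrease, 0)
  expect_match(rep3$note, "zero spread")
})
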