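test_that("degenerate generator settings reproduce the base geometry exactly", {
  cfg <- generator_config(n_residues = 15, n_frames = 4, seed = 1,
                          fluctuation_sigma = 0)
  tr <- generate_trajectory(cfg)
  for (t in 2:4) expect_equal(tr$xyz[t, , ], tr$xyz[1, , ])
})

test_that("the generator is deterministic in (config, seed)", {
  cfg <- generator_config(
    n_residues = 20, n_frames = 10, seed = 42, base_geometry = "compact_walk",
    motion_factors = list(motion_factor(rep(c(1, -1), 10))),
    rigid_body = "random",
    two_state = two_state_config(residues = 30:35, offset = 2, p = 0.1))
  a <- generate_trajectory(cfg)
  b <- generate_trajectory(cfg)
  expect_identical(a$xyz, b$xyz)
  cfg2 <- cfg; cfg2$seed <- 43L
  expect_false(identical(generate_trajectory(cfg2)$xyz, a$xyz))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(generate_trajectory(generator_config(n_residues = 5, n_frames = 2,
                                                 seed = 7)))
  expect_identical(.Random.seed, before)
})

test_that("rigid-body-only trajectories superpose to zero RMSD", {
  cfg <- generator_config(n_residues = 12, n_frames = 20, seed = 8,
                          fluctuation_sigma = 0, rigid_body = "random")
  tr <- generate_trajectory(cfg)
  r <- rmsd_series(tr)
  expect_lt(max(r$values), 1e-6)
})

test_that("sample RMSF recovers sqrt(3) * sigma", {
  # uniform jitter per run: with strongly heterogeneous sigma the best-fit
  # superposition redistributes some misfit from mobile onto quiet
  # residues, which is a property of fitted RMSF itself, not an estimator
  # error (covered by the scaling test below)
  for (sigma in c(0.2, 0.5, 1.0)) {
    cfg <- generator_config(n_residues = 40, n_frames = 2000,
                            seed = 31 + round(10 * sigma),
                            fluctuation_sigma = sigma)
    prof <- rmsf_profile(generate_trajectory(cfg))
    rel <- abs(prof$values - sqrt(3) * sigma) / (sqrt(3) * sigma)
    expect_lt(max(rel), 0.10)
  }
})

test_that("doubling sigma on a residue block doubles its RMSF", {
  base_sig <- rep(0.4, 12)
  cfg1 <- generator_config(n_residues = 12, n_frames = 3000, seed = 13,
                           fluctuation_sigma = base_sig)
  sig2 <- base_sig; sig2[4:6] <- 0.8
  cfg2 <- generator_config(n_residues = 12, n_frames = 3000, seed = 14,
                           fluctuation_sigma = sig2)
  r1 <- rmsf_profile(generate_trajectory(cfg1))$values
  r2 <- rmsf_profile(generate_trajectory(cfg2))$values
  expect_equal(r2[4:6] / r1[4:6], rep(2, 3), tolerance = 0.1)
})

test_that("a shared factor produces the predicted cross-correlation", {
  a <- 0.6; sig <- 0.4
  loading <- c(a, a, -a, 0, 0, 0, 0, 0, 0, 0)
  cfg <- generator_config(n_residues = 10, n_frames = 5000, seed = 21,
                          fluctuation_sigma = sig,
                          motion_factors = list(motion_factor(loading)))
  m <- dcc_matrix(generate_trajectory(cfg), superpose = FALSE)
  pred <- a^2 / (a^2 + sig^2)
  expect_equal(m$values[1, 2], pred, tolerance = 0.05)
  expect_equal(m$values[1, 3], -pred, tolerance = 0.05)
  expect_equal(m$values[4, 5], 0, tolerance = 0.05)
})

test_that("two-state switching yields a bimodal RMSD density", {
  cfg <- generator_config(n_residues = 40, n_frames = 800, seed = 17,
                          base_geometry = "compact_walk",
                          fluctuation_sigma = 0.15,
                          two_state = two_state_config(residues = 40:52,
                                                       offset = 4, p = 0.1))
  tr <- generate_trajectory(cfg)
  r <- rmsd_series(tr)
  dens <- kde_distribution(r)
  modes <- trajnet:::density_modes(dens)
  # keep substantial modes only (> 20% of the peak)
  modes <- modes[dens$density[match(modes, dens$grid)] >
                   0.2 * max(dens$density)]
  expect_gte(length(modes), 2L)
  # the two dominant modes straddle a point between the states
  state_rmsd <- max(r$values) / 2
  expect_true(min(modes) < state_rmsd && max(modes) > state_rmsd)
})

test_that("null variant pairs differ only by sampling noise", {
  cfg <- generator_config(n_residues = 30, n_frames = 1500, seed = 5)
  pair <- make_variant_pair(cfg)
  expect_identical(pair$wt$atoms, pair$variant$atoms)
  d <- delta_profile(rmsf_profile(pair$wt), rmsf_profile(pair$variant))
  expect_lt(max(abs(d$values)), 0.15)  # ~5% of sqrt(3)*sigma
})

test_that("a sigma perturbation shows up as negative delta-RMSF on the block", {
  cfg <- generator_config(n_residues = 30, n_frames = 1500, seed = 9)
  pair <- make_variant_pair(cfg, list(type = "sigma_scale",
                                      residues = 30:40, value = 2))
  d <- delta_profile(rmsf_profile(pair$wt), rmsf_profile(pair$variant))
  block <- parse_residue_label(d$labels)$residue_number %in% 30:40
  expect_true(all(d$values[block] < 0))
  expect_lt(mean(d$values[block]), -0.5)
})

test_that("a base displacement perturbs delta-L near the displaced loop", {
  cfg <- generator_config(n_residues = 60, n_frames = 40, seed = 23,
                          base_geometry = "compact_walk",
                          fluctuation_sigma = 0.2)
  pair <- make_variant_pair(cfg, list(type = "displace",
                                      residues = 50:58, value = 5))
  avg_w <- average_profiles(network_timeseries(pair$wt))
  avg_v <- average_profiles(network_timeseries(pair$variant))
  dL <- delta_profile(network_profile(avg_w, "avgL"),
                      network_profile(avg_v, "avgL"))
  near <- parse_residue_label(dL$labels)$residue_number %in% 48:60
  expect_gt(max(abs(dL$values[near]), na.rm = TRUE), 0.02)
})
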