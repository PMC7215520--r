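make_tetra <- function() {
  matrix(c(0, 0, 0,
           1.5, 0, 0,
           0, 1.5, 0,
           0.3, 0.4, 1.2), 4, 3, byrow = TRUE)
}

test_that("Kabsch superposition handles identity, translation and rotation", {
  x <- make_tetra()
  expect_equal(kabsch_superpose(x, x)$rmsd, 0, tolerance = 1e-12)
  shifted <- sweep(x, 2, c(5, -2, 1), "+")
  expect_equal(kabsch_superpose(shifted, x)$rmsd, 0, tolerance = 1e-12)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  expect_equal(kabsch_superpose(x %*% t(R), x)$rmsd, 0, tolerance = 1e-12)
})

test_that("Kabsch RMSD matches a brute-force rotation-grid minimum", {
  x <- make_tetra()
  th <- pi / 2
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
               byrow = TRUE)
  y <- x %*% t(Rz)
  y[2, ] <- y[2, ] + c(0.6, -0.8, 0)  # 1 A distortion on one vertex
  fit <- kabsch_superpose(y, x)
  expect_gt(fit$rmsd, 0.1)
  expect_equal(fit$rmsd, oracle_grid_rmsd(y, x), tolerance = 1e-3)
  # reflections are excluded: the fitted rotation is proper
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
})

test_that("Kabsch rejects degenerate input", {
  expect_error(kabsch_superpose(matrix(0, 2, 3), matrix(0, 2, 3)), "3 points")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("superposition RMSD is invariant under common rototranslation and symmetric", {
  set.seed(4)
  x <- matrix(rnorm(18), 6, 3)
  y <- x + matrix(rnorm(18, sd = 0.3), 6, 3)
  base <- kabsch_superpose(y, x)$rmsd
  q <- c(0.4, -0.2, 0.8, 0.1); q <- q / sqrt(sum(q^2))
  R <- matrix(c(1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
                2 * (q[2] * q[4] + q[1] * q[3]),
                2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
                2 * (q[3] * q[4] - q[1] * q[2]),
                2 * (q[2] * q[4] - q[1] * q[3]),
                2 * (q[3] * q[4] + q[1] * q[2]), 1 - 2 * (q[2]^2 + q[3]^2)),
              3, 3, byrow = TRUE)
  moved <- function(m) sweep(m %*% t(R), 2, c(3, -1, 7), "+")
  expect_equal(kabsch_superpose(moved(y), moved(x))$rmsd, base,
               tolerance = 1e-9)
  expect_equal(kabsch_superpose(x, y)$rmsd, base, tolerance = 1e-9)
})

test_that("RMSD series is zero for static or translated frames", {
  x <- make_tetra()
  coords <- array(NA_real_, c(3, 4, 3))
  coords[1, , ] <- x
  coords[2, , ] <- x
  coords[3, , ] <- sweep(x, 2, c(1, 0, 0), "+")  # +1 A along x
  tr <- toy_trajectory(coords)
  r <- rmsd_series(tr)
  expect_equal(r$values, rep(0, 3), tolerance = 1e-12)
  expect_equal(r$metric, "RMSD")
})

test_that("radius of gyration matches closed forms", {
  # two atoms 2d apart: each sits d from the centroid, Rg = d
  d <- 1.7
  two <- array(c(0, 2 * d, 0, 0, 0, 0), c(1, 2, 3))
  expect_equal(rg_series(toy_trajectory(two))$values, d)
  # 8 atoms at the corners of a unit cube: Rg = sqrt(3)/2
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  coords <- array(NA_real_, c(1, 8, 3))
  coords[1, , ] <- cube
  expect_equal(rg_series(toy_trajectory(coords))$values, sqrt(3) / 2)
  # translation and rotation invariance
  th <- 1.1
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3,
              byrow = TRUE)
  coords2 <- coords
  coords2[1, , ] <- sweep(cube %*% t(R), 2, c(9, -4, 2), "+")
  expect_equal(rg_series(toy_trajectory(coords2))$values, sqrt(3) / 2)
})

test_that("RMSF of a static trajectory is zero and needs two frames", {
  x <- make_tetra()
  coords <- array(NA_real_, c(2, 4, 3))
  coords[1, , ] <- x
  coords[2, , ] <- x
  expect_equal(rmsf_profile(toy_trajectory(coords))$values, rep(0, 4))
  expect_error(rmsf_profile(toy_trajectory(array(x, c(1, 4, 3)))), "2 frames")
})

test_that("RMSF is invariant to frame order", {
  cfg <- generator_config(n_residues = 10, n_frames = 60, seed = 3)
  tr <- generate_trajectory(cfg)
  r1 <- rmsf_profile(tr)$values
  r2 <- rmsf_profile(subset_frames(tr, 60:1))$values
  expect_equal(r1, r2, tolerance = 1e-5)  # up to mean-fit convergence
})

test_that("delta profiles subtract WT minus variant with the stated sign convention", {
  a <- trajnet:::new_residue_profile(c("Ala23", "Ala24"), c(1.0, 2.0), "RMSF", "WT")
  b <- trajnet:::new_residue_profile(c("Ala23", "Ala24"), c(0.5, 2.5), "RMSF", "V")
  d <- delta_profile(a, b)
  expect_equal(d$values, c(0.5, -0.5))
  expect_equal(d$metric, "deltaRMSF")
  # variant more flexible (larger RMSF) => negative delta
  expect_lt(d$values[2], 0)
  # antisymmetry
  expect_equal(delta_profile(b, a)$values, -d$values)
  # identical profiles give zeros
  expect_equal(delta_profile(a, a)$values, c(0, 0))
  # label mismatch names the first offender
  b2 <- trajnet:::new_residue_profile(c("Ala23", "Gly24"), c(1, 1), "RMSF", "V")
  expect_error(delta_profile(a, b2), "position 2")
})

test_that("KDE integrates to one and matches the standard-normal density", {
  set.seed(123)
  x <- rnorm(1e4)
  dens <- kde_distribution(x)
  expect_equal(trajnet:::trapz(dens$grid, dens$density), 1, tolerance = 1e-3)
  at0 <- dens$density[which.min(abs(dens$grid))]
  expect_equal(at0, 1 / sqrt(2 * pi), tolerance = 0.02)
  expect_error(kde_distribution(rep(1, 5)), "identical")
})

test_that("summary table reproduces the printed percent-difference convention", {
  means <- c(WT = 2.507, S100A = 2.465)
  s <- summary_table(means, "WT", metric = "RMSD")
  expect_equal(round_half_up(s$pct_diff_from_wt[2], 2), 1.68)
  expect_equal(s$pct_diff_from_wt[1], 0)
  means_rg <- c(WT = 18.120, E109D = 17.865)
  s2 <- summary_table(means_rg, "WT", metric = "Rg")
  expect_equal(round_half_up(s2$pct_diff_from_wt[2], 2), 1.41)
  # equal means give exactly zero
  expect_equal(summary_table(c(WT = 5, V = 5), "WT")$pct_diff_from_wt, c(0, 0))
  expect_error(summary_table(c(A = 1, B = 2), "WT"), "missing")
})

test_that("summary table accepts series and an optional frame filter", {
  cfg <- generator_config(n_residues = 8, n_frames = 30, seed = 2)
  trs <- list(generate_trajectory(cfg, label = "WT"),
              generate_trajectory(generator_config(n_residues = 8,
                                                   n_frames = 30, seed = 4),
                                  label = "V1"))
  rg <- lapply(trs, rg_series)
  s_all <- summary_table(rg, "WT")
  s_tail <- summary_table(rg, "WT", frames = 11:30)
  expect_equal(s_all$mean[1], mean(rg[[1]]$values))
  expect_equal(s_tail$mean[2], mean(rg[[2]]$values[11:30]))
})
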