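#' Synthetic trajectory generator configuration
#'
#' Configures the seeded generator of protein-like Calpha/Cbeta
#' trajectories used throughout for testing and for the packaged analyses.
#' The generator emulates a ~270-residue single-chain globular protein
#' trajectory (author numbering starting at 23, as in the carbonic
#' anhydrase VIII models that motivated it): a fixed base geometry plus,
#' per frame, optional correlated group motions (factors), isotropic
#' per-residue Gaussian jitter, optional global rigid-body drift and
#' optional two-state conformational switching.
#'
#' Defaults reflect the emulated study conditions: 268 residues numbered
#' 23-290, 2000 frames at 100 ps per frame (a 200 ns run sampled at the
#' 100 ps network interval), 0.5 A per-axis jitter, and glycines at the
#' positions the protein actually has glycines.
#'
#' @param n_residues Number of residues.
#' @param first_residue_number Author number of the first residue.
#' @param n_frames Number of frames.
#' @param timestep_ps Frame spacing in picoseconds.
#' @param seed Integer seed for all per-frame randomness.
#' @param base_geometry `"helix"` (ideal alpha-helix Calpha trace: rise
#'   1.5 A, 100 degree turn, radius 2.3 A) or `"compact_walk"`
#'   (fixed 3.8 A bond random walk with hard-sphere rejection at 4.0 A,
#'   giving a compact globule with realistic contact density at the 6.7 A
#'   cutoff).
#' @param geometry_seed Seed for the (shared) base geometry, separate from
#'   `seed` so variant pairs with different noise seeds share a topology.
#' @param fluctuation_sigma Per-residue jitter standard deviation per axis
#'   (A); scalar recycled, or length `n_residues`.
#' @param motion_factors List of [motion_factor()] objects inducing
#'   correlated / anti-correlated group motion.
#' @param rigid_body `"none"` or `"random"` (an independent uniform
#'   rototranslation per frame; removed by best-fit superposition).
#' @param two_state Optional [two_state_config()].
#' @param glycine_positions Residue numbers modelled as glycine (Calpha
#'   only, no Cbeta).
#' @param base_displacement Optional permanent perturbation of the base
#'   geometry: a list with `residues` (residue numbers) and `offset` (A),
#'   displacing those residues along their side-chain direction in every
#'   frame (the "displaced loop" variant archetype).
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_residues = 268L,
                             first_residue_number = 23L,
                             n_frames = 2000L,
                             timestep_ps = 100,
                             seed = 1L,
                             base_geometry = c("helix", "compact_walk"),
                             geometry_seed = 73L,
                             fluctuation_sigma = 0.5,
                             motion_factors = list(),
                             rigid_body = c("none", "random"),
                             two_state = NULL,
                             glycine_positions = c(26, 30, 34, 86, 126, 151,
                                                   162, 178, 265, 268, 271),
                             base_displacement = NULL) {
  base_geometry <- match.arg(base_geometry)
  rigid_body <- match.arg(rigid_body)
  if (length(fluctuation_sigma) == 1L) {
    fluctuation_sigma <- rep(fluctuation_sigma, n_residues)
  }
  if (length(fluctuation_sigma) != n_residues) {
    stop("fluctuation_sigma must be scalar or length n_residues")
  }
  if (!all(is.finite(fluctuation_sigma)) || any(fluctuation_sigma < 0)) {
    stop("fluctuation_sigma must be finite and >= 0")
  }
  for (f in motion_factors) {
    if (!inherits(f, "motion_factor")) stop("motion_factors must be motion_factor objects")
    if (length(f$loading) != n_residues) stop("factor loading length != n_residues")
  }
  if (!is.null(two_state) && !inherits(two_state, "two_state_config")) {
    stop("two_state must come from two_state_config()")
  }
  last <- first_residue_number + n_residues - 1L
  glycine_positions <- as.integer(
    glycine_positions[glycine_positions >= first_residue_number &
                        glycine_positions <= last])
  structure(
    list(n_residues = as.integer(n_residues),
         first_residue_number = as.integer(first_residue_number),
         n_frames = as.integer(n_frames), timestep_ps = timestep_ps,
         seed = as.integer(seed), base_geometry = base_geometry,
         geometry_seed = as.integer(geometry_seed),
         fluctuation_sigma = as.numeric(fluctuation_sigma),
         motion_factors = motion_factors, rigid_body = rigid_body,
         two_state = two_state, glycine_positions = glycine_positions,
         base_displacement = base_displacement),
    class = "generator_config"
  )
}

#' Correlated-motion factor
#'
#' A latent isotropic standard-normal 3-vector per frame, shared by all
#' residues, scaled by a signed per-residue loading: residue i is displaced
#' by `loading[i] * z(t)`. Same-sign loadings move together (correlated),
#' opposite signs in anti-phase. For two residues sharing one factor with
#' loading a over jitter sigma, the expected pairwise cross-correlation is
#' `a^2 / (a^2 + sigma^2)` (negated for opposite signs).
#'
#' @param loading Signed per-residue loading (A); length must equal the
#'   configuration's `n_residues`.
#' @return A `motion_factor`.
#' @export
motion_factor <- function(loading) {
  stopifnot(is.numeric(loading), all(is.finite(loading)))
  structure(list(loading = as.numeric(loading)), class = "motion_factor")
}

#' Two-state switching configuration
#'
#' The second conformational state is the base geometry with a contiguous
#' residue block displaced along each residue's deterministic side-chain
#' direction (a whole-body shift would vanish under best-fit
#' superposition). The state flips between frames with symmetric
#' probability `p`, giving a bimodal best-fit RMSD distribution.
#'
#' @param residues Residue numbers displaced in the second state.
#' @param offset Displacement magnitude (A).
#' @param p Per-frame switching probability, in (0, 1).
#' @return A `two_state_config`.
#' @export
two_state_config <- function(residues, offset = 3.0, p = 0.05) {
  stopifnot(length(residues) >= 1, offset > 0, p > 0, p < 1)
  structure(list(residues = as.integer(residues), offset = offset, p = p),
            class = "two_state_config")
}

# Ideal alpha-helix Calpha trace: rise 1.5 A/residue, 100 deg/residue,
# radius 2.3 A. Side-chain direction points radially out from the axis.
helix_geometry <- function(n) {
  i <- seq_len(n) - 1
  th <- i * 100 * pi / 180
  ca <- cbind(2.3 * cos(th), 2.3 * sin(th), 1.5 * i)
  dir <- cbind(cos(th), sin(th), 0)
  list(ca = ca, dir = dir)
}

# Fixed-bond-length (3.8 A) random walk with hard-sphere rejection at
# 4.0 A against all previous residues. Side-chain direction from the local
# bisector: away from the midpoint of the two chain neighbours.
walk_geometry <- function(n, geometry_seed) {
  ca <- matrix(0, n, 3)
  old <- save_rng()
  on.exit(restore_rng(old))
  set.seed(geometry_seed)
  for (i in seq_len(n)[-1]) {
    placed <- FALSE
    for (try in 1:500) {
      v <- stats::rnorm(3)
      v <- v / sqrt(sum(v^2))
      cand <- ca[i - 1, ] + 3.8 * v
      prev <- ca[seq_len(i - 2), , drop = FALSE]
      d2 <- rowSums(sweep(prev, 2, cand)^2)
      if (all(d2 >= 4.0^2)) {
        ca[i, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("compact walk failed to place residue ", i)
  }
  dir <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    lo <- max(i - 1, 1)
    hi <- min(i + 1, n)
    mid <- (ca[lo, ] + ca[hi, ]) / 2
    v <- ca[i, ] - mid
    nv <- sqrt(sum(v^2))
    if (nv < 1e-8) {
      # collinear neighbours: any perpendicular to the chain direction
      b <- ca[hi, ] - ca[lo, ]
      v <- c(-b[2], b[1], 0)
      if (sum(v^2) < 1e-12) v <- c(1, 0, 0)
      nv <- sqrt(sum(v^2))
    }
    dir[i, ] <- v / nv
  }
  list(ca = ca, dir = dir)
}

save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Uniform random rotation matrix (from a normalized quaternion).
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# Base Calpha/Cbeta geometry + atom topology for a config.
base_structure <- function(config) {
  geom <- switch(config$base_geometry,
                 helix = helix_geometry(config$n_residues),
                 compact_walk = walk_geometry(config$n_residues,
                                              config$geometry_seed))
  resno <- config$first_residue_number + seq_len(config$n_residues) - 1L
  is_gly <- resno %in% config$glycine_positions
  resname <- ifelse(is_gly, "GLY", "ALA")
  cb <- geom$ca + 1.53 * geom$dir
  atom_res <- rep(seq_len(config$n_residues), ifelse(is_gly, 1L, 2L))
  atom_name <- unlist(lapply(seq_len(config$n_residues), function(i) {
    if (is_gly[i]) "CA" else c("CA", "CB")
  }))
  coords <- matrix(NA_real_, length(atom_res), 3)
  coords[atom_name == "CA", ] <- geom$ca
  coords[atom_name == "CB", ] <- cb[!is_gly, , drop = FALSE]
  atoms <- data.frame(
    atom_name = atom_name,
    residue_name = resname[atom_res],
    residue_number = resno[atom_res],
    chain_id = "A",
    stringsAsFactors = FALSE
  )
  list(atoms = atoms, coords = coords, atom_res = atom_res,
       resno = resno, dir = geom$dir)
}

#' Generate a synthetic trajectory
#'
#' Frame t is `R_t(base_state(t) + sum_k loading_k * z_k(t) + eps(t)) + b_t`
#' where `z_k(t)` are i.i.d. standard-normal 3-vectors (one per factor per
#' frame), `eps_i(t)` is isotropic Gaussian jitter with per-residue sigma
#' per axis, and `(R_t, b_t)` is the optional rigid-body rototranslation.
#' A residue's displacement is applied to its Calpha and Cbeta alike; the
#' Cbeta sits at a fixed 1.53 A offset from the Calpha along a
#' deterministic local direction (absent for glycines). Identical
#' configurations (including seed) give bit-identical trajectories.
#'
#' @param config A [generator_config()].
#' @param label Label stored on the trajectory.
#' @return A [trajectory()].
#' @export
generate_trajectory <- function(config, label = "synthetic") {
  stopifnot(inherits(config, "generator_config"))
  bs <- base_structure(config)
  if (!is.null(config$base_displacement)) {
    # permanent base-geometry displacement (variant perturbation)
    bd <- config$base_displacement
    sel <- bs$resno %in% bd$residues
    if (!any(sel)) stop("base_displacement residues outside the chain")
    move <- sel[bs$atom_res]
    bs$coords[move, ] <- bs$coords[move, ] +
      bd$offset * bs$dir[bs$atom_res[move], , drop = FALSE]
  }
  nf <- config$n_frames
  nr <- config$n_residues
  na <- nrow(bs$atoms)

  old <- save_rng()
  on.exit(restore_rng(old))
  set.seed(config$seed)

  # state path (two-state switching), then factor latents, then jitter,
  # then rigid-body draws -- fixed order for reproducibility
  state <- rep(1L, nf)
  if (!is.null(config$two_state)) {
    flips <- stats::runif(nf - 1) < config$two_state$p
    state <- 1L + (cumsum(c(FALSE, flips)) %% 2L)
  }
  latents <- lapply(config$motion_factors, function(f) {
    matrix(stats::rnorm(nf * 3), nf, 3)
  })
  eps <- array(stats::rnorm(nf * nr * 3), dim = c(nf, nr, 3)) *
    array(rep(config$fluctuation_sigma, each = nf), dim = c(nf, nr, 3))
  rots <- NULL
  trans <- NULL
  if (config$rigid_body == "random") {
    rots <- lapply(seq_len(nf), function(t) random_rotation())
    trans <- matrix(stats::runif(nf * 3, -10, 10), nf, 3)
  }

  state2 <- bs$coords
  if (!is.null(config$two_state)) {
    sel <- bs$resno %in% config$two_state$residues
    if (!any(sel)) stop("two_state residues outside the chain")
    move <- sel[bs$atom_res]
    state2[move, ] <- state2[move, ] +
      config$two_state$offset * bs$dir[bs$atom_res[move], , drop = FALSE]
  }

  xyz <- array(NA_real_, dim = c(nf, na, 3))
  for (t in seq_len(nf)) {
    disp <- eps[t, , ]                       # n_residues x 3
    for (k in seq_along(latents)) {
      disp <- disp + outer(config$motion_factors[[k]]$loading, latents[[k]][t, ])
    }
    base <- if (state[t] == 1L) bs$coords else state2
    fr <- base + disp[bs$atom_res, , drop = FALSE]
    if (!is.null(rots)) {
      fr <- fr %*% t(rots[[t]]) +
        matrix(trans[t, ], na, 3, byrow = TRUE)
    }
    xyz[t, , ] <- fr
  }
  trajectory(bs$atoms, xyz, label = label, timestep_ps = config$timestep_ps)
}

#' Generate a matched wild-type / variant trajectory pair
#'
#' Produces two trajectories sharing a topology and base geometry but
#' differing by a prescribed perturbation, emulating a WT-versus-variant
#' comparison. The wild type uses `config$seed`; the variant uses
#' `config$seed + 1`, so the two are independent replicates apart from the
#' perturbation.
#'
#' @param config A [generator_config()] describing the wild type.
#' @param perturbation `NULL` for a null pair, or a list with `residues`
#'   (residue numbers) plus one of:
#'   * `type = "sigma_scale"`, `value` = multiplier applied to those
#'     residues' jitter sigma;
#'   * `type = "loading_flip"`, `value` = index of the factor whose loading
#'     signs flip on those residues;
#'   * `type = "displace"`, `value` = base-geometry displacement (A) of
#'     those residues along their side-chain direction.
#' @param labels Length-2 character vector of labels.
#' @return A list with elements `wt` and `variant`, both [trajectory()]s.
#' @export
make_variant_pair <- function(config, perturbation = NULL,
                              labels = c("WT", "variant")) {
  stopifnot(inherits(config, "generator_config"))
  vcfg <- config
  vcfg$seed <- config$seed + 1L
  if (!is.null(perturbation)) {
    resno <- config$first_residue_number + seq_len(config$n_residues) - 1L
    idx <- match(perturbation$residues, resno)
    if (anyNA(idx)) {
      stop("perturbation residues outside the chain: ",
           paste(perturbation$residues[is.na(idx)], collapse = ", "))
    }
    vcfg <- switch(
      perturbation$type,
      sigma_scale = {
        vcfg$fluctuation_sigma[idx] <-
          vcfg$fluctuation_sigma[idx] * perturbation$value
        vcfg
      },
      loading_flip = {
        k <- perturbation$value
        stopifnot(k >= 1, k <= length(vcfg$motion_factors))
        f <- vcfg$motion_factors[[k]]
        f$loading[idx] <- -f$loading[idx]
        vcfg$motion_factors[[k]] <- f
        vcfg
      },
      displace = {
        vcfg$base_displacement <- list(residues = perturbation$residues,
                                       offset = perturbation$value)
        vcfg
      },
      stop("unknown perturbation type: ", perturbation$type)
    )
  }
  wt <- generate_trajectory(config, label = labels[1])
  variant <- generate_trajectory(vcfg, label = labels[2])
  list(wt = wt, variant = variant)
}
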