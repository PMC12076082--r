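# Synthetic two-phase slab configurations and exact binodal points.
# These generators supply ground-truth-known inputs for the slab analysis
# pipeline: a dense central slab plus dilute surroundings whose binned
# density profile matches requested coexisting densities, and noiseless
# (T, rho_l, rho_h) points solving the coexistence laws exactly.

#' Parameters for the synthetic slab generator
#'
#' Molecules are rendered as compact bead clouds: flexible segments as
#' isotropic Gaussian clouds around the molecule centre, rigid segments
#' (TPR repeats, solvating helix) as straight rods with 3.8 A bead spacing
#' in a random orientation. This reproduces the positional/density structure
#' the downstream analyses consume without simulating dynamics.
#'
#' The slab half-width is derived from the mass balance
#' `V_slab = (M_total - rho_l V) / (rho_h - rho_l)` so that the requested
#' densities are achievable with exactly `n_molecules` molecules; an explicit
#' `slab_halfwidth` is checked against it.
#'
#' @param box Box lengths (x, y, z) in Angstrom, z elongated.
#' @param rho_h,rho_l Dense- and dilute-phase mass densities (mg/mL),
#'   `rho_h > rho_l >= 0` (equal densities give a uniform one-phase box).
#' @param n_molecules Number of molecules (default 140, the direct-coexistence
#'   system size this generator emulates).
#' @param construct Optional `construct_spec`; provides bead count, per-bead
#'   masses and rigid blocks. Otherwise give `beads_per_molecule`.
#' @param beads_per_molecule Bead count per molecule when no construct is
#'   given (all beads flexible, 110 Da each).
#' @param slab_halfwidth Optional half-width (Angstrom) of the dense slab;
#'   must agree with the mass-balance value within 5%.
#' @param n_frames Number of frames (independent configurations).
#' @param temperature Temperature label (K) carried by the trajectory.
#' @param bead_sd Gaussian spread of flexible beads about the molecule
#'   centre (Angstrom).
#' @param seed RNG seed; the generator is a pure function of its parameters.
#' @return A `slab_gen_params` list.
#' @export
slab_gen_params <- function(box, rho_h, rho_l, n_molecules = 140L,
                            construct = NULL, beads_per_molecule = NULL,
                            slab_halfwidth = NULL, n_frames = 10L,
                            temperature = 300, bead_sd = 8, seed = 1L) {
  stopifnot(length(box) == 3L, all(box > 0), n_molecules > 0,
            rho_h >= rho_l, rho_l >= 0, n_frames >= 1L, bead_sd > 0)
  if (!is.null(construct)) {
    stopifnot(inherits(construct, "construct_spec"))
    mass <- residue_masses(construct$sequence)
    rigid <- rigid_flags(construct)
    seg_id <- integer(construct$length)
    for (k in seq_along(construct$segments)) {
      s <- construct$segments[[k]]
      seg_id[s$start:s$end] <- k
    }
  } else {
    stopifnot(!is.null(beads_per_molecule), beads_per_molecule >= 1L)
    mass <- rep(110, beads_per_molecule)
    rigid <- rep(FALSE, beads_per_molecule)
    seg_id <- rep(1L, beads_per_molecule)
  }
  structure(
    list(box = as.numeric(box), rho_h = rho_h, rho_l = rho_l,
         n_molecules = as.integer(n_molecules), bead_mass = mass,
         bead_rigid = rigid, bead_segment = seg_id,
         slab_halfwidth = slab_halfwidth, n_frames = as.integer(n_frames),
         temperature = temperature, bead_sd = bead_sd, seed = seed),
    class = "slab_gen_params"
  )
}

# Mass-balance slab geometry: half-width and molecule split for the
# requested densities. Errors if the box/molecule budget cannot realise them.
.slab_geometry <- function(p) {
  M_mol <- sum(p$bead_mass)
  M_tot <- p$n_molecules * M_mol
  V <- prod(p$box)
  rho_mean <- M_tot / V * .DA_PER_A3_IN_MG_ML
  if (p$rho_h == p$rho_l) {
    return(list(uniform = TRUE, halfwidth = NA_real_,
                n_dense = p$n_molecules, n_dilute = 0L,
                rho_mean = rho_mean))
  }
  rh <- p$rho_h / .DA_PER_A3_IN_MG_ML
  rl <- p$rho_l / .DA_PER_A3_IN_MG_ML
  Vs <- (M_tot - rl * V) / (rh - rl)
  if (Vs <= 0 || Vs >= V) {
    stop(sprintf(paste0(
      "requested densities unachievable with %d molecules in this box: ",
      "overall density is %.3g mg/mL and must lie strictly between rho_l ",
      "and rho_h; maximum achievable density is %.3g mg/mL"),
      p$n_molecules, rho_mean, rho_mean))
  }
  w <- Vs / (2 * p$box[1L] * p$box[2L])
  if (!is.null(p$slab_halfwidth) &&
      abs(p$slab_halfwidth - w) > 0.05 * w) {
    stop(sprintf(paste0(
      "slab_halfwidth %.4g A inconsistent with the requested densities ",
      "(mass balance requires %.4g A)"), p$slab_halfwidth, w))
  }
  if (p$box[3L] <= 3 * (2 * w)) {
    stop(sprintf(
      "box z (%.4g A) must exceed 3x the slab width (slab width %.4g A)",
      p$box[3L], 2 * w))
  }
  n_dense <- as.integer(round(rh * Vs / M_mol))
  n_dense <- max(1L, min(p$n_molecules, n_dense))
  list(uniform = FALSE, halfwidth = w, n_dense = n_dense,
       n_dilute = p$n_molecules - n_dense, rho_mean = rho_mean)
}

#' Generate a synthetic two-phase slab trajectory
#'
#' Partitions molecules between a central dense slab and the surrounding
#' dilute region so that the binned mass-density profile plateaus at the
#' requested `rho_h` (inside) and `rho_l` (outside), with periodic
#' boundaries and a deterministic RNG stream. Frames are independent
#' configurations of the same molecules (molecule count and total bead mass
#' are conserved across frames).
#'
#' @param params A [slab_gen_params()] object.
#' @return A [slab_trajectory()].
#' @export
#' @examples
#' p <- slab_gen_params(box = c(100, 100, 600), rho_h = 300, rho_l = 10,
#'                      n_molecules = 60, beads_per_molecule = 20,
#'                      n_frames = 2, seed = 7)
#' traj <- gen_slab_trajectory(p)
gen_slab_trajectory <- function(params) {
  stopifnot(inherits(params, "slab_gen_params"))
  geo <- .slab_geometry(params)
  nb <- length(params$bead_mass)
  N <- params$n_molecules
  box <- params$box
  zc <- box[3L] / 2
  with_seed(params$seed, {
    frames <- vector("list", params$n_frames)
    for (f in seq_len(params$n_frames)) {
      if (geo$uniform) {
        cz <- stats::runif(N, 0, box[3L])
      } else {
        w <- geo$halfwidth
        cz <- numeric(N)
        cz[seq_len(geo$n_dense)] <- stats::runif(geo$n_dense, zc - w, zc + w)
        if (geo$n_dilute > 0L) {
          u <- stats::runif(geo$n_dilute, 0, box[3L] - 2 * w)
          cz[geo$n_dense + seq_len(geo$n_dilute)] <- (zc + w + u) %% box[3L]
        }
      }
      cx <- stats::runif(N, 0, box[1L])
      cy <- stats::runif(N, 0, box[2L])
      xyz <- matrix(0, nrow = N * nb, ncol = 3L)
      for (m in seq_len(N)) {
        off <- .molecule_offsets(params)
        idx <- (m - 1L) * nb + seq_len(nb)
        xyz[idx, 1L] <- cx[m] + off[, 1L]
        xyz[idx, 2L] <- cy[m] + off[, 2L]
        xyz[idx, 3L] <- cz[m] + off[, 3L]
      }
      frames[[f]] <- wrap_coords(xyz, box)
    }
    slab_trajectory(
      frames = frames,
      mol = rep(seq_len(N), each = nb),
      mass = rep(params$bead_mass, times = N),
      box = box, temperature = params$temperature
    )
  })
}

# Bead offsets of one molecule about its centre: Gaussian clouds for
# flexible segments, randomly oriented straight rods (3.8 A spacing) for
# rigid ones, each anchored near the centre.
.molecule_offsets <- function(params) {
  nb <- length(params$bead_mass)
  off <- matrix(0, nrow = nb, ncol = 3L)
  sd <- params$bead_sd
  for (k in unique(params$bead_segment)) {
    idx <- which(params$bead_segment == k)
    if (params$bead_rigid[idx[1L]]) {
      u <- stats::rnorm(3L)
      u <- u / sqrt(sum(u^2))
      t <- (seq_along(idx) - (length(idx) + 1) / 2) * 3.8
      anchor <- stats::rnorm(3L, 0, sd)
      off[idx, ] <- outer(t, u) +
        matrix(anchor, nrow = length(idx), ncol = 3L, byrow = TRUE)
    } else {
      off[idx, ] <- matrix(stats::rnorm(3L * length(idx), 0, sd), ncol = 3L)
    }
  }
  off
}

#' Exact coexistence points from the coexistence laws
#'
#' Generates noiseless binodal points at the given temperatures by solving
#' simultaneously the law of coexisting densities,
#' `(rho_h - rho_l)^nu = d (1 - T/T_c)` with `nu = 3.06` (the Ising critical
#' exponent), and the law of rectilinear diameters,
#' `rho_h + rho_l = 2 rho_c + 2 A (T - T_c)`.
#'
#' @param tc Critical temperature (K).
#' @param rho_c Critical density (mg/mL).
#' @param d Amplitude parameter of the coexisting-density law.
#' @param A Slope parameter of the rectilinear-diameter law (mg/mL/K).
#' @param temperatures Temperatures (K), all strictly below `tc`.
#' @param exponent Critical exponent (default 3.06).
#' @return A data.frame (class `coexistence_points`) with columns `T`,
#'   `rho_l`, `rho_h`.
#' @export
#' @examples
#' pts <- gen_binodal_points(350, 0.3, 1, 0, temperatures = c(315, 330, 345))
gen_binodal_points <- function(tc, rho_c, d, A, temperatures,
                               exponent = 3.06) {
  stopifnot(tc > 0, d > 0, length(temperatures) >= 1L)
  if (any(temperatures >= tc)) {
    stop("all temperatures must be strictly below tc")
  }
  diff <- (d * (1 - temperatures / tc))^(1 / exponent)
  sum_ <- 2 * rho_c + 2 * A * (temperatures - tc)
  rho_l <- (sum_ - diff) / 2
  rho_h <- (sum_ + diff) / 2
  if (any(rho_l < 0)) {
    stop("parameters give negative dilute-phase density at the lowest ",
         "temperature; reduce d or the temperature span")
  }
  structure(
    data.frame(T = temperatures, rho_l = rho_l, rho_h = rho_h),
    class = c("coexistence_points", "data.frame")
  )
}
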