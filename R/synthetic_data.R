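# ---------------------------------------------------------------------------
# Synthetic systems with known ground truth.
#
# Every generator is a pure function of (parameters, seed): the RNG state of
# the calling session is saved and restored, so identical inputs always give
# bit-identical outputs.  The schedules are kinematic (no force field): they
# prescribe exactly the geometric observable the analysis stage is supposed
# to recover, which is what makes them usable as oracles.
# ---------------------------------------------------------------------------

with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Von Mises random angles
#'
#' Best-Fisher rejection sampler.  Used for all angular noise so that
#' noisy dihedrals stay on the circle (a Gaussian in angle space would
#' leak across the +/-180 wrap).
#'
#' @param n Number of draws.
#' @param mu_deg Mean direction, degrees.
#' @param kappa Concentration (>= 0); `Inf` returns `mu_deg` exactly.
#' @return Angles in degrees in (-180, 180].
#' @export
rvonmises <- function(n, mu_deg = 0, kappa = 1) {
  if (!is.finite(kappa)) return(rep(wrap_angle(mu_deg), n))
  if (kappa < 1e-10) {
    return(wrap_angle(stats::runif(n, -180, 180) + mu_deg))
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
        out[i] <- sign(u[3] - 0.5) * acos(pmin(1, pmax(-1, f)))
        break
      }
    }
  }
  wrap_angle(mu_deg + out * 180 / pi)
}

# -- chain building --------------------------------------------------------

# Internal-coordinate constants for the polyalanine builder (Angstrom /
# degrees).  Self-consistent textbook geometry, recorded in one place.
backbone_geometry <- list(
  bond_n_ca = 1.46, bond_ca_c = 1.52, bond_c_n = 1.33,
  bond_c_o = 1.23, bond_ca_cb = 1.53,
  angle_n_ca_c = 111, angle_ca_c_n = 117, angle_c_n_ca = 121,
  angle_ca_c_o = 121, angle_n_ca_cb = 110.5,
  torsion_omega = 180, torsion_cb_improper = 122.5
)

#' Build an ideal polyalanine chain
#'
#' Sequential internal-coordinate (NeRF) placement of an N/CA/C/O/CB
#' backbone with fixed standard bond lengths and angles, omega = 180, and
#' uniform (phi, psi).  At the canonical alpha-helical pair
#' (phi = -57, psi = -47) consecutive CA-CA distances are ~3.8 A and the
#' rise per residue ~1.5 A.
#'
#' @param n_residues Number of residues (>= 5).
#' @param phi,psi Backbone torsions, degrees.
#' @param chain_id Chain identifier for the topology.
#' @param resno_start First residue number.
#' @return List with `topology` and `frame` (n x 3 coordinate matrix).
#' @export
build_ideal_helix <- function(n_residues, phi = -57, psi = -47,
                              chain_id = "A", resno_start = 1L) {
  if (n_residues < 5) stop("n_residues must be >= 5")
  g <- backbone_geometry
  n_xyz <- ca_xyz <- c_xyz <- vector("list", n_residues)
  n_xyz[[1]] <- c(0, 0, 0)
  ca_xyz[[1]] <- c(g$bond_n_ca, 0, 0)
  th <- (180 - g$angle_n_ca_c) * pi / 180
  c_xyz[[1]] <- ca_xyz[[1]] + g$bond_ca_c * c(cos(th), sin(th), 0)
  for (i in seq_len(n_residues)[-1]) {
    n_xyz[[i]] <- place_atom(n_xyz[[i - 1]], ca_xyz[[i - 1]], c_xyz[[i - 1]],
                             g$bond_c_n, g$angle_ca_c_n, psi)
    ca_xyz[[i]] <- place_atom(ca_xyz[[i - 1]], c_xyz[[i - 1]], n_xyz[[i]],
                              g$bond_n_ca, g$angle_c_n_ca, g$torsion_omega)
    c_xyz[[i]] <- place_atom(c_xyz[[i - 1]], n_xyz[[i]], ca_xyz[[i]],
                             g$bond_ca_c, g$angle_n_ca_c, phi)
  }
  rows <- list()
  coords <- list()
  for (i in seq_len(n_residues)) {
    o_xyz <- place_atom(n_xyz[[i]], ca_xyz[[i]], c_xyz[[i]],
                        g$bond_c_o, g$angle_ca_c_o, wrap_angle(psi + 180))
    cb_xyz <- place_atom(c_xyz[[i]], n_xyz[[i]], ca_xyz[[i]],
                         g$bond_ca_cb, g$angle_n_ca_cb,
                         g$torsion_cb_improper)
    nm <- c("N", "CA", "C", "O", "CB")
    el <- c("N", "C", "C", "O", "C")
    for (k in seq_along(nm)) {
      rows[[length(rows) + 1L]] <- data.frame(
        atom_name = nm[k], element = el[k], residue_name = "ALA",
        residue_number = resno_start + i - 1L, chain_id = chain_id,
        stringsAsFactors = FALSE
      )
    }
    coords[[length(coords) + 1L]] <-
      rbind(n_xyz[[i]], ca_xyz[[i]], c_xyz[[i]], o_xyz, cb_xyz)
  }
  atoms <- do.call(rbind, rows)
  atoms$vdw_radius <- lookup_vdw_radius(atoms$element, atoms$atom_name)
  list(topology = topology(atoms), frame = do.call(rbind, coords))
}

# -- portal trajectory ------------------------------------------------------

#' Aperture schedule for the synthetic portal
#'
#' Prescribes the per-frame target separation between the axes of the two
#' flanking helices, plus isotropic Gaussian coordinate noise.
#'
#' @param d Numeric vector: target inter-helix separation per frame (A, > 0).
#' @param noise_sigma Per-atom Gaussian coordinate noise, A.
#' @param seed RNG seed.
#' @return Object of class `"aperture_schedule"`.
#' @export
aperture_schedule <- function(d, noise_sigma = 0, seed = 1L) {
  if (any(d <= 0)) stop("all target separations must be positive")
  structure(list(d = as.numeric(d), noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "aperture_schedule")
}

# Rotate coordinates so the principal axis of `axis_coords` maps onto z.
align_axis_to_z <- function(coords, axis_coords) {
  ctr <- colMeans(axis_coords)
  x <- sweep(axis_coords, 2, ctr)
  v <- svd(x)$v[, 1]
  z <- c(0, 0, 1)
  axis <- cross3(v, z)
  s <- vnorm(axis)
  if (s < 1e-12) {
    rot <- diag(3) * sign(sum(v * z))
    if (det(rot) < 0) rot <- diag(c(1, -1, sign(sum(v * z))))
  } else {
    axis <- axis / s
    ang <- atan2(s, sum(v * z))
    kx <- matrix(c(0, -axis[3], axis[2],
                   axis[3], 0, -axis[1],
                   -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
    rot <- diag(3) + sin(ang) * kx + (1 - cos(ang)) * (kx %*% kx)
  }
  sweep(coords, 2, ctr) %*% t(rot)
}

#' Build a two-helix portal trajectory
#'
#' Two parallel ideal alpha-helices (chains A and B) whose axes run along
#' z; frame t places them at x = -d(t)/2 and +d(t)/2 and adds per-atom
#' Gaussian noise.  Deterministic under the schedule's seed.
#'
#' @param n_per_helix Residues per helix.
#' @param schedule An [aperture_schedule()].
#' @param n_frames Must equal the schedule length.
#' @param time_per_frame ns per frame.
#' @return A [trajectory()] with chains A and B.
#' @export
build_portal_trajectory <- function(n_per_helix, schedule,
                                    n_frames = length(schedule$d),
                                    time_per_frame = 0.04) {
  stopifnot(inherits(schedule, "aperture_schedule"))
  if (n_frames != length(schedule$d)) {
    stop("n_frames must equal the schedule length")
  }
  hx <- build_ideal_helix(n_per_helix, chain_id = "A")
  ca_idx <- which(hx$topology$atoms$atom_name == "CA")
  base <- align_axis_to_z(hx$frame, hx$frame[ca_idx, , drop = FALSE])
  atoms_a <- hx$topology$atoms
  atoms_b <- atoms_a
  atoms_b$chain_id <- "B"
  atoms <- rbind(atoms_a, atoms_b)
  atoms$atom_index <- NULL
  top <- topology(atoms)
  nat <- nrow(base)
  coords <- array(NA_real_, dim = c(2 * nat, 3, n_frames))
  with_seed(schedule$seed, {
    for (t in seq_len(n_frames)) {
      off <- schedule$d[t] / 2
      fa <- sweep(base, 2, c(-off, 0, 0), "+")
      fb <- sweep(base, 2, c(+off, 0, 0), "+")
      fr <- rbind(fa, fb)
      if (schedule$noise_sigma > 0) {
        fr <- fr + matrix(stats::rnorm(length(fr), sd = schedule$noise_sigma),
                          nrow = nrow(fr))
      }
      coords[, , t] <- fr
    }
  })
  trajectory(top, coords, time_per_frame = time_per_frame)
}

#' Measured inter-helix separation of a portal trajectory
#'
#' Distance between the CA centroids of chains A and B, per frame; the
#' observable the aperture schedule prescribes.
#'
#' @param traj A two-chain portal trajectory.
#' @return Numeric vector, one separation (A) per frame.
#' @export
portal_separation <- function(traj) {
  a <- traj$topology$atoms
  ia <- which(a$chain_id == "A" & a$atom_name == "CA")
  ib <- which(a$chain_id == "B" & a$atom_name == "CA")
  if (!length(ia) || !length(ib)) stop("trajectory lacks chain A/B CA atoms")
  vapply(seq_len(n_frames(traj)), function(t) {
    fr <- get_frame(traj, t)
    vnorm(colMeans(fr[ib, , drop = FALSE]) - colMeans(fr[ia, , drop = FALSE]))
  }, numeric(1))
}

# -- rotamer trajectory -----------------------------------------------------

#' Chi1 rotamer schedule
#'
#' @param chi1 Per-frame target chi1, degrees in (-180, 180].
#' @param kappa Von Mises concentration of the angular noise
#'   (`Inf` = noiseless).
#' @param seed RNG seed.
#' @return Object of class `"rotamer_schedule"`.
#' @export
rotamer_schedule <- function(chi1, kappa = Inf, seed = 1L) {
  chi1 <- as.numeric(chi1)
  if (any(chi1 <= -180 | chi1 > 180)) {
    stop("chi1 targets must lie in (-180, 180]")
  }
  structure(list(chi1 = chi1, kappa = kappa, seed = as.integer(seed)),
            class = "rotamer_schedule")
}

#' Build a single-side-chain rotamer trajectory
#'
#' A rigid tryptophan-like fragment (N, CA, C, O, CB fixed) whose CG is
#' re-placed each frame so that the measured chi1 torsion
#' (N-CA-CB-CG) equals the scheduled target plus von Mises noise.
#'
#' @param schedule A [rotamer_schedule()].
#' @param n_frames Must equal the schedule length.
#' @param residue_number Residue number of the fragment (default 140).
#' @param time_per_frame ns per frame.
#' @return A [trajectory()] with one TRP residue on chain A.
#' @export
build_rotamer_trajectory <- function(schedule,
                                     n_frames = length(schedule$chi1),
                                     residue_number = 140L,
                                     time_per_frame = 0.04) {
  stopifnot(inherits(schedule, "rotamer_schedule"))
  if (n_frames != length(schedule$chi1)) {
    stop("n_frames must equal the schedule length")
  }
  g <- backbone_geometry
  ca <- c(0, 0, 0)
  n <- c(g$bond_n_ca, 0, 0)
  thb <- g$angle_n_ca_cb * pi / 180
  cb <- g$bond_ca_cb * c(cos(thb), sin(thb), 0)
  cc <- place_atom(cb, n, ca, g$bond_ca_c, g$angle_n_ca_c, -120)
  oo <- place_atom(n, ca, cc, g$bond_c_o, g$angle_ca_c_o, 0)
  atoms <- data.frame(
    atom_name = c("N", "CA", "C", "O", "CB", "CG"),
    element = c("N", "C", "C", "O", "C", "C"),
    residue_name = "TRP",
    residue_number = as.integer(residue_number),
    chain_id = "A",
    stringsAsFactors = FALSE
  )
  atoms$vdw_radius <- lookup_vdw_radius(atoms$element, atoms$atom_name)
  top <- topology(atoms)
  coords <- array(NA_real_, dim = c(6, 3, n_frames))
  with_seed(schedule$seed, {
    chi <- if (is.finite(schedule$kappa)) {
      wrap_angle(schedule$chi1 +
                   rvonmises(n_frames, 0, schedule$kappa))
    } else {
      schedule$chi1
    }
    for (t in seq_len(n_frames)) {
      cg <- place_atom(n, ca, cb, 1.52, 114, chi[t])
      coords[, , t] <- rbind(n, ca, cc, oo, cb, cg)
    }
  })
  trajectory(top, coords, time_per_frame = time_per_frame)
}

# -- pKa tables -------------------------------------------------------------

#' Generate multi-method pKa prediction tables with controlled agreement
#'
#' Emulates running several pKa predictors over the same protein: each
#' method reports the true value plus method noise; with probability
#' `outlier_prob` a prediction is displaced by at least one pKa unit, which
#' the consensus rule must reject.
#'
#' @param true_values data.frame with columns `chain_id`, `residue_number`,
#'   `residue_name`, `pka` (the ground truth).
#' @param method_noise Named numeric vector of per-method Gaussian sigmas
#'   (names become the method labels; >= 2 methods required).
#' @param outlier_prob Probability that any single prediction is an outlier.
#' @param seed RNG seed.
#' @return data.frame with columns `chain_id`, `residue_number`,
#'   `residue_name`, `method`, `pka` (long format, one row per
#'   residue-method pair).
#' @export
build_pka_tables <- function(true_values,
                             method_noise = c(propka = 0.02, hpp = 0.02,
                                              rosetta = 0.02),
                             outlier_prob = 0, seed = 1L) {
  if (length(method_noise) < 2) stop("need at least 2 methods")
  stopifnot(all(c("chain_id", "residue_number", "residue_name", "pka")
                %in% names(true_values)))
  with_seed(seed, {
    out <- list()
    for (m in names(method_noise)) {
      v <- true_values$pka + stats::rnorm(nrow(true_values),
                                          sd = method_noise[[m]])
      is_out <- stats::runif(nrow(true_values)) < outlier_prob
      if (any(is_out)) {
        shift <- (1 + stats::runif(sum(is_out))) *
          sample(c(-1, 1), sum(is_out), replace = TRUE)
        v[is_out] <- v[is_out] + shift
      }
      out[[m]] <- data.frame(
        chain_id = true_values$chain_id,
        residue_number = true_values$residue_number,
        residue_name = true_values$residue_name,
        method = m, pka = v, stringsAsFactors = FALSE
      )
    }
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  })
}

# -- analytic fixtures ------------------------------------------------------

#' Build a literal-coordinate fixture system
#'
#' One atom per row, each its own residue, placed exactly at the given
#' coordinates: the fixture of choice for analytic SASA and occupancy
#' oracles (isolated spheres, full burial, known overlaps).
#'
#' @param positions n x 3 matrix of coordinates (A).
#' @param elements Character vector of element symbols, recycled.
#' @param radii Optional explicit radii; default looked up by element.
#' @return A one-frame [trajectory()].
#' @export
fixture_atoms <- function(positions, elements = "C", radii = NULL) {
  positions <- matrix(as.numeric(positions), ncol = 3)
  n <- nrow(positions)
  elements <- rep_len(elements, n)
  atoms <- data.frame(
    atom_name = toupper(elements),
    element = toupper(elements),
    residue_name = "UNK",
    residue_number = seq_len(n),
    chain_id = "A",
    stringsAsFactors = FALSE
  )
  atoms$vdw_radius <- if (is.null(radii)) {
    lookup_vdw_radius(atoms$element, atoms$atom_name)
  } else {
    rep_len(radii, n)
  }
  trajectory(topology(atoms), positions, time_per_frame = 0.04)
}
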