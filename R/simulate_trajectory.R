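#' Specification for a synthetic trajectory with analytic ground truth
#'
#' Each residue contributes three backbone-like atoms (N, H, CA). CA
#' positions fluctuate about a helical reference with isotropic Gaussian
#' noise of per-residue standard deviation `sigma` (so the analytic RMSF
#' is `sigma * sqrt(3)`), and the NH bond vector wobbles uniformly inside
#' a cone of semi-angle `cone_angle` about a fixed per-residue axis (so
#' the analytic order parameter is `S2 = (cos t0 * (1 + cos t0) / 2)^2`).
#' Frames are independent equilibrium samples; there are no kinetics,
#' which is sufficient because every implemented estimator is an
#' equilibrium average.
#'
#' @param n_residues Number of residues (>= 2).
#' @param n_frames Number of frames (>= 2).
#' @param dt Time per frame (ps, > 0).
#' @param sigma Per-residue positional noise standard deviation (Angstrom);
#'   recycled to `n_residues`.
#' @param cone_angle Per-residue cone semi-angle theta0 (degrees, in
#'   `[0, 90]`); recycled to `n_residues`.
#' @param rigid_motion If `TRUE`, each frame is additionally rotated and
#'   translated by a random rigid transform (global tumbling).
#' @param nh_missing Integer residue indices with no amide H
#'   (proline-like); their H atom is omitted.
#' @param seed RNG seed.
#' @return A list of class `traj_spec`.
#' @export
traj_spec <- function(n_residues, n_frames, dt = 1, sigma = 0,
                      cone_angle = 0, rigid_motion = FALSE,
                      nh_missing = integer(0), seed = 1) {
  if (n_residues < 2) stop("n_residues must be >= 2")
  if (n_frames < 2) stop("n_frames must be >= 2")
  if (dt <= 0) stop("dt must be > 0")
  sigma <- rep_len(as.numeric(sigma), n_residues)
  cone_angle <- rep_len(as.numeric(cone_angle), n_residues)
  if (any(sigma < 0)) stop("sigma must be >= 0")
  if (any(cone_angle < 0 | cone_angle > 90))
    stop("cone_angle must be in [0, 90] degrees")
  nh_missing <- as.integer(nh_missing)
  if (any(nh_missing < 1 | nh_missing > n_residues))
    stop("nh_missing indices out of range")
  structure(list(n_residues = as.integer(n_residues),
                 n_frames = as.integer(n_frames), dt = dt, sigma = sigma,
                 cone_angle = cone_angle, rigid_motion = isTRUE(rigid_motion),
                 nh_missing = nh_missing, seed = as.integer(seed)),
            class = "traj_spec")
}

# Reference geometry: CA on a regular helix (rise 1.5 A, radius 2.3 A,
# 100 degrees per residue); N at a fixed lab-frame offset from CA; the NH
# cone axis points radially outward with a fixed axial tilt. Arbitrary but
# nondegenerate, which is all superposition and the observables need.
reference_geometry <- function(n_residues) {
  i <- seq_len(n_residues)
  phi <- (i - 1) * 100 * pi / 180
  ca <- cbind(2.3 * cos(phi), 2.3 * sin(phi), 1.5 * (i - 1))
  n_off <- c(-1.20, 0.70, -0.45)
  n <- sweep(ca, 2, n_off, "+")
  axis <- cbind(cos(phi), sin(phi), rep(0.4, n_residues))
  axis <- axis / sqrt(rowSums(axis^2))
  list(ca = ca, n = n, axis = axis)
}

# Uniform sampling inside a cone of semi-angle theta0 about unit axis a:
# cos(theta) uniform on [cos(theta0), 1], phi uniform on [0, 2*pi). This
# makes S2 = (cos t0 * (1 + cos t0) / 2)^2 exact.
sample_cone <- function(n, axis, theta0_deg) {
  c0 <- cos(theta0_deg * pi / 180)
  u <- stats::runif(n, c0, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - u^2))
  b <- complete_basis(axis)
  outer(s * cos(phi), b$e1) + outer(s * sin(phi), b$e2) + outer(u, axis)
}

#' Analytic diffusion-in-a-cone order parameter
#'
#' @param theta0_deg Cone semi-angle (degrees).
#' @return `S2 = (cos t0 * (1 + cos t0) / 2)^2`.
#' @export
cone_s2 <- function(theta0_deg) {
  c0 <- cos(theta0_deg * pi / 180)
  (c0 * (1 + c0) / 2)^2
}

#' Generate a synthetic trajectory with known RMSF and S2
#'
#' @param spec A [traj_spec()].
#' @return A [trajectory()] whose `"truth"` attribute records the analytic
#'   per-residue RMSF (`sigma * sqrt(3)`), the analytic S2
#'   ([cone_s2()] of each cone angle), the sampled NH unit vectors before
#'   any rigid transform (`frames x residues x 3`), and the missing-NH
#'   mask.
#' @export
generate_trajectory <- function(spec) {
  stopifnot(inherits(spec, "traj_spec"))
  set.seed(spec$seed)
  nr <- spec$n_residues
  nf <- spec$n_frames
  geo <- reference_geometry(nr)

  # atom table: N, H (unless masked), CA per residue
  rows <- list()
  for (i in seq_len(nr)) {
    names_i <- if (i %in% spec$nh_missing) c("N", "CA") else c("N", "H", "CA")
    rows[[i]] <- data.frame(elety = names_i, resno = i,
                            resid = if (i %in% spec$nh_missing) "PRO" else "ALA",
                            element = substr(names_i, 1, 1),
                            stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  na <- nrow(atoms)

  nh <- array(NA_real_, c(nf, nr, 3))
  coords <- array(0, c(nf, na, 3))
  idx <- 0L
  for (i in seq_len(nr)) {
    has_h <- !(i %in% spec$nh_missing)
    mu <- sample_cone(nf, geo$axis[i, ], spec$cone_angle[i])
    if (has_h) nh[, i, ] <- mu
    # N fixed at reference; CA jitters isotropically; H rides the NH vector
    n_xyz <- matrix(geo$n[i, ], nf, 3, byrow = TRUE)
    ca_xyz <- matrix(geo$ca[i, ], nf, 3, byrow = TRUE) +
      matrix(stats::rnorm(nf * 3, sd = spec$sigma[i]), nf, 3)
    coords[, idx + 1L, ] <- n_xyz
    if (has_h) {
      coords[, idx + 2L, ] <- n_xyz + 1.01 * mu
      coords[, idx + 3L, ] <- ca_xyz
      idx <- idx + 3L
    } else {
      coords[, idx + 2L, ] <- ca_xyz
      idx <- idx + 2L
    }
  }

  if (spec$rigid_motion) {
    for (f in seq_len(nf)) {
      rot <- random_rotation()
      trans <- stats::runif(3, -20, 20)
      coords[f, , ] <- coords[f, , ] %*% t(rot) +
        matrix(trans, na, 3, byrow = TRUE)
    }
  }

  traj <- trajectory(coords, atoms, times = (seq_len(nf) - 1) * spec$dt)
  attr(traj, "truth") <- list(
    rmsf = spec$sigma * sqrt(3),
    s2 = cone_s2(spec$cone_angle),
    nh_vectors = nh,
    nh_missing = seq_len(nr) %in% spec$nh_missing,
    spec = spec
  )
  traj
}
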