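# Scalar geometric observables: radius of gyration, end-to-end distance,
# and Shrake-Rupley solvent-accessible surface area.

# Standard element masses for optional mass weighting.
.element_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                     S = 32.06)

# Default van der Waals radii (Angstrom); unknown elements fall back to
# the carbon-like default 1.70.
.vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20)

#' Van der Waals radii for a vector of element symbols
#' @param elements Character vector of element symbols.
#' @param default Radius for unknown elements (Angstrom).
#' @return Numeric radii (Angstrom).
#' @export
vdw_radii <- function(elements, default = 1.70) {
  r <- .vdw_radii[elements]
  r[is.na(r)] <- default
  unname(r)
}

#' Radius of gyration of one frame
#'
#' Mass-weighted Rg about the center of mass. Weights default to unit
#' masses; pass `masses = "element"` together with a trajectory-derived
#' atom table to use standard element masses.
#'
#' @param frame `atoms x 3` coordinate matrix.
#' @param selection Atom mask (default: all).
#' @param masses Per-atom weights, or `NULL` for unit masses.
#' @return Rg (Angstrom).
#' @export
radius_of_gyration <- function(frame, selection = NULL, masses = NULL) {
  frame <- as.matrix(frame)
  sel <- selection %||% rep(TRUE, nrow(frame))
  x <- frame[sel, , drop = FALSE]
  if (nrow(x) == 0) stop("empty selection")
  m <- masses %||% rep(1, nrow(x))
  if (length(m) != nrow(x)) m <- m[sel]
  com <- colSums(x * m) / sum(m)
  sqrt(sum(m * rowSums(sweep(x, 2, com)^2)) / sum(m))
}

#' End-to-end distance of one frame
#'
#' Euclidean distance between two designated terminal atoms.
#'
#' @param frame `atoms x 3` coordinate matrix.
#' @param first Index of the first terminal atom.
#' @param last Index of the last terminal atom.
#' @return Distance (Angstrom).
#' @export
end_to_end <- function(frame, first, last) {
  frame <- as.matrix(frame)
  if (first < 1 || first > nrow(frame) || last < 1 || last > nrow(frame))
    stop("terminal atom index out of range")
  sqrt(sum((frame[first, ] - frame[last, ])^2))
}

#' Time series of Rg and end-to-end distance over a trajectory
#'
#' Convenience wrapper reporting the time evolution of both collapse
#' observables. End-to-end uses the first and last CA atom by default.
#'
#' @param traj A [trajectory()].
#' @param selection Atom mask for Rg (default: all atoms).
#' @param masses Optional per-atom masses for Rg.
#' @return Data frame `(frame, time, rg, end_to_end)`.
#' @export
rg_series <- function(traj, selection = NULL, masses = NULL) {
  ca <- which(select_atoms(traj, "CA"))
  if (length(ca) < 2) stop("need at least two CA atoms for end-to-end")
  ends <- c(ca[1], ca[length(ca)])
  nf <- n_frames(traj)
  rg <- numeric(nf); ee <- numeric(nf)
  for (f in seq_len(nf)) {
    fc <- frame_coords(traj, f)
    rg[f] <- radius_of_gyration(fc, selection, masses)
    ee[f] <- end_to_end(fc, ends[1], ends[2])
  }
  data.frame(frame = seq_len(nf), time = traj$times, rg = rg,
             end_to_end = ee)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Distributes `n_points` quasi-uniform points (deterministic golden-
#' spiral lattice) on each atom's solvent-expanded sphere of radius
#' `r_i + probe`; a point is exposed when it lies strictly outside every
#' other atom's expanded sphere. Per-atom SASA is
#' `4 * pi * (r_i + probe)^2` times the exposed fraction.
#'
#' @param frame `atoms x 3` coordinate matrix.
#' @param radii Per-atom van der Waals radii (Angstrom), all > 0.
#' @param probe Probe (water) radius, default 1.4 Angstrom.
#' @param n_points Points per sphere, >= 32; default 960.
#' @return List with `total` and `per_atom` SASA (Angstrom^2).
#' @export
sasa <- function(frame, radii, probe = 1.4, n_points = 960) {
  frame <- as.matrix(frame)
  n <- nrow(frame)
  radii <- rep_len(as.numeric(radii), n)
  if (any(radii <= 0)) stop("radii must be > 0")
  if (probe <= 0) stop("probe must be > 0")
  if (n_points < 32) stop("n_points must be >= 32")
  pts <- golden_spiral_points(n_points)
  rext <- radii + probe
  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    # neighbor prefilter: only atoms whose expanded spheres can reach
    d2 <- rowSums(sweep(frame, 2, frame[i, ])^2)
    nb <- which(d2 < (rext[i] + rext)^2 & seq_len(n) != i)
    p <- pts * rext[i]
    p <- sweep(p, 2, frame[i, ], "+")
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- rowSums(sweep(p, 2, frame[j, ])^2)
      exposed <- exposed & (dj2 > rext[j]^2)
      if (!any(exposed)) break
    }
    per_atom[i] <- 4 * pi * rext[i]^2 * mean(exposed)
  }
  list(total = sum(per_atom), per_atom = per_atom)
}

#' SASA of one trajectory frame using the atom table's radii
#'
#' @param traj A [trajectory()].
#' @param i Frame index.
#' @param probe Probe radius (Angstrom).
#' @param n_points Points per sphere.
#' @return As [sasa()].
#' @export
sasa_frame <- function(traj, i = 1, probe = 1.4, n_points = 960) {
  radii <- traj$atoms$radius %||% vdw_radii(traj$atoms$element)
  if (all(is.na(radii))) radii <- vdw_radii(traj$atoms$element)
  sasa(frame_coords(traj, i), radii, probe, n_points)
}
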