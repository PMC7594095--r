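#' Trajectory container
#'
#' A minimal in-memory trajectory: a `frames x atoms x 3` coordinate array
#' (Angstrom), an atom table, and a per-frame time axis (ps). This is the
#' raw material for every structural observable (RMSD, RMSF, Rg,
#' end-to-end, SASA) and for NH bond-vector extraction.
#'
#' @param coords Numeric array `frames x atoms x 3` (Angstrom).
#' @param atoms Data frame with columns `elety` (atom name, e.g. "CA"),
#'   `resno` (integer residue number), `resid` (residue name) and
#'   `element`; an optional `radius` column (van der Waals, Angstrom)
#'   overrides the element lookup in [sasa()].
#' @param times Numeric vector of frame times (ps), strictly increasing.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(coords, atoms, times = NULL) {
  stopifnot(is.array(coords), length(dim(coords)) == 3, dim(coords)[3] == 3)
  if (!all(is.finite(coords))) stop("trajectory coordinates must be finite")
  if (nrow(atoms) != dim(coords)[2])
    stop("atom table length must equal the coordinate atom dimension")
  req <- c("elety", "resno", "resid", "element")
  if (!all(req %in% names(atoms)))
    stop("atom table needs columns: ", paste(req, collapse = ", "))
  if (is.null(times)) times <- seq_len(dim(coords)[1]) - 1
  if (length(times) != dim(coords)[1])
    stop("times length must equal the number of frames")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(list(coords = coords, atoms = atoms, times = as.numeric(times)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("trajectory: %d frames, %d atoms, %d residues, span %.1f ps\n",
              d[1], d[2], length(unique(x$atoms$resno)),
              diff(range(x$times))))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A [trajectory()].
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Extract one frame as an atoms x 3 coordinate matrix
#' @param traj A [trajectory()].
#' @param i Frame index.
#' @return Numeric matrix `atoms x 3`.
#' @export
frame_coords <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  m <- traj$coords[i, , , drop = FALSE]
  dim(m) <- dim(m)[2:3]
  m
}

#' Logical atom selection by atom name
#' @param traj A [trajectory()].
#' @param elety Atom names to keep (default `"CA"`).
#' @return Logical vector over atoms.
#' @export
select_atoms <- function(traj, elety = "CA") traj$atoms$elety %in% elety

#' Backbone atom selection
#'
#' The backbone set is configurable because reported backbone RMSDs differ
#' between conventions; the default is N, CA, C, O with a three-atom
#' N, CA, C alternative.
#'
#' @param traj A [trajectory()].
#' @param set `"NCACO"` (default) or `"NCAC"`.
#' @return Logical vector over atoms.
#' @export
select_backbone <- function(traj, set = c("NCACO", "NCAC")) {
  set <- match.arg(set)
  names <- if (set == "NCACO") c("N", "CA", "C", "O") else c("N", "CA", "C")
  select_atoms(traj, names)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj A [trajectory()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  nf <- n_frames(traj)
  # bio3d xyz layout is x1 y1 z1 x2 y2 z2 ... per row
  xyz <- matrix(t(apply(traj$coords, 1, function(m) as.vector(t(m)))),
                nrow = nf)
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = traj$atoms$resno,
                   resid = traj$atoms$resid,
                   elety = traj$atoms$elety)
  invisible(path)
}

#' Read a multi-model PDB file into a trajectory
#'
#' @param path PDB file (models become frames).
#' @param dt Time per frame (ps) used to build the time axis.
#' @return A [trajectory()].
#' @export
read_trajectory_pdb <- function(path, dt = 1) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  nf <- nrow(pdb$xyz)
  na <- nrow(pdb$atom)
  coords <- array(NA_real_, c(nf, na, 3))
  for (f in seq_len(nf)) {
    coords[f, , ] <- matrix(pdb$xyz[f, ], ncol = 3, byrow = TRUE)
  }
  elety <- trimws(pdb$atom$elety)
  atoms <- data.frame(
    elety = elety,
    resno = pdb$atom$resno,
    resid = trimws(pdb$atom$resid),
    element = substr(elety, 1, 1),
    stringsAsFactors = FALSE
  )
  trajectory(coords, atoms, times = (seq_len(nf) - 1) * dt)
}

#' Per-residue scalar profile
#'
#' The unit of all per-residue comparisons: one scalar per residue (RMSF in
#' Angstrom, S2 dimensionless, a difference track, ...). Residue numbering
#' follows the input verbatim; profiles are keyed by those numbers.
#'
#' @param residue_ids Integer residue numbers.
#' @param values One scalar per residue.
#' @param metric Label, e.g. `"RMSF"` or `"S2"`.
#' @param units Unit string, e.g. `"Angstrom"` or `""`.
#' @return A data frame of class `residue_profile` with columns
#'   `residue_id`, `value` and attributes `metric`, `units`.
#' @export
residue_profile <- function(residue_ids, values, metric = "value",
                            units = "") {
  if (length(residue_ids) != length(values))
    stop("residue_ids and values must have equal length")
  out <- data.frame(residue_id = as.integer(residue_ids),
                    value = as.numeric(values))
  attr(out, "metric") <- metric
  attr(out, "units") <- units
  class(out) <- c("residue_profile", "data.frame")
  out
}
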