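#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation (determinant +1, reflections corrected) and
#' translation that minimize the RMSD between selected atoms of `mobile`
#' and `reference`, via SVD of the covariance of the centered selections.
#'
#' @param mobile Numeric `atoms x 3` coordinate matrix.
#' @param reference Numeric `atoms x 3` matrix, same atom count.
#' @param selection Logical or integer atom mask used for the fit
#'   (default: all atoms). At least 3 non-collinear atoms are required.
#' @return A list with `rotation` (3x3, applied to row vectors by right
#'   multiplication), `translation`, `rmsd` (post-fit, over the
#'   selection), and `fitted` (the whole transformed `mobile`).
#' @export
superpose <- function(mobile, reference, selection = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3, ncol(reference) == 3,
            nrow(mobile) == nrow(reference))
  sel <- selection %||% rep(TRUE, nrow(mobile))
  p <- mobile[sel, , drop = FALSE]
  q <- reference[sel, , drop = FALSE]
  if (nrow(p) < 3) stop("superposition needs at least 3 selected atoms")
  cp <- colMeans(p); cq <- colMeans(q)
  pc <- sweep(p, 2, cp); qc <- sweep(q, 2, cq)
  # collinearity: centered selection of rank < 2 has no unique rotation
  sv <- svd(pc)$d
  if (sv[2] <= max(sv[1], 1) * 1e-10)
    stop("degenerate (collinear) selection: superposition is not unique")
  h <- crossprod(pc, qc)
  s <- svd(h)
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted_sel <- pc %*% rot
  rmsd <- sqrt(mean(rowSums((fitted_sel - qc)^2)))
  fitted <- sweep(sweep(mobile, 2, cp) %*% rot, 2, cq, "+")
  list(rotation = rot, translation = cq - as.vector(cp %*% rot),
       rmsd = rmsd, fitted = fitted)
}

#' RMSD between two frames after optimal superposition
#'
#' @inheritParams superpose
#' @return RMSD (Angstrom) over the selection.
#' @export
rmsd <- function(mobile, reference, selection = NULL) {
  superpose(mobile, reference, selection)$rmsd
}

#' Frame-by-frame superposed RMSD series
#'
#' Tracks the time evolution of the RMSD of each frame from a reference
#' after least-squares fitting, the standard convergence diagnostic.
#'
#' @param traj A [trajectory()].
#' @param reference Frame index into `traj` (default 1) or an
#'   `atoms x 3` matrix.
#' @param selection Atom mask for fit and RMSD (default: backbone
#'   N, CA, C, O).
#' @return Data frame `(frame, time, rmsd)` with attributes `mean` and
#'   `se` (standard error over frames).
#' @export
rmsd_series <- function(traj, reference = 1, selection = NULL) {
  sel <- selection %||% select_backbone(traj)
  ref <- if (is.matrix(reference)) reference else frame_coords(traj, reference)
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    superpose(frame_coords(traj, f), ref, sel)$rmsd
  }, numeric(1))
  out <- data.frame(frame = seq_along(vals), time = traj$times, rmsd = vals)
  attr(out, "mean") <- mean(vals)
  attr(out, "se") <- stats::sd(vals) / sqrt(length(vals))
  out
}

# Fit every frame of a trajectory onto a reference frame using `sel` for
# the fit; returns the full fitted coordinate array.
fit_frames <- function(traj, reference, sel) {
  nf <- n_frames(traj)
  out <- array(NA_real_, dim(traj$coords))
  for (f in seq_len(nf)) {
    out[f, , ] <- superpose(frame_coords(traj, f), reference, sel)$fitted
  }
  out
}

#' Per-residue root-mean-square fluctuation
#'
#' Two-pass protocol: every frame is first fitted onto an initial
#' reference (frame 1), the mean structure of the fitted frames is
#' computed, every original frame is re-fitted onto that mean, and
#' `RMSF_i = sqrt(mean |r_i - <r_i>|^2)` is taken about the final mean.
#' Global rigid motion is thereby removed before fluctuations are
#' measured.
#'
#' @param traj A [trajectory()] with at least 2 frames.
#' @param selection Atom mask; default CA atoms, the conventional
#'   per-residue flexibility track.
#' @return A [residue_profile()] of RMSF (Angstrom), one value per
#'   residue covered by the selection.
#' @export
rmsf <- function(traj, selection = NULL) {
  if (n_frames(traj) < 2) stop("RMSF needs at least 2 frames")
  sel <- selection %||% select_atoms(traj, "CA")
  fit1 <- fit_frames(traj, frame_coords(traj, 1), sel)
  mean1 <- apply(fit1, c(2, 3), mean)
  fit2 <- fit_frames(traj, mean1, sel)
  mean2 <- apply(fit2, c(2, 3), mean)
  dev2 <- sweep(fit2, c(2, 3), mean2)
  msf <- apply(dev2^2, 2, sum) / dim(fit2)[1]  # per-atom sum over x,y,z
  sel_idx <- which(if (is.logical(sel)) sel else seq_len(nrow(traj$atoms)) %in% sel)
  residue_profile(traj$atoms$resno[sel_idx], sqrt(msf[sel_idx]),
                  metric = "RMSF", units = "Angstrom")
}
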