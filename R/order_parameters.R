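#' Per-residue NH bond-vector series
#'
#' @param vectors Array `frames x residues x 3`; rows for residues without
#'   an amide H are `NA` and flagged in `missing`, never zero-filled.
#' @param residue_ids Integer residue numbers.
#' @param times Frame times (ps).
#' @param missing Logical per-residue missing flag.
#' @return Object of class `bond_vector_series`.
#' @export
bond_vector_series <- function(vectors, residue_ids, times,
                               missing = NULL) {
  stopifnot(length(dim(vectors)) == 3, dim(vectors)[3] == 3,
            dim(vectors)[2] == length(residue_ids),
            dim(vectors)[1] == length(times))
  missing <- missing %||% apply(vectors, 2, function(v) anyNA(v))
  norms <- sqrt(apply(vectors^2, c(1, 2), sum))
  ok <- norms[, !missing, drop = FALSE]
  if (length(ok) && any(abs(ok - 1) > 1e-6))
    stop("bond vectors must be unit-norm within 1e-6")
  structure(list(vectors = vectors, residue_ids = as.integer(residue_ids),
                 times = as.numeric(times), missing = missing),
            class = "bond_vector_series")
}

#' Extract normalized NH bond vectors from a trajectory
#'
#' Computes the unit H - N vector per residue per frame. Because the
#' order parameter measures internal motion only, global tumbling must be
#' removed first: by default every frame is superposed onto a reference
#' frame (backbone N + CA fit) before vectors are taken. Residues lacking
#' an amide H (e.g. proline) are flagged missing and excluded downstream.
#'
#' @param traj A [trajectory()].
#' @param superpose Remove global rigid motion by per-frame superposition
#'   onto `reference` before extraction (default `TRUE`).
#' @param reference Reference frame index for the superposition.
#' @return A [bond_vector_series()].
#' @export
extract_nh_vectors <- function(traj, superpose = TRUE, reference = 1) {
  res_ids <- sort(unique(traj$atoms$resno))
  n_idx <- h_idx <- integer(length(res_ids))
  for (k in seq_along(res_ids)) {
    rows <- which(traj$atoms$resno == res_ids[k])
    n_idx[k] <- rows[match("N", traj$atoms$elety[rows])]
    h_idx[k] <- rows[match("H", traj$atoms$elety[rows])]
  }
  if (all(is.na(h_idx)) || all(is.na(n_idx)))
    stop("no NH pairs found in trajectory")
  missing <- is.na(h_idx) | is.na(n_idx)

  coords <- traj$coords
  if (superpose) {
    sel <- select_atoms(traj, c("N", "CA"))
    coords <- fit_frames(traj, frame_coords(traj, reference), sel)
  }
  nf <- dim(coords)[1]
  vec <- array(NA_real_, c(nf, length(res_ids), 3))
  for (k in which(!missing)) {
    v <- coords[, h_idx[k], ] - coords[, n_idx[k], ]
    v <- v / sqrt(rowSums(v^2))
    vec[, k, ] <- v
  }
  bond_vector_series(vec, res_ids, traj$times, missing)
}

# Second Legendre polynomial.
p2 <- function(x) (3 * x^2 - 1) / 2

# Split frame indices into non-overlapping windows of `wf` frames each;
# incomplete trailing frames are dropped.
window_starts <- function(n, wf) {
  nw <- n %/% wf
  if (nw == 0) integer(0) else (seq_len(nw) - 1) * wf + 1
}

#' Windowed P2 orientational correlation function
#'
#' Within each non-overlapping window,
#' `C(t) = < P2( mu(tau) . mu(tau + t) ) >` averaged over all valid time
#' origins (multi-origin averaging), with `P2(x) = (3 x^2 - 1) / 2`.
#'
#' @param series A [bond_vector_series()].
#' @param residue Residue id to analyze.
#' @param window_length Window length (ps); must not exceed the
#'   trajectory span.
#' @param max_lag Maximum lag (ps); default half the window, beyond which
#'   origin averaging becomes too shallow to be reliable.
#' @return A list (one element per window) of data frames
#'   `(lag, value, n_pairs)` with `lag` in ps.
#' @export
correlation_p2 <- function(series, residue, window_length,
                           max_lag = window_length / 2) {
  k <- match(residue, series$residue_ids)
  if (is.na(k)) stop("unknown residue id: ", residue)
  if (series$missing[k]) stop("residue ", residue, " has no NH vector")
  dt <- diff(series$times[1:2])
  nf <- dim(series$vectors)[1]
  wf <- floor(window_length / dt + 1e-9)
  if (wf > nf) stop("window longer than trajectory")
  lag_max <- floor(max_lag / dt + 1e-9)
  v <- series$vectors[, k, ]
  lapply(window_starts(nf, wf), function(s) {
    w <- v[s:(s + wf - 1), , drop = FALSE]
    lags <- 0:min(lag_max, wf - 1)
    vals <- vapply(lags, function(l) {
      n <- wf - l
      dots <- rowSums(w[1:n, , drop = FALSE] * w[(1 + l):(l + n), , drop = FALSE])
      mean(p2(pmin(1, pmax(-1, dots))))
    }, numeric(1))
    data.frame(lag = lags * dt, value = vals, n_pairs = wf - lags)
  })
}

# Direct second-moment S2 for one window of unit vectors (n x 3):
# S2 = (3/2) * sum_ab <mu_a mu_b>^2 - 1/2. Lies in [0, 1] because the
# second-moment tensor is PSD with unit trace.
s2_direct_window <- function(w) {
  m <- crossprod(w) / nrow(w)
  # clamp round-off excursions outside the mathematical range
  min(1, max(0, 1.5 * sum(m^2) - 0.5))
}

#' Generalized order parameter profile from windowed estimates
#'
#' Splits the trajectory into non-overlapping windows of `window_length`
#' and estimates S2 per residue per window, then reports the mean over
#' windows with the window-to-window spread. Two standard MD estimators
#' are exposed:
#' * `direct` (default): `S2 = (3/2) * sum_ab <mu_a mu_b>^2 - 1/2`, the
#'   second-moment tensor average over the window;
#' * `plateau`: the mean of the P2 correlation function over the final
#'   `plateau_frac` of computed lags.
#' The two agree when the correlation function is converged within the
#' window, which is the practical check that the window is long enough.
#'
#' @param series A [bond_vector_series()].
#' @param window_length Window length (ps).
#' @param estimator `"direct"` or `"plateau"`.
#' @param plateau_frac Fraction of trailing lags averaged by the plateau
#'   estimator (default 0.2).
#' @param max_lag_frac Maximum correlation lag as a fraction of the
#'   window (plateau estimator only; default 0.5).
#' @return Data frame of class `order_parameter_profile` with columns
#'   `residue_id`, `value` (mean S2 over windows), `window_sd`,
#'   `n_windows`; missing-NH residues are omitted.
#' @export
s2_profile <- function(series, window_length,
                       estimator = c("direct", "plateau"),
                       plateau_frac = 0.2, max_lag_frac = 0.5) {
  estimator <- match.arg(estimator)
  dt <- diff(series$times[1:2])
  nf <- dim(series$vectors)[1]
  wf <- floor(window_length / dt + 1e-9)
  starts <- window_starts(nf, wf)
  if (length(starts) == 0) stop("no complete window in trajectory")
  keep <- which(!series$missing)
  est <- matrix(NA_real_, length(starts), length(keep))
  for (jj in seq_along(keep)) {
    v <- series$vectors[, keep[jj], ]
    for (si in seq_along(starts)) {
      w <- v[starts[si]:(starts[si] + wf - 1), , drop = FALSE]
      if (estimator == "direct") {
        est[si, jj] <- s2_direct_window(w)
      } else {
        lag_max <- floor(wf * max_lag_frac)
        lags <- 0:lag_max
        vals <- vapply(lags, function(l) {
          n <- wf - l
          dots <- rowSums(w[1:n, , drop = FALSE] *
                            w[(1 + l):(l + n), , drop = FALSE])
          mean(p2(pmin(1, pmax(-1, dots))))
        }, numeric(1))
        tail_n <- max(1, ceiling(length(vals) * plateau_frac))
        est[si, jj] <- mean(utils::tail(vals, tail_n))
      }
    }
  }
  out <- data.frame(
    residue_id = series$residue_ids[keep],
    value = colMeans(est),
    window_sd = apply(est, 2, function(x) if (length(x) > 1) stats::sd(x) else 0),
    n_windows = length(starts)
  )
  attr(out, "metric") <- "S2"
  attr(out, "units") <- ""
  attr(out, "estimator") <- estimator
  class(out) <- c("order_parameter_profile", "residue_profile", "data.frame")
  out
}

#' Number of non-overlapping analysis windows in a span
#'
#' @param span Trajectory span and `window_length` window size, in the
#'   same time unit (e.g. ns).
#' @param window_length Window size.
#' @return `floor(span / window_length)`; 0 with a warning when the
#'   window exceeds the span.
#' @export
window_count <- function(span, window_length) {
  if (span <= 0 || window_length <= 0) stop("span and window must be > 0")
  if (window_length > span) {
    warning("window longer than span: 0 windows")
    return(0L)
  }
  as.integer(floor(span / window_length + 1e-9))
}

#' Merge replicate per-residue profiles into mean and standard error
#'
#' Independent repeat simulations are combined per residue as
#' `mean` and `se = sd / sqrt(n)`. With a single replicate the SE is
#' reported as 0 and flagged (`attr(,"se_defined") = FALSE`).
#'
#' @param profiles List of [residue_profile()] /
#'   `order_parameter_profile` data frames with identical `residue_id`.
#' @return Data frame `(residue_id, mean, se, n)`.
#' @export
replicate_merge <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  ids <- profiles[[1]]$residue_id
  for (p in profiles) {
    if (!identical(p$residue_id, ids))
      stop("replicates must cover identical residue ids")
  }
  vals <- sapply(profiles, function(p) p$value)
  vals <- matrix(vals, nrow = length(ids))
  n <- length(profiles)
  out <- data.frame(
    residue_id = ids,
    mean = rowMeans(vals),
    se = if (n > 1) apply(vals, 1, stats::sd) / sqrt(n) else rep(0, length(ids)),
    n = n
  )
  attr(out, "se_defined") <- n > 1
  out
}
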