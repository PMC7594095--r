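#' Per-residue difference between two profiles with change flags
#'
#' Computes `delta_i = b_i - a_i` over the residues common to both
#' profiles and flags each residue `decreased` / `unchanged` /
#' `increased` against a symmetric threshold `tau`. This is the
#' comparison underlying catalytic-vs-non-catalytic plasticity contrasts:
#' a binding event that rigidifies an interface shows up as a stretch of
#' `decreased` RMSF flags.
#'
#' @param a,b [residue_profile()]s (state A and state B).
#' @param tau Flagging threshold in the profile's units (default 0.1,
#'   appropriate for RMSF in Angstrom; use ~0.05 for S2).
#' @param regions Optional named list of `c(first, last)` residue ranges
#'   summarized separately (e.g. a binding interface).
#' @return Data frame `(residue_id, a, b, delta, flag)` of class
#'   `profile_comparison`, with attributes `tau`, `summary` (mean delta,
#'   fraction decreased/increased) and `regions` (per-region mean delta
#'   and flag counts).
#' @export
compare_profiles <- function(a, b, tau = 0.1, regions = NULL) {
  common <- intersect(a$residue_id, b$residue_id)
  if (length(common) == 0) stop("profiles share no residues")
  common <- sort(common)
  av <- a$value[match(common, a$residue_id)]
  bv <- b$value[match(common, b$residue_id)]
  delta <- bv - av
  flag <- ifelse(delta > tau, "increased",
                 ifelse(delta < -tau, "decreased", "unchanged"))
  out <- data.frame(residue_id = common, a = av, b = bv, delta = delta,
                    flag = flag, stringsAsFactors = FALSE)
  attr(out, "tau") <- tau
  attr(out, "summary") <- list(
    mean_delta = mean(delta),
    fraction_decreased = mean(flag == "decreased"),
    fraction_increased = mean(flag == "increased")
  )
  if (!is.null(regions)) {
    attr(out, "regions") <- lapply(regions, function(rg) {
      in_rg <- common >= rg[1] & common <= rg[2]
      list(residues = sum(in_rg),
           mean_delta = mean(delta[in_rg]),
           n_decreased = sum(flag[in_rg] == "decreased"),
           n_increased = sum(flag[in_rg] == "increased"))
    })
  }
  class(out) <- c("profile_comparison", "data.frame")
  out
}

#' Agreement between a simulated profile and a reference profile
#'
#' RMS deviation over common residues with a pass/fail verdict, the
#' profile analogue of "within statistical error": a simulated S2 track
#' agrees with an NMR-derived one when the RMS deviation stays below the
#' tolerance.
#'
#' @param sim Simulated profile (`value` column per residue).
#' @param ref Reference [residue_profile()].
#' @param tolerance RMS tolerance for the verdict (default 0.1).
#' @return List with `rms`, `per_residue` (data frame of absolute
#'   deviations), and `verdict` (`"pass"`/`"fail"`).
#' @export
profile_agreement <- function(sim, ref, tolerance = 0.1) {
  common <- intersect(sim$residue_id, ref$residue_id)
  if (length(common) == 0) stop("profiles share no residues")
  common <- sort(common)
  sv <- sim$value[match(common, sim$residue_id)]
  rv <- ref$value[match(common, ref$residue_id)]
  dev <- sv - rv
  list(rms = sqrt(mean(dev^2)),
       per_residue = data.frame(residue_id = common, abs_delta = abs(dev)),
       verdict = if (sqrt(mean(dev^2)) <= tolerance) "pass" else "fail")
}

#' Benchmark force fields against experimental reference observables
#'
#' For each force field and scalar observable, replicate values are
#' reduced to mean and standard error and compared to the reference by
#' the `|mean - ref| <= z * SE` rule (default `z = 2`), the
#' operationalization of agreement "within statistical error". Profile
#' observables (a list of per-replicate profiles vs a reference profile)
#' are merged with [replicate_merge()] and judged by RMS deviation
#' against `profile_tolerance`.
#'
#' @param runs Named list (force field) of named lists (observable);
#'   each scalar observable is a numeric vector of replicate values, each
#'   profile observable a list of profiles.
#' @param reference Named list of reference values: scalars, or a
#'   [residue_profile()] for profile observables. Observables without a
#'   reference are skipped with a warning.
#' @param z Width of the agreement band in standard errors (default 2).
#' @param profile_tolerance RMS tolerance for profile observables
#'   (default 0.1).
#' @return Data frame `(force_field, observable, mean, se, n, reference,
#'   verdict)`, ranked by the number of passing observables per force
#'   field; profile rows report the RMS deviation in `mean`.
#' @export
benchmark_forcefield <- function(runs, reference, z = 2,
                                 profile_tolerance = 0.1) {
  stopifnot(length(runs) >= 1, z > 0)
  rows <- list()
  for (ff in names(runs)) {
    for (obs in names(runs[[ff]])) {
      if (is.null(reference[[obs]])) {
        warning("no reference for observable '", obs, "': skipped")
        next
      }
      val <- runs[[ff]][[obs]]
      ref <- reference[[obs]]
      if (is.list(val) && is.data.frame(ref)) {
        merged <- replicate_merge(val)
        sim <- data.frame(residue_id = merged$residue_id,
                          value = merged$mean)
        agr <- profile_agreement(sim, ref, tolerance = profile_tolerance)
        rows[[length(rows) + 1L]] <- data.frame(
          force_field = ff, observable = obs, mean = agr$rms,
          se = NA_real_, n = length(val), reference = NA_real_,
          verdict = agr$verdict, stringsAsFactors = FALSE)
      } else {
        val <- as.numeric(val)
        m <- mean(val)
        se <- if (length(val) > 1) stats::sd(val) / sqrt(length(val)) else 0
        ok <- abs(m - ref) <= z * se
        rows[[length(rows) + 1L]] <- data.frame(
          force_field = ff, observable = obs, mean = m, se = se,
          n = length(val), reference = ref,
          verdict = if (ok) "pass" else "fail", stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(force_field = character(0), observable = character(0),
                      mean = numeric(0), se = numeric(0), n = integer(0),
                      reference = numeric(0), verdict = character(0)))
  }
  out <- do.call(rbind, rows)
  npass <- tapply(out$verdict == "pass", out$force_field, sum)
  out$force_field <- factor(out$force_field,
                            levels = names(sort(npass, decreasing = TRUE)))
  out <- out[order(out$force_field, out$observable), ]
  out$force_field <- as.character(out$force_field)
  rownames(out) <- NULL
  attr(out, "z") <- z
  out
}
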