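# TSV ingestion for the annotation side of the network analysis: ID
# lists, the E3 -> substrate map, and optional localization labels.

#' Load annotation sets from TSV files
#'
#' @param ubp_file One-column TSV of Ub-binding protein IDs (header
#'   allowed; `#` comments ignored).
#' @param e3_file One-column TSV of E3 ligase IDs.
#' @param substrates_file Two-column TSV `(e3_id, substrate_id)`.
#' @param localization_file Optional two-column TSV `(id, compartment)`;
#'   multiple rows per ID accumulate labels.
#' @return An [annotation_sets()].
#' @export
load_annotation_sets <- function(ubp_file, e3_file, substrates_file,
                                 localization_file = NULL) {
  read_ids <- function(path) {
    x <- read_tsv(path)
    as.character(x[[1]])
  }
  subs_df <- read_tsv(substrates_file)
  if (ncol(subs_df) < 2) stop("substrate map needs 2 columns")
  substrates <- split(as.character(subs_df[[2]]),
                      as.character(subs_df[[1]]))
  localization <- NULL
  if (!is.null(localization_file)) {
    loc_df <- read_tsv(localization_file)
    localization <- split(as.character(loc_df[[2]]),
                          toupper(trimws(as.character(loc_df[[1]]))))
  }
  annotation_sets(read_ids(ubp_file), read_ids(e3_file), substrates,
                  localization)
}

#' Load a reference per-residue profile from a two-column TSV
#'
#' The exchange format for experimental reference tracks (e.g. an
#' NMR-derived S2 profile): `residue_id` then `value`, `#` comments
#' ignored.
#'
#' @param path TSV file.
#' @param metric,units Labels attached to the profile.
#' @return A [residue_profile()].
#' @export
load_reference_profile <- function(path, metric = "S2", units = "") {
  x <- read_tsv(path)
  if (ncol(x) < 2) stop("reference profile needs 2 columns")
  residue_profile(x[[1]], x[[2]], metric = metric, units = units)
}

#' Write a per-residue profile as TSV
#'
#' @param profile A [residue_profile()] or `order_parameter_profile`.
#' @param path Output file.
#' @param seed,params Recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path, seed = NULL, params = NULL) {
  params <- c(params,
              list(metric = attr(profile, "metric") %||% "value",
                   units = attr(profile, "units") %||% ""))
  write_tsv(as.data.frame(profile), path, seed = seed, params = params)
}
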