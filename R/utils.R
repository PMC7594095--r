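# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Uniform random unit vectors on the sphere
#'
#' Draws `n` points uniformly distributed on the unit sphere, used as the
#' isotropic (fully disordered) null for orientational statistics: a bond
#' vector resampled this way has order parameter S2 = 0 in expectation.
#'
#' @param n Number of vectors.
#' @return An `n x 3` matrix of unit row vectors.
#' @export
runif_sphere <- function(n) {
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(s * cos(phi), s * sin(phi), z)
}

# Uniformly distributed random rotation matrix (via unit quaternion).
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  quaternion_to_rotation(q)
}

quaternion_to_rotation <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

# Orthonormal basis (e1, e2) completing unit vector a to a right-handed frame.
complete_basis <- function(a) {
  ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * a) * a
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(
    a[2] * e1[3] - a[3] * e1[2],
    a[3] * e1[1] - a[1] * e1[3],
    a[1] * e1[2] - a[2] * e1[1]
  )
  list(e1 = e1, e2 = e2)
}

# Deterministic quasi-uniform sphere lattice (Fibonacci / golden spiral).
# Returns n x 3 unit vectors; used by the Shrake-Rupley SASA routine.
golden_spiral_points <- function(n) {
  stopifnot(n >= 1)
  k <- seq_len(n)
  z <- (2 * k - 1) / n - 1
  golden <- pi * (3 - sqrt(5))
  phi <- golden * (k - 1)
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(s * cos(phi), s * sin(phi), z)
}

# Provenance header written at the top of every output table.
provenance_header <- function(seed = NULL, params = NULL) {
  ver <- as.character(utils::packageVersion("plastnet"))
  items <- c(sprintf("plastnet=%s", ver))
  if (!is.null(seed)) items <- c(items, sprintf("seed=%s", format(seed)))
  if (length(params)) {
    items <- c(items, paste(names(params), vapply(params, format, ""),
                            sep = "=", collapse = " "))
  }
  paste0("# ", paste(items, collapse = " "))
}

#' Write a table as TSV with a provenance comment header
#'
#' @param x A data frame.
#' @param path Output file.
#' @param seed Optional seed recorded in the header.
#' @param params Optional named list of parameters recorded in the header.
#' @param col_names Write the column-name row (disable for edge lists,
#'   whose readers treat every non-comment line as data).
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path, seed = NULL, params = NULL,
                      col_names = TRUE) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(provenance_header(seed, params), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = col_names)
  invisible(path)
}

#' Read a TSV written by [write_tsv()] (comment lines ignored)
#'
#' @param path Input file.
#' @return A data frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
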