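#' Undirected simple protein-protein interaction network
#'
#' Wraps an igraph graph; construction canonicalizes IDs (trimmed,
#' uppercased), collapses duplicate and reversed edges, and drops
#' self-loops (counted).
#'
#' @param edges Two-column character matrix or data frame of ID pairs.
#' @param nodes Optional extra node IDs (isolated nodes).
#' @return Object of class `ppi_network`.
#' @export
ppi_network <- function(edges, nodes = NULL) {
  if (is.data.frame(edges)) edges <- as.matrix(edges[, 1:2])
  edges <- matrix(toupper(trimws(as.character(edges))), ncol = 2)
  if (any(edges == "")) stop("empty protein ID in edge list")
  self <- edges[, 1] == edges[, 2]
  n_self <- sum(self)
  edges <- edges[!self, , drop = FALSE]
  if (nrow(edges)) {
    key <- apply(edges, 1, function(e) paste(sort(e), collapse = "\t"))
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  nodes <- unique(c(as.vector(edges), toupper(trimws(nodes %||% character(0)))))
  g <- igraph::graph_from_data_frame(
    d = as.data.frame(edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  structure(list(graph = g, self_loops_dropped = n_self),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("ppi_network: %d proteins, %d interactions (%d self-loops dropped)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              x$self_loops_dropped))
  invisible(x)
}

#' Load a PPI network from a TSV edge list
#'
#' Expects at least two tab-separated ID columns per line; lines starting
#' with `#` are ignored. A malformed line aborts with its line number.
#'
#' @param path Edge-list file.
#' @return A [ppi_network()].
#' @export
load_network <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 0L) < 2)
  if (length(bad)) {
    stop("malformed edge line ", which(keep)[bad[1]], " in ", path,
         ": fewer than 2 columns")
  }
  if (!any(keep)) return(ppi_network(matrix(character(0), ncol = 2)))
  edges <- t(vapply(fields, function(f) f[1:2], character(2)))
  ppi_network(edges)
}

#' Interactors (neighbors) of a protein
#'
#' @param net A [ppi_network()].
#' @param id Protein ID.
#' @return Sorted character vector of neighbor IDs; an unknown ID yields
#'   an empty set with a warning.
#' @export
interactors <- function(net, id) {
  id <- toupper(trimws(id))
  if (!id %in% igraph::V(net$graph)$name) {
    warning("protein '", id, "' not in network")
    return(character(0))
  }
  sort(igraph::neighbors(net$graph, id)$name)
}

#' Annotation sets for the ubiquitin-network analysis
#'
#' @param ubp_ids Ubiquitin-binding protein IDs.
#' @param e3_ids E3 RING ligase IDs.
#' @param substrates Named list: E3 ID -> character vector of substrate
#'   IDs. Keys must be a subset of `e3_ids`.
#' @param localization Optional named list: ID -> compartment labels.
#' @return Object of class `annotation_sets`.
#' @export
annotation_sets <- function(ubp_ids, e3_ids, substrates,
                            localization = NULL) {
  canon <- function(x) toupper(trimws(x))
  ubp_ids <- unique(canon(ubp_ids))
  e3_ids <- unique(canon(e3_ids))
  substrates <- lapply(substrates, canon)
  names(substrates) <- canon(names(substrates))
  if (any(c(ubp_ids, e3_ids, unlist(substrates)) == ""))
    stop("protein IDs must be nonempty")
  if (!all(names(substrates) %in% e3_ids))
    stop("substrate map keys must be a subset of e3_ids")
  if (!is.null(localization)) {
    names(localization) <- canon(names(localization))
  }
  structure(list(ubp_ids = ubp_ids, e3_ids = e3_ids,
                 substrates = substrates, localization = localization),
            class = "annotation_sets")
}

# Deterministic ranking: descending score, ties broken lexicographically.
ranked_list <- function(ids, scores) {
  stopifnot(length(ids) == length(scores), all(scores >= 0))
  ids <- unname(as.character(ids))
  scores <- unname(as.numeric(scores))
  o <- order(-scores, ids)
  out <- data.frame(rank = seq_along(ids), id = ids[o],
                    score = scores[o], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("ranked_list", "data.frame")
  out
}

#' Rank E3 ligases by connectivity degree with Ub-binding proteins
#'
#' The connectivity degree of an E3 is the number of its substrates that
#' are also interactors of Ub-binding proteins — the strength of the
#' length-3 linkage Ub - UBP - shared interactor - E3 that marks the E3
#' as a candidate Ub binder. `mode = "union"` (default) counts distinct
#' shared proteins, `|substrates(E3) /\\ U_u interactors(u)|`;
#' `mode = "sum"` counts (UBP, protein) pairs,
#' `sum_u |substrates(E3) /\\ interactors(u)|`.
#'
#' @param net A [ppi_network()].
#' @param ann An [annotation_sets()]; the substrate map must be nonempty.
#' @param mode `"union"` or `"sum"`.
#' @return A ranked data frame `(rank, id, score)` over all E3s (an E3
#'   without substrates scores 0), with attribute `n_positive`, the
#'   number of E3s with score > 0.
#' @export
e3_connectivity_degree <- function(net, ann, mode = c("union", "sum")) {
  mode <- match.arg(mode)
  if (length(ann$substrates) == 0) stop("substrate map is empty")
  ubp_int <- lapply(ann$ubp_ids, function(u)
    suppressWarnings(interactors(net, u)))
  pool <- unique(unlist(ubp_int))
  scores <- vapply(ann$e3_ids, function(e) {
    subs <- ann$substrates[[e]]
    if (is.null(subs) || length(subs) == 0) return(0)
    if (mode == "union") {
      length(intersect(subs, pool))
    } else {
      sum(vapply(ubp_int, function(s) length(intersect(subs, s)), 0L))
    }
  }, numeric(1))
  out <- ranked_list(ann$e3_ids, scores)
  attr(out, "n_positive") <- sum(scores > 0)
  attr(out, "mode") <- mode
  out
}

#' Rank Ub-binding proteins by interactors shared with a seed ligase
#'
#' For a seed E3 (e.g. Arkadia or Ark2C), scores every Ub-binding
#' protein by how many of the seed's substrates are among its
#' interactors: `score(u) = |substrates(seed) /\\ interactors(u)|`.
#' High scorers are the UBPs most "structurally reachable" from the seed
#' through shared partners.
#'
#' @param net A [ppi_network()].
#' @param ann An [annotation_sets()].
#' @param seed_e3 Seed ligase ID; must have recorded substrates.
#' @return A ranked data frame `(rank, id, score)` over `ubp_ids`.
#' @export
rank_ubps_for_seed <- function(net, ann, seed_e3) {
  seed_e3 <- toupper(trimws(seed_e3))
  subs <- ann$substrates[[seed_e3]]
  if (is.null(subs) || length(subs) == 0)
    stop("seed ligase '", seed_e3, "' has no recorded substrates")
  scores <- vapply(ann$ubp_ids, function(u) {
    length(intersect(subs, suppressWarnings(interactors(net, u))))
  }, numeric(1))
  ranked_list(ann$ubp_ids, scores)
}

#' Predict new interactors of a seed ligase by UBP recurrence
#'
#' Completes the length-3 inference: take the `top_k` Ub-binding
#' proteins most connected to the seed (via [rank_ubps_for_seed()]),
#' pool their interactors, remove the seed's known substrates and the
#' seed itself, and score each remaining candidate by recurrence — the
#' number of top-k UBPs that interact with it. Candidates recurring
#' across several top UBPs are the putative new interactors.
#'
#' @param net A [ppi_network()].
#' @param ann An [annotation_sets()].
#' @param seed_e3 Seed ligase ID.
#' @param top_k Number of top UBPs pooled (default 5); clipped with a
#'   warning when it exceeds the available UBPs.
#' @param localization_filter If `TRUE`, keep only candidates sharing at
#'   least one compartment label with the seed (requires
#'   `ann$localization`).
#' @param exclude Candidate IDs to drop (e.g. polyubiquitin precursors,
#'   which bind trivially and carry no interaction insight).
#' @return A ranked data frame `(rank, id, score)` of candidates.
#' @export
predict_interactors <- function(net, ann, seed_e3, top_k = 5,
                                localization_filter = FALSE,
                                exclude = NULL) {
  stopifnot(top_k >= 1)
  seed_e3 <- toupper(trimws(seed_e3))
  ubp_rank <- rank_ubps_for_seed(net, ann, seed_e3)
  if (top_k > nrow(ubp_rank)) {
    warning("top_k clipped from ", top_k, " to ", nrow(ubp_rank))
    top_k <- nrow(ubp_rank)
  }
  top <- ubp_rank$id[seq_len(top_k)]
  int_sets <- lapply(top, function(u)
    suppressWarnings(interactors(net, u)))
  cand <- unique(unlist(int_sets))
  cand <- setdiff(cand, c(ann$substrates[[seed_e3]], seed_e3,
                          toupper(trimws(exclude %||% character(0)))))
  if (isTRUE(localization_filter)) {
    loc <- ann$localization
    if (is.null(loc)) stop("localization_filter requires ann$localization")
    seed_loc <- loc[[seed_e3]]
    cand <- cand[vapply(cand, function(id)
      length(intersect(loc[[id]] %||% character(0), seed_loc)) > 0,
      logical(1))]
  }
  if (length(cand) == 0)
    return(ranked_list(character(0), numeric(0)))
  rec <- vapply(cand, function(id)
    sum(vapply(int_sets, function(s) id %in% s, logical(1))), numeric(1))
  ranked_list(cand, rec)
}

#' Degree-normalized length-3 path score between two proteins
#'
#' The L3 link-prediction score: over all ordered intermediate pairs
#' `(u, v)` with edges `x-u`, `u-v`, `v-y`,
#' `p(x, y) = sum 1 / sqrt(deg(u) * deg(v))`. Many degree-normalized
#' paths of length three predict a direct interaction even when `x` and
#' `y` share no neighbors.
#'
#' @param net A [ppi_network()].
#' @param x,y Distinct protein IDs. An absent node scores 0 with a
#'   warning.
#' @return Numeric score >= 0.
#' @export
l3_score <- function(net, x, y) {
  x <- toupper(trimws(x)); y <- toupper(trimws(y))
  if (identical(x, y)) stop("l3_score requires two distinct proteins")
  g <- net$graph
  vn <- igraph::V(g)$name
  if (!x %in% vn || !y %in% vn) {
    warning("node absent from network: score 0")
    return(0)
  }
  nx <- igraph::neighbors(g, x)$name
  ny <- igraph::neighbors(g, y)$name
  if (length(nx) == 0 || length(ny) == 0) return(0)
  deg <- igraph::degree(g)
  total <- 0
  for (u in nx) {
    nu <- igraph::neighbors(g, u)$name
    vs <- intersect(nu, ny)
    if (length(vs))
      total <- total + sum(1 / sqrt(deg[[u]] * deg[vs]))
  }
  unname(total)
}

#' Write a ranking as TSV with rank/id/score columns
#'
#' @param ranking A ranked data frame from the `*_rank*`/predict
#'   functions.
#' @param path Output file.
#' @param seed Optional seed recorded in the provenance header.
#' @param params Optional parameter list for the header.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path, seed = NULL, params = NULL) {
  write_tsv(as.data.frame(ranking), path, seed = seed, params = params)
}
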