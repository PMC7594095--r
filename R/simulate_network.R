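#' Specification for a synthetic ubiquitin interaction network
#'
#' Builds a network with planted, recoverable structure: a Ub hub wired
#' to Ub-binding proteins (UBPs), a disjoint interactor pool per UBP, E3
#' ligases whose substrate sets overlap the pooled UBP interactors by a
#' designed amount, a seed ligase whose substrates are concentrated in
#' the pools of the first few UBPs, planted "true interactor" nodes
#' connected to all of those top UBPs, background nodes, and optional
#' uniform edge noise.
#'
#' @param n_ubp Number of Ub-binding proteins (>= 0).
#' @param n_e3 Number of E3 ligases (>= 0).
#' @param n_background Number of background proteins (>= 0).
#' @param planted_e3_overlap Integer vector (recycled to `n_e3`): number
#'   of each E3's substrates drawn from the pooled UBP interactors. This
#'   is the planted connectivity degree.
#' @param seed_substrate_count Substrates of the seed ligase (>= 0; 0
#'   disables the seed arm).
#' @param edge_noise Probability of each random extra edge, in `[0, 1]`.
#' @param pool_size Interactors per UBP (grown automatically when the
#'   requested overlaps need more).
#' @param seed RNG seed.
#' @return A list of class `net_spec`.
#' @export
net_spec <- function(n_ubp = 6, n_e3 = 8, n_background = 20,
                     planted_e3_overlap = 0, seed_substrate_count = 6,
                     edge_noise = 0, pool_size = 8, seed = 1) {
  if (n_ubp < 0 || n_e3 < 0 || n_background < 0 || seed_substrate_count < 0)
    stop("counts must be >= 0")
  if (edge_noise < 0 || edge_noise > 1) stop("edge_noise must be in [0, 1]")
  planted_e3_overlap <- as.integer(rep_len(planted_e3_overlap, max(n_e3, 0)))
  if (any(planted_e3_overlap < 0)) stop("overlaps must be >= 0")
  structure(list(n_ubp = as.integer(n_ubp), n_e3 = as.integer(n_e3),
                 n_background = as.integer(n_background),
                 planted_e3_overlap = planted_e3_overlap,
                 seed_substrate_count = as.integer(seed_substrate_count),
                 edge_noise = edge_noise, pool_size = as.integer(pool_size),
                 seed = as.integer(seed)),
            class = "net_spec")
}

# Strictly decreasing allocation of `total` seed substrates over up to
# `k` UBP pools (so the planted UBP ranking has no ties).
allocate_decreasing <- function(total, k, pool_size) {
  if (total == 0 || k == 0) return(integer(0))
  k <- min(k, total)
  while (k > 1 && total < k * (k + 1) / 2) k <- k - 1
  q <- (total - k * (k - 1) / 2) %/% k
  counts <- q + (k - 1):0
  r <- total - sum(counts)
  if (r > 0) counts[seq_len(r)] <- counts[seq_len(r)] + 1
  if (counts[1] > pool_size)
    stop("seed_substrate_count too large for the UBP pools")
  counts
}

#' Generate a planted ubiquitin interaction network
#'
#' @param spec A [net_spec()].
#' @return List with `network` (a [ppi_network()]), `annotations`
#'   (an [annotation_sets()]), and `truth`: the planted
#'   `e3_ranking` (connectivity degrees before noise), the planted
#'   `seed_ubp_ranking`, and `seed_interactors`, the planted true
#'   interactors of the seed ligase.
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "net_spec"))
  set.seed(spec$seed)
  n_true <- if (spec$seed_substrate_count > 0 && spec$n_ubp > 0) 4L else 0L

  ubp <- sprintf("UBP%03d", seq_len(spec$n_ubp))
  e3 <- sprintf("E3X%03d", seq_len(spec$n_e3))
  bg <- sprintf("BGD%03d", seq_len(spec$n_background))
  true_int <- sprintf("TRUEINT%02d", seq_len(n_true))

  # pool sizing: must cover the seed allocation; overlaps draw from the
  # pooled union so only the union size constrains them
  seed_alloc <- allocate_decreasing(spec$seed_substrate_count,
                                    min(3, spec$n_ubp),
                                    .Machine$integer.max)
  pool_size <- max(spec$pool_size,
                   if (length(seed_alloc)) max(seed_alloc) else 0L)
  pools <- lapply(seq_len(spec$n_ubp), function(u)
    sprintf("INT%03dP%02d", u, seq_len(pool_size)))
  pool_union <- unlist(pools)

  if (spec$n_e3 > 0 && any(spec$planted_e3_overlap > length(pool_union)))
    stop("planted overlap exceeds the pooled UBP interactors")

  edges <- list()
  add_edges <- function(a, b) edges[[length(edges) + 1L]] <<- cbind(a, b)
  if (spec$n_ubp > 0) add_edges("UB", ubp)
  for (u in seq_len(spec$n_ubp)) add_edges(ubp[u], pools[[u]])
  # background chain keeps background nodes non-isolated
  if (spec$n_background > 1)
    add_edges(bg[-spec$n_background], bg[-1])

  # E3 substrate sets: planted overlap drawn from the pooled interactors
  # plus two private substrates each (in-graph, hanging off background)
  substrates <- list()
  for (j in seq_len(spec$n_e3)) {
    ov <- spec$planted_e3_overlap[j]
    shared <- if (ov > 0) sample(pool_union, ov) else character(0)
    priv <- sprintf("SUB%03dP%d", j, 1:2)
    substrates[[e3[j]]] <- c(shared, priv)
    if (spec$n_background > 0)
      add_edges(priv, sample(bg, 2, replace = TRUE))
  }

  seed_id <- NULL
  seed_truth <- NULL
  if (spec$seed_substrate_count > 0 && spec$n_ubp > 0) {
    seed_id <- "SEEDE3"
    seed_subs <- unlist(lapply(seq_along(seed_alloc), function(u)
      pools[[u]][seq_len(seed_alloc[u])]))
    substrates[[seed_id]] <- seed_subs
    # planted true interactors: wired to every top UBP so recurrence
    # ranks them above ordinary single-pool interactors
    k_top <- length(seed_alloc)
    for (t in true_int) add_edges(ubp[seq_len(k_top)], t)
    seed_scores <- numeric(spec$n_ubp)
    seed_scores[seq_along(seed_alloc)] <- seed_alloc
    seed_truth <- list(
      ubp_ranking = ranked_list(ubp, seed_scores),
      interactors = sort(true_int),
      top_k = k_top
    )
  }

  edge_mat <- do.call(rbind, edges)
  if (is.null(edge_mat)) edge_mat <- matrix(character(0), ncol = 2)
  all_nodes <- unique(c("UB", ubp, pool_union, bg, true_int,
                        unlist(substrates), as.vector(edge_mat)))

  if (spec$edge_noise > 0 && length(all_nodes) > 1) {
    pairs <- utils::combn(all_nodes, 2)
    pick <- stats::runif(ncol(pairs)) < spec$edge_noise
    if (any(pick)) edge_mat <- rbind(edge_mat, t(pairs[, pick, drop = FALSE]))
  }

  net <- ppi_network(edge_mat, nodes = all_nodes)
  ann <- annotation_sets(ubp_ids = ubp,
                         e3_ids = c(e3, seed_id),
                         substrates = substrates)
  truth <- list(
    e3_ranking = if (spec$n_e3 > 0)
      ranked_list(e3, as.numeric(spec$planted_e3_overlap))
    else ranked_list(character(0), numeric(0)),
    seed = seed_id,
    seed_ubp_ranking = seed_truth$ubp_ranking,
    seed_interactors = seed_truth$interactors,
    seed_top_k = seed_truth$top_k
  )
  list(network = net, annotations = ann, truth = truth)
}

#' Write a generated network to TSV files
#'
#' Writes `<prefix>_edges.tsv` (two ID columns), `<prefix>_ubp.tsv`,
#' `<prefix>_e3.tsv`, `<prefix>_substrates.tsv` (e3_id, substrate_id)
#' and `<prefix>_truth.tsv` (the planted E3 ranking).
#'
#' @param sim Output of [generate_network()].
#' @param prefix Path prefix.
#' @param seed Seed recorded in provenance headers.
#' @return Character vector of the files written, invisibly.
#' @export
write_network_tsv <- function(sim, prefix, seed = NULL) {
  el <- igraph::as_edgelist(sim$network$graph)
  files <- c(
    edges = paste0(prefix, "_edges.tsv"),
    ubp = paste0(prefix, "_ubp.tsv"),
    e3 = paste0(prefix, "_e3.tsv"),
    substrates = paste0(prefix, "_substrates.tsv"),
    truth = paste0(prefix, "_truth.tsv")
  )
  write_tsv(data.frame(a = el[, 1], b = el[, 2]), files["edges"], seed,
            col_names = FALSE)
  write_tsv(data.frame(id = sim$annotations$ubp_ids), files["ubp"], seed)
  write_tsv(data.frame(id = sim$annotations$e3_ids), files["e3"], seed)
  subs <- sim$annotations$substrates
  write_tsv(data.frame(
    e3_id = rep(names(subs), lengths(subs)),
    substrate_id = unlist(subs, use.names = FALSE)), files["substrates"], seed)
  write_tsv(as.data.frame(sim$truth$e3_ranking), files["truth"], seed)
  invisible(files)
}
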