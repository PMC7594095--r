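toy_path <- function(f) system.file("extdata", f, package = "plastnet")

toy_net <- function() load_network(toy_path("toy_ppi_edges.tsv"))

toy_ann <- function(loc = FALSE) {
  load_annotation_sets(toy_path("toy_ubp.tsv"), toy_path("toy_e3.tsv"),
                       toy_path("toy_substrates.tsv"),
                       if (loc) toy_path("toy_localization.tsv"))
}

test_that("edge lists are canonicalized: self-loops and duplicates go", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "B\tA", "B\tB"), f)
  net <- load_network(f)
  expect_equal(igraph::ecount(net$graph), 1)
  expect_equal(net$self_loops_dropped, 1)
  expect_setequal(igraph::V(net$graph)$name, c("A", "B"))
  # IDs are trimmed and uppercased
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(" a \tb", "B\ta"), f2)
  expect_equal(igraph::ecount(load_network(f2)$graph), 1)
})

test_that("empty and malformed edge files are handled", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), f)
  empty <- load_network(f)
  expect_equal(igraph::vcount(empty$graph), 0)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "LONELY"), f2)
  expect_error(load_network(f2), "line 2")
})

test_that("the toy network matches hand counts", {
  net <- toy_net()
  expect_equal(igraph::vcount(net$graph), 8)  # UB, UBP1-2, S1, S2, C1, C3, T1
  expect_equal(igraph::ecount(net$graph), 9)
  expect_setequal(interactors(net, "UBP1"), c("C1", "S1", "S2", "UB"))
  expect_setequal(interactors(net, "UBP2"), c("C1", "C3", "S2", "UB"))
  expect_warning(out <- interactors(net, "NOPE"), "not in network")
  expect_identical(out, character(0))
})

test_that("connectivity degree counts common interactors by hand", {
  net <- toy_net()
  ann <- toy_ann()
  rk <- e3_connectivity_degree(net, ann)
  df <- as.data.frame(rk)
  # E3A substrates {S1,S2,S3} vs UBP interactor union {C1,C3,S1,S2,UB} -> 2
  expect_equal(df$score[df$id == "E3A"], 2)
  expect_equal(df$score[df$id == "E3B"], 0)  # disjoint
  expect_equal(attr(rk, "n_positive"), 1)
  # sum mode counts (UBP, protein) pairs: S1 once, S2 twice -> 3
  rk_sum <- e3_connectivity_degree(net, ann, mode = "sum")
  expect_equal(as.data.frame(rk_sum)$score[rk_sum$id == "E3A"], 3)
})

test_that("seed-UBP ranking counts shared interactors by hand", {
  net <- toy_net()
  ann <- toy_ann()
  rk <- rank_ubps_for_seed(net, ann, "E3A")
  expect_equal(rk$id, c("UBP1", "UBP2"))
  expect_equal(rk$score, c(2, 1))  # {S1,S2} vs {S2}
  expect_error(rank_ubps_for_seed(net, ann, "E3B2"), "no recorded substrates")
})

test_that("interactor prediction scores candidates by recurrence", {
  net <- toy_net()
  ann <- toy_ann()
  pred <- predict_interactors(net, ann, "E3A", top_k = 2, exclude = "UB")
  # candidates after removing substrates, seed, UB: C1 (both UBPs), C3 (one)
  expect_equal(pred$id, c("C1", "C3"))
  expect_equal(pred$score, c(2, 1))
  expect_warning(predict_interactors(net, ann, "E3A", top_k = 10,
                                     exclude = "UB"), "clipped")
  # localization refinement keeps only compartment-sharing candidates
  pred_loc <- predict_interactors(net, toy_ann(loc = TRUE), "E3A",
                                  top_k = 2, localization_filter = TRUE,
                                  exclude = "UB")
  expect_equal(pred_loc$id, "C1")
})

test_that("prediction of only-substrate interactors yields an empty list", {
  net <- ppi_network(rbind(c("UBP1", "S1"), c("E3Q", "S1")))
  ann <- annotation_sets("UBP1", "E3Q", list(E3Q = c("S1", "E3Q2")))
  pred <- predict_interactors(net, ann, "E3Q", top_k = 1, exclude = "E3Q")
  expect_equal(nrow(pred), 0)
})

test_that("L3 score matches hand evaluation on a path graph", {
  net <- ppi_network(rbind(c("X", "A"), c("A", "B"), c("B", "Y")))
  expect_equal(l3_score(net, "X", "Y"), 0.5)  # 1/sqrt(2*2)
  expect_equal(l3_score(net, "X", "B"), 0)    # no length-3 path
  expect_error(l3_score(net, "X", "X"), "distinct")
  expect_warning(z <- l3_score(net, "X", "NOPE"), "absent")
  expect_equal(z, 0)
})

test_that("L3 score equals brute-force enumeration and is symmetric", {
  set.seed(42)
  for (i in 1:25) {
    net <- random_test_network(15, 0.2)
    ids <- igraph::V(net$graph)$name
    pair <- sample(ids, 2)
    expect_equal(l3_score(net, pair[1], pair[2]),
                 l3_brute_force(net, pair[1], pair[2]), tolerance = 1e-12)
    expect_equal(l3_score(net, pair[1], pair[2]),
                 l3_score(net, pair[2], pair[1]), tolerance = 1e-12)
  }
})

test_that("rankings break score ties lexicographically", {
  rk <- plastnet:::ranked_list(c("ZZ", "AA", "MM"), c(1, 1, 1))
  expect_equal(rk$id, c("AA", "MM", "ZZ"))
  expect_equal(rk$rank, 1:3)
})

test_that("connectivity degree is monotone under edge addition", {
  set.seed(7)
  sim <- generate_network(net_spec(n_ubp = 4, n_e3 = 6,
                                   planted_e3_overlap = c(5, 4, 3, 2, 1, 0),
                                   seed_substrate_count = 0, seed = 7))
  base <- e3_connectivity_degree(sim$network, sim$annotations)
  # add edges from a UBP to previously unlinked substrates
  el <- igraph::as_edgelist(sim$network$graph)
  subs <- unique(unlist(sim$annotations$substrates))
  extra <- cbind("UBP001", subs[1:5])
  denser <- ppi_network(rbind(el, extra),
                        nodes = igraph::V(sim$network$graph)$name)
  more <- e3_connectivity_degree(denser, sim$annotations)
  b <- setNames(base$score, base$id)
  m <- setNames(more$score, more$id)
  expect_true(all(m[names(b)] >= b))
})
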