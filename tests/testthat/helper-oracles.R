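# Independent oracles used to cross-check the implementation. Each one
# deliberately takes a different algorithmic route from the code it
# checks.

# Horn's quaternion method for least-squares superposition: builds the
# 4x4 key matrix from the centered covariance and takes its dominant
# eigenvector, entirely avoiding the SVD route used by superpose().
quaternion_superpose_rmsd <- function(mobile, reference) {
  p <- sweep(mobile, 2, colMeans(mobile))
  q <- sweep(reference, 2, colMeans(reference))
  s <- crossprod(p, q)  # s[a, b] = sum_i p_ia * q_ib
  sxx <- s[1, 1]; sxy <- s[1, 2]; sxz <- s[1, 3]
  syx <- s[2, 1]; syy <- s[2, 2]; syz <- s[2, 3]
  szx <- s[3, 1]; szy <- s[3, 2]; szz <- s[3, 3]
  n4 <- matrix(c(
    sxx + syy + szz, syz - szy,       szx - sxz,       sxy - syx,
    syz - szy,       sxx - syy - szz, sxy + syx,       szx + sxz,
    szx - sxz,       sxy + syx,      -sxx + syy - szz, syz + szy,
    sxy - syx,       szx + sxz,       syz + szy,      -sxx - syy + szz
  ), 4, 4, byrow = TRUE)
  lambda <- max(eigen(n4, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(p^2) + sum(q^2) - 2 * lambda) / nrow(p)
  sqrt(max(0, msd))
}

# Brute-force L3 score: explicit enumeration of every ordered
# intermediate pair over the adjacency matrix.
l3_brute_force <- function(net, x, y) {
  g <- net$graph
  a <- as.matrix(igraph::as_adjacency_matrix(g))
  nodes <- rownames(a)
  deg <- rowSums(a)
  total <- 0
  for (u in nodes) {
    if (a[x, u] == 0) next
    for (v in nodes) {
      if (a[u, v] == 1 && a[v, y] == 1) {
        total <- total + 1 / sqrt(deg[[u]] * deg[[v]])
      }
    }
  }
  total
}

# Erdos-Renyi style random network over letter-number IDs.
random_test_network <- function(n_nodes = 30, p_edge = 0.15) {
  ids <- sprintf("P%02d", seq_len(n_nodes))
  pairs <- t(combn(ids, 2))
  keep <- runif(nrow(pairs)) < p_edge
  ppi_network(pairs[keep, , drop = FALSE], nodes = ids)
}

# Closed-form exposed area of two equal intersecting spheres of radius r
# at center separation d < 2r: each sphere loses a cap of height
# h = r - d/2, area 2*pi*r*h.
two_sphere_exposed_area <- function(r, d) {
  h <- r - d / 2
  2 * (4 * pi * r^2 - 2 * pi * r * h)
}

# Random rigid transform applied to an atoms x 3 matrix.
apply_random_rigid <- function(x) {
  rot <- plastnet:::random_rotation()
  tr <- runif(3, -10, 10)
  sweep(x %*% t(rot), 2, tr, "+")
}

# Compare two rankings on their substance (order, ids, scores), ignoring
# bookkeeping attributes.
expect_same_ranking <- function(actual, expected) {
  expect_equal(actual$rank, expected$rank)
  expect_equal(actual$id, expected$id)
  expect_equal(actual$score, expected$score)
}
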