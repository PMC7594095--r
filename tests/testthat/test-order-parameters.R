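make_series <- function(vectors, dt = 1) {
  bond_vector_series(vectors, seq_len(dim(vectors)[2]),
                     (seq_len(dim(vectors)[1]) - 1) * dt)
}

test_that("NH extraction round-trips the generator's stored vectors", {
  tr <- generate_trajectory(traj_spec(6, 100, cone_angle = 25, seed = 3))
  bv <- extract_nh_vectors(tr, superpose = FALSE)
  expect_true(max(abs(bv$vectors - attr(tr, "truth")$nh_vectors)) < 1e-9)
})

test_that("superposed extraction removes global tumbling", {
  # same seed with and without rigid motion yields identical cone draws;
  # after tumbling removal the fitted vectors differ from the reference
  # ones only by the fixed rotation of the reference frame, to which S2
  # and the P2 correlation are invariant
  bv_ref <- extract_nh_vectors(
    generate_trajectory(traj_spec(8, 300, cone_angle = 30, seed = 5)),
    superpose = FALSE)
  bv_fit <- extract_nh_vectors(
    generate_trajectory(traj_spec(8, 300, cone_angle = 30,
                                  rigid_motion = TRUE, seed = 5)),
    superpose = TRUE)
  s2_ref <- s2_profile(bv_ref, window_length = 100)
  s2_fit <- s2_profile(bv_fit, window_length = 100)
  expect_equal(s2_fit$value, s2_ref$value, tolerance = 1e-9)
  cf_ref <- correlation_p2(bv_ref, 4, window_length = 300)[[1]]
  cf_fit <- correlation_p2(bv_fit, 4, window_length = 300)[[1]]
  expect_equal(cf_fit$value, cf_ref$value, tolerance = 1e-9)
  # without tumbling removal the apparent S2 is destroyed
  bv_raw <- extract_nh_vectors(
    generate_trajectory(traj_spec(8, 300, cone_angle = 30,
                                  rigid_motion = TRUE, seed = 5)),
    superpose = FALSE)
  s2_raw <- s2_profile(bv_raw, window_length = 100)
  expect_true(all(s2_raw$value < s2_ref$value - 0.2))
})

test_that("proline-masked residues are flagged and excluded from S2", {
  tr <- generate_trajectory(traj_spec(5, 200, cone_angle = 20,
                                      nh_missing = 2, seed = 4))
  bv <- extract_nh_vectors(tr, superpose = FALSE)
  expect_true(bv$missing[2])
  expect_error(correlation_p2(bv, 2, 100), "no NH vector")
  prof <- s2_profile(bv, window_length = 100)
  expect_false(2 %in% prof$residue_id)
  expect_equal(prof$residue_id, c(1, 3, 4, 5))
})

test_that("a hand-built NH pair normalizes to the unit z vector", {
  coords <- array(0, c(2, 2, 3))
  coords[, 2, 3] <- 1.01  # H straight above N
  atoms <- data.frame(elety = c("N", "H"), resno = 1, resid = "ALA",
                      element = c("N", "H"))
  tr <- trajectory(coords, atoms)
  bv <- extract_nh_vectors(tr, superpose = FALSE)
  expect_equal(bv$vectors[1, 1, ], c(0, 0, 1), tolerance = 1e-12)
})

test_that("P2 correlation is 1 for static vectors at every lag", {
  v <- array(rep(c(0, 0, 1), each = 40), c(40, 1, 3))
  cf <- correlation_p2(make_series(v), 1, window_length = 20)
  expect_equal(length(cf), 2)  # two non-overlapping windows
  for (w in cf) {
    expect_equal(w$value, rep(1, nrow(w)), tolerance = 1e-9)
    expect_equal(w$value[1], 1, tolerance = 1e-12)  # C(0) = 1
    expect_equal(w$n_pairs, seq(20, by = -1, length.out = nrow(w)))
  }
})

test_that("alternating orthogonal vectors give P2(0) = -0.5 at odd lags", {
  n <- 60
  v <- array(NA_real_, c(n, 1, 3))
  v[seq(1, n, 2), 1, ] <- rep(c(1, 0, 0), each = length(seq(1, n, 2)))
  v[seq(2, n, 2), 1, ] <- rep(c(0, 1, 0), each = length(seq(2, n, 2)))
  cf <- correlation_p2(make_series(v), 1, window_length = n)[[1]]
  odd <- cf$lag %% 2 == 1
  expect_equal(cf$value[odd], rep(-0.5, sum(odd)), tolerance = 1e-12)
  expect_equal(cf$value[!odd], rep(1, sum(!odd)), tolerance = 1e-12)
})

test_that("isotropically resampled vectors decorrelate to zero", {
  set.seed(10)
  v <- array(NA_real_, c(10000, 1, 3))
  v[, 1, ] <- runif_sphere(10000)
  cf <- correlation_p2(make_series(v), 1, window_length = 10000,
                       max_lag = 50)[[1]]
  expect_true(all(abs(cf$value[cf$lag > 0]) < 0.02))
  prof <- s2_profile(make_series(v), window_length = 1000)
  expect_lt(abs(prof$value), 0.02)
})

test_that("direct estimator is exact for static vectors and bounded", {
  v <- array(rep(c(0.6, 0.8, 0), each = 50), c(50, 1, 3))
  prof <- s2_profile(make_series(v), window_length = 50)
  expect_equal(prof$value, 1, tolerance = 1e-12)  # exact up to round-off
  set.seed(11)
  for (i in 1:25) {
    w <- runif_sphere(sample(5:50, 1))
    s2 <- plastnet:::s2_direct_window(w)
    expect_gte(s2, 0)
    expect_lte(s2, 1)
  }
})

test_that("cone-model S2 matches the analytic value and is monotone", {
  for (ang in c(20, 60)) {
    tr <- generate_trajectory(traj_spec(2, 10000, cone_angle = ang,
                                        seed = 30 + ang))
    prof <- s2_profile(extract_nh_vectors(tr, superpose = FALSE),
                       window_length = 1000)
    expect_true(all(abs(prof$value - cone_s2(ang)) < 0.02))
  }
  # nested cones: smaller cone, larger S2
  expect_gt(cone_s2(10), cone_s2(30))
  tr_sm <- generate_trajectory(traj_spec(2, 5000, cone_angle = 15, seed = 41))
  tr_lg <- generate_trajectory(traj_spec(2, 5000, cone_angle = 45, seed = 42))
  s_sm <- s2_profile(extract_nh_vectors(tr_sm, superpose = FALSE), 1000)
  s_lg <- s2_profile(extract_nh_vectors(tr_lg, superpose = FALSE), 1000)
  expect_true(all(s_sm$value > s_lg$value))
})

test_that("direct and plateau estimators agree on cone-model data", {
  tr <- generate_trajectory(traj_spec(3, 10000, cone_angle = 35, seed = 50))
  bv <- extract_nh_vectors(tr, superpose = FALSE)
  direct <- s2_profile(bv, window_length = 1000, estimator = "direct")
  plateau <- s2_profile(bv, window_length = 1000, estimator = "plateau")
  expect_true(all(abs(direct$value - plateau$value) < 0.05))
})

test_that("S2 is invariant under one fixed global rotation of all vectors", {
  tr <- generate_trajectory(traj_spec(4, 2000, cone_angle = 40, seed = 60))
  bv <- extract_nh_vectors(tr, superpose = FALSE)
  set.seed(61)
  rot <- plastnet:::random_rotation()
  rotated <- bv$vectors
  for (k in seq_len(dim(rotated)[2]))
    rotated[, k, ] <- rotated[, k, ] %*% t(rot)
  bv_rot <- make_series(rotated)
  p1 <- s2_profile(bv, window_length = 500)
  p2_ <- s2_profile(bv_rot, window_length = 500)
  expect_equal(p2_$value, p1$value, tolerance = 1e-9)
})

test_that("window counting follows the floor rule", {
  expect_identical(window_count(150, 5), 30L)
  expect_identical(window_count(5, 5), 1L)
  expect_warning(n0 <- window_count(4, 5), "0 windows")
  expect_identical(n0, 0L)
  expect_error(window_count(-1, 5), "> 0")
})

test_that("replicate merging reports mean and standard error", {
  p <- function(vals) residue_profile(1:2, vals)
  one <- replicate_merge(list(p(c(0.8, 0.6))))
  expect_equal(one$se, c(0, 0))
  expect_false(attr(one, "se_defined"))
  four <- replicate_merge(rep(list(p(c(0.8, 0.8))), 4))
  expect_equal(four$mean, c(0.8, 0.8))
  expect_equal(four$se, c(0, 0))
  two <- replicate_merge(list(p(c(0.6, 0.6)), p(c(0.8, 0.8))))
  expect_equal(two$mean, c(0.7, 0.7))
  expect_equal(two$se, c(0.1, 0.1))  # sd/sqrt(2) = 0.1414.../1.414...
  expect_error(replicate_merge(list(p(c(1, 1)), residue_profile(2:3, c(1, 1)))),
               "identical residue ids")
})
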