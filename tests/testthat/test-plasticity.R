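prof <- function(ids, vals) residue_profile(ids, vals, metric = "RMSF",
                                            units = "Angstrom")

test_that("comparing a profile with itself flags nothing", {
  a <- prof(1:10, runif(10))
  cmp <- compare_profiles(a, a, tau = 0.1)
  expect_true(all(cmp$delta == 0))
  expect_true(all(cmp$flag == "unchanged"))
})

test_that("a constant shift is flagged uniformly with the right mean", {
  a <- prof(1:20, rep(1, 20))
  b <- prof(1:20, rep(1.5, 20))
  cmp <- compare_profiles(a, b, tau = 0.1)
  expect_true(all(cmp$flag == "increased"))
  expect_equal(attr(cmp, "summary")$mean_delta, 0.5)
  expect_equal(attr(cmp, "summary")$fraction_increased, 1)
})

test_that("comparison is antisymmetric and restricted to the overlap", {
  a <- prof(1:15, runif(15))
  b <- prof(6:20, runif(15))
  ab <- compare_profiles(a, b)
  ba <- compare_profiles(b, a)
  expect_equal(ab$residue_id, 6:15)
  expect_equal(ab$delta, -ba$delta)
  expect_error(compare_profiles(prof(1:5, 1:5), prof(6:9, 6:9)),
               "share no residues")
})

test_that("a planted rigidified stretch is flagged with zero false flags", {
  sigma_a <- rep(0.8, 40)
  sigma_b <- sigma_a
  sigma_b[10:20] <- 0.3
  a <- rmsf(generate_trajectory(traj_spec(40, 3000, sigma = sigma_a,
                                          seed = 70)))
  b <- rmsf(generate_trajectory(traj_spec(40, 3000, sigma = sigma_b,
                                          seed = 71)))
  tau <- 0.3 * sqrt(3) / 2
  cmp <- compare_profiles(a, b, tau = tau,
                          regions = list(stretch = c(10, 20)))
  expect_identical(cmp$residue_id[cmp$flag == "decreased"], 10:20)
  expect_false(any(cmp$flag == "increased"))
  rg <- attr(cmp, "regions")$stretch
  expect_equal(rg$n_decreased, 11)
  expect_lt(rg$mean_delta, -tau)
})

test_that("profile agreement reports RMS deviation and a verdict", {
  a <- prof(1:10, seq(0.5, 0.9, length.out = 10))
  self <- profile_agreement(a, a)
  expect_equal(self$rms, 0)
  expect_equal(self$verdict, "pass")
  shifted <- prof(1:10, a$value + 0.2)
  agr <- profile_agreement(shifted, a, tolerance = 0.1)
  expect_equal(agr$rms, 0.2, tolerance = 1e-12)
  expect_equal(agr$verdict, "fail")
  expect_equal(agr$per_residue$abs_delta, rep(0.2, 10), tolerance = 1e-12)
})

test_that("cone-model S2 agrees with its analytic truth profile", {
  angles <- seq(15, 60, length.out = 6)
  tr <- generate_trajectory(traj_spec(6, 30000, cone_angle = angles,
                                      seed = 80))
  sim <- s2_profile(extract_nh_vectors(tr, superpose = FALSE),
                    window_length = 1000)
  truth <- residue_profile(1:6, cone_s2(angles), metric = "S2")
  agr <- profile_agreement(sim, truth, tolerance = 0.1)
  expect_lt(agr$rms, 0.03)
  expect_equal(agr$verdict, "pass")
})

test_that("scalar benchmarking applies the z * SE rule monotonically", {
  runs <- list(ff = list(rg = c(10, 10, 10, 10)))
  exact <- benchmark_forcefield(runs, list(rg = 10))
  expect_equal(exact$verdict, "pass")
  # mean = ref + 3 * SE must fail at z = 2 but pass at z = 4
  vals <- c(9.9, 10.1, 10.0, 10.2)
  off <- mean(vals) - 3 * sd(vals) / 2  # reference 3 SE below the mean
  runs2 <- list(ff = list(rg = vals))
  expect_equal(benchmark_forcefield(runs2, list(rg = off), z = 2)$verdict,
               "fail")
  expect_equal(benchmark_forcefield(runs2, list(rg = off), z = 4)$verdict,
               "pass")
  expect_warning(benchmark_forcefield(runs, list(other = 1)),
                 "no reference")
})

test_that("a planted force-field benchmark separates good from bad", {
  # three synthetic "force fields": two at the reference cone angle, one
  # too wide; judged against the analytic 30-degree S2 profile
  ref_profile <- residue_profile(1:4, rep(cone_s2(30), 4), metric = "S2")
  make_ff <- function(angle, seed) {
    lapply(1:2, function(r) {
      tr <- generate_trajectory(traj_spec(4, 5000, cone_angle = angle,
                                          seed = seed + r))
      s2_profile(extract_nh_vectors(tr, superpose = FALSE),
                 window_length = 1000)
    })
  }
  runs <- list(ff_a = list(s2 = make_ff(30, 100)),
               ff_b = list(s2 = make_ff(30, 200)),
               ff_c = list(s2 = make_ff(50, 300)))
  res <- benchmark_forcefield(runs, list(s2 = ref_profile),
                              profile_tolerance = 0.05)
  verdicts <- setNames(res$verdict, res$force_field)
  expect_equal(verdicts[["ff_a"]], "pass")
  expect_equal(verdicts[["ff_b"]], "pass")
  expect_equal(verdicts[["ff_c"]], "fail")
})
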