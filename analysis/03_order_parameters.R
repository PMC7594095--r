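#!/usr/bin/env Rscript
# NH bond-vector order parameters per state (windowed direct estimator),
# plus the force-field benchmark: replicate runs per parameter set
# merged and judged against the analytic reference S2 profile.

source(file.path("analysis", "00_config.R"))
dir.create(file.path(RESULTS, "order_parameters"), showWarnings = FALSE,
           recursive = TRUE)
out <- function(f) file.path(RESULTS, "order_parameters", f)

specs <- state_specs()
for (state in names(specs)) {
  tr <- generate_trajectory(specs[[state]])
  bv <- extract_nh_vectors(tr)   # tumbling removed by superposition
  prof <- s2_profile(bv, window_length = WINDOW_PS)
  write_profile_tsv(prof, out(paste0("s2_", state, ".tsv")),
                    seed = specs[[state]]$seed,
                    params = list(window_ps = WINDOW_PS,
                                  estimator = "direct"))
  truth <- attr(tr, "truth")$s2
  message(sprintf("%-13s mean S2 %.3f (true %.3f), max |err| %.3f over %d windows",
                  state, mean(prof$value), mean(truth),
                  max(abs(prof$value - truth)),
                  unique(prof$n_windows)))
}

# force-field benchmark: replicates per parameter set vs the reference
ref_profile <- residue_profile(seq_len(N_RES),
                               rep(cone_s2(FF_REFERENCE_CONE), N_RES),
                               metric = "S2")
runs <- lapply(seq_along(FF_CONES), function(i) {
  reps <- lapply(seq_len(FF_REPLICATES), function(r) {
    tr <- generate_trajectory(traj_spec(
      N_RES, N_FRAMES, dt = DT_PS, cone_angle = FF_CONES[i],
      rigid_motion = TRUE, seed = SEED + 100L + 10L * i + r))
    s2_profile(extract_nh_vectors(tr), window_length = WINDOW_PS)
  })
  merged <- replicate_merge(reps)
  write_tsv(merged, out(paste0("s2_replicates_", names(FF_CONES)[i], ".tsv")),
            seed = SEED)
  list(s2 = reps)
})
names(runs) <- names(FF_CONES)

bench <- benchmark_forcefield(runs, list(s2 = ref_profile),
                              profile_tolerance = 0.05)
write_tsv(bench, out("forcefield_benchmark.tsv"), seed = SEED,
          params = list(profile_tolerance = 0.05))
for (i in seq_len(nrow(bench))) {
  message(sprintf("%-9s S2 profile RMS deviation %.4f -> %s",
                  bench$force_field[i], bench$mean[i], bench$verdict[i]))
}
message("parameter sets matching the reference cone pass; the over-mobile one fails")
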