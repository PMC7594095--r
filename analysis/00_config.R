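# Shared configuration for the analysis drivers. Each driver is
# standalone: trajectories are cheap to regenerate deterministically from
# these specs, so large intermediates are never written to disk.

library(plastnet)

SEED <- 20201019L
N_RES <- 40L
N_FRAMES <- 1500L   # frames per state at dt = 5 ps (7.5 ns span)
DT_PS <- 5
WINDOW_PS <- 1500   # analysis window (ps): 5 windows per 7.5 ns run
RESULTS <- file.path("results")

# residue stretches of interest: the binding-interface stretch that
# rigidifies in the catalytic assembly, and the helix behind it
REGIONS <- list(interface = c(10, 20), helix = c(21, 28))

# Three simulated states of the same chain. The catalytic complex
# rigidifies the interface stretch (lower positional noise, narrower NH
# cones); the non-catalytic complex mobilizes the whole chain.
state_specs <- function() {
  sigma_free <- rep(0.8, N_RES)
  cone_free <- rep(35, N_RES)

  sigma_cat <- sigma_free
  sigma_cat[REGIONS$interface[1]:REGIONS$interface[2]] <- 0.3
  sigma_cat[REGIONS$helix[1]:REGIONS$helix[2]] <- 0.5
  cone_cat <- cone_free
  cone_cat[REGIONS$interface[1]:REGIONS$interface[2]] <- 15

  sigma_non <- sigma_free * 1.4
  cone_non <- pmin(cone_free * 1.4, 90)

  list(
    free = traj_spec(N_RES, N_FRAMES, dt = DT_PS, sigma = sigma_free,
                     cone_angle = cone_free, rigid_motion = TRUE,
                     seed = SEED),
    catalytic = traj_spec(N_RES, N_FRAMES, dt = DT_PS, sigma = sigma_cat,
                          cone_angle = cone_cat, rigid_motion = TRUE,
                          seed = SEED + 1L),
    noncatalytic = traj_spec(N_RES, N_FRAMES, dt = DT_PS, sigma = sigma_non,
                             cone_angle = cone_non, rigid_motion = TRUE,
                             seed = SEED + 2L)
  )
}

# Force-field emulation for the benchmarking arm: two parameter sets
# reproduce the reference NH cone, one is systematically too mobile.
# Four replicates each, mirroring repeat production runs.
FF_CONES <- c(ff_alpha = 25, ff_beta = 25, ff_gamma = 45)
FF_REFERENCE_CONE <- 25
FF_REPLICATES <- 4L

net_config <- function() {
  net_spec(n_ubp = 8, n_e3 = 12, n_background = 25,
           planted_e3_overlap = 12:1, seed_substrate_count = 6,
           edge_noise = 0, seed = SEED)
}
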