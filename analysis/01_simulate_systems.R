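#!/usr/bin/env Rscript
# Simulate the study systems: three conformational states of one chain
# with analytic ground truth, and a planted ubiquitin interaction
# network. Writes ground-truth sidecars, a small multi-model PDB
# exemplar, and the network TSVs consumed by 05_network_inference.R.

source(file.path("analysis", "00_config.R"))
dir.create(file.path(RESULTS, "sim"), showWarnings = FALSE, recursive = TRUE)

specs <- state_specs()
for (state in names(specs)) {
  tr <- generate_trajectory(specs[[state]])
  truth <- attr(tr, "truth")
  write_tsv(data.frame(residue_id = seq_len(N_RES),
                       rmsf_true = truth$rmsf, s2_true = truth$s2),
            file.path(RESULTS, "sim", paste0("truth_", state, ".tsv")),
            seed = specs[[state]]$seed)
  message(sprintf("%-13s %d frames, mean true RMSF %.3f A, mean true S2 %.3f",
                  state, n_frames(tr), mean(truth$rmsf), mean(truth$s2)))
}

# small exemplar of the on-disk trajectory format (first 25 frames)
ex <- generate_trajectory(traj_spec(N_RES, 25, dt = DT_PS,
                                    sigma = 0.8, cone_angle = 35,
                                    rigid_motion = TRUE, seed = SEED))
write_trajectory_pdb(ex, file.path(RESULTS, "sim", "exemplar_free_25f.pdb"))
message("wrote multi-model PDB exemplar (25 frames)")

sim <- generate_network(net_config())
files <- write_network_tsv(sim, file.path(RESULTS, "sim", "ubnet"),
                           seed = SEED)
message(sprintf("network: %d proteins, %d interactions; %d E3s with planted overlap, seed ligase '%s'",
                igraph::vcount(sim$network$graph),
                igraph::ecount(sim$network$graph),
                nrow(sim$truth$e3_ranking), sim$truth$seed))
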