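#!/usr/bin/env Rscript
# Plasticity contrasts between states: per-residue RMSF and S2 deltas
# with change flags, region summaries over the interface and helix
# stretches, and a short markdown report.

source(file.path("analysis", "00_config.R"))
dir.create(file.path(RESULTS, "plasticity"), showWarnings = FALSE,
           recursive = TRUE)
out <- function(f) file.path(RESULTS, "plasticity", f)

specs <- state_specs()
profs <- list(); s2s <- list()
for (state in names(specs)) {
  tr <- generate_trajectory(specs[[state]])
  profs[[state]] <- rmsf(tr)
  s2s[[state]] <- s2_profile(extract_nh_vectors(tr),
                             window_length = WINDOW_PS)
}

TAU_RMSF <- 0.1
TAU_S2 <- 0.05
pairs <- list(
  free_vs_catalytic = c("free", "catalytic"),
  free_vs_noncatalytic = c("free", "noncatalytic")
)

report <- c("# Plasticity contrasts", "",
            sprintf("RMSF flag threshold tau = %.2f A; S2 threshold %.2f.",
                    TAU_RMSF, TAU_S2), "")
for (nm in names(pairs)) {
  a <- pairs[[nm]][1]; b <- pairs[[nm]][2]
  cmp <- compare_profiles(profs[[a]], profs[[b]], tau = TAU_RMSF,
                          regions = REGIONS)
  write_tsv(as.data.frame(cmp), out(paste0("rmsf_", nm, ".tsv")),
            seed = SEED, params = list(tau = TAU_RMSF))
  cmp_s2 <- compare_profiles(s2s[[a]], s2s[[b]], tau = TAU_S2)
  write_tsv(as.data.frame(cmp_s2), out(paste0("s2_", nm, ".tsv")),
            seed = SEED, params = list(tau = TAU_S2))
  sm <- attr(cmp, "summary")
  rg <- attr(cmp, "regions")
  report <- c(report, sprintf("## %s", nm), "",
              sprintf("- mean RMSF delta %.3f A; %.0f%% of residues decreased, %.0f%% increased",
                      sm$mean_delta, 100 * sm$fraction_decreased,
                      100 * sm$fraction_increased),
              sprintf("- interface (%d-%d): mean delta %.3f A, %d residues decreased",
                      REGIONS$interface[1], REGIONS$interface[2],
                      rg$interface$mean_delta, rg$interface$n_decreased),
              sprintf("- helix (%d-%d): mean delta %.3f A, %d residues decreased",
                      REGIONS$helix[1], REGIONS$helix[2],
                      rg$helix$mean_delta, rg$helix$n_decreased),
              sprintf("- S2 flags: %d residues increased S2 (rigidified), %d decreased",
                      sum(cmp_s2$flag == "increased"),
                      sum(cmp_s2$flag == "decreased")), "")
  message(sprintf("%s: interface mean RMSF delta %.3f A (%d decreased), whole-chain mean %.3f A",
                  nm, rg$interface$mean_delta, rg$interface$n_decreased,
                  sm$mean_delta))
}

writeLines(report, out("report.md"))
message("wrote ", out("report.md"))
message("expected pattern: interface rigidifies in the catalytic complex; the whole chain mobilizes in the non-catalytic one")
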