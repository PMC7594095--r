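# plastnet

Conformational plasticity metrics for molecular-dynamics trajectories
and shared-interactor link inference for ubiquitin-pathway protein
networks, built as one tested R pipeline.

## What it is for

E3 RING ligases catalyze the final transfer of ubiquitin (Ub) onto
substrates. Two questions about them recur: *structurally*, how does
complex formation change the flexibility of a RING domain and its
partners (a rigidified binding interface is a signature of a catalytic
assembly), and *systemically*, which other E3 ligases are likely to
bind ubiquitin, and which new interactors a given ligase might have.
This package serves researchers who work on both fronts:

* The **structural arm** computes per-residue flexibility and shape
  observables from trajectories: Kabsch superposition and RMSD,
  two-pass RMSF, radius of gyration, end-to-end distance,
  Shrake–Rupley SASA, and Lipari–Szabo generalized order parameters
  S² of backbone NH bond vectors from windowed P2 autocorrelation —
  with replicate merging, state-vs-state comparison, and force-field
  benchmarking against a reference profile by the |mean − ref| ≤ z·SE
  rule.
* The **network arm** implements the ℓ = 3 reasoning over a
  protein–protein interaction graph: the degree-normalized length-3
  path score p(x,y) = Σ 1/√(kᵤ·kᵥ), connectivity-degree ranking of E3
  ligases by substrates shared with Ub-binding-protein interactors,
  and recurrence-ranked interactor prediction for a seed ligase.

Synthetic generators with closed-form ground truth make every stage
testable: NH vectors diffusing in a cone of semi-angle θ₀ have exactly
S² = [cos θ₀ (1 + cos θ₀)/2]², Gaussian positional noise σ gives RMSF
= σ√3, and planted interaction networks have known recoverable
rankings.

## Worked example

```r
library(plastnet)

## structural arm: trajectory with known ground truth
tr <- generate_trajectory(traj_spec(n_residues = 20, n_frames = 3000, dt = 1,
                                    sigma = 0.5, cone_angle = 30,
                                    rigid_motion = TRUE, seed = 42))
prof <- rmsf(tr)                                   # two-pass fitted RMSF
s2 <- s2_profile(extract_nh_vectors(tr),           # tumbling removed
                 window_length = 1000)             # 3 windows of 1000 frames

## network arm: planted Ub-interaction network
sim <- generate_network(net_spec(n_ubp = 6, n_e3 = 8,
                                 planted_e3_overlap = 8:1,
                                 seed_substrate_count = 6, seed = 42))
rk <- e3_connectivity_degree(sim$network, sim$annotations)
pred <- predict_interactors(sim$network, sim$annotations, "SEEDE3",
                            top_k = 3, exclude = "UB")
```

This prints (via the obvious `mean`/`head` calls):

```
mean RMSF 0.821 A (analytic sigma*sqrt(3) = 0.866 A)
mean S2 0.653 (analytic cone value = 0.6529)
  rank     id score          rank        id score
1    1 E3X001     8          1    1 TRUEINT01     3
2    2 E3X002     7          2    2 TRUEINT02     3
3    3 E3X003     6          3    3 TRUEINT03     3
```

The RMSF sits a few percent below σ√3 because the superposition fit
absorbs six rigid degrees of freedom (strongest at chain termini —
see the methods vignette); the windowed S² estimate lands on the
analytic cone value; the connectivity-degree ranking recovers the
planted overlaps 8, 7, 6, … exactly; and the planted true interactors
of the seed ligase occupy the top predicted ranks with recurrence 3
(ubiquitin itself is excluded — it recurs trivially).

## The analysis workflow

Numbered drivers under `analysis/` run the full study on synthetic
systems and write tables under `results/`:

```sh
Rscript analysis/01_simulate_systems.R      # states + network, ground truth
Rscript analysis/02_structural_observables.R
Rscript analysis/03_order_parameters.R      # windowed S2 + force-field benchmark
Rscript analysis/04_plasticity_report.R     # state contrasts, region summaries
Rscript analysis/05_network_inference.R     # rankings + interactor prediction
```

`run_demo()` runs a compact version of both arms into one directory
and is byte-deterministic given a seed.

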