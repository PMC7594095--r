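---
title: "Conformational plasticity metrics and ubiquitin-network link inference: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformational plasticity metrics and ubiquitin-network link inference: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastnet)
```

This package implements two complementary analyses of E3 RING ligase
biology in one tested pipeline. The **structural arm** quantifies
per-residue conformational plasticity from molecular-dynamics-style
trajectories — RMSD after optimal superposition, RMSF, radius of
gyration, end-to-end distance, solvent-accessible surface area, and
Lipari–Szabo generalized order parameters $S^2$ of backbone NH bond
vectors — and compares states of a complex (e.g. a catalytic assembly
against a non-catalytic one) or force-field variants against a
reference profile. The **network arm** scores candidate
protein–protein interactions by degree-normalized paths of length
three in an interactome and uses shared-interactor counts to rank E3
ligases by their likelihood of binding ubiquitin and to predict new
interactors of a seed ligase.

Everything is exercised end to end on synthetic data with *analytic*
ground truth, so each estimator can be validated against a closed form
rather than against another implementation.

## The structural observables

### Superposition and RMSD

All positional observables start from least-squares rigid
superposition. `superpose()` implements the Kabsch algorithm: the
covariance of the centered selections is decomposed by SVD and the
smallest singular direction is sign-corrected so the result is always a
proper rotation (determinant $+1$), never a reflection. Selections with
fewer than three atoms, or collinear ones (second singular value below
$10^{-10}$ of scale), are rejected — the rotation is not unique there.
The test suite checks the returned RMSD against an independent
quaternion (Horn) implementation at $10^{-9}$ on a thousand random
point sets.

`rmsd_series()` reports the frame-by-frame fitted RMSD from a reference
with its mean and standard error, the usual convergence diagnostic for
a production run. Because conventions differ on what "backbone" means,
`select_backbone()` offers both N, CA, C, O (default) and N, CA, C.

### RMSF

`rmsf()` uses the two-pass protocol: frames are fitted to an initial
reference (frame 1), the mean structure of the fitted ensemble is
computed, all frames are re-fitted to that mean, and
$\mathrm{RMSF}_i = \sqrt{\langle |\mathbf{r}_i - \langle \mathbf{r}_i
\rangle|^2 \rangle}$ is taken about the final mean, by default over CA
atoms. The fit absorbs six rigid degrees of freedom, so recovered RMSF
is slightly deflated, and most strongly at the chain termini where the
rotational leverage is largest; on the synthetic benchmark (50
residues, 5000 frames, global tumbling on) interior residues recover
$\sigma\sqrt{3}$ within 5 % while terminal residues can deflate by
about 6 %. This is a property of every fitted-RMSF estimator, not of
this implementation, and is why comparisons between states (same
geometry, same bias) are more trustworthy than absolute values.

### Rg, end-to-end, SASA

`radius_of_gyration()` is mass-weighted about the center of mass;
weights default to unity because reported Rg values often are not
mass-weighted and the choice is therefore exposed rather than assumed.
`end_to_end()` is the distance between designated terminal atoms
(first/last CA by default).

`sasa()` is Shrake–Rupley: `n_points` quasi-uniform points on each
atom's solvent-expanded sphere (radius $r_i$ + probe), a point exposed
when strictly outside every other expanded sphere, per-atom area
$4\pi (r_i + p)^2$ times the exposed fraction. The lattice is a
deterministic golden-spiral (Fibonacci) construction, so results are
reproducible bit-for-bit at fixed `n_points`. Defaults: probe 1.4 Å
(water), 960 points, van der Waals radii C 1.70, N 1.55, O 1.52,
S 1.80, H 1.20, others 1.70 Å — all overridable. On the two-sphere
configuration with the analytic cap-intersection answer the error at
960 points is below 1 %. One caveat of lattice quadrature: the error
generally shrinks with `n_points` but not strictly monotonically at
every configuration, because at particular separations a coarse
lattice can cancel fortuitously; the convergence test pins the
configuration it checks.

## Order parameters

### Estimators

The NH bond vector of each residue is extracted per frame as the
normalized H−N difference. Global tumbling must be removed first —
$S^2$ measures internal motion — so `extract_nh_vectors()` superposes
every frame onto a reference (backbone N + CA fit) before taking
vectors; the synthetic tests verify that with tumbling on and removal
enabled the recovered $S^2$ equals the tumbling-free value, and that
skipping removal destroys it.

Two standard MD estimators are implemented, and their agreement is
itself a convergence check (they agree within 0.05 on cone-model data
at 1000-frame windows):

* **direct** (default): from the second-moment tensor over a window,
  $S^2 = \tfrac{3}{2} \sum_{a,b \in \{x,y,z\}} \langle \mu_a \mu_b
  \rangle^2 - \tfrac{1}{2}$. The tensor is positive semi-definite with
  unit trace, so the estimator is mathematically confined to $[0, 1]$;
  round-off excursions are clamped to that range.
* **plateau**: the mean of the orientational correlation function
  $C(t) = \langle P_2(\boldsymbol{\mu}(\tau) \cdot
  \boldsymbol{\mu}(\tau + t)) \rangle$ over the trailing 20 % of
  computed lags (lags up to half the window, multi-origin averaging
  within non-overlapping windows).

Windows are non-overlapping; the profile value is the mean over
windows and the spread the standard deviation across them. A 150 ns
production run with 5 ns windows gives 30 estimates per residue
(`window_count(150, 5)`); the bundled analysis uses 5 windows of
1.5 ns over 7.5 ns synthetic runs, which is ample for the kinetics-free
generator (see below). Residues without an amide H (prolines, termini)
are flagged missing and excluded, never interpolated.

`replicate_merge()` combines repeat runs per residue into mean and
standard error $s/\sqrt{n}$; with one replicate the SE is reported as 0
and flagged undefined.

### Comparisons and benchmarking

`compare_profiles()` takes per-residue differences over the common
residue range and flags each residue against a symmetric threshold
$\tau$: default 0.1 Å for RMSF and 0.05 for $S^2$. No community
standard exists for these thresholds, so they are configuration
values recorded in every output header rather than constants.
Region summaries (e.g. a binding-interface stretch) take explicit
residue ranges. `profile_agreement()` reduces a simulated-vs-reference
profile pair to an RMS deviation with a pass/fail verdict (default
tolerance 0.1).

`benchmark_forcefield()` operationalizes agreement "within statistical
error" as $|\bar{x} - \mathrm{ref}| \le z \cdot \mathrm{SE}$ with
$z = 2$ by default — a two-standard-error band; profile observables
are merged across replicates and judged by RMS deviation. Verdicts are
monotone in $z$ by construction.

## The synthetic trajectory generator

`generate_trajectory()` produces the ground-truth data every structural
estimator is validated against:

* CA atoms sit on a regular helix (rise 1.5 Å, radius 2.3 Å, 100° per
  residue) — arbitrary but documented, chosen only to make
  superposition nondegenerate — and fluctuate with isotropic Gaussian
  noise of per-residue $\sigma$, so the analytic RMSF is
  $\sigma\sqrt{3}$.
* NH vectors wobble uniformly (by solid angle) inside a cone of
  semi-angle $\theta_0$ about a fixed per-residue axis:
  $\cos\theta \sim U[\cos\theta_0, 1]$, $\phi \sim U[0, 2\pi)$. This
  makes the diffusion-in-a-cone closed form exact:
  $S^2 = \left[ \cos\theta_0 (1 + \cos\theta_0)/2 \right]^2$, e.g.
  0.6529 at 30°.
* Optionally every frame is rotated and translated by a random rigid
  transform (global tumbling), and proline-like residues can be
  injected without an H atom to exercise missing-vector handling.

Frames are temporally independent equilibrium samples — there are no
kinetics. That is sufficient because every implemented estimator is an
equilibrium average; it also means correlation functions decay within
one lag, which real trajectories do not do. Consequently, passing
tests demonstrate estimator correctness (formulas, windowing,
superposition, tie-handling), not that any force field reproduces
protein dynamics; solvent, thermostats, and realistic dynamics are out
of scope by design.

## The network arm

`load_network()` ingests a two-column TSV edge list into an undirected
simple graph (igraph underneath): IDs are trimmed and uppercased,
reversed duplicates collapsed, self-loops dropped and counted, and a
malformed line aborts with its line number. E3→substrate links are a
separate curated map (`annotation_sets()`), *not* edges of the PPI
graph — substrate collections are curated evidence of catalysis, not
interactome edges — though nothing prevents a caller from merging them
before `l3_score()` if desired.

Three rankings implement the length-3 reasoning:

* `e3_connectivity_degree()`: the connectivity degree of an E3 is the
  number of its substrates that are also interactors of Ub-binding
  proteins. The default `union` mode counts distinct proteins,
  $|\,\mathrm{substrates}(E3) \cap \bigcup_u \mathrm{interactors}(u)\,|$,
  because a "number of common interactors" counts proteins; a `sum`
  mode (per-UBP intersections summed, counting pairs) is provided since
  the aggregation choice is genuinely open.
* `rank_ubps_for_seed()`: UBPs scored by
  $|\,\mathrm{substrates}(\mathrm{seed}) \cap
  \mathrm{interactors}(u)\,|$.
* `predict_interactors()`: interactors of the top-$k$ UBPs (default
  $k = 5$, matching the number of UBPs typically reported per seed),
  minus the seed's substrates and the seed itself, scored by
  *recurrence* — how many of the top UBPs carry the candidate.
  Ubiquitin-family IDs can be excluded: they recur trivially and say
  nothing about new interactions. An optional localization filter
  keeps candidates sharing at least one compartment label with the
  seed; it is a pure set-overlap on a user-supplied table, never an
  online lookup.

`l3_score()` is the degree-normalized length-3 path count
$p(x, y) = \sum_{u, v} a_{xu} a_{uv} a_{vy} / \sqrt{k_u k_v}$ over
ordered intermediate pairs; the tests verify exact agreement with a
brute-force triple-loop enumeration and symmetry on random graphs.

Every ranking breaks score ties lexicographically by ID, so all
outputs are deterministic and byte-reproducible given the seed.

### The synthetic network generator

`generate_network()` plants recoverable structure: a Ub hub wired to
`n_ubp` Ub-binding proteins, a disjoint pool of interactors per UBP
(8 per UBP by default, grown automatically when requested overlaps
need more), E3s whose substrate sets contain a designed number of
pooled interactors plus two private substrates each (the private
substrates hang off background nodes so that edge noise can perturb
scores), a seed ligase whose substrates are allocated across the first
few UBP pools in strictly decreasing counts (so its UBP ranking has a
unique planted order), four "true interactor" nodes wired to all of
those top UBPs (so recurrence ranks them first), background nodes, and
optional uniform edge noise. Noise-free, all three rankings recover
the planted truth exactly; at 1 % edge noise the recovered
connectivity-degree ranking stays above 0.9 Spearman correlation with
the truth across 20 replicates (the acceptance script recomputes
this). What the generator does *not* emulate: the heavy-tailed degree
distribution, study bias, and false-positive structure of real
interactome data — planted-recovery results validate the scoring
machinery, not biological discovery rates.

## Numerical and design choices

* Ties: lexicographic by ID everywhere a ranking is produced.
* Degenerate inputs error early and specifically: < 3 or collinear
  atoms for superposition, single-frame RMSF, empty selections,
  windows longer than the trajectory, a seed ligase without
  substrates, `x = y` in `l3_score()`.
* A window longer than the span yields 0 windows with a warning, not
  an error, mirroring how a too-short production run should surface.
* "Static vector gives $S^2 = 1$" holds to round-off (the cone axis is
  a normalized double), and the direct estimator clamps to $[0, 1]$.
* Problem sizes in the bundled analysis — 40 residues, 1500 frames at
  5 ps, 5 windows; cone validation at 30 windows × 1000 frames;
  noise-recovery at 50 E3s × 20 replicates — were chosen so the whole
  workflow and test suite complete in a few minutes on one core while
  keeping every statistical margin comfortable.

## Limitations

* No kinetics in the generator: autocorrelation-time diagnostics and
  plateau detection cannot be stress-tested against slow motions.
* No Lipari–Szabo model-free fitting of relaxation rates, spectral
  densities, or anisotropic diffusion; $S^2$ is compared directly to a
  reference profile.
* No DSSP-style secondary-structure assignment; a precomputed
  assignment can be compared externally.
* The network arm performs no enrichment analysis and no live database
  retrieval; all inputs are files.
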