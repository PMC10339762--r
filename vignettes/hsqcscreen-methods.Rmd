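---
title: "Methods: protein-observed HSQC fragment screening with hsqcscreen"
author: "hsqcscreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: protein-observed HSQC fragment screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

`hsqcscreen` implements the analysis side of a protein-observed NMR
fragment screen against a small chemokine: a ~10 kDa, ~75-residue protein
is titrated or mixed with small-molecule fragments, and each sample's
2D ^1^H-^15^N HSQC fingerprint (one peak per backbone NH) reports where
and how strongly compounds bind. The package covers five stages:

1. **Data model and I/O** — Sparky-style peak lists, gridded 2D spectra
   rendered from peak lists, difference spectra.
2. **Synthetic data** — a generator that emulates the statistical
   structure the analysis assumes (fast-exchange shifts under single-site
   binding with ligand depletion, pooled mixtures, titrations, dual-ligand
   schedules, positional measurement noise), plus a packaged 2,678-fragment
   screening fixture with known ground truth.
3. **Pooled-screen triage** — difference intensity analysis (DIA), PCA,
   k-means, hit flagging and iterative 12-plex → 3-plex → single-compound
   deconvolution.
4. **Validation** — peak tracking, combined chemical shift perturbations
   (CSP), significance thresholds, sub-site assignment, dissociation
   constant fitting and binding-mode classification.
5. **Dual titrations** — shift-vector additivity as evidence that two
   fragments occupy adjoining sub-sites simultaneously.

Raw FID processing, resonance assignment, structural modelling and docking
are out of scope; the pipeline starts from processed peak positions.

## Binding model

All simulation and fitting rest on the single-site binding equilibrium
with ligand depletion. For total protein $P_T$ and total ligand $L_T$,
the bound fraction is the exact quadratic root

$$ f(L_T) \;=\; \frac{b - \sqrt{b^2 - 4 P_T L_T}}{2 P_T},
   \qquad b = P_T + L_T + K_d , $$

evaluated in the cancellation-free form $f = 2L_T/(b + \sqrt{b^2 - 4 P_T
L_T})$. Protein concentrations are given in µM and ligand/K~d~ in mM;
units are unified internally. Although the screen operates at
$L_T \gg P_T$ where $f \approx L_T/(L_T+K_d)$, the depletion form is exact
everywhere and costs nothing (`fraction_bound()`).

Under **fast exchange** a residue's peak sits at the population-weighted
average position, so its displacement from apo is $f \cdot
(\Delta\delta_H^{max}, \Delta\delta_N^{max})$, the fragment's maximal
shift scaled by occupancy. Continuous peak movement along a titration is
the experimental signature of this regime; no intermediate- or
slow-exchange broadening is modelled.

For two ligands, `solve_dual_occupancy()` solves the coupled mass
balances by a damped Newton iteration on the free ligand concentrations
(relative tolerance $10^{-12}$):

* **independent sites** — species P, PA, PB and the ternary PAB with no
  cooperativity; site occupancies $f_X = [X]/(K_X + [X])$ decouple given
  the free concentrations (the solver cross-checks against the
  single-ligand quadratic in the tests);
* **competitive** — one shared site, species P, PA, PB; $f_A =
  ([A]/K_A)/(1 + [A]/K_A + [B]/K_B)$, so each ligand suppresses the
  other's occupancy.

## Spectra

Peaks are rendered as separable 2D Gaussians, amplitude-normalised so a
peak on a grid node attains its nominal height, with default widths
(standard deviations) of 0.02 ppm (^1^H) and 0.15 ppm (^15^N). The
default display grid covers the amide region (^1^H 6–11 ppm × 512,
^15^N 100–135 ppm × 256, axes stored ascending); the pipeline's triage
rounds use a coarser 256 × 128 grid over the same region, since the
triage statistics do not require display resolution. A Gaussian rather
than Lorentzian lineshape keeps difference-spectrum lobes compact and the
tests deterministic; no lineshape information is used quantitatively.

Combined CSPs use the community-standard nitrogen weight:
$\Delta\delta = \sqrt{\Delta\delta_H^2 + (0.2\,\Delta\delta_N)^2}$,
and the same scaled space (`weight = 0.2`) is used for peak tracking
distances. Both weights are configurable.

## The synthetic screen

`make_ccl28_fixture()` builds a deterministic screen with the structure of
a real campaign against a CCL28-like chemokine:

* a pseudo-protein of 108 residues with ~75 observable NH peaks
  (N-terminus, prolines and a set of unassigned residues are absent; one
  glutamine side-chain NH is carried as an extra labelled entry),
  placed by a minimum-separation (Poisson-disk) rule in the scaled shift
  plane so the fingerprint is resolvable;
* 2,678 fragments in four commercial-style libraries (1000 + 352 + 726 +
  600), pooled into 224 consecutive 12-plexes;
* 25 active fragments: 13 specific binders with K~d~ 0.85–11 mM split
  4 / 8 / 1 between a cleft bordered by the N-loop and the short helix
  (site 1), the sulfotyrosine-recognition cleft near the β3 strand
  (site 2), and one fragment engaging both; 7 non-specific binders
  perturbing scattered surface residues; 5 pH artifacts perturbing only
  the three histidines;
* a sulfotyrosine probe (K~d~ 10 mM) whose six hotspot reporters —
  C11, K49, R50, R52, I53 and K83 — exceed 0.6 ppm combined CSP at
  100 mM, with sub-cutoff minor perturbations along the cleft.

Design choices worth spelling out:

* **Study conditions.** Protein 50 µM throughout; fragments at 500 µM in
  all pooled rounds; validation titrations 0–6 mM (7 points); sulfotyrosine
  ladder 0, 1, 5, 10, 20, 50, 75, 100 mM; dual titrations 0–3 mM into
  3 mM of the partner. Positional noise is Gaussian with sd 0.004 ppm
  (^1^H) and 0.02 ppm (^15^N) per peak and axis — about a fifth of a
  linewidth, the typical digital precision of automated peak picking.
* **Response calibration.** Each active's maximal shifts are scaled so
  that its primary-screen response is ≈ 0.046 ppm (combined, scaled) at
  its reporter residues, standardised across reporter counts
  ($\times\sqrt{6/n}$), with a floor of ≈ 0.22 ppm combined maximal
  shift; histidine protonation responses are 1.5× larger, reflecting the
  large pH sensitivity of His resonances. Because what is visible in a
  spectrum is the displacement in *linewidth* units and nitrogen-heavy
  shift directions render weaker lobes per scaled ppm, per-residue
  magnitudes are direction-compensated to a common rendered response.
  This encodes the premise that a screening hit is, by definition, a
  compound whose perturbation is visible at the screening concentration.
* **Coherent site patterns.** Within a sub-site, shift directions are
  shared across fragments (small per-fragment jitter), so site-mates
  produce correlated difference patterns — the behaviour that makes PCA
  clustering of hits by sub-site meaningful. S20 moves in opposite
  directions for the two sites, giving the dual pair direction-resolved
  shifts at the shared cleft.
* **Trackability by construction.** Every moving peak's full titration
  trajectory (its longest use across the screen, validation ladder,
  sulfotyrosine ladder and dual experiments) is chosen under a clearance
  constraint against all other peaks and trajectories, and a candidate
  fixture is accepted only after a noiseless end-to-end resolvability
  check (tracking, significance recovery, classification, site calls,
  dual verdicts). This is the synthetic analogue of an experimentalist
  choosing resolvable reporter peaks, and it makes the fixture's ground
  truth recoverable by the analysis it is meant to exercise.

What the generator does **not** emulate: exchange broadening and
line-width changes on binding, relaxation and temperature effects,
baseline/phase artifacts, chemical-structure realism, peak overlap beyond
what the placement rule allows, and intensity noise on the grid (noise
enters through peak positions only). Passing tests therefore demonstrate
the analysis logic under the stated statistical model, not robustness to
every pathology of real spectra.

## Triage

For each round the pipeline simulates one reference (DMSO-only) sample
and one sample per pool, renders all spectra, and computes difference
spectra against the reference.

* **Noise floor.** The DIA floor is calibrated from *blank* differences —
  pairs of independent noise realisations of the reference — pooled over
  three pairs, at the 99.99th percentile of |intensity|. A known-negative
  difference therefore retains essentially no above-floor intensity,
  while genuine peak displacements do.
* **DIA.** `dia_statistic()` sums |intensity| above the floor over the
  grid: a scalar measure of how much a sample deviates from the
  reference.
* **Embedding and clustering.** PCA operates on the flattened,
  floor-thresholded difference grids. Clustering uses k-means (fixed
  seed, 10 restarts) on the leading 16 components augmented with a robust
  DIA outlier score, $\max(0, \log(1+\mathrm{DIA}) - (\mathrm{median} + 2
  \cdot \mathrm{MAD}))$, scaled to the embedding: the reference cluster
  keeps the unperturbed bulk together, and strongly perturbed samples
  separate even when their particular pattern is not captured by the
  leading components. The exported `pca_embed()`/`kmeans_cluster()`
  operations default to the conventional 2-component/3-cluster display
  settings; the pipeline defaults (k = 8, 16 components) were chosen
  because, with several distinct perturbation-pattern families among
  ~200 samples, a 2-D embedding demonstrably merges whole hit families
  into the reference cluster.
* **Flagging.** A sample is flagged when it falls outside the reference
  sample's cluster *and* its DIA exceeds 3× the median DIA of the
  reference cluster. Flags are advisory: false positives in the pooled
  rounds only cost samples in the next round, where fresh noise does not
  reproduce them.
* **Deconvolution.** Fragments of flagged pools are regrouped in manifest
  order into 3-plexes, then singles.
* **Candidate gate.** A flagged single compound becomes a candidate only
  if its difference pattern is consistent with the pooled samples it was
  deconvoluted from: cosine similarity ≥ 0.3 against at least one
  ancestor pool and ≥ 0.1 against every ancestor pool. This mirrors the
  screening practice of accepting single-compound hits whose
  perturbations are consistent with the corresponding 12-plex and 3-plex
  patterns, and it is what makes the final candidate list robust: a noise
  flag is independent of its parents' patterns, a real active correlates
  with all of them.

## Validation

* **Peak tracking** (`track_peaks()`) matches peaks between conditions by
  greedy globally-nearest assignment in the scaled shift space, accepting
  pairs in ascending distance until the jump cutoff (default 0.25 ppm
  scaled); unmatched reference peaks are reported lost rather than
  force-matched. Titrations are tracked point-to-point in concentration
  order, so each step is small even when the total trajectory is long.
* **CSP profile and significance.** Per-residue shift changes between apo
  and the endpoint give combined CSPs; the significance threshold is the
  mean + 2 SD over all tracked residues (the absolute > 0.6 ppm rule is
  available separately for strong probes such as sulfotyrosine).
* **K~d~ fitting** (`fit_kd()`) fits $\Delta\delta_r(L_T) = d_{max,r}
  \cdot f(L_T; K_d)$ to combined CSP versus total ligand. In the default
  global mode one shared K~d~ is fitted across residues; the per-residue
  amplitudes are linear in the model and are profiled out analytically,
  leaving a 1-D optimisation over $\log_{10} K_d$ run from 7 log-spaced
  starts within bounds of 1 µM–1000 mM (L-BFGS-B on the profiled
  objective). The standard error comes from the curvature of the profiled
  RSS at the optimum. Estimates at a search bound are flagged poorly
  determined. A per-residue mode fits each reporter independently and
  summarises by the median.
* **Classification** (`classify_binding()`), rules in order: *pH
  artifact* when every significant residue is a histidine;
  *inconclusive* when nothing is significant or the largest perturbation
  is below an absolute 0.03 ppm detection limit (the relative mean+2SD
  threshold always marks ~2% of residues "significant" on pure noise);
  *non-specific* when the K~d~ pins at the upper bound, the top-point
  occupancy is below 0.2, or fewer than 2 significant residues fall in
  any defined sub-site; *specific* otherwise. The two-residue site
  evidence requirement exists because a single site residue can be a
  chance excursion of the relative threshold.
* **Site assignment** (`assign_site()`): "both" when each sub-site holds
  at least two significant residues, otherwise the majority site,
  otherwise unassigned. The fixture's operational site definitions
  deliberately leave the shared mid-cleft residues (S20, R21, L24, I53)
  unaffiliated, since ligands of either site perturb them.

## Dual titrations

`analyze_dual()` asks whether the two-ligand endpoint displacement equals
the vector sum of the single-ligand displacements at the same
concentrations. The two orders of addition probe the identical
thermodynamic state, so their endpoint estimates are averaged; the order
discrepancy (RMS distance between the two dual endpoints) is reported
and bounded separately. Per-residue residuals are scaled-space norms;
the aggregate is their RMS over the significant residues of either
single-ligand profile. Verdicts with the default 0.02 ppm tolerance
(≈ 5× the ^1^H positional noise): *simultaneous* when both aggregate
residual and order discrepancy are within tolerance; *competitive* when
the residual exceeds tolerance and the observed shifts are systematically
smaller than predicted (regression slope through the origin < 0.9, the
signature of occupancy suppression); *inconclusive* otherwise.

Additivity is evaluated at the endpoint only (3 mM + 3 mM). In the
independent-site model with 50 µM protein and mM ligands, the
depletion-induced coupling between sites shifts occupancies by well under
the tolerance; a dedicated noiseless test asserts (rather than assumes)
that the additivity residual is then < 10⁻⁴ ppm.

## Numerical choices and degenerate inputs

* Dual-equilibrium Newton solve: relative tolerance $10^{-12}$, damped to
  keep free concentrations non-negative, explicit error after 200 steps.
* K~d~ bounds 10⁻³–10³ mM with 7 starts; noiseless round-trips recover
  generating constants to < 0.1% relative error; a strictly linear
  response pins at the upper bound and is flagged rather than reported as
  a finite estimate.
* k-means label permutation is fixed by renumbering so cluster 1 contains
  the reference sample; PCA component signs are fixed by making each
  component's largest-magnitude loading positive.
* Degenerate inputs fail loudly: empty titrations, non-apo first points,
  non-increasing ladders, axis mismatches in difference spectra, < 5
  tracked residues for a significance threshold, < 3 shared residues for
  a profile similarity.

## Problem sizes and determinism

The packaged acceptance checks run the full 2,678-fragment screen
(224 + ~40 + ~30 samples over three rounds at the 256 × 128 triage grid),
25 validation titrations of 7 points each, 20 noisy replicates per dual
mode, and a 200-replicate K~d~ recovery study (K~d~ log-uniform in
0.1–10 mM); the whole suite completes in a few minutes on one CPU. Every
stage draws its randomness through seeds derived from a single master
seed, so a configuration determines the run byte-for-byte;
rerunning `run_pipeline()` with the same config reproduces the summary
exactly.

## Known limitations

* The generator's noise model (positional Gaussian noise only) is
  idealised; DIA floors calibrated from blank differences would need
  re-calibration for spectra with baseline or intensity noise.
* Tracking is greedy nearest-neighbour; it is reliable because the
  fixture guarantees trajectory clearance and titration steps are small,
  but crowded real spectra can defeat it and would need assignments or
  manual curation.
* The triage defaults (k, components, floor quantile, consistency gates)
  were developed against the fixture's statistical structure; on real
  screens they are starting points, and every one of them is a config
  knob.
* Classification thresholds (0.2 saturation cutoff, 0.03 ppm detection
  limit, 2-residue site evidence) operationalise qualitative criteria;
  they are not fitted quantities.
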