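# hsqcscreen

Analysis of protein-observed 2D NMR fragment screens against a small
chemokine target, plus a fully synthetic screening campaign to exercise
every stage of the analysis with known ground truth.

In fragment-based drug discovery by protein-observed NMR, a
¹⁵N-labelled protein (here a CCL28-like chemokine, ~75 observable
backbone NH peaks) is mixed with pooled chemical fragments and each
sample's ¹H-¹⁵N HSQC fingerprint is compared with a reference spectrum.
Fragments that bind shift peaks of the residues they contact; pooled hits
are deconvoluted over 12-plex → 3-plex → single-compound rounds, and
single-compound candidates are validated by titration. `hsqcscreen`
implements this pipeline end to end:

* **Triage** — difference spectra, difference intensity analysis (DIA)
  above a blank-calibrated noise floor, PCA embedding, k-means
  clustering, hit flagging and deconvolution planning, with a final
  cross-round pattern-consistency gate on single-compound candidates.
* **Chemical shift perturbation (CSP) mapping** — peak tracking across
  conditions, combined shifts `Δδ = sqrt(ΔδH² + (0.2·ΔδN)²)`, mean + 2 SD
  significance, absolute hotspot cutoffs, and binding sub-site
  assignment.
* **Affinity fitting** — single-site binding with ligand depletion,

      f = (b − sqrt(b² − 4·P_T·L_T)) / (2·P_T),   b = P_T + L_T + K_d,

  fitted globally across residues (`Δδ_r = d_max,r · f(L_T; K_d)`) with
  the per-residue amplitudes profiled out analytically, and rule-based
  classification into specific / non-specific / pH-artifact /
  inconclusive binding.
* **Dual titrations** — tests whether two fragments occupy adjoining
  sub-sites simultaneously: the two-ligand endpoint displacement should
  equal the vector sum of the single-ligand displacements, irrespective
  of the order of addition. Coupled two-ligand equilibria (independent
  sites with ternary complex, or one shared competitive site) are solved
  numerically for the simulations.
* **Synthetic data** — `make_ccl28_fixture()` builds a deterministic
  2,678-fragment screen (four commercial-style libraries) with 25 active
  compounds: 13 specific binders across two sub-sites (the
  sulfotyrosine-recognition cleft and the adjoining N-loop/helix cleft),
  7 non-specific binders and 5 histidine-only pH artifacts, plus a
  sulfotyrosine probe with six >0.6 ppm hotspot reporters.

See the methods vignette (`vignettes/hsqcscreen-methods.Rmd`) for the
models, thresholds and design decisions.

## Worked example

Simulate a validation titration of the exemplar sY-cleft fragment
(ground-truth K_d 0.85 mM) at the default noise level, fit the
dissociation constant, map the perturbed residues, and test dual binding
with the exemplar N-loop-cleft partner:

```r
library(hsqcscreen)
fixture <- make_ccl28_fixture(seed = 1L)
frag <- fixture$fragments[["SPB07625"]]
series <- simulate_titration(fixture$assignments, frag,
                             ligand_totals = c(0, 0.25, 0.5, 1, 2, 4, 6),
                             protein_conc = 50, seed = 7L)
fit <- fit_kd(series)
print(fit)
#> <kd_fit 'SPB07625'> Kd = 756 uM (stderr 0.0248) | global fit, 7 points, rss 0.00682

profile <- csp_profile(series)
sort(significant_residues(profile))
#> [1] "C11" "C54" "I53" "L24" "R21" "R52" "S20"

classify_binding(series, fit, profile, fixture$assignments,
                 fixture$site_definitions)
#> <binding_class> specific: saturable (occupancy 0.89), Kd 0.756 mM, site residues: C11, R52, C54

run_dual_experiment(fixture$assignments, frag,
                    fixture$fragments[["CC10501"]],
                    mode = "independent_sites", seed = 7L)
#> <dual_result SPB07625 + CC10501> verdict: simultaneous | residual 0.0096, order discrepancy 0.0088 (tol 0.02), slope 0.98
```

The fitted 0.76 mM is the generating 0.85 mM constant recovered from a
noisy 7-point titration (noiseless data round-trips to < 0.1%); the
significant-residue set is exactly the fragment's ground-truth reporter
set; and the dual verdict "simultaneous" reflects additive shift vectors
with an order-of-addition discrepancy below the 0.02 ppm tolerance.

The full screen is one call:

```r
report <- run_pipeline(pipeline_config(seed = 1L))
print(report)
#> <pipeline_report>
#>   fragments screened : 2678
#>   candidates         : 25 (0.93%)
#>   validated hits     : 13 | non-hits: 12
#>   site split         : site1_Nloop_helix=4 site2_sY_cleft=8 both=1 unassigned=0
#>   sY hotspots        : C11, K49, R50, R52, I53, K83
#>   dual verdict       : simultaneous (residual 0.0073)
```

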