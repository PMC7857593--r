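# tagtraj

Trajectory analysis of neutral-lipid (triacylglycerol, TAG) clustering
and binding in membrane simulations, for structural bioinformaticians and
membrane biophysicists who need the standard observables of TAG/lens
studies as tested, scriptable R functions.

TAG is sparingly soluble in phospholipid bilayers and phase-separates
into lens-like clusters above a few mol%.  Ring-shaped membrane proteins
of the seipin family — 11-subunit disks whose luminal helices carry a
TAG-avid serine (S166) — can trap TAGs and seed clusters at
concentrations that would not cluster alone.  `tagtraj` quantifies this
behavior from particle trajectories:

* **Contact occupancy** — for residue *r*, the fraction of sampled frames
  with `min distance(residue, any TAG) <= 0.5 nm`, per time window, with
  replicate mean ± SEM.
* **Clustered fraction** — the fraction of TAGs with **≥ 2** other TAGs
  within 0.5 nm (monomers and dimers count zero by construction), plus
  connected components, cluster sizes and periodic centroids.
* **Short-time diffusion** — the 2D displacement magnitudes over a lag
  Δt follow `P(Δr) = Δr/(2DΔt) · exp(−Δr²/(4DΔt))`; the MLE is closed
  form, `D̂ = Σ Δrᵢ² / (4 n Δt)`, with an exact gamma 95% CI and a KS
  fit diagnostic.  Bound/free conditioning yields the mobility contrast
  of site-bound TAG.
* **Binding kinetics** — dwell events from thresholded TAG–site
  distances, gap merging, censoring, survival curves, and a geometric
  hydrogen-bond criterion (0.35 nm / 150°).
* **Leaflet topography** — per-leaflet height fields from head-group
  positions and mean-curvature maps
  `H = −(∂²h/∂x² + ∂²h/∂y²)/2` (plus the full divergence form), signed
  positive toward the bilayer midplane.
* **Synthetic membrane generator** — seeded overdamped-Langevin dynamics
  with a short-range attraction and an 11-site ring trap (one TAG per
  site, `D_bound < D_free`, Poisson unbinding), emitting trajectories
  *with ground truth* for every estimator.

I/O: multi-frame GRO, extended XYZ (`time_ns=… box_nm=…` comment line),
a long-format CSV dialect, and a topology sidecar CSV.  A config-driven
pipeline (`run_pipeline()`, thin CLI in `inst/scripts/tagtraj`) chains
the stages with manifests and reproducible CSVs.

## Worked example

Simulate the trap condition — 1.25 mol% TAG with the 11-site ring trap,
a concentration that does not cluster on its own — and run the analyses:

```r
library(tagtraj)

cfg <- preset_config("trap_1_25")
sim <- simulate_membrane(cfg, seed = 42)
sim$trajectory
#> tag_trajectory: 86 particles, 20001 frames
#>   time range: 0 - 20000 ns
#>   box (first frame): 40 x 40 x 10 nm
#>   groups: RESIDUE=15, SITE=11, TAG=60

cs <- clustered_fraction_series(sim$trajectory, stride = 200,
                                trap_center = cfg$trap_center)
cs
#> cluster_series: 101 samples, 60 TAGs
#>   clustered fraction: first 0 final 0.0667
#>   final largest cluster size: 4
cs$centroid_dist_to_trap[length(cs$times)]
#> [1] 0.79
```

The clustered fraction grows from zero as the trap nucleates a cluster,
and the final largest cluster sits 0.79 nm from the trap center — inside
the lumen (trap outer radius ≈ 1.7 nm).

```r
sc <- state_conditioned_D(sim$trajectory,
                          bound_intervals = sim$ground_truth$bound_intervals)
sc$D_free
#> diffusion_estimate: D = 0.0089716 nm^2/ns (95% CI 0.0089542-0.0089889),
#>                     n = 1026886, lag = 1 ns, KS = 0.000905
sc$D_bound
#> diffusion_estimate: D = 0.0027329 nm^2/ns (95% CI 0.00272-0.0027458),
#>                     n = 172528, lag = 1 ns, KS = 0.00893
sc$ratio
#> [1] 3.28
```

Free TAG diffuses ~3× faster than site-bound TAG (the generator's input
contrast is 3; the slight overshoot is the confinement bias of the
bound-state observable, quantified in the methods vignette).

```r
ev <- sim$ground_truth$events
mean(ev$dwell_ns[!ev$censored])   # 355 events
#> [1] 492.5
occ <- occupancy_profile(lapply(c(166, 1), function(r)
  contact_series(sim$trajectory, r, stride = 10)), c(0, 20000))
round(occ$occupancy, 3)
#>   166     1
#> 1.000 0.024
```

Mean complex lifetime ≈ 0.49 µs (input 0.5 µs), and the trap-site
residue 166 is in TAG contact essentially always while a distal probe
residue almost never is.

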