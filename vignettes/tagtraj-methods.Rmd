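---
title: "Methods: TAG clustering, binding and diffusion analysis with tagtraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TAG clustering, binding and diffusion analysis with tagtraj}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagtraj)
```

## Scope and scientific setting

Triacylglycerol (TAG) is sparingly soluble in phospholipid bilayers: above
a few mol% it phase-separates into lens-like clusters between the
leaflets.  Ring-shaped membrane proteins of the seipin type — disk-like
oligomers of eleven subunits whose luminal helices carry a serine residue
(S166) with marked TAG affinity — can seed this process at concentrations
that would not cluster on their own.  `tagtraj` implements the trajectory
analyses used to quantify that behavior:

* per-residue **contact occupancy** over time windows, with replicate
  mean ± SEM;
* the per-TAG **clustered fraction** and cluster geometry;
* **short-time lateral diffusion coefficients** from the distribution of
  in-plane displacements, overall and conditioned on binding state;
* **binding dwell times** (complex lifetimes) with survival curves and a
  geometric hydrogen-bond criterion for atomistic inputs;
* per-leaflet **height fields and mean-curvature maps** from head-group
  positions.

Because suitable molecular-dynamics trajectories are large and rarely
deposited, the package also ships a seeded Brownian-dynamics generator
(`simulate_membrane()`) that reproduces the statistical structure those
analyses assume at desk scale, together with exact ground truth for every
estimator.  All analyses use nm and ns internally and orthorhombic
periodic boxes only; triclinic input is rejected.

## Contact occupancy

For a residue \(r\) and sample time \(t\), the contact indicator is

\[ c_r(t) = \mathbf{1}\left[\min_{i \in r,\, j \in \mathrm{TAG}}
   d_{\mathrm{min\,image}}(x_i, x_j) \le 0.5\ \mathrm{nm}\right], \]

the nearest-particle distance between the residue and any TAG molecule
under the minimum-image convention, with the boundary case
\(d = 0.5\) nm counting as contact.  Occupancy over a window
\([t_0, t_1)\) is the fraction of sampled frames in contact; windows are
half-open so consecutive windows partition a trajectory cleanly.  The
default analysis stride is 1 ns: frames finer than the stride are sampled
at the nearest grid point, coarser frames are all used with a warning.
Replicate aggregation reports mean and SEM with the \(n-1\) sample
standard deviation, the standard choice for small replicate counts
(typically \(n = 10\)).

Whether residue–TAG distance should be taken atom-to-atom or to a
molecular surface is ambiguous in the field; `tagtraj` uses the
nearest-particle (atom–atom minimum) reading throughout, for residues and
for TAG–TAG neighbor relations alike.

## The clustered fraction

A TAG molecule *interacts* with another when their molecule–molecule
minimum-image particle distance is at most 0.5 nm, and *counts as
clustered* when it interacts with **at least two** other TAGs.  The
clustered fraction is the fraction of TAGs satisfying that rule, so
monomers and dimers contribute zero by construction.  Note this per-TAG
rule is *not* the connected-component count: in a chain A–B–C only B has
two neighbors, giving fraction 1/3 even though the component has size 3.
Both views are computed — `clustered_fraction_series()` applies the
literal per-TAG rule, while `connected_components()` supplies component
sizes and centroids — and the per-TAG count is always bounded above by
membership in components of size ≥ 3.

Cluster centroids use a periodic (circular-mean) convention per
dimension, so clusters straddling the box boundary average correctly;
the distance from the largest-cluster centroid to a reference point (the
trap center) is reported for lumen-localization analyses.

## Short-time diffusion

For lag \(\Delta t\) (default 1 ns) the in-plane displacement magnitudes
\(\Delta r\) of free 2D diffusion follow

\[ P(\Delta r) = \frac{\Delta r}{2 D \Delta t}
   \exp\!\left(-\frac{\Delta r^2}{4 D \Delta t}\right), \]

the 2D Brownian propagator magnitude distribution.  Its maximum-likelihood
estimate is closed form,

\[ \hat D = \frac{1}{4 n \Delta t} \sum_i \Delta r_i^2, \]

equivalently \(\langle \Delta r^2 \rangle = 4 D \Delta t\).  Each
\(\Delta r_i^2\) is exponential with mean \(4 D \Delta t\), so
\(\sum_i \Delta r_i^2\) is Gamma\((n)\)-distributed and the 95% CI is
exact:
\(\left[S / (4 \Delta t\, q_{0.975}),\ S / (4 \Delta t\, q_{0.025})\right]\)
with \(q_p\) the Gamma\((n, 1)\) quantiles.  A Kolmogorov–Smirnov
statistic against the fitted distribution is reported as a fit-quality
diagnostic (not a formal test, since the parameter is estimated).

Displacements are measured on unwrapped coordinates; unwrapping assumes
every true step is below half the box per dimension, and frames reaching
exactly L/2 are flagged and excluded from displacement intervals.
Intervals are non-overlapping by default so the gamma CI's independence
assumption approximately holds; overlapping intervals are available by
flag.  State-conditioned estimates (`state_conditioned_D()`) keep only
lag intervals lying entirely inside (bound) or entirely outside (free)
the supplied bound intervals; straddling intervals are dropped.

A caveat the generator makes measurable: a site-bound particle is
confined, and confinement depresses the 1-ns mean-square displacement
below \(4 D_{\mathrm{bound}} \Delta t\).  With the default parameters
(\(D_{\mathrm{bound}} = 0.003\) nm²/ns, tether radius 0.6 nm) this bias
is a few percent, so the recovered bound/free mobility ratio slightly
overshoots the input ratio of 3.  The same physics affects any bound-state
short-time D measured on real trajectories.

## Binding kinetics

`bound_series()` thresholds the TAG–site minimum distance at
`cutoff_bind` (default 0.5 nm, the package's single contact cutoff;
configurable).  `extract_dwell_statistics()` turns maximal bound runs
into events, optionally bridging unbound gaps of at most `gap_tolerance`
samples (default 0: the literal single-crossing reading, with the knob
exposed because recrossing tolerances are a genuinely open convention).
Events touching either trajectory end are flagged censored.  Two means
are reported: `mean_lifetime` averages uncensored events only (truncation
would bias the estimate downward), while `mean_dwell_all` is the naive
mean over all events, matching plain run-length accounting.  The survival
curve \(S(t)\) — the fraction of events with dwell ≥ \(t\) — keeps all
events, censored included.

The geometric hydrogen-bond criterion (`hbond_geometric()`) uses the
standard thresholds: donor–acceptor distance ≤ 0.35 nm and
donor–H–acceptor angle ≥ 150°, both configurable.

## Leaflet topography

Head groups are assigned to leaflets by z relative to their median plane.
`height_field()` bins one leaflet's head-group z positions on an
`nx × ny` grid over the periodic box, averages over all frames in the
window, smooths by periodic Gaussian *normalized convolution* (the
count-weighted smoothing also interpolates empty cells), and removes the
spatial mean so heights are relative to the leaflet's own mean plane.
The default 64 × 64 grid with σ = 1 nm resolves features of a few nm
while suppressing single-lipid noise; if more than half the cells receive
no data the function asks for a coarser grid rather than inventing a
surface.  With σ = 0 no smoothing is applied and empty cells are filled
with the mean height and flagged.

Mean curvature comes from periodic finite differences, in two modes:

* `small_slope`: \(H = -\tfrac12 (\partial_{xx} h + \partial_{yy} h)\);
* `full`: \(H = -\tfrac12\, \nabla\!\cdot\!\left(\nabla h /
  \sqrt{1 + |\nabla h|^2}\right)\).

The sign is oriented per leaflet so that \(H > 0\) where the leaflet
bulges **toward the bilayer midplane** (for the lower leaflet an upward
bump is positive; the upper leaflet's sign is flipped), and the
convention string is carried in the output.  The two modes agree within
1% whenever \(\max |\nabla h| < 0.05\).  Validation is against analytic
surfaces (flat plane, linear tilt, sinusoid, shallow paraboloid) because
reference implementations of grid curvature tools leave their filtering
settings undocumented.

## The synthetic membrane generator

`simulate_membrane()` integrates overdamped 2D Langevin dynamics in a
periodic box (kT = 1):

\[ x_{t+\mathrm{d}t} = x_t + \sqrt{2 D\, \mathrm{d}t}\, \xi
   + D\, F\, \mathrm{d}t, \]

with \(D\) the state-dependent diffusivity and \(F\) the pairwise force
from a smooth short-range well
\(U(r) = -\varepsilon (1 - (r/r_c)^2)^2\) for \(r < r_c\) (depth
\(\varepsilon\), range \(r_c\)); the force vanishes smoothly at both
\(r = 0\) and \(r = r_c\), so no repulsive core is needed.  The
integrator refuses configurations whose per-step motion (diffusive plus
maximal drift) exceeds half the attraction range.

The trap is a ring of `n_sites = 11` sites, one S166-like binding site
per subunit.  A free TAG entering `capture_radius` of an unoccupied site
binds (nearest-first when several captures compete); a bound TAG moves
with `D_bound`, is tethered inside the capture disk (excursions are
projected back, infinitesimally inside the radius so the
bound-implies-within-radius invariant survives round-off), and unbinds
as a Poisson process with rate `k_off`.  One TAG per site.  After
unbinding, a TAG must leave the capture disk before it can rebind to the
same site, so ground-truth dwells stay exponential with rate `k_off`
instead of being stitched together by instant recapture.

### Default parameters and why

| parameter | default | rationale |
|---|---|---|
| box | 40 × 40 nm | ~4,800 lipid equivalents at ~0.67 nm²/lipid/leaflet |
| `D_free` | 0.009 nm²/ns | 9 µm²/s, the coarse-grained lipid range |
| `D_bound` | 0.003 nm²/ns | bound/free contrast of 3, and small enough that 1-ns bound displacements (0.012 nm²) sit well below the tether scale (0.36 nm²), keeping confinement bias on \(\hat D_{\mathrm{bound}}\) at a few percent |
| `epsilon` | 2.0 kT | calibrated (script in `inst/scripts/calibrate_attraction.R`) so 2.5 mol% clusters within the default run while 1.25 mol% stays essentially monomeric/dimeric; frozen here |
| `attraction_range` | 0.6 nm | just above the 0.5-nm contact cutoff |
| `ring_radius` | 1.05 nm | places the 11 sites 0.6 nm apart (see below) |
| `capture_radius` | 0.6 nm | contact-scale capture/tether disk |
| `k_off` | 1/500 ns⁻¹ | 0.5 µs mean complex lifetime |
| `dt`, `save_stride` | 0.1 ns, 1 ns | stable integration; 1-ns analysis grid |
| `n_steps` | 200,000 (20 µs) | long enough for diffusion-limited capture of the ring and for spontaneous clustering at 2.5 mol%; multi-µs run lengths are the norm for coarse-grained TAG clustering |
| `n_replicates` | 10 | replicate mean ± SEM convention |

The ring geometry deserves a note.  TAG molecules are *point* particles
here, and the clustering statistic joins molecules within 0.5 nm.  If the
eleven subunit sites were placed on a ring with nm-scale spacing between
sites, site-bound TAGs could never register as one cluster under that
rule, no matter how faithfully each site binds — a pure artifact of the
point-particle coarsening, since real TAGs are themselves ~1 nm objects.
The sites are therefore placed at contact-scale spacing (0.6 nm, ring
radius 1.05 nm): bound TAGs touch, the occupied ring reads as a single
pinned proto-cluster, and free TAGs accreting onto it reproduce the
qualitative phenomenon of interest — nucleation *inside the trap lumen*
at a concentration that does not cluster spontaneously.  The trap region
(ring plus capture disks) spans ~1.7 nm; "centroid inside the lumen"
checks use that outer radius.

### Presets

`preset_config()` encodes the four study conditions: `no_trap_2_5`
(2.5 mol%, spontaneous clustering), `no_trap_1_25` (1.25 mol%, stays
dissolved), `trap_1_25` (1.25 mol% with the ring trap, trap-seeded
clustering), and `replenished_4_85` (a preformed in-ring cluster plus
2.5 mol% free TAG, 4.85 mol% total).  TAG counts are
`round(mol% × n_lipid_equivalents)`: 60, 120 and 233 molecules.

### Reproducibility

All randomness flows from a single seed: the R RNG drives both the R
setup and the compiled stepper, so identical seeds give bit-identical
trajectories, ground truth and downstream CSVs.  Replicate `r` of a
config with base seed `s` uses seed `s + r − 1`.  The pipeline
(`run_pipeline()`) records inputs, parameters, seed, package version and
MD5 checksums of every output in its manifest.

### What the generator does and does not emulate

It emulates: TAG dilution vs clustering as a function of concentration,
trap-seeded nucleation with one TAG per subunit site, a 3× bound/free
mobility contrast observable in 1-ns displacement distributions,
exponential complex lifetimes of order 0.1–0.5 µs, and the replicate
structure of simulation studies.  It does **not** emulate force-field
realism: no lipid chains or solvent, no explicit z dynamics for TAGs (the
in-plane analyses never read z; curvature analyses use separately
constructed bilayer fixtures), no hydrodynamics, no thermostat/barostat
physics, and no protein structure beyond the site ring.  Passing tests on
generator data therefore validate the *estimators* and the qualitative
phenomenology, not any force field.

## Numerical choices and degenerate inputs

* Distance comparisons use `<=` so boundary cases (exactly 0.5 nm) count
  as contact.
* Minimum-image arithmetic is exact for orthorhombic boxes; a brute-force
  27-image enumeration serves as the test oracle.
* Simultaneous captures resolve nearest-first with deterministic
  tie-breaking (particle then site index).
* Degenerate inputs fail loudly: empty groups, overlapping groups,
  all-zero displacement samples, coplanar head-group sheets, windows
  containing no samples, empty trajectories, non-commensurate lags and
  strides.
* Problem sizes used by the test suite: brute-force oracles run on
  20-frame × 50-particle fixtures; estimator recovery uses 10⁴–10⁵
  displacements; replicate orderings use ten 20-µs replicates per
  condition; CI coverage uses 500 samples of n = 1000.  These sizes give
  each statistical check comfortable resolution while keeping a full run
  of the suite in the minutes range.

## Known limitations

* The per-TAG clustering rule excludes chain-end molecules by
  construction; comparisons with component-based statistics should use
  `connected_components()` explicitly.
* Short-time D of bound states carries an intrinsic confinement bias
  (quantified above); it is a property of the observable, not of the
  estimator.
* The leaflet height field assumes a (mostly) constant box across the
  averaging window and a single-valued surface per leaflet; overhangs
  (e.g. a fully formed lens) violate that assumption.
* The CSV trajectory dialect stores the box per row for round-trip
  fidelity; GRO times follow the GROMACS convention (`t=` in ps) and are
  converted to ns on read.
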