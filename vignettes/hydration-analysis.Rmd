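---
title: "Methods: pH-resolved hydration-shell analysis with hydroshell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pH-resolved hydration-shell analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydroshell)
```

## What the package computes

A protein's hydration shell — the layer of ordered water resolved around
its surface — reorganises as solution conditions change. Given a series of
atomic models of the same protein determined at several pH values,
molecular-dynamics trajectories of the solvated protein, and
constant-pH λ-coordinate traces, hydroshell quantifies that
reorganisation along five axes:

1. **Water-site persistence.** Water oxygens from all superposed models are
   pooled and clustered; a site observed (within a distance cutoff) in one
   condition only is *lone*, in two or more conditions *persistent*, and in
   every condition *most persistent*.
2. **MD hydration sites.** Time-averaged water mass density on a voxel
   grid around the protein, smoothed over adjacent voxels, thresholded,
   and reduced to discrete sites by sub-Ångström peak merging.
3. **Residence times.** The continuous survival probability of water in a
   shell around a residue selection, integrated over lag time.
4. **Per-residue statistics.** Bound-water counts per residue and residue
   type, Shrake–Rupley accessible surface area, hydrophilicity and
   surface-area correlations, the desolvation trend of total water count
   against pH, and metal-ion displacement geometry.
5. **Titration.** Deprotonation fractions from λ traces and per-residue
   pKa via Henderson–Hasselbalch/Hill least squares.

## Models and assumptions

**Persistence clustering.** Waters are compared *after* rigid-body
superposition of every model on a reference condition (pH 7 when present;
Kabsch least squares over paired Cα atoms). Clustering is single-linkage
agglomeration: two waters link when their distance is strictly below the
cutoff (default 1.0 Å), and clusters are connected components of the link
graph. Single linkage is parameter-free beyond the cutoff, deterministic,
and equivalent to density-based clustering with a minimum cluster size of
one, which is also how MD density peaks are merged — the same convention
serves both stages. The choice matters at the margins: complete- or
centroid-linkage variants split bridged clusters differently, so counts
from different variants are comparable only within a method. A cluster may
contain two waters of the same condition if linkage bridges them; the
persistence level counts *distinct* conditions.

Two boundary conventions are fixed and documented rather than guessed:
distances exactly equal to the cutoff do **not** link, and the
symmetry-axis tie tolerance is 1e-3 Å (coordinates are deposited at
three decimals, so exact float equality would miss real symmetry sites).

**Solvent chain assignment.** A water or ion takes the chain of its
nearest protein atom. If several chains tie within the tolerance *and*
the tying atoms occupy identical atom indices within their chains, the
site sits on a symmetry axis and the occupancy becomes 1/multiplicity —
0.5, 0.33, 0.25 for two-, three-, fourfold axes, stored at two decimals
as conventionally deposited. Ties between *different* atom indices are
coincidences: occupancy stays 1.0. In both cases the alphabetically first
chain wins. The index comparison uses the full tied index *set* per
chain, not a single representative, because exact geometric degeneracy
makes "the" nearest atom numerically ill-defined.

**Density grids.** Voxel density is mean water-oxygen count per frame
times the water mass (18.015 u) over the voxel volume, reported in kg/L;
one stationary water in a 0.5 Å voxel is ≈ 239.3 kg/L and uniform bulk
water is ≈ 1.0 kg/L, which the test suite verifies analytically.
"Adjacent" voxels for smoothing default to the 6 face-adjacent
neighbours (7-point stencil, the minimal reading of edge-sharing in a
cubic grid); an 18-neighbour face-or-edge variant is available via
`analysis_config(smoothing_neighbors = 18)`. Boundary voxels average
over existing neighbours only, so the stencil conserves total density in
the grid interior but not exactly at the boundary. Local maxima are
voxels at least as dense as all 26 surrounding voxels (plateaus are kept
and subsequently merged); maxima are thresholded (default 6 kg/L)
*before* merging, and merged groups take their density-weighted mean
position (density weighting is stable under grid jitter; an unweighted
mode exists) with the group maximum as the site density.

**Survival probability.** Continuous (strict) survival: a water counts at
lag t only if it is inside the shell at *every* frame from the origin to
t. Exit-and-re-enter does not survive; this is the standard convention
and consistent with the picosecond-scale residence times the method is
designed to resolve. An intermittent variant is deliberately not
implemented. The maximum lag defaults to half the window length to bound
origin-count attrition, and the trapezoidal integral is truncated there
without tail extrapolation — when S at the last lag exceeds 0.05 the
result is flagged as a lower bound. Origins with an empty shell are
skipped; a shell that is never occupied yields an *undefined* curve and
NA residence time, never a silent zero. Note that with continuous
survival, transient bulk waters crossing the shell for a single frame
legitimately pull the integrated τ below the mean bound-state lifetime;
recovery experiments therefore isolate the bound process.

**Titration.** λ below 0.2 counts as protonated, above 0.8 as
deprotonated, in between is discarded. The deprotonation fraction is
reported as n_deprot/(n_prot + n_deprot) by default — the quantity that
rises with pH and feeds the fit — with the complementary
n_prot/(n_prot + n_deprot) convention available as
`convention = "printed"`; the two always sum to one on a countable
trace. The fit is S(pH) = 1/(1 + 10^(n·(pKa − pH))) by
Levenberg–Marquardt least squares, initialised at the pH nearest
S = 0.5 with Hill slope 1, the slope bounded to [0.2, 4]. All-protonated
or all-deprotonated data leave the midpoint outside the sampled range
and are flagged unbounded rather than extrapolated.

## Tunable parameters

All cutoffs live in one `analysis_config()` object:

| parameter | default | units | role |
|---|---|---|---|
| `cluster_cutoff` | 1.0 | Å | cross-condition water linkage (strict `<`) |
| `residue_cutoff` | 3.6 | Å | nearest-residue assignment, bound-water counting, residence shells |
| `shell_cutoff` | 5.0 | Å | density-grid extent and ion-water contact shell |
| `grid_spacing` | 0.5 | Å | voxel edge |
| `density_threshold` | 6 | kg/L | minimum smoothed density for a hydration site |
| `merge_distance` | 1.0 | Å | peak merging (strict `<`) |
| `lambda_low`, `lambda_high` | 0.2, 0.8 | – | λ state thresholds |
| `symmetry_tolerance` | 1e-3 | Å | distance-tie detection |
| `hbond_distance` | 3.5 | Å | hydrogen-bond-range flag for ion contacts |
| `probe_radius`, `asa_points` | 1.4 Å, 960 | – | Shrake–Rupley ASA |

The 3.5 Å hydrogen-bond flag and the Hopp–Woods default hydrophilicity
scale are package choices where the method literature leaves the value
unnamed; both are switchable.

## The synthetic-data generators

Every pipeline stage can be exercised without any external data. The
generators plant *statistics*, not physics:

* `generate_condition_ensemble()` decorates a deterministic toy scaffold
  (a rigid ring with all 20 residue types; a cyclic multi-chain variant
  provides symmetry axes) with shared sites that appear Gaussian-jittered
  in designated conditions, unique lone sites, and optionally filler
  waters whose per-condition totals follow a planted desolvation slope.
  Planted sites keep at least 3 Å mutual separation and the jitter
  displacement is truncated at 2.4 σ, so in the default regime
  (σ = 0.2 Å, cutoff 1.0 Å, separation > 2× cutoff) clustering recovery
  is exact by construction — that is the designed clean-recovery regime,
  and stress tests outside it are available by raising σ. Filler waters
  pack down to 1.2 Å from each other (still above the cutoff, so each is
  its own lone site), which is closer than physical water–water contact:
  filler exists to carry the totals trend, not distance distributions.
* `generate_trajectory()` binds one water per planted site with
  exponential mean dwell time τ and a two-state chain whose stationary
  occupancy is the site occupancy; unbound waters are parked in a far
  reservoir (instant exchange with bulk), and optional background waters
  are redrawn uniformly every frame at a requested bulk density. Site
  occupancies default to 0.6–0.95 with a 0.15 Å bound-state width —
  sharp, well-occupied sites of the kind density thresholding is meant
  to find. Detection degrades, as the method itself does, for
  low-occupancy sites whose density mass straddles voxel corners.
* `generate_lambda_traces()` draws λ as a two-state Gaussian mixture
  (N(0.05, 0.03) / N(0.95, 0.03), clipped to [0, 1]) with the
  deprotonated-state probability given by the planted pKa and Hill slope,
  plus an optional uniform transition-region fraction.

All generators are seeded and byte-identical under a fixed seed, and
write machine-readable ground truth beside the data so tests consume
files, never in-memory shortcuts. What passing these tests does *not*
show: recovery on real data with correlated placement errors, anisotropic
water density, hydrogen-bond network structure, or model-building bias in
which waters get resolved at all.

## Numerical and degenerate-input choices

* Kabsch superposition pairs atoms by chain + residue id + insertion
  code + atom name; unpaired atoms are skipped with a warning when at
  least 90% pair, and error otherwise naming the first unmatched atom.
  Fewer than three pairs is an error.
* Alternate locations collapse to the highest-occupancy conformer (first
  wins ties). Coordinates are Å end to end; no unit conversion at I/O.
* Site-residue votes tie-break to the lower residue id, then chain.
* Cluster output is sorted by descending persistence then centroid
  lexicographic order, so outputs are deterministic and
  order-independent with respect to input model order.
* An empty cluster category yields a degenerate (flagged) distance
  distribution and NA KS entries; the KS statistic itself is the exact
  sup-difference of the two ECDFs on the pooled support.
* With exactly two conditions, "persistent" and "most persistent"
  coincide; sites present in both conditions are labelled most
  persistent.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data
at desk scale, chosen to finish in seconds while leaving the statistics
well-resolved: five-condition ensembles with 20 shared + 7-per-condition
lone sites (and a few hundred to ~2000 filler waters for the
slope-recovery series), 5000-frame trajectories (10 ns at 2 ps spacing,
analysed as ten 1 ns windows), and titration grids of pH 1–10.5 in steps
of 0.5 with 2000 λ samples per point.

## Limitations

* No density-map handling, model refinement, or map-based water
  validation; inputs are coordinate models the user trusts.
* The artifact consumes MD trajectories and λ traces; it runs no
  dynamics and no constant-pH machinery itself.
* Binary trajectory formats are out of scope; multi-model PDB and XYZ
  readers are provided, and anything else should be converted or adapted
  through `md_trajectory()`.
* No electrostatic surface potentials and no coordination-chemistry
  typing of metal sites.
* Published persistence counts from any specific study depend on that
  study's (often unstated) clustering variant and boundary conventions;
  expect agreement up to those choices, which is why the variant and
  conventions here are documented and switchable.
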