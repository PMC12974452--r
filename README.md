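# hydroshell

Quantifying how a protein's hydration shell reorganises across solution
conditions — typically a pH series of high-resolution structures of the
same complex, its MD trajectories, and constant-pH titration output. The
package is aimed at structural biologists and simulators who have (i)
several atomic models of one protein with modeled waters and ions, (ii)
trajectories of the solvated protein, and/or (iii) λ-coordinate traces
from constant-pH MD, and who want the water-centric statistics those data
support.

## What it computes

**Water-site persistence across conditions.** After rigid-body (Kabsch)
superposition of all models on a reference condition, water oxygens are
pooled and clustered by single linkage at a 1.0 Å cutoff (strict `<`).
A site found in one condition only is *lone*; in ≥ 2 conditions
*persistent*; in all conditions *most persistent*. Sites get
nearest-residue assignments (3.6 Å cutoff), per-category nearest
water–water distance distributions, and exact two-sample
Kolmogorov–Smirnov statistics D = sup |F̂₁ − F̂₂|.

**Hydration sites from MD density.** Water mass density ρ on a 0.5 Å
voxel grid within 5 Å of the protein, in kg/L (one stationary water per
0.5 Å voxel ≈ 239.3 kg/L; bulk ≈ 1.0 kg/L), smoothed over face-adjacent
voxels, thresholded at 6 kg/L; peaks closer than 1 Å are merged and each
site is assigned the residue that most often has the closest heavy atom.

**Residence times.** The continuous survival probability
S(t) = ⟨N_surv(t₀, t)/N(t₀)⟩ of waters within 3.6 Å of a residue
selection, integrated by trapezoid to a residence time
τ = ∫ S(t) dt, averaged over non-overlapping trajectory windows.

**Per-residue desolvation statistics.** Bound-water counts per residue
and residue type, Shrake–Rupley accessible surface area, OLS
correlations of counts with ASA or Hopp–Woods hydrophilicity, the
desolvation trend (total waters vs pH, slope in waters per pH unit), and
ion-to-assembly-center displacement geometry with persistence-tagged
ion–water contacts.

**pKa from constant-pH traces.** Deprotonation fractions
S_deprot = n_deprot/(n_prot + n_deprot) from λ counts (λ < 0.2
protonated, λ > 0.8 deprotonated), fitted with
S(pH) = 1/(1 + 10^(n·(pKa − pH))), and grouped into low (2–4), mid
(4–5) and anomalous (> 7) pKa classes.

A seeded synthetic-data module generates ground-truthed inputs for every
stage — multi-condition PDB ensembles with planted persistence and
desolvation structure, toy trajectories with planted hydration sites and
exponential residence times, and λ traces with planted pKa values — so
the whole pipeline is testable offline.

## Worked example

```r
library(hydroshell)

dir <- tempfile("demo")
ens <- generate_condition_ensemble(dir, desolvation_slope = 100,
                                   total_noise_sd = 30, seed = 42)
res <- run_structure_pipeline(ens$paths, file.path(dir, "report"))

res$persistence$histogram
#>    1    2    3    4    5
#> 1897    0    0    0   20
```

The histogram counts clusters by the number of pH conditions they span:
the 20 planted five-way shared sites are recovered as most persistent,
and every remaining water (7 planted lone per condition plus the filler
carrying the desolvation trend) is a lone site.

```r
res$trend
#> <trend_fit> slope 96.23, intercept -149.1, r 0.998 (R^2 0.995), n=5
```

The desolvation fit recovers the planted 100 waters gained per pH unit
within ordinary-least-squares noise (σ = 30 on five totals).

```r
head(res$wss$sites[, c("x","y","z","n_conditions","category",
                       "nearest_residue_name","nearest_distance")], 3)
#>          x       y       z n_conditions        category nearest_residue_name
#> 1 -22.2128 -0.5742 -1.2254            5 most_persistent                  LEU
#> 2 -20.8310  3.4878 -2.3478            5 most_persistent                  HIS
#> 3 -18.3740  0.2582  3.6932            5 most_persistent                  ILE
#>   nearest_distance
#> 1         2.782049
#> 2         2.285650
#> 3         2.659507

round(res$distances$ks_matrix, 3)
#>                  lone persistent most_persistent
#> lone            0.000         NA           0.852
#> persistent         NA         NA              NA
#> most_persistent 0.852         NA           0.000
```

Each site carries its centroid, persistence category and nearest residue;
the KS matrix compares nearest water–water distance distributions between
categories (NA where a category is empty or degenerate). The report
directory holds the same results as TSV/JSON plus a manifest with input
and output checksums.

The trajectory and titration pipelines follow the same pattern:

```r
g <- generate_trajectory(NULL, n_frames = 5000, n_sites = 12, seed = 1)
run_trajectory_pipeline(g$trajectory, "report", window_frames = 500,
                        interval_ns = 1)

lam <- generate_lambda_traces("lam", seed = 1)
run_titration_pipeline(lam$manifest, "report_pka")
```

A thin command-line wrapper is installed at
`system.file("cli", "hydroshell.R", package = "hydroshell")`.

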