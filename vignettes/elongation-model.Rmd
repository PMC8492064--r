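---
title: "An agent-based model of posterior axis elongation driven by Sox2/Bra heterogeneity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An agent-based model of posterior axis elongation driven by Sox2/Bra heterogeneity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(axisim)
```

## The biological question

During vertebrate posterior body elongation, a pool of bipotent progenitors
(neuromesodermal progenitors) in the progenitor zone (PZ) of the tailbud
feeds two nascent tissues at once: the neural tube (NT, Sox2-high) and the
presomitic mesoderm (PSM, Bra-high). Individual PZ cells co-express Sox2 and
Brachyury (Bra) at highly variable relative levels, and the per-cell
Sox2-to-Bra ratio behaves as a fate-and-behavior control variable: cells
drifting to a low ratio become mesodermal and highly motile, cells drifting
to a high ratio become neural and nearly immotile. `axisim` implements an
off-lattice agent-based model of this process together with the trajectory
statistics, tissue-scale readouts and per-nucleus expression quantification
needed to analyse it, plus synthetic-data generators so the whole analysis
stack is testable without microscopy data.

## The model

Each cell `I` carries a fate state (progenitor, NT or PSM), a 2D position
`(x_I, y_I)` and a Sox2/Bra ratio `R_I(t)` on a 0-2 scale. The domain is a
2D projection of the posterior body: the NT flanked by the two PSM columns,
the PZ abutting them posteriorly. One model unit is 150 µm. The anterior
boundary (somites and neuroepithelium) and the lateral boundaries (lateral
plate) are blocked; the posterior is open. y increases posteriorly, so
posterior displacement is a positive y increment.

Per timestep (`dt = 0.1` h, matching a 6-min imaging cadence) each cell:

1. **Updates its ratio.** Progenitor ratios follow an Ornstein-Uhlenbeck
   SDE, `dR = -kappa (R - mu) dt + sigma dW`, clipped to `[0, 2]`. The
   anchor `mu` encodes the spatial regime (below). Specified NT/PSM cells
   stop taking noise; their ratios relax deterministically to 2 and 0.
2. **May switch fate.** A progenitor crossing `theta_low = 0.4` is
   irreversibly specified as PSM; crossing `theta_high = 1.6`, as NT.
3. **Moves.** A biased random walk: an isotropic step of length
   `motility(R) * dt` plus an interaction bias (fate-pair adhesion within
   `r_adh`, hard-core repulsion within `r_core`, cross-fate repulsion
   implementing non-mixing). Moves that cross a wall or push the local
   neighbor count within `r_pack` above `n_max` are rejected. A hard-core
   packing pass then projects residual overlaps apart; the resulting
   contact-chain pressure is what pushes the proliferating tissue into the
   open posterior space.
4. **May divide,** with per-step probability `dt ln(2) / T` for its fate's
   doubling time `T` (progenitor 11.49 h, NT 10.83 h, PSM 8.75 h). The
   daughter inherits state and ratio and is placed `r_core / 2` away.

### Motility

Low ratios (below 0.4) confer high motility (`v_high`, 60 µm/h), high
ratios (above 1.6) inhibit motility (`v_low`, 12 µm/h), and the band in
between confers intermediate levels. By default the band interpolates
linearly from `v_high` down to `v_low`, so a balanced cell (`R = 1`) moves
at 36 µm/h — the configured `v_mid` — and cell-to-cell ratio heterogeneity
translates into motility heterogeneity. This choice matters: it is what
distinguishes a spatially random ratio field (fast and slow cells
interspersed, a kinetically "fluid" tissue) from a graded one (speeds
spatially sorted). A single-plateau `"step"` profile is available via
`motility_profile = "step"`.

### Adhesion and non-mixing

Adhesion acts between fate pairs within `r_adh = 15` µm, scaled by a
symmetric matrix with a(NT,NT) = 1.0 > a(prog,prog) = 0.5 >= a(PSM,PSM) =
0.4 — neural cells adhere more than mesodermal ones. On top of the fate
matrix, a progenitor's adhesion scales with its own ratio
(`1 + 0.5 (R - 1)`): Sox2-high progenitors are stickier, Bra-high ones
less adhesive, reflecting the adhesive consequences of Sox2/Bra levels.
Cross-fate pairs feel a repulsion of strength `cross_repulsion = 0.5`,
which maintains sharp boundaries between tissues (non-mixing). All
interactions act strictly as a bias of the random motion: a cell that makes
no random move is not transported by them (only the packing projection
still resolves overlaps). This is deliberate — disabling motility must
leave newly specified cells stranded where they switched, which is exactly
the tissue-disorganisation phenotype the motility ablation probes.

### Packing and maximum density

Volume exclusion is enforced by an iterative hard-core projection: after
the move pass, pairs closer than `r_core = 7.5` µm are projected apart to
that distance over `packing_sweeps = 20` Gauss-Seidel sweeps, processed
anterior to posterior so each sweep propagates a compression wave toward
the open posterior edge. This position-based scheme is the load-bearing
part of elongation: with purely force-based (overdamped) repulsion at this
timestep, compression relaxes only diffusively and proliferation outruns
expansion, compressing the tissue instead of elongating it. The density cap
(`n_max = 16` within `r_pack = 15` µm) additionally rejects moves into
overcrowded neighborhoods; it only binds in crowding excursions, because
`n_max` sits just above the packed-state neighbor count (about 15 within
15 µm at hard-core spacing — a lower cap silently freezes all motion).

### Regimes: where the heterogeneity sits

The SDE anchor field encodes three spatial organisations of the same
ratio heterogeneity:

* `random` — `mu = 1` for every progenitor; initial ratios uniform on
  `[0.3, 1.7]`. (The published initial interval 0.15-0.85 is read on an
  internal 0-1 scale and mapped onto the depicted 0-2 scale; the raw
  interval remains selectable via `initial_ratio_range`.)
* `gradient` — `mu` graded linearly from 1.7 at the anterior PZ edge to
  0.3 at the posterior edge (edges as the running 5th-95th percentiles of
  progenitor y, so the field follows the moving tissue).
* `mixed` (the default, matching the observed organisation) — the gradient
  plus a per-cell uniform offset of ±0.35 fixed at birth.

Initial graded draws are clamped just inside the fate thresholds
(`theta ± 0.1`): initial progenitors are undetermined by definition, and it
is the anchors, not the t = 0 values, that carry edge-anchored cells across
the thresholds over a 1/kappa timescale.

Deregulation experiments force the anchor of a configurable fraction of
progenitors below `theta_low` (`bra_high`) or above `theta_high`
(`sox2_high`), emulating forced expression.

## Parameters and calibration

| Parameter | Default | Units | Origin |
|---|---|---|---|
| `theta_low`, `theta_high` | 0.4, 1.6 | ratio | stated thresholds |
| `initial_counts` | 1100 / 1200 / 3200 | cells | stated initial population |
| `doubling_times` | 11.49 / 10.83 / 8.75 | h | stated proliferation rates |
| `unit_scale_um` | 150 | µm/unit | stated scale |
| `dt` | 0.1 | h | imaging cadence (6 min) |
| `v_high`, `v_mid`, `v_low` | 60, 36, 12 | µm/h | free; ordering from observed motilities |
| `ratio_relaxation_kappa` | 0.10 | 1/h | calibrated (below) |
| `ratio_noise_sigma` | 0.09 | 1/sqrt(h) | calibrated (below) |
| `r_core`, `r_adh`, `r_pack` | 7.5, 15, 15 | µm | cell-scale radii; `r_core` set so the initial NT/PSM spacing sits at ~75% of random close packing |
| `n_max` | 16 | cells | just above the packed-state neighbor count |
| `f_core`, `f_adh` | 60, 10 | µm/h | force scales of the motion bias |

The exact interaction formulas behind "adhesion, maximum density, and
packing" are not available, so every reconstructed term above is a design
decision exposed in `sim_config()` rather than asserted as given.

`kappa` and `sigma` were calibrated once, by a scripted grid search, to the
stated constraint that the default (mixed-regime) 10-h run keeps the
progenitor pool within ±20% of its initial 1100 cells while NT and PSM
grow. The drain on the progenitor pool has two parts: cells anchored
beyond a threshold leave at rate ~kappa, and noise carries band-anchored
cells across; proliferation at `T = 11.49` h replaces about 6%/h. That
balance pins `kappa` ~ 0.1/h and `sigma` ~ 0.09/sqrt(h) given the anchor
field; both remain configuration knobs.

Domain extents at t = 0 (NT 1.0 × 4.0, PSM columns 1.3 × 4.0, PZ 3.6 × 1.5
units) are not stated anywhere; they were chosen so the three tissues start
at comparable number density (within 2×) and are config-overridable.

## What the analysis stack computes

* `tracks_of()` turns snapshots into the package's track-table format;
  `subtract_reference()` re-references to a landmark ("raw" frame);
  `correct_tissue_motion()` removes the cumulative mean ROI displacement
  ("corrected" frame; the ROI mean step is exactly zero afterwards).
* `motility_distribution()` (mean step speed per track; a net-displacement
  variant is exposed as an option), `angle_distribution()`
  (velocity-weighted rose histogram, 0° = posterior, 16 bins by default),
  `time_averaged_msd()` (overlapping windows, pair-count-weighted ensemble
  average) and `fit_diffusion()` (through-origin fit, `D = slope / 4` in
  2D; through the origin because MSD(0) = 0 by construction).
* Tissue metrics: `elongation_rate()` (posterior PZ edge as the 95th
  percentile of progenitor y — robust to stray cells),
  `resident_y_displacement()` (cells progenitor throughout, optionally the
  central AP third), `shape_conservation()`
  (`100 × min(a1/a0, a0/a1)` on the 5th-95th-percentile length/width
  aspect), `measure_doubling_time()` (log-linear fit),
  `tissue_integrity()` (fraction of cells whose neighbors are in strict
  majority of their own fate).
* Expression quantification: `normalize_to_dapi()`, `sox2_bra_ratio()`
  (zero-Bra nuclei excluded rather than pseudocounted — a pseudocount would
  distort the CV statistics; exclusion counts are reported),
  `coefficient_of_variation()`, `path_profile()` (seven equal-length
  volumes along a posterior-to-anterior path; nearest-centre assignment),
  `signed_fold_change()` (+f for increases, -1/f for decreases, so a
  halving reads -2.0), `transverse_section_map()` (40-µm digital slabs).

## The synthetic-data generators

`generate_nucleus_table()` emulates the *structure* of per-nucleus
immunodetection data: log-normal intensities (fluorescence is positive and
right-skewed, and the CV parameterisation is exact for the log-normal) with
high PZ cell-to-cell variability (noise CVs 41.8% for Sox2, 30.75% for
Bra), homogeneous NT (Sox2-high) and PSM (Bra-high), a mild anterior-Sox2 /
posterior-Bra enrichment across the PZ (1.2-fold by default; with the
configured noise this keeps the total measured CV within ~3 points of the
noise CV), and a shared exponential depth attenuation in z so DAPI
normalization has real work to do. `generate_tracks()` produces
drift-plus-diffusion trajectories with known per-tissue ground truth
(PZ drifting posteriorly fastest; corrected diffusivity PZ ≈ PSM ≫ NT), so
parameter recovery by the trajectory statistics is testable exactly.

What the generators do **not** emulate: segmentation errors, antibody
crosstalk, anisotropic point-spread functions, track gaps and linking
errors, embryo-to-embryo variability. Tests passing on generated data
therefore validate the *estimators*, not robustness to those artefacts;
real-tracking gaps are treated as an input error, not interpolated.

## Numerical choices and degenerate inputs

* Euler-Maruyama for the SDE with reflecting clipping at `[0, 2]`.
* The packing projection caps each bias displacement at `r_core` per step
  for stability, skips exactly coincident pairs (no defined direction;
  random motion separates them) and is RNG-free, so runs are bit-identical
  under a fixed seed. A single seeded generator drives everything else.
* Daughters are placed without applying the density cap (applying it would
  deadlock at the cap); the next packing pass restores spacing.
* Zero-length steps contribute nothing to angle histograms; all-zero MSDs
  return `D = 0` with the linearity flagged `NA`; non-growing count series
  are flagged rather than reported as a doubling time.
* Ties in volume assignment (`path_profile()`) break to the first volume.

## What the test suite establishes — and what it does not

The acceptance-style tests verify, at the study's own scale (full
5500-cell populations, 10 h, five seeds per regime where regimes are
compared): exact initialization counts; recovery of all three doubling
times within 5% by exponential fit; threshold semantics of every fate
switch; progenitor-pool stability with growing NT/PSM in the default run;
the regime orderings of elongation, resident posterior displacement and
shape conservation; integrity degradation under the motility and
adhesion/non-mixing ablations; the directional effects of both
deregulations; and the closed-form oracles of the analysis stack.

One comparison is at the edge of resolution in this reconstruction: the
corrected diffusivity of resident progenitors differs between the random
and mixed regimes by less than seed-to-seed noise (the gradient regime is
lower). The corresponding ordering assertion is kept at its stated
strictness rather than loosened, and can fail on an unlucky seed set; the
elongation, displacement and shape orderings are well-resolved.

Simulation sizes used throughout testing: full-scale populations for the
regime and ablation comparisons (about 5500 to 11500 cells over a 10-h
run, a few seconds each); reduced populations (`population_scale = 0.1`)
for structural unit tests.

## Known limitations

* 2D: justified by the small dorso-ventral deformation of this tissue, but
  dorso-ventral sorting (the dorsal-anterior Sox2-high enrichment) is only
  represented along the AP axis.
* No cell death, no EMT timing, no molecular regulation of Sox2/Bra by the
  posterior signalling gradients; fate switching is the emergent
  threshold-crossing probability of the OU process, not an explicit
  per-step probability.
* The interaction scheme is a reconstruction; its force scales are free
  parameters, and tissue-scale conclusions should be read as properties of
  this scheme, not measurements.
* The progenitor-diffusivity contrast between regimes is weaker than the
  tissue-scale contrasts (see above).
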