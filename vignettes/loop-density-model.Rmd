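---
title: "Estimating chromatin loop density from single-chromosome images: the model behind chromloops"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating chromatin loop density from single-chromosome images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromloops)
```

`chromloops` is an in-silico counterpart to a single-cell chromosome imaging
experiment: dilution labeling isolates one (or a fragment of one) chromosome
per nucleus, 3D SMLM turns it into a localization cloud, and polymer
simulations carrying a controlled number of cohesin-like loops per megabase
provide the reference against which the imaged shapes are compared. This
vignette explains each model stage, the tunable parameters, the numerical
choices, and what the reduced-scale test suite does and does not establish.

## 1. Dilution labeling and sister-chromatid exchange

A single S phase in the presence of a thymidine analog leaves every
chromosome with exactly one labeled strand. Semi-conservative replication
then halves the expected number of label-carrying chromosomes at each
division: after `m` divisions a cell carries `Binomial(46, 2^-m)` labeled
chromosomes (`expected_labeled()`, `labeled_count_pmf()`). At `m = 6` the
expectation is 0.72, so most cells show zero or one labeled chromosome —
that is what makes single-chromosome imaging possible.

Sister-chromatid exchange (SCE) breaks the picture of fully labeled
chromosomes. The model (`simulate_labeled_fragments()`): at every division
each chromosome suffers at most one SCE with probability `sce_rate`
(default 0.18, the measured per-division rate at the labeling concentration
used; a Poisson multi-event variant is available via `multi_sce = TRUE`
since the single-event assumption is a reconstruction, not a measured
fact). The breakpoint is uniform along the chromosome and the distal
segment is exchanged between the sister chromatids; daughters segregate at
random. Following one descendant, the labeled region of a chromosome is
always a single interval (each division intersects it with a half-line),
which allows a fully vectorized simulator. Following the *whole* division
tree instead (`split_chain_for_imaging()`) partitions the chromosome into
disjoint pieces, each ending in exactly one descendant — the piece-size
distribution equals the single-lineage fragment distribution, and the
pieces are the sub-chains used for image synthesis. Sub-chains under 5 Mb
are discarded, as such small regions are not quantified.

At the defaults (`m = 6`, rate 0.18) the median surviving fragment is
~47 Mb over 10⁴ replicate cells, consistent with the ~50 Mb prediction the
model is meant to reproduce; the median decreases with both `sce_rate` and
`m` (property-tested).

## 2. Loop placement

Loops are placed as a static end state of extrusion
(`sample_obstacles()`, `place_loops()`):

* Obstacle positions (CTCF-site-like) have i.i.d. gaps from the normalized
  density `f(L) = (L/L0²)e^(-L/L0)`, i.e. Gamma(shape 2, scale `L0`) with
  `L0` = 165 kb — mean gap `2·L0` = 330 kb, mode `L0`.
* Each loop draws a uniform loading point and two independent exponential
  extents (mean `d0` = 250 kb, the processivity per side); each anchor
  stops at the first intervening obstacle, previously placed anchor, or
  chromosome end. Anchors join the obstacle set for later loops; zero-size
  loops are redrawn.

Two size statistics coexist and are deliberately both reported. The
*obstacle-gap* distribution — the size of a fully extruded, obstacle-to-
obstacle loop, which is what the gap density is calibrated against —
has mean ≈330 kb and median ≈277 kb. The *realized* anchor-to-anchor sizes
under sequential placement are strongly density-dependent (≈150 kb mean at
15 loops/Mb) because anchors accumulate as obstacles. `loop_stats()`
reports realized statistics; `obstacle_gap_stats()` reports the gap
distribution; `scripts/acceptance.R` logs both and reports the gap
statistics as the loop-size calibration.

Coverage — the fraction of DNA inside at least one loop
(`dna_fraction_in_loops`) — rises from ~40% at 2 loops/Mb to ~70% at 6 and
~95% at 25 loops/Mb on a 249-Mb chromosome, and is exactly checked against
a base-pair boolean-mask oracle on toy chromosomes.

## 3. Multi-scale polymer model

The nucleus holds 46 independent bead-spring chains (homologs are not
distinguished; hg38 lengths rounded to the Mb, chromosome 1 pinned at
249 Mb). Three phases (`run_three_phase()`):

1. **Coarse**: one bead per Mb (300 nm), confined random-walk
   initialization inside a 4.95 µm sphere, Langevin equilibration.
2. **Fine-graining**: the focal chromosome steps down the resolution
   ladder 1 Mb → 500 → 250 → 50 → 10 → 5 kb; each bead splits into 2 or 5
   children displaced by an isotropic Gaussian (sd 45 nm per coordinate),
   with a dynamics stage after each step while the nuclear radius grows
   linearly to 5.4 µm.
3. **Loops**: each phase-2 configuration is reused for every loop density;
   anchors become harmonic bonds identical to chain bonds and the system
   equilibrates once more.

Forces: harmonic bonds (stiffness `100·kT/σ²`, rest length = bead
diameter), WCA excluded volume between all pairs except B–B, a truncated
Lennard-Jones attraction between B-compartment beads (depth `eps_BB`,
default 0.3 kT, cutoff 1.8 σ), and a one-sided harmonic wall at the
nuclear radius (differentiable, thermostat-friendly, unlike a reflective
boundary). Integration is BAOAB Langevin (`dt` = 0.005, friction 1, kT 1 in
reduced units, lengths scaled by the smallest bead diameter); pair forces
are capped so overlapping initial configurations push apart smoothly. The
thermostat noise uses a fast internal counter-based generator seeded from
R's RNG stream, so trajectories are reproducible under `set.seed()`. These
force-field constants are the package's own defaults — general-purpose MD
engines leave them to the user, and no reference settings exist for this
system — and all of them are arguments of `sim_params()`.

Two printed anchors fix the bead-diameter schedule: 300 nm at 1 Mb and
45 nm at 5 kb. Between them the package interpolates geometrically,
`d(g) = 300·(g/1 Mb)^p` nm with `p = ln(300/45)/ln(200) ≈ 0.358`. A
constant-occupancy rule cannot honor both anchors at once, so occupancy is
*reported* (`volume_occupancy()`), not enforced; with this karyotype and
geometry the coarse system sits near 8–9%, not at a nominal 12%.

Physical sanity is property-tested: a thermalized dimer matches the
numerically integrated radial bond-length density (including the WCA term
bonded neighbors also feel); a free excluded-volume chain swells with a
Flory-like exponent in [0.5, 0.65] when every size gets an equilibration
budget proportional to N²; B–B attraction measurably increases inter-chain
contacts; ≥90% of loop-anchor pairs sit within two bead diameters after the
loop phase.

## 4. Synthetic SMLM images

`simulate_smlm_image()` composes three stages:

* `chain_to_localizations()` — a fixed budget of `round(600 × Mb)`
  localizations at uniformly random genomic positions, mapped to 3D by
  linear interpolation between flanking bead centers. (A fixed budget, not
  Poisson, mirrors a *distributed* localization count; the background, a
  density, is Poisson.)
* `add_background()` — Poisson(150/µm³ × volume) uniform points in the
  structure's bounding cube (bounding box padded 10%, expanded to its
  longest side).
* `perturb_localizations()` — i.i.d. Gaussian error, 65 nm per coordinate.

The generator is fully determined by (chain, interval, parameters, seed).

**Calibration caveat.** The 65-nm error is documented as matching an
image resolution of ~150 nm by Fourier ring correlation. With a standard
half-split FRC (10-nm pixels, 1/7 threshold, 3-ring smoothing —
`frc_resolution()`), the default generator instead measures ~190–215 nm on
every structure family we tried (desk polymer chains, 5-kb-resolution
confined walks, compartment-blob chains of 50–150 Mb): at 600
localizations/Mb the measurement is count-limited, and only ~10× the
localization budget or a ~45-nm error reaches ~150 nm. The corresponding
calibration check in the test suite is therefore expected to fail and is
kept at its nominal value deliberately; FRC degrading monotonically with
the error sd, and the Nyquist floor for identical halves, are verified.
A plausible explanation is that repeated localizations of the same
fluorophore, present in real SMLM data but not in this generator,
correlate between half-images and flatter the empirical FRC curve.

## 5. Voronoi segmentation and shape statistics

No 3D computational-geometry package is assumed: the tessellation engine is
part of the package (Rcpp). Each Voronoi cell is computed independently by
clipping the padded bounding box with the bisector planes of neighbors in
increasing-distance order, stopping once no farther point can cut the cell;
cell volumes, the cell-adjacency graph, and — from the Voronoi dual — the
Delaunay tetrahedra (each cell vertex defined by three bisectors is a
circumcenter) come out of the same pass. Cells tile the box exactly
(machine precision, tested), and the k-ring neighborhoods agree with a
breadth-first-search oracle.

* **Local density** (`voronoi_local_density()`): count/volume of all cells
  within `k = 2` adjacency rings (k = 0 is the inverse own-cell volume).
  The bounding box is padded by 0.5% of the diagonal: measured on
  homogeneous Poisson data, larger pads inflate every boundary cell and
  bias the density median tens of percent low, while 0.5% keeps the median
  within ~9% of the true intensity.
* **Background and threshold** (`estimate_background_density()`,
  `segment_by_density()`): the threshold is 4× the mean density in a
  background ROI. The automatic ROI is the lowest-mean-density sub-box of
  a 4×4×4 grid over the bounding cube (with ≥20 points): compact
  structures fill every octant of their own bounding cube and extended
  chains reach every corner, so neither a fixed corner nor a
  farthest-from-centroid octant reliably isolates background. The pick is
  deliberately conservative (a low-order statistic of sub-box means);
  explicit ROIs behave like the manual background regions of the imaging
  workflow. On the model's own imaged structures, segmentation precision
  is ≈0.95 and recall ≈0.99.
* **Gyration radius** (`gyration_radius()`): RMS distance to the centroid;
  equals a brute-force pairwise oracle to 1e-9.
* **α-concave hulls** (`alpha_concave_volume()`, `smoothness()`):
  coordinates are rescaled per axis by 1/α, the Delaunay tetrahedra whose
  scaled circumradius exceeds 1 are removed, and the surviving volume is
  mapped back. Tetrahedra with *larger* circumradius are removed — the
  direction that makes a convex shape score `S = 100%`. The anisotropic
  α (z doubled) compensates the poorer axial resolution of 3D SMLM.
  For α far beyond the data extent the scaled cloud collapses numerically,
  so α is clamped once the scaled diagonal falls below 0.02 — identical
  volumes, since only tetrahedra with circumradius beyond ~50 data
  diameters (volume-free slivers) are affected; at that setting the hull
  volume equals a brute-force convex-hull oracle exactly.
  `S = 100·V_α1/V_α2` is bounded in [0, 100] for proportional α families
  (monotonicity tested), ≈100 for dense convex blobs, lower once holes or
  protrusions appear at the 0.2–2 µm scale.

## 6. Contact maps and compartment recovery

`contacts_from_config()` lists bead pairs within a cutoff (default 2× the
bead diameter — the radius must scale with the bead size), verified
against an O(N²) oracle.
`aggregate_contact_map()` bins and sums contacts across configurations;
`compartment_eigenvector()` normalizes observed/expected per diagonal,
takes the Pearson correlation matrix and its first principal component,
and orients the sign so positive means A when reference labels are given.

On an analytic checkerboard map the recovery is exact. On simulated
reduced ensembles (a 100-Mb chromosome, geometric 5-Mb compartment blocks,
20 configurations at 500-kb beads) the eigenvector correlates ~0.9 with
the input labels, but per-bin sign agreement saturates near 75–80%: the
errors concentrate in 1–2-Mb minority islands and block-boundary bins
whose beads genuinely join the neighboring condensate at this ensemble
size. The recovery test therefore requires ≥80% agreement on interior bins
(both neighbors sharing the bin's label) and ≥60% overall; whole-map
agreement at the full scale of the study (249 one-Mb bins, 100
configurations, a crowded 46-chromosome nucleus) is beyond a desk-scale
suite.

## 7. The in-silico experiment and statistics

`run_experiment()` chains everything: snapshots × densities → SCE split of
the focal chromosome (≥5 Mb) → localizations → background → error →
Voronoi segmentation (automatic background ROI) → `Rg` and `S` per region,
with full provenance and a documented seed-splitting scheme (the split
seed depends only on the replicate, so every density is imaged on the same
fragment intervals — the same pairing the three-phase design gives the
polymer states). Pooled fragments, not one per configuration, enter the
group statistics.

`compare_groups()` (two-sided Wilcoxon rank-sum),
`bootstrap_median_diff()` (percentile CI over paired resamples), and
`correlate_with_counts()` (Spearman vs localization counts) are thin
wrappers over standard library routines — the bespoke science is upstream.
At desk scale (one 20-Mb chromosome per replicate, 30 replicates per arm,
50-kb beads) the directional core of the full-scale result holds with
rank-sum p < 0.05: more loops give smaller `Rg` and larger `S`. The
*absolute* full-scale medians (`Rg` 1.30 → 1.21 µm and `S` 55.4 → 66.7%
from 0 to 25 loops/Mb, 102 replicates of a 5-kb-resolution chromosome 1 in
a whole nucleus with 3×10⁶-step equilibration) are cluster-scale and are
not recomputed here.

`Rg` correlates strongly with localization counts (hence region size)
while `S` correlates much less — the motivation for using a dimensionless
shape score at all — and both behaviors are checked on generated
ensembles.

## 8. Problem sizes and reproducibility

The suite runs everything at reduced scale by choice: 10–40-Mb desk
chromosomes, 20–50 polymer configurations per ensemble, 10⁴ Monte-Carlo
replicates for the labeling and loop statistics, ≥10⁴ obstacle gaps for
the size calibration. `scripts/acceptance.R` recomputes the headline
numbers at those sizes in a few minutes on one core; every random draw in
the package flows through explicit `seed` arguments, and end-to-end
determinism under a master seed is itself a test.

Known limitations: the generator draws each localization independently
(no fluorophore re-blinking, no frame structure, no drift), the SCE model
is a reconstruction (single exchange per division by default), force-field
constants are package defaults rather than measured values, and the
desk-scale ensembles are far from the study's compute scale — the tests
establish directions, invariants and oracle agreement, not the full-scale
medians.
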