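# chromloops

Polymer simulation and single-molecule-localization quantification of
chromatin loops in single human cells.

## The problem

Hi-C and related assays say that cohesin extrudes chromatin loops, but they
average over millions of cells, so they cannot say how many loops coexist in
one nucleus at one moment. One way to get at that number is to (i) label and
image large chromatin regions of single chromosomes in situ with 3D
single-molecule localization microscopy (SMLM), (ii) simulate the same
regions with a whole-nucleus polymer model carrying a known number of
cohesin-like loops per megabase, (iii) render the simulated polymers as
synthetic SMLM images with matched localization density, background and
localization error, and (iv) compare shape statistics — the gyration radius
`Rg` and a "smoothness" score `S` — between real and simulated images across
loop densities. The loop density whose simulated statistics match the data is
the estimate.

`chromloops` implements the computational side of that program:

- **Dilution labeling / SCE model.** After `m` divisions post-labeling a
  cell keeps `46·2^-m` labeled chromosomes on average (`p0 = (1-2^-m)^46`,
  `p1 = 46·2^-m (1-2^-m)^45`); sister-chromatid exchange (SCE, probability
  ~0.18 per chromosome per division) fragments the labeled strand. The
  simulator reproduces the predicted labeled-fragment size distribution
  (median ~50 Mb) and splits chromosomes into imaging sub-chains.
- **Loop placement.** Extrusion obstacles are spaced with gap density
  `f(L) = (L/L0²)·e^(-L/L0)` (`L0` = 165 kb, i.e. Gamma(2, L0): mean 330 kb,
  median ~277 kb); loops load uniformly and extrude each side an
  exponential distance (mean `d0` = 250 kb), stopping at obstacles,
  previous anchors, or chromosome ends. Densities 0–25 loops/Mb.
- **Multi-scale polymer dynamics.** 46 chromosomes at 1 Mb/bead (300 nm)
  in a 4.95 µm nucleus with attractive B–B (compartment) interactions;
  one chromosome is progressively fine-grained to 5 kb/bead (45 nm) while
  the nucleus grows to 5.4 µm; loop anchors become harmonic bonds.
  Langevin dynamics (BAOAB) with cell-list neighbor search, in Rcpp.
- **Synthetic SMLM images.** 600 localizations/Mb interpolated along the
  chain, uniform background at 150/µm³ in the bounding cube, isotropic
  Gaussian localization error (65 nm).
- **Quantification.** 3D Voronoi local density (k = 2 adjacency rings),
  background thresholding at 4× a background-ROI density,
  `Rg = sqrt(mean ||x_i - x̄||²)`, anisotropic α-concave-hull volumes at
  α₁ = (100, 100, 200) nm and α₂ = (500, 500, 1000) nm,
  `S = 100·V_α1/V_α2`, and Fourier-ring-correlation resolution. The 3D
  Voronoi/Delaunay engine is built in (convex-cell clipping; the Delaunay
  tetrahedra come from the Voronoi dual).
- **Contact analysis and statistics.** In-silico contact maps, the
  compartment eigenvector (O/E → Pearson correlation → first PC), rank-sum
  comparisons, bootstrap CIs, Spearman correlations with counts.

## Worked example

```r
library(chromloops)

# dilution arithmetic: after 6 divisions ~0.72 labeled chromosomes remain
expected_labeled(6, 46)
#> [1] 0.71875
100 * fraction_with_sce(0.2, 6)   # percent of chromosomes with >= 1 SCE
#> [1] 73.7856

# labeled-fragment sizes across 10,000 replicate cells
fr <- simulate_labeled_fragments(default_human_karyotype(),
                                 m = 6, sce_rate = 0.18,
                                 n_cells = 10000, seed = 1)
median(fr$end - fr$start) / 1e6    # Mb; the predicted median is ~50 Mb
#> [1] 47.45254

# loops at 25 per Mb on a 249-Mb chromosome: how much DNA is in loops?
ls <- place_loops(249e6, density = 25, seed = 1)
loop_stats(ls)$dna_fraction_in_loops
#> [1] 0.9530994

# a reduced end-to-end experiment: simulate, image, segment, measure
cfg <- desk_config(densities = c(0, 25), n_replicates = 20, seed = 5)
tab <- run_experiment(cfg)
summarize_metrics(tab, "rg_nm")
#> # A tibble: 2 × 6
#>   loop_density     n    q1 median    q3   iqr
#>          <dbl> <int> <dbl>  <dbl> <dbl> <dbl>
#> 1            0    25  847.   992. 1094.  247.
#> 2           25    25  774.   908. 1010.  236.
compare_groups(tab[tab$loop_density == 0, ],
               tab[tab$loop_density == 25, ], "s_percent")
#> # A tibble: 1 × 3
#>   median_a median_b p_value
#>      <dbl>    <dbl>   <dbl>
#> 1     44.5     50.4 0.00434
```

More loops make the imaged regions smaller (median `Rg` 992 vs 908 nm
above) and significantly smoother (median `S` 44.5% vs 50.4%, two-sided
rank-sum p = 0.004) — the qualitative signature used to bracket the
in-vivo loop density between ~6 and ~25 per Mb. Smoothness discriminates
at smaller sample sizes than `Rg`, which is why a dimensionless shape
score is used at all.

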