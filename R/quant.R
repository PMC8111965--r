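loc_matrix <- function(locs) {
  stopifnot(all(c("x_nm", "y_nm", "z_nm") %in% names(locs)))
  m <- cbind(locs$x_nm, locs$y_nm, locs$z_nm)
  if (any(!is.finite(m))) rlang::abort("non-finite coordinates")
  m
}

#' Voronoi local density of a 3D localization set
#'
#' Computes the 3D Voronoi tessellation of the localizations, bounded by
#' clipping every cell against the bounding box padded by `pad_frac` of its
#' diagonal. The local density at localization i is the number of cells
#' within graph distance `k` in the cell-adjacency graph (the cell itself
#' included; `k = 0` gives 1 / own cell volume) divided by the summed volume
#' of those cells.
#'
#' Duplicate points make the tessellation degenerate; the input is jittered
#' by a negligible amount and retried once before failing.
#'
#' @param locs Localization tibble (at least 5 localizations).
#' @param k Neighborhood ring count (default 2).
#' @param pad_frac Box padding as a fraction of the bounding-box diagonal
#'   (default 0.005).
#' @return A tibble with columns `density` (localizations per nm^3) and
#'   `cell_volume` (nm^3), one row per localization, with attributes
#'   `adjacency` (list of 1-based neighbor indices) and `k`.
#' @export
voronoi_local_density <- function(locs, k = 2, pad_frac = 0.005) {
  stopifnot(k >= 0, nrow(locs) >= 5)
  m <- loc_matrix(locs)
  lo <- apply(m, 2, min)
  hi <- apply(m, 2, max)
  pad <- sqrt(sum((hi - lo)^2)) * pad_frac
  if (pad == 0) rlang::abort("degenerate localization set (all points identical)")
  cells <- tryCatch(
    voronoi_cells_cpp(m, lo - pad, hi + pad, FALSE),
    error = function(e) {
      jit <- matrix(stats::runif(length(m), -pad * 1e-9, pad * 1e-9),
                    ncol = 3)
      voronoi_cells_cpp(m + jit, lo - pad, hi + pad, FALSE)
    }
  )
  dens <- kring_density_cpp(cells$adjacency, cells$volumes, k)
  out <- tibble::tibble(density = dens, cell_volume = cells$volumes)
  attr(out, "adjacency") <- cells$adjacency
  attr(out, "k") <- k
  out
}

# automatic background ROI: the padded bounding cube is divided into a
# grid_n^3 grid and the sub-box with the lowest mean local density (among
# boxes holding at least min_points localizations) is taken as background.
# Compact structures fill every octant of their own bounding cube, so the
# search must be finer than octants to find structure-free space
roi_auto <- function(locs, densities, min_points, grid_n = 4) {
  cube <- bounding_cube(locs)
  side <- cube$side / grid_n
  cells <- as.matrix(expand.grid(seq_len(grid_n) - 1, seq_len(grid_n) - 1,
                                 seq_len(grid_n) - 1))
  best <- NULL
  best_mean <- Inf
  for (ci in seq_len(nrow(cells))) {
    b <- cells[ci, ]
    r <- list(lo = cube$lo + b * side, hi = cube$lo + (b + 1) * side)
    inside <- in_box(locs, r)
    if (sum(inside) < min_points) next
    m <- mean(densities$density[inside])
    if (m < best_mean) {
      best_mean <- m
      best <- r
    }
  }
  if (is.null(best)) {
    rlang::abort("no bounding-cube sub-box holds enough localizations for a background ROI")
  }
  best
}

in_box <- function(locs, r) {
  locs$x_nm >= r$lo[1] & locs$x_nm <= r$hi[1] &
    locs$y_nm >= r$lo[2] & locs$y_nm <= r$hi[2] &
    locs$z_nm >= r$lo[3] & locs$z_nm <= r$hi[3]
}

#' Estimate the background localization density
#'
#' Mean Voronoi local density over the localizations inside a background
#' region of interest. The ROI is either given explicitly as an axis-aligned
#' box, or (for synthetic data) chosen automatically as the octant of the
#' padded bounding cube with the lowest mean local density (among octants
#' holding at least `min_points` localizations).
#'
#' @param locs Localization tibble.
#' @param densities Density tibble from [voronoi_local_density()].
#' @param roi `"auto"` or a numeric vector
#'   `c(x0, y0, z0, x1, y1, z1)` in nm.
#' @param min_points Minimum number of localizations required inside the ROI
#'   (default 20).
#' @return Background density in localizations per nm^3.
#' @export
estimate_background_density <- function(locs, densities, roi = "auto",
                                        min_points = 20) {
  if (identical(roi, "auto")) {
    r <- roi_auto(locs, densities, min_points)
  } else {
    stopifnot(is.numeric(roi), length(roi) == 6)
    r <- list(lo = roi[1:3], hi = roi[4:6])
  }
  inside <- in_box(locs, r)
  if (sum(inside) < min_points) {
    rlang::abort(paste0("only ", sum(inside),
                        " localizations in background ROI (need ",
                        min_points, ")"))
  }
  mean(densities$density[inside])
}

#' Threshold localizations against the background density
#'
#' Retains localizations whose local density is at least `bg_factor` times
#' the background density (ties retained); all others are considered
#' background and eliminated.
#'
#' @param locs Localization tibble.
#' @param densities Density tibble from [voronoi_local_density()].
#' @param bg_density Background density (localizations per nm^3).
#' @param bg_factor Threshold multiplier (default 4).
#' @return The localization tibble with a logical `retained` column and
#'   attributes `threshold` and `bg_density`.
#' @export
segment_by_density <- function(locs, densities, bg_density, bg_factor = 4) {
  stopifnot(nrow(locs) == nrow(densities), bg_factor >= 0, bg_density >= 0)
  threshold <- bg_factor * bg_density
  out <- dplyr::mutate(locs, retained = densities$density >= threshold)
  attr(out, "threshold") <- threshold
  attr(out, "bg_density") <- bg_density
  out
}

#' Gyration radius of a localization set
#'
#' `Rg = sqrt(mean(||x_i - centroid||^2))`: the root-mean-square distance of
#' the localizations from their centroid, the standard size measure of an
#' imaged chromatin region.
#'
#' @param locs Localization tibble (at least one row).
#' @return Gyration radius in nm.
#' @export
gyration_radius <- function(locs) {
  if (nrow(locs) == 0) rlang::abort("empty localization set")
  m <- loc_matrix(locs)
  ctr <- colMeans(m)
  sqrt(mean(rowSums((m - rep(ctr, each = nrow(m)))^2)))
}

#' Volume of the anisotropic alpha-concave hull
#'
#' Computes the Delaunay tetrahedralization of the localizations after
#' rescaling each axis by `1 / alpha`, removes every tetrahedron whose
#' circumsphere radius in the rescaled space exceeds 1 (equivalently, whose
#' circum-ellipsoid in the original space exceeds the `alpha` radii), and
#' returns the total volume of the surviving tetrahedra in the original
#' space. As `alpha` grows the hull converges to the convex hull; for
#' `alpha` below the point spacing the volume is 0.
#'
#' @param locs Localization tibble (at least 5 points in general position).
#' @param alpha Numeric length-3 vector of ellipsoid radii in nm
#'   (x, y, z).
#' @return Hull volume in nm^3.
#' @export
alpha_concave_volume <- function(locs, alpha) {
  stopifnot(length(alpha) == 3, all(alpha > 0), nrow(locs) >= 5)
  m <- loc_matrix(locs)
  # alpha far beyond the data extent is numerically degenerate (the scaled
  # point cloud collapses); shrink it uniformly so the scaled diagonal stays
  # at 0.02 -- identical result, since only tetrahedra with circumradius
  # beyond ~50 data diameters are affected and those are volume-free
  # slivers
  rng <- apply(m, 2, function(v) diff(range(v)))
  diag_s <- sqrt(sum((rng / alpha)^2))
  if (diag_s < 0.02) alpha <- alpha * (diag_s / 0.02)
  sm <- sweep(m, 2, alpha, "/")
  lo <- apply(sm, 2, min)
  hi <- apply(sm, 2, max)
  # circumcenters of retained tetrahedra (scaled radius <= 1) lie within 1
  # of a point, so a fixed pad of 2.5 scaled units captures them all
  cells <- tryCatch(
    voronoi_cells_cpp(sm, lo - 2.5, hi + 2.5, TRUE),
    error = function(e) {
      diag <- sqrt(sum((hi - lo)^2)) + 1
      jit <- matrix(stats::runif(length(sm), -diag * 1e-9, diag * 1e-9),
                    ncol = 3)
      voronoi_cells_cpp(sm + jit, lo - 2.5, hi + 2.5, TRUE)
    }
  )
  keep <- cells$circumradius <= 1
  sum(cells$tet_volume[keep]) * prod(alpha)
}

#' Smoothness of a localization set
#'
#' `S = 100 * V_alpha1 / V_alpha2`, the percent ratio of the fine-scale to
#' the coarse-scale alpha-concave hull volume. Convex, smooth shapes give
#' S near 100%; sub-micron holes and protrusions reduce it.
#'
#' @param locs Localization tibble.
#' @param alpha1 Fine-scale ellipsoid radii in nm (default
#'   `c(100, 100, 200)`).
#' @param alpha2 Coarse-scale radii, componentwise proportional to and at
#'   least `alpha1` (default `c(500, 500, 1000)`).
#' @return Smoothness in percent.
#' @export
smoothness <- function(locs, alpha1 = c(100, 100, 200),
                       alpha2 = c(500, 500, 1000)) {
  stopifnot(all(alpha2 >= alpha1))
  ratios <- alpha2 / alpha1
  if (max(ratios) - min(ratios) > 1e-9 * max(ratios)) {
    rlang::abort("alpha2 must be proportional to alpha1")
  }
  v2 <- alpha_concave_volume(locs, alpha2)
  if (v2 == 0) rlang::abort("coarse alpha hull has zero volume")
  v1 <- alpha_concave_volume(locs, alpha1)
  100 * v1 / v2
}

#' Image resolution by Fourier ring correlation
#'
#' The localizations are split into two random halves, each rendered as a
#' 2D x-y histogram at `pixel_nm`; the FRC curve is the ring-wise normalized
#' cross-correlation of their Fourier transforms, smoothed by a 3-ring
#' moving average. The resolution is the inverse of the spatial frequency
#' at the first crossing below `threshold` (conventionally 1/7). If the
#' curve stays above the threshold out to the Nyquist frequency the
#' resolution is reported as `2 * pixel_nm` (the Nyquist floor); if it
#' starts below the threshold the image is unresolved and `NA` is returned.
#'
#' @param locs Localization tibble (>= 1000 localizations recommended).
#' @param pixel_nm Rendering pixel size in nm (default 10).
#' @param threshold FRC threshold (default 1/7).
#' @param split If `FALSE`, correlate the full set with itself (FRC is
#'   identically 1; used to verify the Nyquist floor).
#' @param seed Optional integer seed for the random split.
#' @return Resolution in nm (`NA` if unresolved).
#' @export
frc_resolution <- function(locs, pixel_nm = 10, threshold = 1 / 7,
                           split = TRUE, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  n <- nrow(locs)
  stopifnot(n >= 10)
  if (split) {
    half <- sample.int(n, floor(n / 2))
    a <- locs[half, ]
    b <- locs[-half, ]
  } else {
    a <- locs
    b <- locs
  }
  xr <- range(locs$x_nm)
  yr <- range(locs$y_nm)
  npx <- 2^ceiling(log2(max(diff(xr), diff(yr)) / pixel_nm + 2))
  npx <- max(npx, 64)
  if (npx > 2048) {
    pixel_nm <- pixel_nm * npx / 2048
    npx <- 2048
  }
  render <- function(h) {
    ix <- pmin(pmax(floor((h$x_nm - xr[1]) / pixel_nm), 0), npx - 1)
    iy <- pmin(pmax(floor((h$y_nm - yr[1]) / pixel_nm), 0), npx - 1)
    img <- matrix(0, npx, npx)
    tab <- table(ix * npx + iy)
    idx <- as.integer(names(tab)) + 1L
    img[idx] <- as.numeric(tab)
    img
  }
  fa <- stats::fft(render(a))
  fb <- stats::fft(render(b))
  # ring index per frequency pixel (FFT layout: frequency k/npx, wrapped)
  fi <- c(0:(npx / 2), (npx / 2 - 1):1)
  ring <- outer(fi^2, fi^2, "+")
  ring <- floor(sqrt(ring))
  nr <- npx / 2
  num <- rowsum(as.vector(Re(fa * Conj(fb))), as.vector(ring))
  d1 <- rowsum(as.vector(Mod(fa)^2), as.vector(ring))
  d2 <- rowsum(as.vector(Mod(fb)^2), as.vector(ring))
  rid <- as.integer(rownames(num))
  keep <- rid >= 1 & rid <= nr
  frc <- num[keep] / sqrt(d1[keep] * d2[keep])
  frc <- stats::filter(frc, rep(1 / 3, 3), sides = 2)
  frc[is.na(frc)] <- 1  # edge rings keep their neighbors' trend
  r <- rid[keep]
  below <- which(frc < threshold)
  if (length(below) == 0) return(2 * pixel_nm)
  first <- below[1]
  if (first == 1) return(NA_real_)
  # linear interpolation between the last ring above and the first below
  f1 <- frc[first - 1]
  f2 <- frc[first]
  rc <- r[first - 1] + (f1 - threshold) / (f1 - f2)
  freq <- rc / (npx * pixel_nm)
  1 / freq
}
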