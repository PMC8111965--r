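#' Convert a polymer chain interval into structure localizations
#'
#' Emulates the labeling density of the imaging experiment: `round(locs_per_mb
#' * interval_size / 1 Mb)` genomic positions are drawn uniformly over the
#' interval and each is mapped to 3D by linear interpolation between the
#' centers of the two flanking beads. The localization budget is a fixed
#' (rounded) count, matching a fixed number of distributed localizations
#' rather than a Poisson density.
#'
#' @param chain A bead chain (see [init_coarse_nucleus()]): list with
#'   `bin_edges` (bp) and `positions` (N x 3 nm matrix).
#' @param interval Numeric length-2 vector `c(start, end)` in bp, within the
#'   chain's chromosome.
#' @param locs_per_mb Localizations per megabase (default 600).
#' @param seed Optional integer seed.
#' @return A localization tibble with columns `x_nm`, `y_nm`, `z_nm`,
#'   `source` (here `"structure"`).
#' @export
chain_to_localizations <- function(chain, interval, locs_per_mb = 600,
                                   seed = NULL) {
  stopifnot(length(interval) == 2, interval[2] > interval[1],
            interval[1] >= min(chain$bin_edges),
            interval[2] <= max(chain$bin_edges))
  if (!is.null(seed)) withr::local_seed(seed)
  n <- round(locs_per_mb * (interval[2] - interval[1]) / 1e6)
  if (n == 0) {
    return(tibble::tibble(x_nm = numeric(), y_nm = numeric(),
                          z_nm = numeric(), source = character()))
  }
  g <- stats::runif(n, interval[1], interval[2])
  # bead centers sit at bin midpoints; interpolate genomic position between
  # consecutive centers (clamped at the chain ends)
  mid <- (chain$bin_edges[-1] + chain$bin_edges[-length(chain$bin_edges)]) / 2
  xyz <- vapply(1:3, function(d) {
    stats::approx(mid, chain$positions[, d], xout = g, rule = 2)$y
  }, numeric(n))
  if (n == 1) xyz <- matrix(xyz, nrow = 1)
  tibble::tibble(x_nm = xyz[, 1], y_nm = xyz[, 2], z_nm = xyz[, 3],
                 source = "structure")
}

# axis-aligned bounding cube of the structure, padded and expanded to the
# longest side
bounding_cube <- function(locs, pad_frac = 0.1) {
  m <- cbind(locs$x_nm, locs$y_nm, locs$z_nm)
  lo <- apply(m, 2, min)
  hi <- apply(m, 2, max)
  side <- max(hi - lo) * (1 + pad_frac)
  ctr <- (lo + hi) / 2
  list(lo = ctr - side / 2, hi = ctr + side / 2, side = side)
}

#' Add uniform background localizations
#'
#' Appends `Poisson(bg_density x cube volume)` uniformly distributed points
#' in the axis-aligned bounding cube of the structure (bounding box padded
#' by 10% and expanded to its longest side), emulating unspecific
#' localizations around the imaged region.
#'
#' @param locs Localization tibble (non-empty; it defines the cube).
#' @param bg_density Background density in localizations per cubic
#'   micrometer (default 150).
#' @param seed Optional integer seed.
#' @return The localization tibble with background rows appended
#'   (`source = "background"`).
#' @export
add_background <- function(locs, bg_density = 150, seed = NULL) {
  stopifnot(nrow(locs) > 0, bg_density >= 0)
  if (bg_density == 0) return(locs)
  if (!is.null(seed)) withr::local_seed(seed)
  cube <- bounding_cube(locs)
  vol_um3 <- (cube$side / 1e3)^3
  n <- stats::rpois(1, bg_density * vol_um3)
  bg <- tibble::tibble(
    x_nm = stats::runif(n, cube$lo[1], cube$hi[1]),
    y_nm = stats::runif(n, cube$lo[2], cube$hi[2]),
    z_nm = stats::runif(n, cube$lo[3], cube$hi[3]),
    source = "background"
  )
  dplyr::bind_rows(locs, bg)
}

#' Apply isotropic Gaussian localization error
#'
#' Adds i.i.d. Gaussian noise with standard deviation `loc_error_sd` to each
#' coordinate of every localization, emulating the finite localization
#' precision of the microscope (the default 65 nm reproduces an image
#' resolution of about 150 nm by Fourier ring correlation).
#'
#' @param locs Localization tibble.
#' @param loc_error_sd Per-coordinate standard deviation in nm (default 65).
#' @param seed Optional integer seed.
#' @return The perturbed localization tibble.
#' @export
perturb_localizations <- function(locs, loc_error_sd = 65, seed = NULL) {
  stopifnot(loc_error_sd >= 0)
  if (loc_error_sd == 0 || nrow(locs) == 0) return(locs)
  if (!is.null(seed)) withr::local_seed(seed)
  n <- nrow(locs)
  dplyr::mutate(locs,
                x_nm = .data$x_nm + stats::rnorm(n, 0, loc_error_sd),
                y_nm = .data$y_nm + stats::rnorm(n, 0, loc_error_sd),
                z_nm = .data$z_nm + stats::rnorm(n, 0, loc_error_sd))
}

#' Read / write localization tables
#'
#' CSV with a header; columns `x_nm`, `y_nm`, `z_nm` are required, a
#' `source` column is optional (imports without one get
#' `source = "unknown"`). Extra columns (e.g. `frame`, `intensity`) are
#' preserved. Coordinates round-trip at full double precision.
#'
#' @param locs Localization tibble.
#' @param path File path.
#' @return `read_localizations()` returns a localization tibble.
#' @export
write_localizations <- function(locs, path) {
  readr::write_csv(locs, path)
  invisible(path)
}

#' @rdname write_localizations
#' @export
read_localizations <- function(path) {
  locs <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("x_nm", "y_nm", "z_nm"), names(locs))
  if (length(missing) > 0) {
    rlang::abort(paste0("missing required column(s): ",
                        paste(missing, collapse = ", ")))
  }
  for (cn in c("x_nm", "y_nm", "z_nm")) {
    if (!is.numeric(locs[[cn]])) {
      rlang::abort(paste0("non-numeric coordinates in column ", cn))
    }
  }
  if (!"source" %in% names(locs)) locs$source <- "unknown"
  locs
}

#' End-to-end synthetic SMLM image of a chain fragment
#'
#' Convenience wrapper: structure localizations ([chain_to_localizations()]),
#' uniform background ([add_background()]) and localization error
#' ([perturb_localizations()]) in the order of the imaging model.
#'
#' @inheritParams chain_to_localizations
#' @inheritParams add_background
#' @inheritParams perturb_localizations
#' @return A localization tibble with `source` labels.
#' @export
simulate_smlm_image <- function(chain, interval, locs_per_mb = 600,
                                bg_density = 150, loc_error_sd = 65,
                                seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  chain_to_localizations(chain, interval, locs_per_mb) |>
    add_background(bg_density) |>
    perturb_localizations(loc_error_sd)
}
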