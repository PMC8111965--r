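#' Run the full in-silico imaging experiment
#'
#' For every polymer snapshot produced by [run_three_phase()] and every loop
#' density: the focal chromosome is split into labeled sub-chains by the
#' dilution/SCE model (sub-chains below `min_fragment` are discarded),
#' each sub-chain is converted to a synthetic SMLM localization set
#' (structure localizations, uniform background, localization error), the
#' set is segmented by Voronoi density against the automatically estimated
#' background, and the gyration radius and smoothness of the retained
#' localizations are recorded.
#'
#' @param config Configuration list as for [run_three_phase()]; additional
#'   imaging elements `locs_per_mb` (600), `bg_density` (150 per um^3),
#'   `loc_error_sd` (65 nm), `min_fragment` (5 Mb), `sce_rate` (0.18) and
#'   `m_divisions` (6) are recognized.
#' @param snapshots Optionally, precomputed snapshots from
#'   [run_three_phase()] (skips the polymer stage).
#' @return A region-metrics tibble: one row per imaged region with
#'   `region_id`, `replicate`, `loop_density`, `fragment_start`,
#'   `fragment_end`, `fragment_size`, `n_locs`, `rg_nm`, `s_percent`,
#'   `seed`.
#' @export
run_experiment <- function(config, snapshots = NULL) {
  cfg <- config
  if (is.null(snapshots)) snapshots <- run_three_phase(cfg)
  locs_per_mb <- cfg$locs_per_mb %||% 600
  bg_density <- cfg$bg_density %||% 150
  loc_error_sd <- cfg$loc_error_sd %||% 65
  min_fragment <- cfg$min_fragment %||% 5e6
  sce_rate <- cfg$sce_rate %||% 0.18
  m_div <- cfg$m_divisions %||% 6
  base_seed <- cfg$seed %||% 1
  rows <- list()
  for (si in seq_along(snapshots)) {
    snap <- snapshots[[si]]
    chain <- snap$state$chains[[cfg$fine_chrom]]
    len <- chain$bin_edges[length(chain$bin_edges)]
    # split seed depends on the replicate only: every loop density of one
    # replicate is imaged on the same fragment intervals (paired arms)
    s_img <- (base_seed + 104729 * snap$replicate) %% .Machine$integer.max
    frags <- split_chain_for_imaging(len, m = m_div, sce_rate = sce_rate,
                                     min_size = min_fragment, seed = s_img)
    if (nrow(frags) == 0) next
    for (fi in seq_len(nrow(frags))) {
      s_frag <- (s_img + fi) %% .Machine$integer.max
      met <- tryCatch(
        quantify_fragment(chain, c(frags$start[fi], frags$end[fi]),
                          locs_per_mb = locs_per_mb, bg_density = bg_density,
                          loc_error_sd = loc_error_sd, seed = s_frag),
        error = function(e) NULL
      )
      if (is.null(met)) next
      rows[[length(rows) + 1]] <- tibble::tibble(
        region_id = sprintf("r%03d_d%g_f%d", snap$replicate, snap$density, fi),
        replicate = snap$replicate,
        loop_density = snap$density,
        fragment_start = frags$start[fi],
        fragment_end = frags$end[fi],
        fragment_size = frags$end[fi] - frags$start[fi],
        n_locs = met$n_locs, rg_nm = met$rg_nm, s_percent = met$s_percent,
        seed = s_frag
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Segment and quantify one synthetic chromatin region
#'
#' The per-region quantification used by [run_experiment()]: synthetic SMLM
#' image of the chain interval, Voronoi local density (k rings),
#' background-octant density estimate, thresholding at `bg_factor` times the
#' background, then gyration radius and smoothness of the retained
#' localizations.
#'
#' @inheritParams simulate_smlm_image
#' @param k,bg_factor,alpha1,alpha2 Quantification parameters (see
#'   [voronoi_local_density()], [segment_by_density()], [smoothness()]).
#' @return A one-row tibble: `n_locs` (retained), `rg_nm`, `s_percent`.
#' @export
quantify_fragment <- function(chain, interval, locs_per_mb = 600,
                              bg_density = 150, loc_error_sd = 65, k = 2,
                              bg_factor = 4, alpha1 = c(100, 100, 200),
                              alpha2 = c(500, 500, 1000), seed = NULL) {
  locs <- simulate_smlm_image(chain, interval, locs_per_mb, bg_density,
                              loc_error_sd, seed = seed)
  dens <- voronoi_local_density(locs, k = k)
  bg <- estimate_background_density(locs, dens)
  seg <- segment_by_density(locs, dens, bg, bg_factor)
  kept <- seg[seg$retained, ]
  if (nrow(kept) < 10) rlang::abort("fewer than 10 retained localizations")
  tibble::tibble(n_locs = nrow(kept), rg_nm = gyration_radius(kept),
                 s_percent = smoothness(kept, alpha1, alpha2))
}

#' Compare a metric between two groups (two-sided rank-sum test)
#'
#' @param table_a,table_b Region-metrics tibbles (at least 3 rows each).
#' @param metric Column name to compare (e.g. `"rg_nm"`, `"s_percent"`).
#' @return A one-row tibble: `median_a`, `median_b`, `p_value`.
#' @export
compare_groups <- function(table_a, table_b, metric) {
  for (tb in list(table_a, table_b)) {
    if (!metric %in% names(tb)) {
      rlang::abort(paste0("metric not in table: ", metric))
    }
    if (nrow(tb) < 3) rlang::abort("need at least 3 rows per group")
  }
  a <- table_a[[metric]]
  b <- table_b[[metric]]
  wt <- stats::wilcox.test(a, b, alternative = "two.sided", exact = FALSE)
  tibble::tibble(median_a = stats::median(a), median_b = stats::median(b),
                 p_value = wt$p.value)
}

#' Bootstrap confidence interval for a median difference
#'
#' Percentile 95% CI of `median(A) - median(B)` over `n_boot` paired
#' resamples (each group resampled with replacement).
#'
#' @param table_a,table_b Region-metrics tibbles.
#' @param metric Column to compare.
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param seed Optional integer seed.
#' @return A one-row tibble: `diff`, `ci_low`, `ci_high`.
#' @export
bootstrap_median_diff <- function(table_a, table_b, metric, n_boot = 1000,
                                  seed = NULL) {
  stopifnot(n_boot >= 100)
  if (!is.null(seed)) withr::local_seed(seed)
  a <- table_a[[metric]]
  b <- table_b[[metric]]
  boots <- vapply(seq_len(n_boot), function(i) {
    stats::median(sample(a, replace = TRUE)) -
      stats::median(sample(b, replace = TRUE))
  }, numeric(1))
  ci <- stats::quantile(boots, c(0.025, 0.975), names = FALSE)
  tibble::tibble(diff = stats::median(a) - stats::median(b),
                 ci_low = ci[1], ci_high = ci[2])
}

#' Correlate a metric with localization counts
#'
#' Spearman correlation between the chosen metric and `n_locs`; gyration
#' radii are expected to correlate strongly with counts (hence with region
#' size), smoothness only weakly.
#'
#' @param table Region-metrics tibble (>= 5 rows).
#' @param metric Column name.
#' @return A one-row tibble: `spearman_rho`, `p_value`.
#' @export
correlate_with_counts <- function(table, metric) {
  if (!metric %in% names(table)) {
    rlang::abort(paste0("metric not in table: ", metric))
  }
  stopifnot(nrow(table) >= 5)
  x <- table[[metric]]
  y <- table$n_locs
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rlang::abort("constant column: correlation undefined")
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)
  )
  tibble::tibble(spearman_rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Numeric violin-plot summary per loop density
#'
#' Quartiles, median and interquartile range of a metric by loop density —
#' the numeric content of the violin plots used to compare conditions.
#'
#' @param table Region-metrics tibble.
#' @param metric Column name.
#' @return A tibble with one row per `loop_density`.
#' @export
summarize_metrics <- function(table, metric) {
  table |>
    dplyr::group_by(.data$loop_density) |>
    dplyr::summarise(
      n = dplyr::n(),
      q1 = stats::quantile(.data[[metric]], 0.25),
      median = stats::median(.data[[metric]]),
      q3 = stats::quantile(.data[[metric]], 0.75),
      iqr = .data$q3 - .data$q1,
      .groups = "drop"
    )
}

#' Violin plot of a metric across loop densities
#'
#' @param table Region-metrics tibble.
#' @param metric Column name (default `"rg_nm"`).
#' @return A ggplot object.
#' @export
plot_metric_violin <- function(table, metric = "rg_nm") {
  ggplot2::ggplot(table, ggplot2::aes(factor(.data$loop_density),
                                      .data[[metric]])) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.4, size = 0.8) +
    ggplot2::stat_summary(fun = stats::median, geom = "crossbar",
                          width = 0.5, color = "red", linewidth = 0.3) +
    ggplot2::labs(x = "loops per Mb", y = metric)
}

#' 2D scatter view of a localization set
#'
#' @param locs Localization tibble.
#' @param color Column used for point color (default `source`).
#' @return A ggplot object.
#' @export
plot_localizations <- function(locs, color = "source") {
  ggplot2::ggplot(locs, ggplot2::aes(.data$x_nm, .data$y_nm,
                                     color = .data[[color]])) +
    ggplot2::geom_point(size = 0.3, alpha = 0.5) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)")
}

#' Tidy a system state into a bead-level tibble
#'
#' @param x A `system_state`.
#' @param ... Unused.
#' @return A tibble with one row per bead.
#' @export
tidy.system_state <- function(x, ...) {
  dplyr::bind_rows(lapply(x$chains, function(ch) {
    n <- nrow(ch$positions)
    tibble::tibble(chrom = ch$chrom, bead = seq_len(n),
                   bin_start = ch$bin_edges[-(n + 1)],
                   bin_end = ch$bin_edges[-1],
                   compartment = ch$compartment,
                   x_nm = ch$positions[, 1], y_nm = ch$positions[, 2],
                   z_nm = ch$positions[, 3])
  }))
}

#' One-row summary of a system state
#'
#' @param x A `system_state`.
#' @param ... Unused.
#' @return A tibble: chain count, bead count, nuclear radius, occupancy,
#'   loop-bond count.
#' @export
glance.system_state <- function(x, ...) {
  tibble::tibble(
    n_chains = length(x$chains),
    n_beads = sum(vapply(x$chains, function(ch) nrow(ch$positions), 1L)),
    nuclear_radius_nm = x$nuclear_radius,
    volume_occupancy = volume_occupancy(x),
    n_loop_bonds = nrow(x$extra_bonds)
  )
}
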