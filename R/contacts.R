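#' Spatial contacts within a bead chain
#'
#' All unordered bead pairs whose centers lie within `cutoff_nm`, excluding
#' self-pairs, found with a uniform spatial grid. The default cutoff is
#' twice the chain's bead diameter (it must scale with the resolution).
#'
#' @param chain A `bead_chain`.
#' @param cutoff_nm Contact radius in nm (default `2 * bead_diameter`).
#' @return A tibble with columns `i`, `j` (1-based bead indices, `i < j`).
#' @export
contacts_from_config <- function(chain, cutoff_nm = NULL) {
  cutoff_nm <- cutoff_nm %||% (2 * chain$bead_diameter)
  stopifnot(cutoff_nm > 0)
  pr <- contact_pairs_cpp(chain$positions, cutoff_nm)
  tibble::tibble(i = pr[, 1], j = pr[, 2])
}

#' Aggregate an in-silico contact map over configurations
#'
#' Bins each configuration's contacts at `bin_size` and sums the counts
#' across configurations. Counts are symmetric by construction; raw counts
#' are stored (use log1p for display).
#'
#' @param snapshots A list of `system_state` objects, or of snapshot lists
#'   holding a `state` element (as returned by [run_three_phase()]).
#' @param chrom_id Chromosome to map.
#' @param bin_size Map bin size in bp.
#' @param cutoff_nm Contact radius (default `2 * bead_diameter`).
#' @return A `contact_map` object: list with `chrom`, `bin_size`, `counts`
#'   (symmetric matrix), `n_configs`.
#' @export
aggregate_contact_map <- function(snapshots, chrom_id, bin_size,
                                  cutoff_nm = NULL) {
  states <- lapply(snapshots, function(s) if (inherits(s, "system_state")) s else s$state)
  chains <- lapply(states, function(st) {
    ch <- st$chains[[chrom_id]]
    if (is.null(ch)) rlang::abort(paste0("chain missing: ", chrom_id))
    ch
  })
  res <- vapply(chains, function(ch) ch$bin_edges[2] - ch$bin_edges[1],
                numeric(1))
  if (length(unique(res)) != 1) rlang::abort("snapshots have mixed resolutions")
  len <- chains[[1]]$bin_edges[length(chains[[1]]$bin_edges)]
  n_bins <- ceiling(len / bin_size)
  counts <- matrix(0, n_bins, n_bins)
  for (ch in chains) {
    mid <- (ch$bin_edges[-1] + ch$bin_edges[-length(ch$bin_edges)]) / 2
    bead_bin <- pmin(floor(mid / bin_size) + 1, n_bins)
    pr <- contacts_from_config(ch, cutoff_nm)
    bi <- bead_bin[pr$i]
    bj <- bead_bin[pr$j]
    for (t in seq_along(bi)) {
      counts[bi[t], bj[t]] <- counts[bi[t], bj[t]] + 1
      counts[bj[t], bi[t]] <- counts[bj[t], bi[t]] + 1
    }
  }
  structure(list(chrom = chrom_id, bin_size = bin_size, counts = counts,
                 n_configs = length(chains)),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map %s: %d x %d bins of %g bp, %d configs, %g contacts>\n",
              x$chrom, nrow(x$counts), ncol(x$counts), x$bin_size,
              x$n_configs, sum(x$counts) / 2))
  invisible(x)
}

#' Compartment eigenvector of a contact map
#'
#' Observed/expected normalization by the mean of each diagonal, Pearson
#' correlation matrix across bins, then the first principal component. If
#' reference A/B labels are given the sign is oriented so that positive
#' entries correlate with the A compartment.
#'
#' @param map A `contact_map`.
#' @param labels Optional reference labels (`"A"`/`"B"`, one per bin) for
#'   sign orientation.
#' @return Numeric vector, one signed entry per bin (NA for bins with empty
#'   marginals).
#' @export
compartment_eigenvector <- function(map, labels = NULL) {
  counts <- map$counts
  n <- nrow(counts)
  if (n < 10) rlang::abort("need at least 10 bins")
  good <- rowSums(counts) > 0
  if (sum(good) < 10) rlang::abort("need at least 10 bins with nonzero marginals")
  m <- counts[good, good, drop = FALSE]
  ng <- nrow(m)
  # observed / expected: divide each diagonal by its mean
  oe <- m
  for (d in 0:(ng - 1)) {
    idx <- cbind(seq_len(ng - d), seq_len(ng - d) + d)
    mu <- mean(m[idx])
    if (mu > 0) {
      oe[idx] <- m[idx] / mu
      oe[idx[, c(2, 1), drop = FALSE]] <- oe[idx]
    }
  }
  if (stats::sd(as.vector(oe)) < 1e-12) {
    rlang::abort("degenerate contact map: constant observed/expected matrix")
  }
  cc <- suppressWarnings(stats::cor(oe))
  cc[!is.finite(cc)] <- 0
  pc <- stats::prcomp(cc, center = TRUE, scale. = FALSE)
  ev <- pc$rotation[, 1]
  out <- rep(NA_real_, n)
  out[good] <- ev
  if (!is.null(labels)) {
    stopifnot(length(labels) == n)
    ind <- as.numeric(labels == "A")
    rho <- suppressWarnings(stats::cor(out[good], ind[good]))
    if (!is.na(rho) && rho < 0) out <- -out
  }
  out
}

#' Export a contact map as TSV (with a BED sidecar of bins)
#'
#' @param map A `contact_map`.
#' @param path Output TSV path; the bin definitions go to
#'   `paste0(path, ".bins.bed")`.
#' @export
write_contact_map <- function(map, path) {
  utils::write.table(map$counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  n <- nrow(map$counts)
  bed <- data.frame(chrom = map$chrom, start = (seq_len(n) - 1) * map$bin_size,
                    end = seq_len(n) * map$bin_size)
  utils::write.table(bed, paste0(path, ".bins.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Plot a contact map
#'
#' Natural-log(1 + count) heat map of the binned contact matrix.
#'
#' @param object A `contact_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.contact_map <- function(object, ...) {
  n <- nrow(object$counts)
  df <- expand.grid(bin_i = seq_len(n), bin_j = seq_len(n))
  df$log_count <- log1p(as.vector(object$counts))
  ggplot2::ggplot(df, ggplot2::aes(.data$bin_i, .data$bin_j,
                                   fill = .data$log_count)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "ln(1 + count)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "bin", y = "bin",
                  title = sprintf("%s contact map (%d configs)",
                                  object$chrom, object$n_configs))
}
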