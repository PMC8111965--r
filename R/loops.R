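#' Sample extrusion-obstacle positions along a chromosome
#'
#' Potential loop-extrusion obstacles (CTCF-binding-site-like) are placed by
#' drawing successive inter-obstacle gaps i.i.d. from the normalized density
#' `f(L) = (L / L0^2) exp(-L / L0)`, i.e. Gamma(shape 2, scale `L0`), whose
#' mean is `2 * L0` and mode `L0`. The first obstacle sits at a uniform
#' phase within its gap so the process is stationary along the chromosome;
#' positions beyond `chrom_length` are truncated.
#'
#' @param chrom_length Chromosome length in bp.
#' @param L0 Gap scale in bp (default 165 kb).
#' @param seed Optional integer seed.
#' @return A tibble with column `position` (bp, strictly increasing), with
#'   attributes `chrom_length` and `L0`.
#' @export
sample_obstacles <- function(chrom_length, L0 = 165e3, seed = NULL) {
  stopifnot(chrom_length > L0, L0 > 0)
  if (!is.null(seed)) withr::local_seed(seed)
  n_guess <- ceiling(chrom_length / (2 * L0) * 1.25) + 50
  pos <- -stats::runif(1) * stats::rgamma(1, shape = 2, scale = L0)
  out <- numeric(0)
  repeat {
    gaps <- stats::rgamma(n_guess, shape = 2, scale = L0)
    pos <- pos + cumsum(gaps)
    out <- c(out, pos[pos > 0 & pos < chrom_length])
    if (pos[length(pos)] >= chrom_length) break
    pos <- pos[length(pos)]
  }
  obs <- tibble::tibble(position = out)
  attr(obs, "chrom_length") <- chrom_length
  attr(obs, "L0") <- L0
  obs
}

#' Mean and median inter-obstacle gap
#'
#' The gap distribution between successive obstacles is what the loop-size
#' distribution is calibrated against (fully extruded loops span exactly one
#' inter-obstacle interval): Gamma(2, `L0`) has mean `2 L0` = 330 kb and
#' median about 277 kb at the default `L0` = 165 kb.
#'
#' @param obstacles Obstacle tibble from [sample_obstacles()].
#' @return A tibble with columns `n_gaps`, `mean_gap`, `median_gap` (bp).
#' @export
obstacle_gap_stats <- function(obstacles) {
  g <- diff(obstacles$position)
  tibble::tibble(n_gaps = length(g), mean_gap = mean(g),
                 median_gap = stats::median(g))
}

#' Place cohesin-like loops via obstacle-limited anchor extension
#'
#' Static end-state sampler for loop extrusion: `round(density *
#' chrom_length / 1 Mb)` loops are placed sequentially. Each loop starts at
#' a uniform loading point; both anchors extend outward by independent
#' exponential distances with mean `d0` (the processivity) but stop early at
#' the nearest intervening obstacle, previously placed anchor, or chromosome
#' end. Placed anchors act as obstacles for subsequent loops. Zero-size
#' loops are discarded and redrawn.
#'
#' @param chrom_length Chromosome length in bp.
#' @param obstacles Obstacle tibble from [sample_obstacles()], or `NULL` to
#'   sample one internally.
#' @param density Target loop density in loops per Mb (0-25).
#' @param d0 Mean per-side processivity in bp (default 250 kb).
#' @param L0 Gap scale used when `obstacles` is `NULL`.
#' @param seed Optional integer seed.
#' @return A loop-set tibble with columns `left`, `right`, `loading_point`
#'   (bp) and `stop_left`, `stop_right` (factors: processivity, obstacle,
#'   prior_anchor, chrom_end), with attributes `chrom_length`, `density`,
#'   `d0`.
#' @export
place_loops <- function(chrom_length, obstacles = NULL, density,
                        d0 = 250e3, L0 = 165e3, seed = NULL) {
  stopifnot(density >= 0, d0 > 0)
  if (!is.null(seed)) withr::local_seed(seed)
  if (is.null(obstacles)) obstacles <- sample_obstacles(chrom_length, L0)
  n <- round(density * chrom_length / 1e6)
  if (n > chrom_length) rlang::abort("density exhausts distinct loading points")
  reasons <- c("processivity", "obstacle", "prior_anchor", "chrom_end")
  if (n == 0) {
    ls <- tibble::tibble(left = numeric(), right = numeric(),
                         loading_point = numeric(),
                         stop_left = factor(character(), levels = reasons),
                         stop_right = factor(character(), levels = reasons))
  } else {
    raw <- place_loops_cpp(chrom_length, obstacles$position, n, d0)
    ls <- tibble::tibble(
      left = raw$left, right = raw$right, loading_point = raw$loading_point,
      stop_left = factor(reasons[raw$stop_left + 1L], levels = reasons),
      stop_right = factor(reasons[raw$stop_right + 1L], levels = reasons)
    )
  }
  attr(ls, "chrom_length") <- chrom_length
  attr(ls, "density") <- density
  attr(ls, "d0") <- d0
  ls
}

#' Total length of the union of genomic intervals
#'
#' @param start,end Interval bounds (bp, half-open).
#' @return Union length in bp.
#' @export
interval_union_length <- function(start, end) {
  stopifnot(length(start) == length(end), all(end >= start))
  if (length(start) == 0) return(0)
  o <- order(start)
  start <- start[o]; end <- end[o]
  hi <- cummax(end)
  new_block <- c(TRUE, start[-1] > hi[-length(hi)])
  block <- cumsum(new_block)
  sum(vapply(split(seq_along(start), block), function(i) {
    max(end[i]) - min(start[i])
  }, numeric(1)))
}

#' Summary statistics of a placed loop set
#'
#' @param loopset Loop-set tibble from [place_loops()].
#' @return A one-row tibble: `n_loops`, `mean_size`, `median_size` (bp; `NA`
#'   when empty), `loops_per_mb`, and `dna_fraction_in_loops` (fraction of
#'   the chromosome inside at least one loop).
#' @export
loop_stats <- function(loopset) {
  chrom_length <- attr(loopset, "chrom_length")
  stopifnot(!is.null(chrom_length))
  sizes <- loopset$right - loopset$left
  tibble::tibble(
    n_loops = nrow(loopset),
    mean_size = if (length(sizes)) mean(sizes) else NA_real_,
    median_size = if (length(sizes)) stats::median(sizes) else NA_real_,
    loops_per_mb = nrow(loopset) / (chrom_length / 1e6),
    dna_fraction_in_loops =
      interval_union_length(loopset$left, loopset$right) / chrom_length
  )
}

#' Read / write loop sets as BEDPE
#'
#' Columns: chrom, left, left+1, chrom, right, right+1, name,
#' stop_left/stop_right. Tab-separated, no header.
#'
#' @param loopset Loop-set tibble.
#' @param path File path.
#' @param chrom Chromosome name written to the BEDPE (default "chr1").
#' @export
write_loops_bedpe <- function(loopset, path, chrom = "chr1") {
  df <- data.frame(
    chrom1 = chrom, start1 = loopset$left, end1 = loopset$left + 1,
    chrom2 = chrom, start2 = loopset$right, end2 = loopset$right + 1,
    name = paste0("loop", seq_len(nrow(loopset))),
    stops = paste(loopset$stop_left, loopset$stop_right, sep = "/")
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_loops_bedpe
#' @export
read_loops_bedpe <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE)
  stops <- strsplit(as.character(raw[[8]]), "/", fixed = TRUE)
  reasons <- c("processivity", "obstacle", "prior_anchor", "chrom_end")
  tibble::tibble(
    left = raw[[2]], right = raw[[5]],
    loading_point = NA_real_,
    stop_left = factor(vapply(stops, `[`, "", 1), levels = reasons),
    stop_right = factor(vapply(stops, `[`, "", 2), levels = reasons)
  )
}
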