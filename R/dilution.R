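#' Dilution-labeling arithmetic
#'
#' After one round of replication in the presence of EdU, each chromosome
#' carries exactly one labeled strand. Each subsequent division without EdU
#' halves, on average, the number of label-carrying chromosomes
#' (semi-conservative replication): after `m` divisions a cell carries
#' `n_chrom * 2^-m` labeled chromosomes on average, and the number of
#' labeled chromosomes is Binomial(`n_chrom`, `2^-m`).
#'
#' @param m Number of cell divisions after EdU wash-out (non-negative
#'   integer).
#' @param n_chrom Number of chromosomes (default 46).
#' @return `expected_labeled()`: the expected number of labeled chromosomes.
#'   `labeled_count_pmf()`: a numeric vector of length `n_chrom + 1` giving
#'   P(0), P(1), ..., P(n_chrom) labeled chromosomes.
#' @examples
#' expected_labeled(6)        # 0.71875, i.e. ~0.72 labeled chromosomes
#' labeled_count_pmf(6)[1:2]  # p0 = (1 - 2^-6)^46, p1 = 46 * 2^-6 * (1 - 2^-6)^45
#' @export
expected_labeled <- function(m, n_chrom = 46) {
  stopifnot(m >= 0)
  n_chrom * 2^-m
}

#' @rdname expected_labeled
#' @export
labeled_count_pmf <- function(m, n_chrom = 46) {
  stopifnot(m >= 0)
  q <- 2^-m
  stats::dbinom(0:n_chrom, size = n_chrom, prob = q)
}

#' Fraction of chromosomes with at least one sister-chromatid exchange
#'
#' With a per-chromosome per-division probability `rate` of undergoing at
#' least one sister-chromatid exchange (SCE), the fraction of chromosomes
#' affected after `m` divisions is `1 - (1 - rate)^m`.
#'
#' @param rate SCE probability per chromosome per division, in \[0, 1\].
#' @param m Number of divisions.
#' @return The affected fraction (dimensionless).
#' @examples
#' fraction_with_sce(0.2, 6)  # 0.737856, i.e. ~74%
#' @export
fraction_with_sce <- function(rate, m) {
  stopifnot(rate >= 0, rate <= 1, m >= 0)
  1 - (1 - rate)^m
}

# Number of SCE breakpoints for one chromosome in one division.
# Default model: at most one event, with probability `rate`. The Poisson
# variant draws Poisson(lambda) with lambda chosen so P(>=1) = rate,
# allowing several exchanges per division.
draw_n_sce <- function(n, rate, multi_sce) {
  if (multi_sce) {
    stats::rpois(n, -log1p(-rate))
  } else {
    as.integer(stats::runif(n) < rate)
  }
}

#' Simulate EdU-labeled chromatin fragments after dilution and SCE
#'
#' Simulates, per chromosome and per replicate cell, `m` rounds of
#' semi-conservative replication. At each division the chromosome undergoes
#' an SCE with probability `sce_rate`; the breakpoint is uniform on the
#' chromosome and the strand segment distal to it is exchanged between the
#' two sister chromatids. One daughter is then followed at random
#' (equivalent to sampling one descendant cell). The labeled intervals of
#' the followed cell are reported, dropping intervals shorter than
#' `min_size`.
#'
#' @param karyotype Karyotype tibble (`chrom`, `length`).
#' @param m Divisions after wash-out (default 6).
#' @param sce_rate Per-chromosome per-division SCE probability
#'   (default 0.18).
#' @param min_size Minimum reported fragment length in bp (default 0).
#' @param n_cells Number of replicate cells to simulate (default 1).
#' @param multi_sce If `TRUE`, allow several SCE breakpoints per division
#'   (Poisson with the same per-division hit probability); the default
#'   single-event model places at most one.
#' @param seed Optional integer seed.
#' @return A tibble with columns `cell`, `chrom`, `start`, `end`
#'   (0-based half-open bp). Cells with no surviving label contribute no
#'   rows.
#' @export
simulate_labeled_fragments <- function(karyotype, m = 6, sce_rate = 0.18,
                                       min_size = 0, n_cells = 1,
                                       multi_sce = FALSE, seed = NULL) {
  validate_karyotype(karyotype)
  stopifnot(m >= 1, min_size >= 0, n_cells >= 1,
            sce_rate >= 0, sce_rate <= 1)
  if (!is.null(seed)) withr::local_seed(seed)

  if (!multi_sce) {
    n <- n_cells * nrow(karyotype)
    L <- rep(karyotype$length, times = n_cells)
    cell <- rep(seq_len(n_cells), each = nrow(karyotype))
    chrom <- rep(karyotype$chrom, times = n_cells)
    lo <- rep(0, n)
    hi <- L
    alive <- rep(TRUE, n)
    for (d in seq_len(m)) {
      sce <- stats::runif(n) < sce_rate
      b <- stats::runif(n, 0, L)
      keep_first <- stats::runif(n) < 0.5
      # without SCE the whole label sits on one sister; with SCE the
      # breakpoint splits it, proximal part on one sister, distal on the other
      lost <- !sce & !keep_first
      hi <- ifelse(sce & keep_first, pmin(hi, b), hi)
      lo <- ifelse(sce & !keep_first, pmax(lo, b), lo)
      alive <- alive & !lost & (lo < hi)
    }
    out <- tibble::tibble(cell = cell, chrom = chrom, start = lo, end = hi)
    out <- out[alive & (out$end - out$start >= min_size), ]
    return(out[order(out$cell, match(out$chrom, karyotype$chrom)), ])
  }

  # general multi-breakpoint model: explicit interval bookkeeping
  res <- vector("list", n_cells * nrow(karyotype))
  idx <- 1L
  for (ci in seq_len(n_cells)) {
    for (k in seq_len(nrow(karyotype))) {
      L <- karyotype$length[k]
      iv <- matrix(c(0, L), ncol = 2)
      for (d in seq_len(m)) {
        if (is.null(iv)) break
        nb <- draw_n_sce(1, sce_rate, TRUE)
        b <- sort(stats::runif(nb, 0, L))
        sis <- split_intervals_at(iv, b, L)
        # DNA conservation: the two sisters together carry the parent label
        stopifnot(abs(iv_len(sis$a) + iv_len(sis$b) - iv_len(iv)) < 1e-6)
        iv <- if (stats::runif(1) < 0.5) sis$a else sis$b
      }
      if (!is.null(iv) && nrow(iv) > 0) {
        res[[idx]] <- tibble::tibble(cell = ci, chrom = karyotype$chrom[k],
                                     start = iv[, 1], end = iv[, 2])
        idx <- idx + 1L
      }
    }
  }
  out <- dplyr::bind_rows(res[seq_len(idx - 1L)])
  if (nrow(out) == 0) return(tibble::tibble(cell = integer(), chrom = character(),
                                            start = numeric(), end = numeric()))
  out[out$end - out$start >= min_size, ]
}

iv_len <- function(iv) if (is.null(iv) || nrow(iv) == 0) 0 else sum(iv[, 2] - iv[, 1])

# Split labeled intervals between the two sister chromatids given sorted SCE
# breakpoints: segments of [0, L] delimited by the breakpoints alternate
# between sisters, so the labeled intervals are intersected with the even-
# or odd-parity segments.
split_intervals_at <- function(iv, breaks, L) {
  if (length(breaks) == 0) return(list(a = iv, b = iv[0, , drop = FALSE]))
  edges <- c(0, breaks, L)
  segs <- cbind(edges[-length(edges)], edges[-1])
  parity <- seq_len(nrow(segs)) %% 2 == 1
  inter <- function(keep) {
    out <- matrix(numeric(0), ncol = 2)
    for (s in which(keep)) {
      lo <- pmax(iv[, 1], segs[s, 1])
      hi <- pmin(iv[, 2], segs[s, 2])
      ok <- lo < hi
      if (any(ok)) out <- rbind(out, cbind(lo[ok], hi[ok]))
    }
    out[order(out[, 1]), , drop = FALSE]
  }
  list(a = inter(parity), b = inter(!parity))
}

#' Split one chromosome into labeled sub-chains for image synthesis
#'
#' Runs the same dilution/SCE generative model as
#' [simulate_labeled_fragments()], but follows the full division tree of one
#' chromosome rather than a single descendant: the SCE breakpoints
#' accumulated across the tree partition the chromosome into contiguous
#' pieces, each ending up in exactly one descendant cell. The pooled pieces
#' are the sub-chains used to emulate the genomic extent of singly labeled
#' chromatin regions; pieces shorter than `min_size` (default 5 Mb) are
#' excluded, as such small regions are not analyzed.
#'
#' The piece-size distribution equals the fragment-size distribution of
#' [simulate_labeled_fragments()] conditional on a surviving fragment, since
#' each piece segregates to a uniformly random descendant.
#'
#' @param chrom_length Chromosome length in bp.
#' @param m,sce_rate,multi_sce As in [simulate_labeled_fragments()].
#' @param min_size Minimum sub-chain length in bp (default 5 Mb).
#' @param seed Optional integer seed.
#' @return A tibble with columns `start`, `end` (bp), disjoint and sorted.
#' @export
split_chain_for_imaging <- function(chrom_length, m = 6, sce_rate = 0.18,
                                    min_size = 5e6, multi_sce = FALSE,
                                    seed = NULL) {
  stopifnot(chrom_length > min_size, m >= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  L <- chrom_length
  recurse <- function(iv, depth) {
    if (is.null(iv) || nrow(iv) == 0) return(NULL)
    if (depth == 0) return(list(iv))
    nb <- draw_n_sce(1, sce_rate, multi_sce)
    sis <- split_intervals_at(iv, sort(stats::runif(nb, 0, L)), L)
    stopifnot(abs(iv_len(sis$a) + iv_len(sis$b) - iv_len(iv)) < 1e-6)
    c(recurse(sis$a, depth - 1), recurse(sis$b, depth - 1))
  }
  pieces <- recurse(matrix(c(0, L), ncol = 2), m)
  iv <- do.call(rbind, pieces)
  iv <- iv[iv[, 2] - iv[, 1] >= min_size, , drop = FALSE]
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  tibble::tibble(start = iv[, 1], end = iv[, 2])
}

#' Read / write labeled fragments as BED
#'
#' Three tab-separated columns (chrom, start, end), no header.
#'
#' @param fragments Fragment tibble with `chrom`, `start`, `end`.
#' @param path File path.
#' @export
write_fragments_bed <- function(fragments, path) {
  utils::write.table(fragments[, c("chrom", "start", "end")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_fragments_bed
#' @export
read_fragments_bed <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end"),
                           colClasses = c("character", "numeric", "numeric"))
  tibble::as_tibble(raw)
}
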