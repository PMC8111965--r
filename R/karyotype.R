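#' Default near-diploid human karyotype
#'
#' Returns the 46-chromosome complement used throughout the package: two
#' copies of each autosome plus X and Y, with hg38-like lengths rounded to
#' the megabase and chromosome 1 pinned at exactly 249 Mb. The 46
#' chromosomes are modeled as 46 independent chains; homologs are not
#' distinguished, so the two copies share a name prefix and differ by an
#' `_a`/`_b` suffix.
#'
#' @return A tibble with columns `chrom` (character, unique) and
#'   `length` (base pairs, strictly positive).
#' @examples
#' k <- default_human_karyotype()
#' nrow(k)                      # 46
#' k$length[k$chrom == "chr1_a"]  # 249e6
#' @export
default_human_karyotype <- function() {
  # hg38 chromosome lengths, Mb-rounded; chr1 fixed at 249 Mb
  mb <- c(
    chr1 = 249, chr2 = 242, chr3 = 198, chr4 = 190, chr5 = 182,
    chr6 = 171, chr7 = 159, chr8 = 145, chr9 = 138, chr10 = 134,
    chr11 = 135, chr12 = 133, chr13 = 114, chr14 = 107, chr15 = 102,
    chr16 = 90, chr17 = 83, chr18 = 80, chr19 = 59, chr20 = 64,
    chr21 = 47, chr22 = 51, chrX = 156, chrY = 57
  )
  auto <- names(mb)[1:22]
  chrom <- c(paste0(auto, "_a"), paste0(auto, "_b"), "chrX", "chrY")
  len <- c(mb[auto], mb[auto], mb["chrX"], mb["chrY"]) * 1e6
  tibble::tibble(chrom = chrom, length = unname(len))
}

validate_karyotype <- function(karyotype) {
  stopifnot(
    is.data.frame(karyotype),
    all(c("chrom", "length") %in% names(karyotype)),
    !anyDuplicated(karyotype$chrom),
    all(karyotype$length > 0)
  )
  invisible(karyotype)
}

chrom_length <- function(karyotype, chrom_id) {
  i <- match(chrom_id, karyotype$chrom)
  if (is.na(i)) {
    rlang::abort(paste0("unknown chromosome: ", chrom_id))
  }
  karyotype$length[i]
}

#' Write / read a karyotype as two-column TSV
#'
#' @param karyotype A karyotype tibble (`chrom`, `length`).
#' @param path File path.
#' @return `read_karyotype()` returns the karyotype tibble;
#'   `write_karyotype()` returns `path` invisibly.
#' @export
write_karyotype <- function(karyotype, path) {
  validate_karyotype(karyotype)
  readr::write_tsv(karyotype[, c("chrom", "length")], path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_karyotype
#' @export
read_karyotype <- function(path) {
  k <- readr::read_tsv(path, col_names = c("chrom", "length"),
                       col_types = "cd", progress = FALSE)
  validate_karyotype(k)
  k
}

#' Generate a synthetic A/B compartment track
#'
#' Substitutes for a Hi-C-derived compartment eigenvector: the chromosome is
#' tiled at `bin_size` and labels alternate between A and B in blocks whose
#' lengths (in bins) are geometrically distributed with mean
#' `mean_block_len / bin_size`, emulating the megabase-scale alternation of
#' compartments along real chromosomes.
#'
#' @param karyotype Karyotype tibble.
#' @param chrom_id Chromosome to generate a track for.
#' @param bin_size Bin width in bp (default 1 Mb).
#' @param mean_block_len Mean compartment block length in bp (default 3 Mb);
#'   must be at least `bin_size`.
#' @param seed Optional integer seed for reproducibility.
#' @return A compartment-track tibble with columns `chrom`, `start`, `end`
#'   (0-based half-open bp) and `label` (`"A"`/`"B"`), one row per bin, plus
#'   attributes `bin_size` and `chrom_length`.
#' @export
synthetic_compartment_track <- function(karyotype, chrom_id, bin_size = 1e6,
                                        mean_block_len = 3e6, seed = NULL) {
  stopifnot(bin_size > 0, mean_block_len >= bin_size)
  len <- chrom_length(karyotype, chrom_id)
  n_bins <- ceiling(len / bin_size)
  if (!is.null(seed)) withr::local_seed(seed)
  # geometric block lengths in bins, support >= 1, mean = mean_block_len/bin_size
  p <- bin_size / mean_block_len
  labels <- character(0)
  cur <- sample(c("A", "B"), 1)
  while (length(labels) < n_bins) {
    blk <- stats::rgeom(1, p) + 1
    labels <- c(labels, rep(cur, blk))
    cur <- if (cur == "A") "B" else "A"
  }
  labels <- labels[seq_len(n_bins)]
  new_compartment_track(chrom_id, bin_size, len, labels)
}

new_compartment_track <- function(chrom_id, bin_size, chrom_length, labels) {
  n_bins <- length(labels)
  stopifnot(n_bins == ceiling(chrom_length / bin_size),
            all(labels %in% c("A", "B")))
  start <- (seq_len(n_bins) - 1) * bin_size
  tr <- tibble::tibble(
    chrom = chrom_id,
    start = start,
    end = pmin(start + bin_size, chrom_length),
    label = labels
  )
  attr(tr, "bin_size") <- bin_size
  attr(tr, "chrom_length") <- chrom_length
  tr
}

#' Read / write a BED-like compartment track
#'
#' The file has four tab-separated columns and no header: chrom, start, end,
#' value. The value is either a literal `A`/`B` label or a signed
#' eigenvector entry, mapped by the package's sign convention positive = A,
#' negative = B. Intervals must tile the chromosome exactly at `bin_size`
#' (no gaps, no overlaps); a zero eigenvector entry is ambiguous and is an
#' error.
#'
#' @param path File path.
#' @param bin_size Expected bin width in bp.
#' @param track A compartment-track tibble (for writing).
#' @return `read_compartment_track()` returns a compartment-track tibble.
#' @export
read_compartment_track <- function(path, bin_size) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end", "value"),
                           colClasses = c("character", "numeric", "numeric",
                                          "character"))
  if (nrow(raw) == 0) rlang::abort("empty compartment track")
  if (length(unique(raw$chrom)) != 1) {
    rlang::abort("compartment track must cover a single chromosome")
  }
  raw <- raw[order(raw$start), ]
  chrom_length <- max(raw$end)
  n_bins <- ceiling(chrom_length / bin_size)
  exp_start <- (seq_len(n_bins) - 1) * bin_size
  exp_end <- pmin(exp_start + bin_size, chrom_length)
  if (nrow(raw) != n_bins || any(raw$start != exp_start) ||
      any(raw$end != exp_end)) {
    rlang::abort("intervals do not tile the chromosome at bin_size (gap or overlap)")
  }
  v <- raw$value
  lab <- ifelse(v %in% c("A", "B"), v, NA_character_)
  num <- suppressWarnings(as.numeric(v))
  needs_num <- is.na(lab)
  if (any(needs_num & is.na(num))) {
    rlang::abort("track values must be A/B labels or numeric eigenvector entries")
  }
  if (any(needs_num & num == 0)) {
    rlang::abort("zero eigenvector value: compartment sign is ambiguous")
  }
  lab[needs_num] <- ifelse(num[needs_num] > 0, "A", "B")
  new_compartment_track(raw$chrom[1], bin_size, chrom_length, lab)
}

#' @rdname read_compartment_track
#' @export
write_compartment_track <- function(track, path) {
  utils::write.table(track[, c("chrom", "start", "end", "label")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
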