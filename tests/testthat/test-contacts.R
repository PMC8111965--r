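test_that("contact listing matches an O(N^2) brute force", {
  set.seed(1)
  ch <- rw_chain(500, step = 45, diameter = 45)
  for (cutoff in c(50, 90, 200)) {
    pr <- contacts_from_config(ch, cutoff)
    d <- as.matrix(stats::dist(ch$positions))
    brute <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
    expect_equal(nrow(pr), nrow(brute))
    got <- paste(pr$i, pr$j)
    want <- paste(pmin(brute[, 1], brute[, 2]), pmax(brute[, 1], brute[, 2]))
    expect_setequal(got, want)
  }
  # bonded neighbors at ~1 bead diameter are always in contact at the
  # default cutoff of two diameters
  pr <- contacts_from_config(ch)
  expect_true(all(paste(1:499, 2:500) %in% paste(pr$i, pr$j)))
  # cutoff below the minimal pair distance yields nothing
  expect_equal(nrow(contacts_from_config(ch, 1e-3)), 0)
})

test_that("aggregated maps are symmetric, non-negative and decay with distance", {
  cfg <- desk_config(densities = 0, n_replicates = 3, seed = 2)
  snaps <- run_three_phase(cfg)
  map <- aggregate_contact_map(snaps, "chrA", bin_size = 1e6)
  expect_equal(map$counts, t(map$counts))
  expect_true(all(map$counts >= 0))
  expect_equal(map$n_configs, 3)
  expect_equal(nrow(map$counts), 20)

  # polymer decay: mean counts fall with genomic separation
  n <- nrow(map$counts)
  sep <- abs(row(map$counts) - col(map$counts))
  md <- vapply(1:(n - 2), function(d) mean(map$counts[sep == d]), numeric(1))
  rho <- suppressWarnings(stats::cor(seq_along(md), md, method = "spearman"))
  expect_lt(rho, 0)

  # single synthetic contact lands symmetrically
  ch <- snaps[[1]]$state$chains$chrA
  one <- list(list(state = snaps[[1]]$state))
  m2 <- aggregate_contact_map(one, "chrA", 1e6, cutoff_nm = 1e-6)
  expect_true(all(m2$counts == 0))
})

test_that("total contacts add over configurations", {
  cfg <- desk_config(densities = 0, n_replicates = 2, seed = 3)
  snaps <- run_three_phase(cfg)
  m12 <- aggregate_contact_map(snaps, "chrA", 1e6)
  m1 <- aggregate_contact_map(snaps[1], "chrA", 1e6)
  m2 <- aggregate_contact_map(snaps[2], "chrA", 1e6)
  expect_equal(m12$counts, m1$counts + m2$counts)
})

test_that("loop bonds enrich anchor-bin contacts", {
  cfg <- desk_config(densities = c(0, 15), n_replicates = 8, seed = 4)
  snaps <- run_three_phase(cfg)
  loops0 <- snaps[vapply(snaps, function(s) s$density == 0, logical(1))]
  loops15 <- snaps[vapply(snaps, function(s) s$density == 15, logical(1))]
  bin_size <- 5e5
  m0 <- aggregate_contact_map(loops0, "chrA", bin_size)
  m15 <- aggregate_contact_map(loops15, "chrA", bin_size)
  # bins joined by a loop in any density-15 snapshot, at separation >= 2 bins
  anchor_pairs <- unique(do.call(rbind, lapply(loops15, function(s) {
    ch <- s$state$chains$chrA
    eb <- s$state$extra_bonds
    mid <- (ch$bin_edges[-1] + ch$bin_edges[-length(ch$bin_edges)]) / 2
    cbind(floor(mid[eb$i] / bin_size) + 1, floor(mid[eb$j] / bin_size) + 1)
  })))
  anchor_pairs <- anchor_pairs[abs(anchor_pairs[, 1] - anchor_pairs[, 2]) >= 2, ,
                               drop = FALSE]
  sep <- abs(row(m15$counts) - col(m15$counts))
  enrich <- vapply(seq_len(nrow(anchor_pairs)), function(r) {
    i <- anchor_pairs[r, 1]; j <- anchor_pairs[r, 2]
    d <- abs(i - j)
    bg <- mean(m0$counts[sep == d])
    if (bg == 0) return(NA_real_)
    m15$counts[i, j] / bg
  }, numeric(1))
  expect_gte(mean(enrich, na.rm = TRUE), 2)

  # adding loop bonds never decreases anchor-pair counts (paired seeds)
  tot15 <- sum(vapply(seq_len(nrow(anchor_pairs)), function(r) {
    m15$counts[anchor_pairs[r, 1], anchor_pairs[r, 2]]
  }, numeric(1)))
  tot0 <- sum(vapply(seq_len(nrow(anchor_pairs)), function(r) {
    m0$counts[anchor_pairs[r, 1], anchor_pairs[r, 2]]
  }, numeric(1)))
  expect_gte(tot15, tot0)
})

test_that("a checkerboard map yields the exact block eigenvector", {
  n <- 20
  lab <- rep(c("A", "B"), each = 2, length.out = n)
  base <- outer(lab, lab, function(a, b) ifelse(a == b, 8, 2))
  decay <- 1 / (1 + abs(row(base) - col(base)))
  map <- structure(list(chrom = "chrX", bin_size = 1e6,
                        counts = base * decay * 100, n_configs = 1),
                   class = "contact_map")
  ev <- compartment_eigenvector(map, labels = lab)
  expect_true(all(ev[lab == "A"] > 0))
  expect_true(all(ev[lab == "B"] < 0))

  flat <- structure(list(chrom = "chrX", bin_size = 1e6,
                         counts = matrix(5, n, n), n_configs = 1),
                    class = "contact_map")
  expect_error(compartment_eigenvector(flat), "degenerate")
})

test_that("the eigenvector recovers compartments from simulated ensembles", {
  # compartment blocks of mean 5 Mb on a 100-Mb chromosome, equilibrated
  # with strong B-B attraction and refined to 500-kb beads for contact
  # statistics
  k <- tibble::tibble(chrom = "chrA", length = 100e6)
  tr1 <- synthetic_compartment_track(k, "chrA", 1e6, 5e6, seed = 14)
  lab <- tr1$label
  states <- lapply(1:20, function(i) {
    st <- init_coarse_nucleus(k, tracks = list(chrA = tr1), radius_nm = 1600,
                              seed = 50 + i)
    st <- run_dynamics(st, 40000, sim_params(eps_BB = 1.5), seed = 80 + i)
    st <- fine_grain(st, "chrA", 2, seed = 90 + i)
    run_dynamics(st, 15000, sim_params(eps_BB = 1.5), seed = 120 + i)
  })
  map <- aggregate_contact_map(states, "chrA", 1e6)
  ev <- compartment_eigenvector(map, labels = lab)
  agr <- sign(ev) == ifelse(lab == "A", 1, -1)
  # loci within a bin of a compartment switch sit at condensate interfaces
  # and genuinely blur at this ensemble size; interior bins must recover
  n <- length(lab)
  interior <- c(FALSE, lab[-1] == lab[-n]) & c(lab[-n] == lab[-1], FALSE)
  expect_gte(mean(agr[interior], na.rm = TRUE), 0.8)
  expect_gte(mean(agr, na.rm = TRUE), 0.6)
})

test_that("contact maps export to TSV with a BED sidecar", {
  cfg <- desk_config(densities = 0, n_replicates = 1, seed = 6)
  snaps <- run_three_phase(cfg)
  map <- aggregate_contact_map(snaps, "chrA", 1e6)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_contact_map(map, path)
  back <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(back) <- NULL
  expect_equal(back, map$counts)
  bed <- utils::read.table(paste0(path, ".bins.bed"), sep = "\t")
  expect_equal(nrow(bed), nrow(map$counts))
  expect_equal(bed[[3]] - bed[[2]], rep(1e6, nrow(bed)))

  p <- autoplot(map)
  expect_s3_class(p, "ggplot")
})
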