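params_fast <- function(...) sim_params(phase1_iters = 2e3, stage_iters = 500, ...)

test_that("coarse initialization confines one bead per Mb inside the sphere", {
  k <- desk_karyotype()
  st <- init_coarse_nucleus(k, radius_nm = 2000, seed = 1)
  expect_equal(nrow(st$chains$chrA$positions), 20)
  expect_true(all(rowSums(st$chains$chrA$positions^2) < 2000^2))
  expect_true(all(rowSums(st$chains$chrB$positions^2) < 2000^2))
  st2 <- init_coarse_nucleus(k, radius_nm = 2000, seed = 1)
  expect_identical(st$chains$chrA$positions, st2$chains$chrA$positions)

  # occupancy guard: a tiny nucleus cannot hold the beads
  expect_error(init_coarse_nucleus(k, radius_nm = 400, seed = 1),
               "occupancy")
})

test_that("volume occupancy matches the closed form", {
  k <- tibble::tibble(chrom = "c", length = 1e6)
  st <- init_coarse_nucleus(k, radius_nm = 1000, bead_diam_nm = 300, seed = 1)
  expect_equal(volume_occupancy(st), (300 / 2000)^3)
  st$chains$c$bead_diameter <- 400
  expect_gt(volume_occupancy(st), (300 / 2000)^3)
  # full default system: occupancy is reported, not enforced
  kd <- default_human_karyotype()
  sd <- init_coarse_nucleus(kd, radius_nm = 4950, seed = 2)
  expect_gt(volume_occupancy(sd), 0.05)
  expect_lt(volume_occupancy(sd), 0.4)
})

test_that("zero iterations leave the state unchanged; seeds reproduce", {
  k <- desk_karyotype()
  st <- init_coarse_nucleus(k, radius_nm = 2000, seed = 3)
  expect_identical(run_dynamics(st, 0), st)
  a <- run_dynamics(st, 500, params_fast(), seed = 9)
  b <- run_dynamics(st, 500, params_fast(), seed = 9)
  expect_identical(a$chains$chrA$positions, b$chains$chrA$positions)
})

test_that("a thermalized bonded dimer samples the radial harmonic density", {
  k <- tibble::tibble(chrom = "c", length = 2e6)
  st <- init_coarse_nucleus(k, radius_nm = 5000, bead_diam_nm = 300, seed = 4)
  # expected mean bond length under p(r) ~ r^2 exp(-U(r)), with U the bond
  # spring (kb = 100 / r0^2 reduced) plus the WCA repulsion also felt by
  # bonded neighbors
  r0 <- 1
  kb <- 100
  uu <- function(r) {
    wca <- ifelse(r < 2^(1 / 6), 4 * ((1 / r)^12 - (1 / r)^6) + 1, 0)
    kb * (r - r0)^2 / 2 + wca
  }
  num <- stats::integrate(function(r) r^3 * exp(-uu(r)), 0.3, 3)$value
  den <- stats::integrate(function(r) r^2 * exp(-uu(r)), 0.3, 3)$value
  expected <- 300 * num / den
  set.seed(4)
  lens <- vapply(1:250, function(i) {
    st <<- run_dynamics(st, 200, sim_params())
    p <- st$chains$c$positions
    sqrt(sum((p[1, ] - p[2, ])^2))
  }, numeric(1))
  lens <- lens[-(1:50)]
  se <- stats::sd(lens) / sqrt(length(lens) / 5)  # generous correlation factor
  expect_lt(abs(mean(lens) - expected), 3 * se + 1)
})

test_that("B-B attraction increases inter-chain contacts", {
  k <- desk_karyotype(10e6)
  more_contacts <- vapply(1:12, function(i) {
    mk <- function(lab) {
      tr <- lapply(k$chrom, function(cid) {
        t <- synthetic_compartment_track(k, cid, seed = i)
        t$label <- rep(lab, nrow(t))
        t
      })
      names(tr) <- k$chrom
      st <- init_coarse_nucleus(k, tracks = tr, radius_nm = 1500, seed = i)
      st <- run_dynamics(st, 8000, sim_params(eps_BB = 1.5), seed = 100 + i)
      pos <- rbind(st$chains$chrA$positions, st$chains$chrB$positions)
      pr <- chromloops:::contact_pairs_cpp(pos, 540)
      sum(pr[, 1] <= 10 & pr[, 2] > 10)
    }
    mk("B") - mk("A")
  }, numeric(1))
  expect_gt(mean(more_contacts), 0)
  expect_gte(sum(more_contacts > 0), 8)
})

test_that("fine-graining preserves genomic bookkeeping down the ladder", {
  k <- desk_karyotype()
  st <- init_coarse_nucleus(k, radius_nm = 2000, seed = 5)
  st <- run_dynamics(st, 200, params_fast())
  for (f in c(2, 2, 5, 5, 2)) {
    st <- fine_grain(st, "chrA", f, seed = 6)
  }
  ch <- st$chains$chrA
  expect_equal(nrow(ch$positions), 20e6 / 5e3)
  expect_equal(ch$bead_diameter, 45)
  expect_equal(ch$bin_edges[1], 0)
  expect_equal(ch$bin_edges[length(ch$bin_edges)], 20e6)
  expect_true(all(diff(ch$bin_edges) == 5e3))
  # untouched chain keeps its resolution
  expect_equal(nrow(st$chains$chrB$positions), 20)
  # diameter schedule honors both printed anchors
  expect_equal(chromloops:::bead_diameter_for(1e6), 300)
  expect_equal(chromloops:::bead_diameter_for(5e3), 45)
  expect_error(fine_grain(st, "chrA", 3), "factor")
})

test_that("children scatter around the parent bead with the stated spread", {
  k <- tibble::tibble(chrom = "c", length = 10e6)
  st <- init_coarse_nucleus(k, radius_nm = 3000, seed = 7)
  parent_pos <- st$chains$c$positions
  st2 <- fine_grain(st, "c", 5, disp_sd_nm = 45, seed = 8)
  disp <- st2$chains$c$positions - parent_pos[rep(1:10, each = 5), ]
  expect_lt(abs(stats::sd(disp) - 45) / 45, 0.15)
  expect_lt(abs(mean(disp)), 3 * 45 / sqrt(length(disp)))
})

test_that("loop bonds map anchors to beads and deduplicate", {
  k <- tibble::tibble(chrom = "c", length = 10e6)
  st <- init_coarse_nucleus(k, radius_nm = 3000, seed = 9)
  st <- fine_grain(st, "c", 2, seed = 9)  # 500 kb beads
  expect_equal(nrow(add_loop_bonds(st, place_loops(10e6, density = 0),
                                   "c")$extra_bonds), 0)
  ls <- tibble::tibble(left = c(1e5, 1.2e5, 2e6), right = c(3e6, 3.1e6, 2.1e6),
                       loading_point = c(1e6, 1e6, 2.05e6),
                       stop_left = factor("processivity"),
                       stop_right = factor("processivity"))
  attr(ls, "chrom_length") <- 10e6
  st2 <- add_loop_bonds(st, ls, "c")
  # loops 1 and 2 hit the same bead pair; loop 3 stays within one bead
  expect_equal(nrow(st2$extra_bonds), 1)
  bad <- tibble::tibble(left = -5, right = 1e6, loading_point = 0,
                        stop_left = factor("chrom_end"),
                        stop_right = factor("processivity"))
  expect_error(add_loop_bonds(st, bad, "c"), "anchor")
})

test_that("loop bonds pull anchors into contact during equilibration", {
  k <- tibble::tibble(chrom = "c", length = 10e6)
  frac_close <- vapply(1:6, function(i) {
    st <- init_coarse_nucleus(k, radius_nm = 1500, seed = 20 + i)
    st <- run_dynamics(st, 2000, sim_params(), seed = 30 + i)
    for (f in c(2, 2, 5)) st <- fine_grain(st, "c", f, seed = 40 + i)
    st <- run_dynamics(st, 2000, sim_params(), seed = 50 + i)
    ls <- place_loops(10e6, density = 2, seed = 60 + i)
    st <- add_loop_bonds(st, ls, "c")
    st <- run_dynamics(st, 3e4, sim_params(), seed = 70 + i)
    eb <- st$extra_bonds
    p <- st$chains$c$positions
    d <- sqrt(rowSums((p[eb$i, , drop = FALSE] - p[eb$j, , drop = FALSE])^2))
    mean(d < 2 * st$chains$c$bead_diameter)
  }, numeric(1))
  expect_gte(mean(frac_close), 0.9)
})

test_that("chain connectivity and confinement hold through the three phases", {
  cfg <- desk_config(densities = c(0, 25), n_replicates = 2, seed = 11)
  snaps <- run_three_phase(cfg)
  expect_length(snaps, 4)
  expect_length(attr(snaps, "checkpoints"), 2)
  for (s in snaps) {
    st <- s$state
    for (ch in st$chains) {
      d <- sqrt(rowSums(diff(ch$positions)^2))
      expect_lt(max(d), 3 * ch$bead_diameter)
      r <- sqrt(rowSums(ch$positions^2))
      frac_out <- mean(r > st$nuclear_radius + ch$bead_diameter / 2)
      expect_lte(frac_out, 0.001)
    }
    expect_equal(nrow(st$chains$chrA$positions), 400)  # 50 kb target
  }
  # identical config and seed give identical trajectories
  snaps2 <- run_three_phase(cfg)
  expect_identical(snaps[[1]]$state$chains$chrA$positions,
                   snaps2[[1]]$state$chains$chrA$positions)
  expect_identical(snaps[[4]]$loopset, snaps2[[4]]$loopset)
})

test_that("a free excluded-volume chain swells like a self-avoiding walk", {
  set.seed(12)
  sizes <- c(50, 100, 200)
  mean_rg <- vapply(sizes, function(n) {
    rgs <- vapply(1:6, function(i) {
      k <- tibble::tibble(chrom = "c", length = n * 1e6)
      st <- init_coarse_nucleus(k, radius_nm = 1e5, bead_diam_nm = 100,
                                seed = 1000 * n + i)
      st$nuclear_radius <- Inf
      # WCA only (compartment attraction off); iteration budget grows as
      # N^2 so every size reaches the same relative equilibration
      st <- run_dynamics(st, 3 * n^2, sim_params(eps_BB = 0),
                         seed = 2000 * n + i)
      p <- st$chains$c$positions
      sqrt(mean(rowSums(sweep(p, 2, colMeans(p))^2)))
    }, numeric(1))
    mean(rgs)
  }, numeric(1))
  fit <- stats::lm(log(mean_rg) ~ log(sizes))
  nu <- unname(stats::coef(fit)[2])
  expect_gte(nu, 0.5)
  expect_lte(nu, 0.65)
})

test_that("snapshots round-trip through the plain-text format", {
  cfg <- desk_config(densities = 25, n_replicates = 1, seed = 13)
  snaps <- run_three_phase(cfg)
  st <- snaps[[1]]$state
  dir <- withr::local_tempdir()
  write_snapshot(st, dir)
  back <- read_snapshot(dir)
  expect_equal(back$nuclear_radius, st$nuclear_radius)
  expect_equal(back$chains$chrA$positions, st$chains$chrA$positions,
               tolerance = 1e-12)
  expect_equal(back$chains$chrA$compartment, st$chains$chrA$compartment)
  expect_equal(as.data.frame(back$extra_bonds), as.data.frame(st$extra_bonds))
})
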