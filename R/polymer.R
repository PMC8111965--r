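#' Simulation parameters for the bead-spring model
#'
#' Reduced Langevin-dynamics units: energies in kT, lengths in nm (scaled
#' internally by the smallest bead diameter), time in units of the damping
#' time. Defaults: unit temperature and friction, `dt = 0.005`, bond
#' stiffness `100 kT / sigma^2` (sigma = bond rest length), B-B attraction
#' well depth `0.3 kT` with cutoff `1.8 sigma`, purely repulsive (WCA)
#' interactions otherwise.
#'
#' @param kT Thermal energy (reduced; fixed at 1 in the integrator).
#' @param friction Langevin friction (1/time).
#' @param dt Integration time step.
#' @param bond_k Bond stiffness prefactor (kT / sigma^2 units).
#' @param eps_BB B-B attraction well depth (kT).
#' @param lj_cut_attract B-B cutoff in units of the pair diameter.
#' @param phase1_iters Coarse-phase iteration budget.
#' @param stage_iters Per-stage budget for fine-graining and loop phases.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(kT = 1, friction = 1, dt = 0.005, bond_k = 100,
                       eps_BB = 0.3, lj_cut_attract = 1.8,
                       phase1_iters = 3e6, stage_iters = 1e5) {
  stopifnot(kT > 0, friction > 0, dt > 0, bond_k > 0, eps_BB >= 0,
            lj_cut_attract > 1, dt * friction < 1)
  structure(list(kT = kT, friction = friction, dt = dt, bond_k = bond_k,
                 eps_BB = eps_BB, lj_cut_attract = lj_cut_attract,
                 phase1_iters = phase1_iters, stage_iters = stage_iters),
            class = "sim_params")
}

# diameter schedule: geometric interpolation in log-diameter between the
# 300 nm @ 1 Mb and 45 nm @ 5 kb anchors: d(g) = 300 (g / 1 Mb)^p,
# p = ln(300/45) / ln(200)
bead_diameter_for <- function(bin_size) {
  p <- log(300 / 45) / log(200)
  300 * (bin_size / 1e6)^p
}

new_bead_chain <- function(chrom, bin_edges, bead_diameter, positions,
                           compartment) {
  n <- length(bin_edges) - 1
  stopifnot(nrow(positions) == n, length(compartment) == n,
            all(diff(bin_edges) > 0), all(is.finite(positions)))
  structure(list(chrom = chrom, bin_edges = bin_edges,
                 bead_diameter = bead_diameter, positions = positions,
                 compartment = compartment),
            class = "bead_chain")
}

#' @export
print.bead_chain <- function(x, ...) {
  cat(sprintf("<bead_chain %s: %d beads x %g bp, diameter %.1f nm>\n",
              x$chrom, nrow(x$positions), x$bin_edges[2] - x$bin_edges[1],
              x$bead_diameter))
  invisible(x)
}

#' @export
print.system_state <- function(x, ...) {
  cat(sprintf("<system_state: %d chains, %d beads, R = %.0f nm, %d loop bonds>\n",
              length(x$chains), sum(vapply(x$chains, function(ch)
                nrow(ch$positions), 1L)), x$nuclear_radius,
              if (is.null(x$extra_bonds)) 0L else nrow(x$extra_bonds)))
  invisible(x)
}

new_system_state <- function(chains, nuclear_radius, extra_bonds = NULL) {
  if (is.null(extra_bonds)) {
    extra_bonds <- tibble::tibble(chrom1 = character(), i = integer(),
                                  chrom2 = character(), j = integer())
  }
  structure(list(chains = chains, nuclear_radius = nuclear_radius,
                 extra_bonds = extra_bonds),
            class = "system_state")
}

#' Initialize a coarse-grained whole-nucleus system
#'
#' One chain per chromosome at one bead per `bin_size` (default 1 Mb, bead
#' diameter 300 nm). Initial conformations are confined random walks with
#' step length equal to the bead diameter; steps leaving the nuclear sphere
#' are redrawn. Compartment labels are copied per bead from the supplied
#' tracks.
#'
#' @param karyotype Karyotype tibble.
#' @param tracks Named list of compartment-track tibbles (one per
#'   chromosome, at `bin_size`), or `NULL` to generate synthetic tracks
#'   internally.
#' @param radius_nm Nuclear radius (default 4950).
#' @param bead_diam_nm Bead diameter (default 300).
#' @param bin_size Genomic bin per bead (default 1 Mb).
#' @param seed Optional integer seed.
#' @return A `system_state` object.
#' @export
init_coarse_nucleus <- function(karyotype, tracks = NULL, radius_nm = 4950,
                                bead_diam_nm = 300, bin_size = 1e6,
                                seed = NULL) {
  validate_karyotype(karyotype)
  if (!is.null(seed)) withr::local_seed(seed)
  if (is.null(tracks)) {
    tracks <- lapply(karyotype$chrom, function(cid) {
      synthetic_compartment_track(karyotype, cid, bin_size = bin_size)
    })
    names(tracks) <- karyotype$chrom
  }
  occ <- sum(ceiling(karyotype$length / bin_size)) *
    (bead_diam_nm / (2 * radius_nm))^3
  if (occ > 0.4) {
    rlang::abort(sprintf("volume occupancy %.2f exceeds 40%%: radius too small",
                         occ))
  }
  chains <- lapply(karyotype$chrom, function(cid) {
    len <- chrom_length(karyotype, cid)
    n <- ceiling(len / bin_size)
    tr <- tracks[[cid]]
    if (is.null(tr) || nrow(tr) != n) {
      rlang::abort(paste0("no compartment track at bin_size for ", cid))
    }
    pos <- matrix(0, n, 3)
    # random start well inside the sphere
    repeat {
      p <- stats::runif(3, -radius_nm, radius_nm)
      if (sum(p^2) < (0.9 * radius_nm)^2) break
    }
    pos[1, ] <- p
    if (n > 1) {
      for (i in 2:n) {
        repeat {
          step <- stats::rnorm(3)
          step <- step / sqrt(sum(step^2)) * bead_diam_nm
          cand <- pos[i - 1, ] + step
          if (sum(cand^2) < radius_nm^2) break
        }
        pos[i, ] <- cand
      }
    }
    edges <- c(seq(0, len, by = bin_size))
    if (edges[length(edges)] < len) edges <- c(edges, len)
    new_bead_chain(cid, edges, bead_diam_nm, pos, tr$label)
  })
  names(chains) <- karyotype$chrom
  new_system_state(chains, radius_nm)
}

#' Volume occupancy of a system
#'
#' Sum of bead volumes divided by the nuclear sphere volume.
#'
#' @param state A `system_state`.
#' @return Occupied volume fraction.
#' @export
volume_occupancy <- function(state) {
  bead_vol <- sum(vapply(state$chains, function(ch) {
    nrow(ch$positions) * (4 / 3) * pi * (ch$bead_diameter / 2)^3
  }, numeric(1)))
  bead_vol / ((4 / 3) * pi * state$nuclear_radius^3)
}

flatten_state <- function(state) {
  chains <- state$chains
  n_beads <- vapply(chains, function(ch) nrow(ch$positions), 1L)
  offset <- c(0, cumsum(n_beads))[seq_along(chains)]
  names(offset) <- names(chains)
  pos <- do.call(rbind, lapply(chains, `[[`, "positions"))
  diam <- unlist(lapply(chains, function(ch)
    rep(ch$bead_diameter, nrow(ch$positions))), use.names = FALSE)
  lab <- unlist(lapply(chains, function(ch)
    as.integer(ch$compartment == "B")), use.names = FALSE)
  bonds <- do.call(rbind, lapply(seq_along(chains), function(ci) {
    n <- n_beads[ci]
    if (n < 2) return(NULL)
    cbind(offset[ci] + seq_len(n - 1), offset[ci] + seq_len(n - 1) + 1,
          chains[[ci]]$bead_diameter)
  }))
  eb <- state$extra_bonds
  if (nrow(eb) > 0) {
    loop_bonds <- cbind(offset[eb$chrom1] + eb$i, offset[eb$chrom2] + eb$j,
                        vapply(eb$chrom1, function(cn)
                          chains[[cn]]$bead_diameter, numeric(1)))
    bonds <- rbind(bonds, loop_bonds)
  }
  list(pos = pos, diam = diam, lab = lab,
       bonds = bonds[, 1:2, drop = FALSE] - 1L,
       bond_r0 = bonds[, 3], offset = offset, n_beads = n_beads)
}

#' Advance Langevin dynamics
#'
#' Velocity-Verlet (BAOAB) Langevin integration of the full system under
#' chain bonds, loop bonds, excluded volume (WCA), B-B attraction and
#' spherical confinement. The trajectory is reproducible under a fixed seed.
#'
#' @param state A `system_state`.
#' @param n_iter Number of iterations (0 returns the state unchanged).
#' @param params A [sim_params()] list.
#' @param seed Optional integer seed.
#' @return The advanced `system_state`.
#' @export
run_dynamics <- function(state, n_iter, params = sim_params(), seed = NULL) {
  stopifnot(n_iter >= 0)
  if (n_iter == 0) return(state)
  if (!is.null(seed)) withr::local_seed(seed)
  fl <- flatten_state(state)
  bonds <- fl$bonds
  storage.mode(bonds) <- "integer"
  newpos <- run_dynamics_cpp(fl$pos, fl$diam, fl$lab, bonds, fl$bond_r0,
                             state$nuclear_radius, as.integer(n_iter),
                             params$dt, params$friction, params$eps_BB,
                             params$lj_cut_attract, params$bond_k)
  for (ci in seq_along(state$chains)) {
    idx <- fl$offset[ci] + seq_len(fl$n_beads[ci])
    state$chains[[ci]]$positions <- newpos[idx, , drop = FALSE]
  }
  state
}

#' Fine-grain one chromosome by an integer factor
#'
#' Replaces each bead of the target chain by `factor` smaller beads placed
#' at the parent position plus an isotropic Gaussian displacement
#' (sd `disp_sd_nm` per coordinate). Bead diameters follow the geometric
#' log-diameter schedule anchored at 300 nm per 1 Mb and 45 nm per 5 kb;
#' compartment labels are inherited from the parent bead. The resolution
#' ladder is 1 Mb - 500 kb - 250 kb - 50 kb - 10 kb - 5 kb (factors 2 and 5
#' only).
#'
#' @param state A `system_state`.
#' @param chrom_id Chain to refine.
#' @param factor Subdivision factor, 2 or 5.
#' @param disp_sd_nm Gaussian displacement sd (default 45).
#' @param new_radius_nm Updated nuclear radius (default: unchanged).
#' @param seed Optional integer seed.
#' @return The refined `system_state`.
#' @export
fine_grain <- function(state, chrom_id, factor, disp_sd_nm = 45,
                       new_radius_nm = NULL, seed = NULL) {
  if (!factor %in% c(2, 5)) rlang::abort("factor must be 2 or 5")
  ch <- state$chains[[chrom_id]]
  if (is.null(ch)) rlang::abort(paste0("unknown chain: ", chrom_id))
  if (nrow(state$extra_bonds) > 0 &&
      any(state$extra_bonds$chrom1 == chrom_id |
          state$extra_bonds$chrom2 == chrom_id)) {
    rlang::abort("cannot fine-grain a chain that already has loop bonds")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  bin <- ch$bin_edges[2] - ch$bin_edges[1]
  if (bin %% factor != 0) rlang::abort("factor does not divide the bin size")
  new_bin <- bin / factor
  n_old <- nrow(ch$positions)
  parent <- rep(seq_len(n_old), each = factor)
  pos <- ch$positions[parent, , drop = FALSE] +
    matrix(stats::rnorm(n_old * factor * 3, 0, disp_sd_nm), ncol = 3)
  len <- ch$bin_edges[length(ch$bin_edges)]
  edges <- seq(0, by = new_bin, length.out = n_old * factor + 1)
  edges[length(edges)] <- len  # last bin absorbs a partial tail, if any
  chain <- new_bead_chain(ch$chrom, edges, bead_diameter_for(new_bin), pos,
                          ch$compartment[parent])
  state$chains[[chrom_id]] <- chain
  if (!is.null(new_radius_nm)) state$nuclear_radius <- new_radius_nm
  state
}

#' Add loop bonds from a placed loop set
#'
#' Each loop contributes one harmonic bond (identical to the chain bonds)
#' between the beads containing its two anchors; duplicate bead pairs
#' collapse to one bond, and loops whose anchors fall in the same bead are
#' skipped (a bond of a bead to itself is meaningless).
#'
#' @param state A `system_state`.
#' @param loopset Loop-set tibble from [place_loops()].
#' @param chrom_id Target chain.
#' @return The `system_state` with loop bonds appended.
#' @export
add_loop_bonds <- function(state, loopset, chrom_id) {
  ch <- state$chains[[chrom_id]]
  if (is.null(ch)) rlang::abort(paste0("unknown chain: ", chrom_id))
  len <- ch$bin_edges[length(ch$bin_edges)]
  if (nrow(loopset) == 0) return(state)
  if (any(loopset$left < 0 | loopset$right > len)) {
    rlang::abort("loop anchor outside chromosome")
  }
  bi <- findInterval(loopset$left, ch$bin_edges, rightmost.closed = TRUE)
  bj <- findInterval(loopset$right, ch$bin_edges, rightmost.closed = TRUE)
  lo <- pmin(bi, bj)
  hi <- pmax(bi, bj)
  keep <- lo != hi
  pairs <- unique(tibble::tibble(chrom1 = chrom_id, i = lo[keep],
                                 chrom2 = chrom_id, j = hi[keep]))
  state$extra_bonds <- unique(dplyr::bind_rows(state$extra_bonds, pairs))
  state
}

#' Three-phase multi-scale simulation
#'
#' Phase 1: coarse-grained whole nucleus (one bead per Mb), Langevin
#' equilibration. Phase 2: the focal chromosome is fine-grained down the
#' resolution ladder with a dynamics stage after each refinement while the
#' nuclear radius grows linearly between `radius_nm` and `final_radius_nm`.
#' Phase 3: each end-of-phase-2 configuration is reused as the initial state
#' for every requested loop density; loop bonds are added and the system is
#' equilibrated once more.
#'
#' @param config A list with elements `karyotype`, `fine_chrom`, `densities`
#'   (loops per Mb), `n_replicates`, `params` ([sim_params()]),
#'   `radius_nm`, `final_radius_nm`, `bin_size`, `target_bin`, `L0`, `d0`,
#'   `seed`, and optionally `tracks`. See [desk_config()] for a reduced
#'   preset.
#' @return A list of snapshots, each a list with `replicate`, `density`,
#'   `loopset` and `state`; the shared phase-2 checkpoints are attached as
#'   attribute `checkpoints`.
#' @export
run_three_phase <- function(config) {
  cfg <- config
  stopifnot(!is.null(cfg$karyotype), !is.null(cfg$fine_chrom),
            !is.null(cfg$densities), !is.null(cfg$n_replicates))
  params <- cfg$params %||% sim_params()
  ladder <- ladder_factors(cfg$bin_size %||% 1e6, cfg$target_bin %||% 5e3)
  radii <- seq(cfg$radius_nm %||% 4950, cfg$final_radius_nm %||% 5400,
               length.out = length(ladder) + 1)[-1]
  base_seed <- cfg$seed %||% 1
  checkpoints <- vector("list", cfg$n_replicates)
  snapshots <- list()
  for (rep_i in seq_len(cfg$n_replicates)) {
    s_rep <- (base_seed + 7919 * rep_i) %% .Machine$integer.max
    state <- init_coarse_nucleus(cfg$karyotype, cfg$tracks,
                                 radius_nm = cfg$radius_nm %||% 4950,
                                 bead_diam_nm = cfg$bead_diam_nm %||% 300,
                                 bin_size = cfg$bin_size %||% 1e6,
                                 seed = s_rep)
    state <- run_dynamics(state, params$phase1_iters, params, seed = s_rep + 1)
    for (st in seq_along(ladder)) {
      state <- fine_grain(state, cfg$fine_chrom, ladder[st],
                          new_radius_nm = radii[st], seed = s_rep + 10 + st)
      state <- run_dynamics(state, params$stage_iters, params,
                            seed = s_rep + 100 + st)
    }
    checkpoints[[rep_i]] <- state
    len <- chrom_length(cfg$karyotype, cfg$fine_chrom)
    for (di in seq_along(cfg$densities)) {
      dens <- cfg$densities[di]
      s_loop <- s_rep + 1000 + di
      loops <- place_loops(len, density = dens, d0 = cfg$d0 %||% 250e3,
                           L0 = cfg$L0 %||% 165e3, seed = s_loop)
      st3 <- add_loop_bonds(state, loops, cfg$fine_chrom)
      st3 <- run_dynamics(st3, params$stage_iters, params, seed = s_loop + 1)
      snapshots[[length(snapshots) + 1]] <-
        list(replicate = rep_i, density = dens, loopset = loops, state = st3)
    }
  }
  attr(snapshots, "checkpoints") <- checkpoints
  snapshots
}

ladder_factors <- function(from_bin, to_bin) {
  ladder_bins <- c(1e6, 5e5, 2.5e5, 5e4, 1e4, 5e3)
  i <- match(from_bin, ladder_bins)
  j <- match(to_bin, ladder_bins)
  if (is.na(i) || is.na(j) || j < i) {
    rlang::abort("resolution must follow the 1 Mb-500-250-50-10-5 kb ladder")
  }
  if (i == j) return(integer(0))
  ladder_bins[i:(j - 1)] / ladder_bins[(i + 1):j]
}

#' Reduced desk-scale configuration
#'
#' A small whole-pipeline preset (two 20-Mb chromosomes, shortened
#' iteration budgets, 50-kb target resolution) used for smoke tests and
#' examples; the full-scale configuration ([full_scale_config()]) keeps (46
#' chromosomes, 5-kb target, 3e6/1e5 iteration budgets) and is cluster
#' scale.
#'
#' @param densities Loop densities (per Mb) for phase 3.
#' @param n_replicates Number of independent replicates.
#' @param seed Master seed.
#' @return A config list for [run_three_phase()].
#' @export
desk_config <- function(densities = c(0, 25), n_replicates = 1, seed = 1) {
  kar <- tibble::tibble(chrom = c("chrA", "chrB"), length = c(20e6, 20e6))
  list(karyotype = kar, fine_chrom = "chrA", densities = densities,
       n_replicates = n_replicates,
       params = sim_params(phase1_iters = 5e3, stage_iters = 1e3),
       radius_nm = 2000, final_radius_nm = 2200, bin_size = 1e6,
       target_bin = 5e4, seed = seed)
}

#' Full-scale experiment configuration
#'
#' 46 chromosomes at 1 Mb, chromosome 1 refined to 5 kb, densities
#' 0-25 loops/Mb, 102 replicates; requires cluster-scale compute.
#'
#' @param seed Master seed.
#' @return A config list for [run_three_phase()].
#' @export
full_scale_config <- function(seed = 1) {
  list(karyotype = default_human_karyotype(), fine_chrom = "chr1_a",
       densities = c(0, 2, 4, 6, 10, 15, 20, 25), n_replicates = 102,
       params = sim_params(), radius_nm = 4950, final_radius_nm = 5400,
       bin_size = 1e6, target_bin = 5e3, seed = seed)
}

#' Write / read a system snapshot as plain text
#'
#' A snapshot directory holds one `beads.csv` (chain, bead index, bin
#' edges, diameter, compartment, x/y/z) plus a `meta.json` with the nuclear
#' radius and loop bonds.
#'
#' @param state A `system_state`.
#' @param dir Output directory (created if missing).
#' @export
write_snapshot <- function(state, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  beads <- dplyr::bind_rows(lapply(state$chains, function(ch) {
    n <- nrow(ch$positions)
    tibble::tibble(
      chrom = ch$chrom, bead = seq_len(n),
      bin_start = ch$bin_edges[-(n + 1)], bin_end = ch$bin_edges[-1],
      diameter = ch$bead_diameter, compartment = ch$compartment,
      x_nm = ch$positions[, 1], y_nm = ch$positions[, 2],
      z_nm = ch$positions[, 3]
    )
  }))
  readr::write_csv(beads, file.path(dir, "beads.csv"))
  jsonlite::write_json(
    list(nuclear_radius = state$nuclear_radius,
         extra_bonds = state$extra_bonds),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname write_snapshot
#' @export
read_snapshot <- function(dir) {
  beads <- readr::read_csv(file.path(dir, "beads.csv"),
                           show_col_types = FALSE, progress = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  chains <- lapply(split(beads, factor(beads$chrom, unique(beads$chrom))),
                   function(b) {
    b <- b[order(b$bead), ]
    new_bead_chain(b$chrom[1], c(b$bin_start, b$bin_end[nrow(b)]),
                   b$diameter[1], cbind(b$x_nm, b$y_nm, b$z_nm),
                   b$compartment)
  })
  eb <- tibble::as_tibble(meta$extra_bonds)
  if (nrow(eb) == 0) eb <- NULL
  new_system_state(chains[unique(beads$chrom)], meta$nuclear_radius, eb)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
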