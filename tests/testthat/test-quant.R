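test_that("Voronoi density recovers a homogeneous Poisson intensity", {
  set.seed(1)
  n <- 10000
  locs <- uniform_locs(n, side = 1000)  # 1000 nm cube -> n per 1e9 nm^3
  d <- voronoi_local_density(locs, k = 2)
  expect_lt(abs(stats::median(d$density) - n / 1e9) / (n / 1e9), 0.1)
  expect_true(all(d$density > 0))
})

test_that("k = 0 density is exactly the inverse own-cell volume", {
  set.seed(2)
  locs <- uniform_locs(500)
  d0 <- voronoi_local_density(locs, k = 0)
  expect_equal(d0$density, 1 / d0$cell_volume)
})

test_that("k-ring neighborhoods agree with a breadth-first-search oracle", {
  set.seed(3)
  locs <- uniform_locs(150)
  d <- voronoi_local_density(locs, k = 2)
  adj <- attr(d, "adjacency")
  for (k in 0:3) {
    dk <- voronoi_local_density(locs, k = k)
    for (i in c(1, 17, 50, 150)) {
      ring <- bfs_ring_oracle(adj, i, k)
      expect_equal(dk$density[i], length(ring) / sum(dk$cell_volume[ring]),
                   tolerance = 1e-12)
    }
  }
})

test_that("Voronoi cell volumes tile the clipped bounding box", {
  set.seed(4)
  locs <- uniform_locs(800)
  d <- voronoi_local_density(locs, k = 0, pad_frac = 0.01)
  m <- cbind(locs$x_nm, locs$y_nm, locs$z_nm)
  pad <- sqrt(sum((apply(m, 2, max) - apply(m, 2, min))^2)) * 0.01
  box <- prod(apply(m, 2, max) - apply(m, 2, min) + 2 * pad)
  expect_equal(sum(d$cell_volume), box, tolerance = 1e-9)
})

test_that("duplicate localizations are jittered and retried", {
  set.seed(5)
  locs <- uniform_locs(100)
  locs2 <- dplyr::bind_rows(locs, locs[1:3, ])
  expect_no_error(voronoi_local_density(locs2, k = 1))
})

test_that("background estimation is accurate, translation-invariant, strict", {
  set.seed(6)
  # pure background at 150 per um^3 in a 4 um cube
  n <- round(150 * 64)
  locs <- uniform_locs(n, side = 4000)
  d <- voronoi_local_density(locs, k = 2)
  est <- estimate_background_density(locs, d,
                                     roi = c(500, 500, 500, 3500, 3500, 3500))
  expect_lt(abs(est - 150e-9) / 150e-9, 0.10)
  # the automatic pick (lowest-density sub-box) is deliberately
  # conservative on homogeneous data but stays in range
  est_auto <- estimate_background_density(locs, d, roi = "auto")
  expect_lt(abs(est_auto - 150e-9) / 150e-9, 0.35)
  expect_lt(est_auto, est)

  shifted <- dplyr::mutate(locs, x_nm = x_nm + 5e5, y_nm = y_nm - 3e5)
  d2 <- voronoi_local_density(shifted, k = 2)
  est2 <- estimate_background_density(shifted, d2,
                                      roi = c(5e5, -3e5, 0, 5e5 + 4000,
                                              -3e5 + 4000, 4000))
  expect_lt(abs(est2 - est) / est, 0.15)

  expect_error(estimate_background_density(locs, d, roi = c(0, 0, 0, 1, 1, 1)),
               "background ROI")
})

test_that("density segmentation separates structure from background", {
  set.seed(7)
  # image the model's own structure: a desk-scale polymer chain at a
  # mid-range loop density, with the default imaging parameters
  snaps <- run_three_phase(desk_config(densities = 6, n_replicates = 1,
                                       seed = 21))
  ch <- snaps[[1]]$state$chains[["chrA"]]
  locs <- simulate_smlm_image(ch, c(0, 20e6), seed = 31)
  d <- voronoi_local_density(locs, k = 2)
  bg <- estimate_background_density(locs, d, roi = "auto")
  seg <- segment_by_density(locs, d, bg, bg_factor = 4)
  tt <- table(seg$source, seg$retained)
  precision <- tt["structure", "TRUE"] / sum(tt[, "TRUE"])
  recall <- tt["structure", "TRUE"] / sum(tt["structure", ])
  expect_gte(precision, 0.9)
  expect_gte(recall, 0.8)

  # nesting: larger factor can only shrink the retained set
  seg8 <- segment_by_density(locs, d, bg, bg_factor = 8)
  expect_true(all(seg$retained[seg8$retained]))
  # zero factor retains everything
  expect_true(all(segment_by_density(locs, d, bg, 0)$retained))
})

test_that("gyration radius matches closed forms and a pairwise oracle", {
  one <- tibble::tibble(x_nm = 5, y_nm = 5, z_nm = 5)
  expect_equal(gyration_radius(one), 0)
  two <- tibble::tibble(x_nm = c(0, 100), y_nm = 0, z_nm = 0)
  expect_equal(gyration_radius(two), 50)
  expect_error(gyration_radius(two[0, ]), "empty")

  set.seed(8)
  locs <- uniform_locs(1000)
  expect_equal(gyration_radius(locs), rg_pairwise_oracle(locs),
               tolerance = 1e-9)
})

test_that("rigid motions leave Rg and S invariant as expected", {
  set.seed(9)
  locs <- ball_locs(600, radius = 300)
  rg0 <- gyration_radius(locs)
  s0 <- smoothness(locs)

  shifted <- dplyr::mutate(locs, x_nm = x_nm + 1234, y_nm = y_nm - 987,
                           z_nm = z_nm + 55)
  expect_equal(gyration_radius(shifted), rg0, tolerance = 1e-9)
  expect_equal(smoothness(shifted), s0, tolerance = 1e-6)

  # rotation about z: Rg unchanged, S unchanged (alpha is anisotropic only
  # along z)
  th <- 0.7
  rotz <- dplyr::mutate(locs,
                        x0 = x_nm, y0 = y_nm,
                        x_nm = cos(th) * x0 - sin(th) * y0,
                        y_nm = sin(th) * x0 + cos(th) * y0)
  expect_equal(gyration_radius(rotz), rg0, tolerance = 1e-9)
  expect_equal(smoothness(rotz), s0, tolerance = 0.02 * s0)

  # a rotation mixing z with x changes S but not Rg
  rotx <- dplyr::mutate(locs,
                        y0 = y_nm, z0 = z_nm,
                        y_nm = cos(th) * y0 - sin(th) * z0,
                        z_nm = sin(th) * y0 + cos(th) * z0)
  expect_equal(gyration_radius(rotx), rg0, tolerance = 1e-9)
})

test_that("alpha hull converges to the convex hull and to zero", {
  set.seed(10)
  locs <- uniform_locs(60, side = 500)
  v_inf <- alpha_concave_volume(locs, c(1e9, 1e9, 1e9))
  expect_equal(v_inf, convex_hull_volume_oracle(locs), tolerance = 1e-6)

  # alpha below the minimal spacing removes every tetrahedron
  expect_equal(alpha_concave_volume(locs, c(1, 1, 1)), 0)
})

test_that("dense uniform sampling recovers the cube volume", {
  set.seed(11)
  locs <- uniform_locs(10000, side = 1000)  # 1 um cube
  v <- alpha_concave_volume(locs, c(500, 500, 1000))
  expect_lt(abs(v - 1e9) / 1e9, 0.1)
})

test_that("alpha-hull volume is monotone in alpha, bounding S in [0, 100]", {
  set.seed(12)
  locs <- ball_locs(1500, radius = 400)
  scales <- c(0.5, 1, 2, 4, 8)
  vols <- vapply(scales, function(s) {
    alpha_concave_volume(locs, s * c(100, 100, 200))
  }, numeric(1))
  expect_true(all(diff(vols) >= 0))

  expect_equal(smoothness(locs, c(100, 100, 200), c(100, 100, 200)), 100)
  s <- smoothness(locs)
  expect_gte(s, 0)
  expect_lte(s, 100)
  expect_error(smoothness(locs, c(100, 100, 200), c(500, 500, 500)),
               "proportional")
})

test_that("a dense convex blob is smooth; a drilled tunnel reduces S", {
  set.seed(13)
  blob <- ball_locs(10000, radius = 600)
  s_blob <- smoothness(blob)
  expect_gt(s_blob, 90)

  tunnel <- blob[blob$x_nm^2 + blob$y_nm^2 > 200^2, ]
  s_tunnel <- smoothness(tunnel)
  expect_lt(s_tunnel, s_blob)
})

test_that("FRC reports the Nyquist floor for identical halves and degrades
           with localization error", {
  set.seed(14)
  ch <- rw_chain(400, step = 100)
  locs <- simulate_smlm_image(ch, c(0, 20e6), seed = 1)
  expect_equal(frc_resolution(locs, split = FALSE), 20)

  r65 <- frc_resolution(locs, seed = 2)
  locs130 <- simulate_smlm_image(ch, c(0, 20e6), loc_error_sd = 130, seed = 1)
  r130 <- frc_resolution(locs130, seed = 2)
  expect_gt(r65, 2 * 10)
  expect_gt(r130, r65)
})
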