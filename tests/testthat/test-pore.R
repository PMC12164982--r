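pore_marker_topology <- function() {
  channel_topology(do.call(rbind, lapply(c("A", "B", "C"), function(ch) {
    data.frame(chain = ch, resnum = c(2444L, 2449L, 2450L, 2454L),
               resname = c("TYR", "LEU", "VAL", "PHE"), beadname = "BB",
               species = "protein", leaflet = "none", stringsAsFactors = FALSE)
  })))
}

marker_coords <- function(top_pts, mid_pts, bot_pts, alt_pts = mid_pts) {
  do.call(rbind, lapply(1:3, function(c_) {
    rbind(top_pts[[c_]], alt_pts[[c_]], mid_pts[[c_]], bot_pts[[c_]])
  }))
}

test_that("Heron's formula matches hand values and the cross-product oracle", {
  expect_equal(heron_area(3, 4, 5), 6)
  expect_equal(heron_area(2, 2, 2), sqrt(3), tolerance = 1e-9)
  expect_equal(heron_area(2, 2, 2), 1.7321, tolerance = 1e-4)
  # degenerate side triples give zero
  expect_equal(heron_area(1, 1, 3), 0)
  set.seed(71)
  for (i in 1:500) {
    A <- runif(3, 0, 10); B <- runif(3, 0, 10); C <- runif(3, 0, 10)
    a <- sqrt(sum((B - C)^2)); b <- sqrt(sum((A - C)^2))
    c_ <- sqrt(sum((A - B)^2))
    oracle <- cross_product_area(A, B, C)
    expect_lt(abs(heron_area(a, b, c_) - oracle) / max(oracle, 1e-12), 1e-9)
    # invariance under side permutation
    expect_equal(heron_area(a, b, c_), heron_area(c_, a, b), tolerance = 1e-12)
  }
})

test_that("pore triangles use the level markers and respect overrides", {
  # 3-4-5 right triangle at the top level
  top_pts <- list(c(0, 0, 6), c(3, 0, 6), c(3, 4, 6))
  mid_pts <- list(c(0, 0, 5), c(2, 0, 5), c(1, sqrt(3), 5))
  bot_pts <- list(c(0, 0, 4), c(1, 0, 4), c(0.5, 0.5, 4))
  alt_pts <- list(c(0, 0, 5), c(4, 0, 5), c(2, 2 * sqrt(3), 5))
  coords <- marker_coords(top_pts, mid_pts, bot_pts, alt_pts)
  coords[, 1:2] <- coords[, 1:2] + 10
  tr <- toy_trajectory(coords, box = c(30, 30, 30),
                       topology = pore_marker_topology())
  expect_equal(pore_triangle(tr, "top")$area, 6, tolerance = 1e-9)
  expect_equal(pore_triangle(tr, "middle")$area, sqrt(3), tolerance = 1e-9)
  # short-helix-mutant convention: chain C middle marker is L2449
  shm <- pore_triangle(tr, "middle", residue_overrides = c(C = 2449))
  # vertices become mid A, mid B, alt C = (0,0),(2,0),(2, 2*sqrt(3))
  expect_equal(shm$area, cross_product_area(c(0, 0, 5), c(2, 0, 5),
                                            c(2, 2 * sqrt(3), 5)),
               tolerance = 1e-9)
  expect_error(pore_triangle(tr, "middle", residue_overrides = c(Z = 2449)),
               "unknown chain")
})

test_that("generator pore side series are recovered per frame and per level", {
  sim <- small_sim()
  for (lv in c("top", "middle", "bottom")) {
    tri <- pore_triangle(sim$trajectory, lv)
    expect_equal(tri$a, sim$ground_truth$pore_sides[, lv], tolerance = 1e-9,
                 ignore_attr = TRUE)
    # generator triangles are equilateral: area consistency check
    expect_equal(tri$area, sqrt(3) / 4 * tri$a^2, tolerance = 1e-9)
  }
})

test_that("larger generator side parameters dilate the computed areas every frame", {
  wide <- channel_sim_params(n_frames = 40,
                             pore_side_mean = c(top = 2.8, middle = 2.2,
                                                bottom = 2.5))
  narrow <- channel_sim_params(n_frames = 40)
  a_wide <- pore_triangle(simulate_channel(
    wide, membrane_spec(n_lipids = 30), seed = 4)$trajectory, "middle")$area
  a_narrow <- pore_triangle(simulate_channel(
    narrow, membrane_spec(n_lipids = 30), seed = 4)$trajectory, "middle")$area
  expect_true(all(a_wide > a_narrow))
})

test_that("the hollow-channel voxel phantom volume is exact", {
  # filled 20^3 block with an empty 3 x 3 channel along z: 180 cavity voxels
  occ <- array(TRUE, c(20, 20, 20))
  occ[9:11, 9:11, ] <- FALSE
  res <- cavity_from_occupancy(occ, spacing = 1.4, dim_threshold = 3)
  expect_equal(nrow(res$voxels), 180L)
  expect_equal(res$volume_A3, 180 * 1.4^3, tolerance = 1e-12)
  # monotone in the buriedness threshold
  # the open channel is enclosed along only 4 axes, so dim 5 empties it
  expect_warning(res5 <- cavity_from_occupancy(occ, spacing = 1.4,
                                               dim_threshold = 5),
                 "no cavity")
  expect_lte(nrow(res5$voxels), nrow(res$voxels))
  # fully solid block has no cavity
  expect_warning(res0 <- cavity_from_occupancy(array(TRUE, c(8, 8, 8))),
                 "no cavity")
  expect_equal(res0$volume_A3, 0)
  # a seed outside the cavity gives an empty result with a warning
  expect_warning(resx <- cavity_from_occupancy(occ, seed_voxel = c(1, 1, 1)),
                 "seed voxel")
  expect_equal(resx$volume_A3, 0)
})

test_that("the cylinder phantom volume converges to pi r^2 L within 10%", {
  r_cyl <- 5; len_vox <- 15
  for (spacing in c(1.4, 0.7)) {
    half <- ceiling(12 / spacing)
    nxy <- 2 * half + 1
    cx <- half + 1
    centers <- (seq_len(nxy) - cx) * spacing
    rr <- sqrt(outer(centers^2, centers^2, "+"))
    occ2d <- rr > r_cyl
    occ <- array(rep(occ2d, len_vox), c(nxy, nxy, len_vox))
    res <- cavity_from_occupancy(occ, spacing = spacing, dim_threshold = 3)
    analytic <- pi * r_cyl^2 * (len_vox * spacing)
    expect_lt(abs(res$volume_A3 - analytic) / analytic, 0.10)
  }
})

test_that("bead-level cavity volume detects an enclosed pore and is monotone in dim", {
  # a ring wall of beads around an empty channel, stacked along z
  ang <- seq(0, 2 * pi, length.out = 25)[-25]
  wall <- do.call(rbind, lapply(seq(0, 1.2, by = 0.2), function(z) {
    cbind(0.8 * cos(ang), 0.8 * sin(ang), z)
  }))
  n <- nrow(wall)
  top <- toy_topology(n, chain = "A", resnum = 2440L, resname = "POR")
  f <- new_frame(wall + 5, c(10, 10, 10))
  res3 <- cavity_volume(f, top, residue_set = 2440L, spacing = 1.4,
                        dim_threshold = 3)
  expect_gt(res3$volume_A3, 0)
  res5 <- cavity_volume(f, top, residue_set = 2440L, spacing = 1.4,
                        dim_threshold = 5)
  expect_lte(res5$volume_A3, res3$volume_A3)
  expect_equal(res3$volume_A3, nrow(res3$voxels) * 1.4^3)
})

test_that("cavity volume of the synthetic pore is reproducible and positive", {
  sim <- small_sim()
  f <- sim$trajectory$frames[[1]]
  res <- cavity_volume(f, sim$trajectory$topology)
  expect_gt(res$volume_nm3, 0)
  res2 <- cavity_volume(f, sim$trajectory$topology)
  expect_identical(res$volume_A3, res2$volume_A3)
})
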