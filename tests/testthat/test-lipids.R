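# constructed system: one protein chain with two residues + lipids
contact_topology <- function(n_lipid, species = "PIP2") {
  prot <- do.call(rbind, lapply(c("A", "B", "C"), function(ch) {
    data.frame(chain = ch, resnum = c(10L, 11L), resname = "RES",
               beadname = "BB", species = "protein", leaflet = "none",
               stringsAsFactors = FALSE)
  }))
  lip <- data.frame(chain = NA_character_,
                    resnum = 100L + seq_len(n_lipid), resname = species,
                    beadname = ifelse(species == "PIP2", "P1", "PO4"),
                    species = species, leaflet = "lower",
                    stringsAsFactors = FALSE)
  channel_topology(rbind(prot, lip))
}

test_that("a fixed lipid at 0.5 nm from one residue gives a unit contact rate", {
  top <- contact_topology(1)
  prot <- rbind(c(1, 1, 1), c(3, 3, 3),          # chain A res 10, 11
                c(7, 7, 7), c(7, 9, 7),          # chain B
                c(12, 12, 12), c(12, 14, 12))    # chain C
  lipid <- c(1.5, 1, 1)                          # 0.5 nm from A res 10 only
  coords <- lapply(1:100, function(i) rbind(prot, lipid))
  tr <- toy_trajectory(coords, box = c(20, 20, 20),
                       topology = top)
  prof <- residue_lipid_contacts(tr, residue_set = c(10L, 11L),
                                 species = "PIP2", cutoff = 0.6)
  # chain-averaged: contact on 1 of 3 chains in every frame
  expect_equal(prof$contacts[prof$resnum == 10], 1 / 3, tolerance = 1e-12)
  expect_equal(prof$contacts[prof$resnum == 11], 0)
  # same geometry at 0.7 nm -> no contact
  coords2 <- lapply(1:10, function(i) rbind(prot, c(1.7, 1, 1)))
  tr2 <- toy_trajectory(coords2, box = c(20, 20, 20), topology = top)
  prof2 <- residue_lipid_contacts(tr2, c(10L, 11L), "PIP2", cutoff = 0.6)
  expect_true(all(prof2$contacts == 0))
  expect_error(residue_lipid_contacts(tr, c(10L, 11L), "DPSM"), "not present")
})

test_that("contact counting equals the O(N^2) 27-image brute-force oracle", {
  set.seed(31)
  box <- c(6, 6, 6)
  n_lip <- 12
  top <- contact_topology(n_lip)
  n_fr <- 40
  coords <- lapply(seq_len(n_fr), function(i) {
    matrix(runif(3 * (6 + n_lip), 0, 6), ncol = 3)
  })
  tr <- toy_trajectory(coords, box = box, topology = top)
  cutoff <- 0.8
  prof <- residue_lipid_contacts(tr, c(10L, 11L), "PIP2", cutoff = cutoff)
  # brute force: loop every frame, chain, residue, lipid over all 27 images
  brute <- matrix(0, 2, 3)
  for (t in seq_len(n_fr)) {
    for (ci in 1:3) {
      for (ri in 1:2) {
        prot_row <- (ci - 1) * 2 + ri
        for (l in seq_len(n_lip)) {
          dd <- brute_min_image(coords[[t]][prot_row, ],
                                coords[[t]][6 + l, ], box)
          if (dd <= cutoff) brute[ri, ci] <- brute[ri, ci] + 1
        }
      }
    }
  }
  expected <- rowMeans(brute) / (n_fr * n_lip)
  expect_equal(prof$contacts, unname(expected), tolerance = 1e-12)
})

test_that("interhelix contacts localise to the constructed tip pair", {
  # mostly-bound kinetics keep the tips engaged
  p <- channel_sim_params(n_frames = 150, k_on = 0.3, k_off0 = 0.05)
  sim <- simulate_channel(p, membrane_spec(n_lipids = 30), seed = 33)
  expect_gte(mean(sim$ground_truth$bound), 0.5)
  # bound tips sit ~1 nm apart in the generator; a 1.2 nm cutoff probes them
  ih <- interhelix_contacts(sim$trajectory, cutoff = 1.2)
  peak <- ih[which.max(ih$frequency), ]
  expect_equal(peak$sh_resnum, 176L)
  expect_equal(peak$lh_resnum, 1912L)
  # at the 0.6 nm default the constructed geometry has no contacts
  ih0 <- interhelix_contacts(subset_frames(sim$trajectory, 1:20), cutoff = 0.6)
  expect_true(all(ih0$frequency == 0))
})

test_that("unbound-only frames give an all-zero interhelix map", {
  p <- channel_sim_params(n_frames = 50, k_on = 0, k_off0 = 0.3)
  sim <- simulate_channel(p, membrane_spec(n_lipids = 30), seed = 3)
  # force the initial state unbound by dropping early frames where tips
  # may still be close
  gt_unbound <- which(rowSums(sim$ground_truth$bound) == 0 &
                      apply(sim$ground_truth$tip_distance, 1, min) > 1.4)
  expect_gte(length(gt_unbound), 5)
  ih <- interhelix_contacts(subset_frames(sim$trajectory, gt_unbound),
                            cutoff = 1.2)
  expect_true(all(ih$frequency == 0))
})

test_that("density maps conserve mass and ideal-gas lipids stay Poisson-uniform", {
  # one immobile bead
  top <- contact_topology(1)
  coords <- lapply(1:5, function(i) {
    rbind(matrix(5, 6, 3), c(2.05, 3.05, 1))
  })
  tr <- toy_trajectory(coords, box = c(20, 20, 20), topology = top)
  dm <- lipid_density_map(tr, "PIP2", bin = 0.1, fit = FALSE)
  expect_equal(sum(dm$values), 1)
  expect_equal(sum(dm$values > 0), 1L)
  # uniform ideal gas: per-bin counts within 4 sigma Poisson bounds
  set.seed(41)
  n_lip <- 400
  top2 <- contact_topology(n_lip)
  coords2 <- lapply(1:30, function(i) {
    rbind(matrix(1, 6, 3), cbind(runif(n_lip, 0, 8), runif(n_lip, 0, 8),
                                 rep(1, n_lip)))
  })
  tr2 <- toy_trajectory(coords2, box = c(8, 8, 8), topology = top2)
  dm2 <- lipid_density_map(tr2, "PIP2", bin = 2, fit = FALSE)
  expect_equal(sum(dm2$values), n_lip, tolerance = 1e-12)
  lam <- n_lip / length(dm2$values)      # expected lipids per bin per frame
  se <- sqrt(lam / 30)
  expect_true(all(abs(dm2$values - lam) < 4 * se))
})

test_that("PIP2 density concentrates near the handshake sites", {
  sim <- small_sim()
  dm <- lipid_density_map(sim$trajectory, "PIP2", bin = 1, fit = FALSE)
  box <- sim$trajectory$frames[[1]]$box
  ctr <- box[1:2] / 2
  nx <- nrow(dm$values)
  rr <- sqrt((row(dm$values) - 0.5 - ctr[1])^2 +
             (col(dm$values) - 0.5 - ctr[2])^2)
  # anchored walkers sit near the helix-tip radius (~11 nm), bulk far out
  near <- rr > 6 & rr < 15
  far <- rr >= 16
  expect_gt(max(dm$values[near]), max(dm$values[far]) * 2)
})

test_that("PIP2 pool counting is inclusive and monotone in the cutoff", {
  # three PIP2 at 1, 2, 3 nm from the single SH bead
  prot <- do.call(rbind, lapply(c("A", "B", "C"), function(ch) {
    data.frame(chain = ch, resnum = 176L, resname = "SH", beadname = "BB",
               species = "protein", leaflet = "none", stringsAsFactors = FALSE)
  }))
  lip <- data.frame(chain = NA_character_, resnum = 301:303, resname = "PIP2",
                    beadname = "P1", species = "PIP2", leaflet = "lower",
                    stringsAsFactors = FALSE)
  top <- channel_topology(rbind(prot, lip))
  coords <- rbind(c(5, 5, 5), c(25, 25, 5), c(45, 45, 5),
                  c(6, 5, 5), c(7, 5, 5), c(8, 5, 5))
  tr <- toy_trajectory(coords, box = c(60, 60, 20), topology = top)
  pool25 <- pip2_pool_series(tr, cutoff = 2.5)
  expect_equal(pool25[1, 1], 2L, ignore_attr = TRUE)
  pool20 <- pip2_pool_series(tr, cutoff = 2.0)
  expect_equal(pool20[1, 1], 2L, ignore_attr = TRUE)  # inclusive boundary
  pool10 <- pip2_pool_series(tr, cutoff = 1.0)
  expect_equal(pool10[1, 1], 1L, ignore_attr = TRUE)
  expect_true(all(pool10 <= pool20) && all(pool20 <= pool25))
})

test_that("systems without PIP2 give an all-zero pool with a warning", {
  p <- channel_sim_params(n_frames = 5)
  sim <- simulate_channel(p, membrane_spec_no_pip2(n_lipids = 40), seed = 2)
  expect_warning(pool <- pip2_pool_series(sim$trajectory), "no PIP2")
  expect_true(all(pool == 0))
})

test_that("leaflet height maps recover flat and analytic dome surfaces", {
  # flat leaflet at z = 2
  n <- 400
  top <- channel_topology(data.frame(
    chain = NA_character_, resnum = seq_len(n), resname = "POPC",
    beadname = "PO4", species = "POPC", leaflet = "lower",
    stringsAsFactors = FALSE))
  set.seed(51)
  coords <- lapply(1:10, function(i) {
    cbind(runif(n, 0, 10), runif(n, 0, 10), rep(2, n))
  })
  tr <- toy_trajectory(coords, box = c(10, 10, 10), topology = top)
  hm <- leaflet_height_map(tr, "lower", bin = 1)
  expect_true(all(abs(hm$values[!hm$mask] - 2) < 1e-12))
  expect_equal(dome_depth(hm), 0, tolerance = 1e-12)
  # analytic dome, noiseless samples on h(x, y) with D = 5, sigma = 5
  n2 <- 3000
  top2 <- channel_topology(data.frame(
    chain = NA_character_, resnum = seq_len(n2), resname = "POPC",
    beadname = "PO4", species = "POPC", leaflet = "lower",
    stringsAsFactors = FALSE))
  xy <- cbind(runif(n2, 0, 40), runif(n2, 0, 40))
  z <- 10 + dome_height(xy[, 1], xy[, 2], depth = 5, sigma = 5,
                        center = c(20, 20))
  tr2 <- toy_trajectory(list(cbind(xy, z)), box = c(40, 40, 20),
                        topology = top2)
  hm2 <- leaflet_height_map(tr2, "lower", bin = 1)
  expect_equal(min(hm2$values[!hm2$mask]) , 10 - 5, tolerance = 0.2)
  expect_equal(dome_depth(hm2), 5, tolerance = 0.25)
  expect_error(leaflet_height_map(tr2, "sideways"), "leaflet")
})

test_that("the trilobate dome shows a three-fold angular signature", {
  set.seed(61)
  n <- 6000
  top <- channel_topology(data.frame(
    chain = NA_character_, resnum = seq_len(n), resname = "POPC",
    beadname = "PO4", species = "POPC", leaflet = "lower",
    stringsAsFactors = FALSE))
  xy <- cbind(runif(n, 0, 40), runif(n, 0, 40))
  z <- 10 + dome_height(xy[, 1], xy[, 2], depth = 5, sigma = 7,
                        trilobate = 0.3, center = c(20, 20))
  tr <- toy_trajectory(list(cbind(xy, z)), box = c(40, 40, 20), topology = top)
  hm <- leaflet_height_map(tr, "lower", bin = 1)
  # sample the map on a ring at r ~ sigma and Fourier-analyse the angle
  ang <- seq(0, 2 * pi, length.out = 121)[-121]
  ring <- sapply(ang, function(a) {
    i <- pmin(pmax(round(20 + 7 * cos(a)), 1), nrow(hm$values))
    j <- pmin(pmax(round(20 + 7 * sin(a)), 1), ncol(hm$values))
    hm$values[i, j]
  })
  sp <- Mod(fft(ring - mean(ring)))[2:10]   # harmonics 1..9
  expect_equal(which.max(sp), 3L)
})

test_that("dome depth orderings are preserved between deep and shallow domes", {
  mk <- function(depth, seed) {
    p <- channel_sim_params(n_frames = 10, dome_depth = depth,
                            dome_trilobate = 0)
    sim <- simulate_channel(p, membrane_spec(n_lipids = 400), seed = seed)
    dome_depth(leaflet_height_map(sim$trajectory, "lower", bin = 2))
  }
  expect_gt(mk(6, 9), mk(2, 9))
})
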