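# constructed trimer with THU1/THU6/THU9, L71 and a pore bead per chain
blade_topology <- function() {
  channel_topology(do.call(rbind, lapply(c("A", "B", "C"), function(ch) {
    data.frame(chain = ch,
               resnum = c(1L, 6L, 9L, 71L, 2440L),
               resname = c("THU1", "THU6", "THU9", "LEU", "POR"),
               beadname = c("BB", "BB", "BB", "CA", "BB"),
               species = "protein", leaflet = "none",
               stringsAsFactors = FALSE)
  })))
}

blade_coords <- function(thu1, thu6, thu9, l71, pore) {
  do.call(rbind, lapply(1:3, function(c_) {
    rbind(thu1[[c_]], thu6[[c_]], thu9[[c_]], l71[[c_]], pore[[c_]])
  }))
}

equilateral_l71 <- function(side) {
  r <- side / sqrt(3)
  lapply(c(90, -30, -150) * pi / 180, function(a) {
    c(20 + r * cos(a), 20 + r * sin(a), 5)
  })
}

test_that("blade distance, angle and height on constructed geometry", {
  ctr <- c(20, 20, 5)
  thu1 <- list(c(32, 20, 1), c(20, 32, 5), c(8, 20, 5))
  thu6 <- list(c(26, 20, 5), c(20, 26, 5), c(14, 20, 5))
  thu9 <- list(c(22, 20, 5), c(20, 22, 5), c(18, 20, 5))
  # chain A: right angle at THU6 in xy (arm THU1 straight out, then bend)
  thu1[[1]] <- c(26, 26, 5)
  pore <- list(ctr, ctr, ctr)
  tr <- toy_trajectory(blade_coords(thu1, thu6, thu9, equilateral_l71(3), pore),
                       box = c(40, 40, 40), topology = blade_topology())
  d <- blade_distance(tr)
  expect_equal(unname(d[1, "B"]), 12)   # (20,32,5) vs pore (20,20,5)
  a <- blade_angle(tr)
  expect_equal(unname(a[1, "A"]), 90)   # arms (0,6) and (-4,0) in xy
  expect_equal(unname(a[1, "B"]), 180)  # collinear through THU6
  h <- blade_height(tr)
  expect_equal(unname(h[1, "B"]), 0)
  thu1[[3]] <- c(8, 20, 1)      # 4 nm below the pore plane
  tr2 <- toy_trajectory(blade_coords(thu1, thu6, thu9, equilateral_l71(3), pore),
                        box = c(40, 40, 40), topology = blade_topology())
  expect_equal(unname(blade_height(tr2)[1, "C"]), 4)
})

test_that("a purely vertical arm is flagged as a degenerate projection", {
  thu6 <- list(c(26, 20, 5), c(20, 26, 5), c(14, 20, 5))
  thu1 <- list(c(26, 20, 9), c(20, 32, 5), c(8, 20, 5))  # chain A arm in +z only
  thu9 <- list(c(22, 20, 5), c(20, 22, 5), c(18, 20, 5))
  pore <- list(c(20, 20, 5), c(20, 20, 5), c(20, 20, 5))
  tr <- toy_trajectory(blade_coords(thu1, thu6, thu9, equilateral_l71(3), pore),
                       box = c(40, 40, 40), topology = blade_topology())
  expect_warning(a <- blade_angle(tr), "degenerate")
  expect_true(is.na(a[1, "A"]))
  expect_false(is.na(a[1, "B"]))
})

test_that("blade angle is invariant under global rotation and translation", {
  sim <- small_sim()
  tr <- sim$trajectory
  sub <- subset_frames(tr, 1:5)
  a0 <- blade_angle(sub)
  R <- rot_z(37)
  moved <- sub
  moved$frames <- lapply(sub$frames, function(f) {
    f$coords <- f$coords %*% t(R)
    f$coords <- sweep(f$coords, 2, c(3, -1, 2), "+")
    f$box <- f$box * 5   # avoid wrap effects after rotation
    f
  })
  expect_equal(blade_angle(moved), a0, tolerance = 1e-9)
})

test_that("blade metrics recover the generator OU means within 3 se", {
  # equal bound/unbound means isolate the OU recovery question
  p <- channel_sim_params(n_frames = 2000, mu_d_bound = 13, mu_d_unbound = 13,
                          mu_theta_bound = 105, mu_theta_unbound = 105)
  sim <- simulate_channel(p, membrane_spec(n_lipids = 60), seed = 17)
  bd <- blade_distance(sim$trajectory)
  ba <- blade_angle(sim$trajectory)
  # var of an OU mean over T frames ~ 2 sigma^2 tau / T
  se_d <- sqrt(2 * p$sigma_d^2 * p$tau_d / (p$n_frames * 3))
  se_th <- sqrt(2 * p$sigma_theta^2 * p$tau_theta / (p$n_frames * 3))
  expect_lt(abs(mean(bd) - 13), 3 * se_d)
  expect_lt(abs(mean(ba) - 105), 3 * se_th)
  expect_equal(dim(bd), c(2000L, 3L))
  # blade height matches the analytic dome height at the blade position
  bh <- blade_height(sim$trajectory)
  expect_equal(bh, sim$ground_truth$blade_height, tolerance = 0.05,
               ignore_attr = TRUE)
})

test_that("conformation histograms integrate to 1 and obey total probability", {
  sim <- small_sim()
  tr <- sim$trajectory
  d <- blade_distance(tr); a <- blade_angle(tr)
  hs <- classify_handshakes(tip_distance_series(tr))
  dr <- c(5, 25); thr <- c(60, 180)
  freq <- handshake_frequencies(hs)
  hall <- conformation_histogram(d, a, hs$count, k = NULL,
                                 d_range = dr, theta_range = thr)
  expect_equal(sum(hall$density) * hall$bin_d * hall$bin_theta, 1,
               tolerance = 1e-12)
  mix <- 0
  for (k in 0:3) {
    if (freq[[k + 1]] == 0) next
    hk <- conformation_histogram(d, a, hs$count, k = k,
                                 d_range = dr, theta_range = thr)
    expect_equal(sum(hk$density) * hk$bin_d * hk$bin_theta, 1,
                 tolerance = 1e-12)
    mix <- mix + freq[[k + 1]] * hk$density
  }
  # law of total probability: the frequency-weighted mixture of the
  # conditional histograms is the unconditional histogram (exact)
  expect_equal(mix, hall$density, tolerance = 1e-9)
  # all mass in one bin
  h1 <- conformation_histogram(rep(12.1, 10), rep(100.5, 10), rep(3L, 10),
                               k = 3)
  expect_equal(max(h1$density), 1 / (0.25 * 2))
  expect_warning(conformation_histogram(12, 100, 3L, k = 0), "empty")
})

test_that("bound conformations concentrate at smaller distance and angle", {
  # slow kinetics and fast blade relaxation, so blades track the state
  p <- channel_sim_params(n_frames = 2500, k_on = 0.01, k_off0 = 0.01,
                          beta = 0, tau_d = 10, tau_theta = 10)
  sim <- simulate_channel(p, membrane_spec(n_lipids = 60), seed = 23)
  tr <- sim$trajectory
  hs <- classify_handshakes(tip_distance_series(tr))
  d <- blade_distance(tr); a <- blade_angle(tr)
  expect_gte(sum(hs$count == 3), 50)
  expect_gte(sum(hs$count == 0), 50)
  mode_of <- function(k) {
    h <- conformation_histogram(d, a, hs$count, k = k, d_range = c(5, 25),
                                theta_range = c(60, 180))
    ij <- which(h$density == max(h$density), arr.ind = TRUE)[1, ]
    c(h$d_breaks[ij[1]], h$theta_breaks[ij[2]])
  }
  m3 <- mode_of(3); m0 <- mode_of(0)
  expect_lt(m3[1], m0[1])
  expect_lt(m3[2], m0[2])
})

test_that("compact/extended classification uses the 13 nm / 100 degree rules", {
  expect_equal(classify_conformation(12.0, 95), "compact")
  expect_equal(classify_conformation(14.0, 95), "extended")
  expect_equal(classify_conformation(12.5, 110), "intermediate")
  expect_equal(classify_conformation(13.0, 90), "intermediate")
  expect_error(classify_conformation(NA, 90), "finite")
})

test_that("projected area follows r_b = mean side / sqrt(3)", {
  pore <- list(c(20, 20, 5), c(20, 20, 5), c(20, 20, 5))
  thu6 <- list(c(26, 20, 5), c(20, 26, 5), c(14, 20, 5))
  thu1 <- list(c(32, 20, 5), c(20, 32, 5), c(8, 20, 5))
  thu9 <- list(c(22, 20, 5), c(20, 22, 5), c(18, 20, 5))
  tr <- toy_trajectory(blade_coords(thu1, thu6, thu9, equilateral_l71(3), pore),
                       box = c(40, 40, 40), topology = blade_topology())
  pa <- projected_area(tr)
  expect_equal(pa$d_mean, 3, tolerance = 1e-9)
  expect_equal(pa$r_b, 1.7321, tolerance = 1e-4)
  expect_equal(pa$area, 9.4248, tolerance = 1e-4)
  expect_equal(pa$area, pi * pa$r_b^2, tolerance = 1e-12)
  # isosceles 3, 3, 4
  l71 <- list(c(0, 0, 5), c(4, 0, 5), c(2, sqrt(5), 5))
  l71 <- lapply(l71, function(x) x + c(18, 18, 0))
  tr2 <- toy_trajectory(blade_coords(thu1, thu6, thu9, l71, pore),
                        box = c(40, 40, 40), topology = blade_topology())
  pa2 <- projected_area(tr2)
  expect_equal(pa2$d_mean, 10 / 3, tolerance = 1e-9)
  expect_equal(pa2$r_b, 1.9245, tolerance = 1e-4)
  # coincident markers
  l0 <- list(c(20, 20, 5), c(20, 20, 5), c(20, 20, 5))
  tr3 <- toy_trajectory(blade_coords(thu1, thu6, thu9, l0, pore),
                        box = c(40, 40, 40), topology = blade_topology())
  expect_equal(projected_area(tr3)$area, 0)
})
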