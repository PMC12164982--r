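# Synthetic trimeric-channel generator.
#
# Emits coarse-grained-like trajectories with known ground truth: three
# blades of nine THU marker beads whose tip-to-pore distance and vertex
# angle follow Ornstein-Uhlenbeck processes, SH/LH handshake helices whose
# tip separation switches between a bound state (~1 nm) and an unbound OU
# state (~4 nm) under a two-state Markov chain with PIP2-dependent release
# rate, PIP2 walkers that anchor near the helix tips, phosphate headgroups
# sampling a trilobate membrane dome, and pore marker triangles with
# prescribed side series.

#' Synthetic channel simulation parameters
#'
#' Defaults define the package's reference study conditions: 3000 frames at
#' 1 ns/frame, blades relaxing between compact (bound) and extended
#' (unbound) means, handshake release rate suppressed by the local PIP2
#' pool (`k_off(n) = k_off0 * exp(-beta * n)`), and a 5-nm-deep trilobate
#' membrane dome.
#'
#' @param n_frames number of frames.
#' @param dt ns per frame.
#' @param mu_d_bound,mu_d_unbound blade tip-to-pore distance means (nm) when
#'   both / neither of a chain's handshakes are formed (interpolated for
#'   one of two).
#' @param tau_d,sigma_d blade-distance OU relaxation (frames) and sd (nm).
#' @param mu_theta_bound,mu_theta_unbound blade vertex-angle means (deg).
#' @param tau_theta,sigma_theta blade-angle OU parameters.
#' @param k_on handshake formation rate (1/ns).
#' @param k_off0 base release rate (1/ns) at zero PIP2 pool.
#' @param beta pool coupling (per PIP2 molecule) in the release rate.
#' @param bound_mean,bound_jitter tip distance in the bound state (nm).
#' @param unbound_mean,unbound_tau,unbound_sigma tip-distance OU in the
#'   unbound state.
#' @param release_jump tip distance (nm) immediately after a release event:
#'   the tips separate fast once the anionic screen is lost.
#' @param k_anchor_bound,k_anchor_unbound per-walker PIP2 anchoring rates
#'   (1/ns) while the pair is bound / unbound.
#' @param k_release per-walker PIP2 de-anchoring rate (1/ns).
#' @param dome_depth,dome_sigma,dome_trilobate membrane dome depth D (nm),
#'   width sigma (nm) and three-fold amplitude a in
#'   `h = -D exp(-r^2/(2 sigma^2)) (1 + a cos 3 theta)`.
#' @param pore_side_mean named means of the pore triangle side (nm) at the
#'   top/middle/bottom marker levels.
#' @param pore_side_sd,pore_side_tau OU parameters of the side series.
#' @param lipid_step_sd 2D diffusion step sd per frame (nm) for bulk lipids.
#' @return A `channel_sim_params` list.
#' @export
channel_sim_params <- function(n_frames = 3000L, dt = 1,
                               mu_d_bound = 12, mu_d_unbound = 15,
                               tau_d = 50, sigma_d = 0.8,
                               mu_theta_bound = 95, mu_theta_unbound = 115,
                               tau_theta = 50, sigma_theta = 5,
                               k_on = 0.05, k_off0 = 0.5, beta = 1.0,
                               bound_mean = 1.0, bound_jitter = 0.1,
                               unbound_mean = 4.0, unbound_tau = 20,
                               unbound_sigma = 0.8, release_jump = 2.2,
                               k_anchor_bound = 0.08,
                               k_anchor_unbound = 0.02,
                               k_release = 0.03,
                               dome_depth = 5, dome_sigma = 7,
                               dome_trilobate = 0.2,
                               pore_side_mean = c(top = 2.2, middle = 1.6,
                                                  bottom = 1.9),
                               pore_side_sd = 0.05, pore_side_tau = 20,
                               lipid_step_sd = 0.1) {
  p <- as.list(environment())
  for (nm in c("dt", "tau_d", "sigma_d", "tau_theta", "sigma_theta",
               "bound_jitter", "unbound_tau", "unbound_sigma",
               "k_release", "pore_side_tau")) {
    stopifnot_scalar_num(p[[nm]], nm, positive = TRUE)
  }
  for (nm in c("k_on", "k_off0", "beta", "k_anchor_bound",
               "k_anchor_unbound", "dome_depth", "dome_sigma",
               "dome_trilobate", "lipid_step_sd")) {
    if (p[[nm]] < 0) abort_config(sprintf("`%s` must be >= 0", nm))
  }
  if (p$n_frames < 1) abort_config("n_frames must be >= 1")
  # discretisation guard: per-step switching probability must stay moderate
  pmax_step <- 1 - exp(-max(p$k_on, p$k_off0) * p$dt)
  if (pmax_step > 0.5) {
    abort_config(sprintf(
      "dt too large: per-step transition probability %.2f > 0.5", pmax_step))
  }
  class(p) <- "channel_sim_params"
  p
}

#' Membrane dome height surface
#'
#' `h(x, y) = -D exp(-r^2 / (2 sigma^2)) (1 + a cos(3 theta))` relative to
#' the flat leaflet baseline, with `(r, theta)` polar coordinates about
#' `center`.
#'
#' @param x,y coordinates (nm), vectorised.
#' @param depth dome depth D (nm).
#' @param sigma dome width (nm).
#' @param trilobate three-fold amplitude a.
#' @param center length-2 dome centre.
#' @return Height offsets (nm, <= 0 for a dome).
#' @export
dome_height <- function(x, y, depth, sigma, trilobate = 0, center = c(0, 0)) {
  dx <- x - center[1]; dy <- y - center[2]
  r2 <- dx^2 + dy^2
  th <- atan2(dy, dx)
  -depth * exp(-r2 / (2 * sigma^2)) * (1 + trilobate * cos(3 * th))
}

#' Two-state handshake kinetics with a latent PIP2 pool
#'
#' Simulates one handshake pair: a continuous-time two-state Markov chain
#' (bound/unbound) discretised exactly per frame, with release rate
#' `k_off(n) = k_off0 * exp(-beta * n)` where `n` is the instantaneous
#' anchored-PIP2 pool. The pool is a birth-death chain over `n_pip2` walkers
#' whose anchoring rate depends on the binding state. Tip distance is
#' `bound_mean + jitter` while bound and an OU process around
#' `unbound_mean` while unbound.
#'
#' @param params a [channel_sim_params()].
#' @param n_pip2 number of PIP2 walkers available to this pair.
#' @param seed optional seed (`NULL`: current RNG stream).
#' @param init_bound initial binding state.
#' @param init_pool initial anchored count (default: `n_pip2` if starting
#'   bound, 0 otherwise).
#' @return data.frame with columns `frame`, `bound`, `distance`, `pool`.
#' @export
simulate_pair_dynamics <- function(params = channel_sim_params(),
                                   n_pip2 = 5L, seed = NULL,
                                   init_bound = TRUE, init_pool = NULL) {
  p <- params
  n <- p$n_frames
  with_seed(seed, {
    bound <- logical(n); pool <- integer(n); d <- numeric(n)
    b <- init_bound
    np <- if (is.null(init_pool)) (if (init_bound) n_pip2 else 0L)
          else as.integer(init_pool)
    p_anchor_b <- 1 - exp(-p$k_anchor_bound * p$dt)
    p_anchor_u <- 1 - exp(-p$k_anchor_unbound * p$dt)
    p_release  <- 1 - exp(-p$k_release * p$dt)
    dcur <- if (b) p$bound_mean else p$unbound_mean
    for (t in seq_len(n)) {
      # pool birth-death
      pa <- if (b) p_anchor_b else p_anchor_u
      births <- if (n_pip2 - np > 0) stats::rbinom(1, n_pip2 - np, pa) else 0L
      deaths <- if (np > 0) stats::rbinom(1, np, p_release) else 0L
      np <- np + births - deaths
      # binding state: exact two-state discretisation at the frozen rates
      koff <- p$k_off0 * exp(-p$beta * np)
      rate <- p$k_on + koff
      if (rate > 0) {
        pi_b <- p$k_on / rate
        p_next_bound <- pi_b + ((b * 1) - pi_b) * exp(-rate * p$dt)
        b_new <- stats::runif(1) < p_next_bound
      } else {
        b_new <- b
      }
      # tip distance; release separates the tips quickly (loss of the PIP2
      # screen leaves like charges face to face), so the series leaves the
      # bound band on the release frame
      if (b_new) {
        dcur <- p$bound_mean + stats::rnorm(1, 0, p$bound_jitter)
      } else {
        if (b) dcur <- max(p$release_jump, dcur)
        dcur <- ou_step(dcur, p$unbound_mean, p$unbound_tau,
                        p$unbound_sigma, p$dt, stats::rnorm(1))
      }
      b <- b_new
      bound[t] <- b; pool[t] <- np; d[t] <- dcur
    }
    data.frame(frame = seq_len(n), bound = bound, distance = d, pool = pool)
  })
}

# solve the planar THU1 radius r so that the 3D tip-to-pore distance equals
# d3 when THU1 sits on the dome surface; returns list(xy, z) for THU1 and
# the solved planar construction.
solve_blade_xy <- function(d3, theta_deg, u, c0, cz, dome, h0) {
  th <- theta_deg * pi / 180
  # arm direction: -u rotated by +theta about z
  w <- c(cos(th) * (-u[1]) - sin(th) * (-u[2]),
         sin(th) * (-u[1]) + cos(th) * (-u[2]))
  r <- d3
  thu1 <- c0
  z1 <- cz
  for (iter in 1:60) {
    disc <- r^2 - 64 * sin(th)^2
    if (disc < 0) disc <- 0
    L1 <- 8 * cos(th) + sqrt(disc)
    if (L1 < 0.1) L1 <- 0.1
    thu1 <- c0 + 8 * u + L1 * w
    z1 <- cz + dome_height(thu1[1], thu1[2], dome$depth, dome$sigma,
                           dome$trilobate, center = c0)
    dz <- z1 - (cz + h0)
    r_new <- sqrt(max(d3^2 - dz^2, 1))
    if (abs(r_new - r) < 1e-10) { r <- r_new; break }
    r <- r_new
  }
  # final pass with converged r
  disc <- max(r^2 - 64 * sin(th)^2, 0)
  L1 <- max(8 * cos(th) + sqrt(disc), 0.1)
  thu1 <- c0 + 8 * u + L1 * w
  z1 <- cz + dome_height(thu1[1], thu1[2], dome$depth, dome$sigma,
                         dome$trilobate, center = c0)
  list(thu1 = thu1, z1 = z1, L1 = L1, w = w)
}

#' Simulate a trimeric channel plus lipid trajectory with ground truth
#'
#' Builds a full synthetic trajectory: per-chain THU1-THU9 blade markers,
#' SH (residues 176-203) and LH (1912-1951) handshake helices with tip
#' separations driven by [simulate_pair_dynamics()], L71 area markers,
#' inner-pore residues 2433-2462 with triangle marker levels, PIP2 walkers
#' anchored near the SH while their pair is bound, and bulk lipid
#' headgroups diffusing on the dome-shaped leaflets.
#'
#' @param params a [channel_sim_params()].
#' @param membrane a [membrane_spec()] giving lipid counts and the box.
#' @param seed integer seed; the same seed reproduces the trajectory and
#'   ground truth bit-identically.
#' @return list with `trajectory` (a `trajectory`) and `ground_truth`
#'   (class `ground_truth`: per-frame per-pair `bound`, `tip_distance`,
#'   `pool`; per-frame per-chain `blade_distance`, `blade_angle`,
#'   `blade_height`; `pore_sides`; dome parameters; and
#'   `state_rule_mismatch`, the fraction of frames whose emitted tip
#'   distance disagrees with the 1.5-nm rule).
#' @export
simulate_channel <- function(params = channel_sim_params(),
                             membrane = membrane_spec(), seed = 1L) {
  p <- params
  n <- p$n_frames
  box <- c(membrane$box_xy, 24)
  c0 <- membrane$box_xy / 2
  cz <- box[3] / 2
  chains <- c("A", "B", "C")
  phi <- c(90, -30, -150) * pi / 180   # clockwise from +z: decreasing angle
  dome <- list(depth = p$dome_depth, sigma = p$dome_sigma,
               trilobate = p$dome_trilobate)
  h0 <- dome_height(c0[1], c0[2], dome$depth, dome$sigma, dome$trilobate,
                    center = c0)
  counts <- membrane_counts(membrane)
  n_pip2 <- as.integer(counts$lower["PIP2"])
  if (is.na(n_pip2)) n_pip2 <- 0L
  n_pp <- n_pip2 %/% 3L
  n_pip2_bulk_only <- n_pip2 - 3L * n_pp

  with_seed(seed, {
    # --- per-pair handshake kinetics (pair j: SH of chain j, LH of succ(j))
    pairs <- lapply(1:3, function(j) {
      simulate_pair_dynamics(p, n_pip2 = n_pp, init_bound = TRUE)
    })
    bound <- matrix(sapply(pairs, `[[`, "bound"), n, 3)
    tipd  <- matrix(sapply(pairs, `[[`, "distance"), n, 3)
    pool  <- matrix(sapply(pairs, `[[`, "pool"), n, 3)

    # --- blade OU with binding-dependent means
    # chain c participates in pair c (SH) and pair pred(c) (LH)
    pred <- c(3L, 1L, 2L)
    nb_chain <- bound + bound[, pred, drop = FALSE]  # 0,1,2 per chain
    blade_d <- matrix(0, n, 3); blade_th <- matrix(0, n, 3)
    for (cix in 1:3) {
      mu_d  <- p$mu_d_unbound +
        (p$mu_d_bound - p$mu_d_unbound) * nb_chain[, cix] / 2
      mu_th <- p$mu_theta_unbound +
        (p$mu_theta_bound - p$mu_theta_unbound) * nb_chain[, cix] / 2
      blade_d[, cix]  <- ou_series(n, mu_d, p$tau_d, p$sigma_d, p$dt)
      blade_th[, cix] <- ou_series(n, mu_th, p$tau_theta, p$sigma_theta, p$dt)
    }

    # --- pore triangle side series per level
    levels <- c("top", "middle", "bottom")
    sides <- matrix(sapply(levels, function(l) {
      ou_series(n, p$pore_side_mean[[l]], p$pore_side_tau, p$pore_side_sd, p$dt)
    }), n, 3, dimnames = list(NULL, levels))

    # --- topology ------------------------------------------------------
    prot_rows <- do.call(rbind, lapply(chains, function(ch) {
      rbind(
        data.frame(chain = ch, resnum = 1:9, resname = paste0("THU", 1:9),
                   beadname = "BB", stringsAsFactors = FALSE),
        data.frame(chain = ch, resnum = 176:203, resname = "SH",
                   beadname = "BB", stringsAsFactors = FALSE),
        data.frame(chain = ch, resnum = 1912:1951, resname = "LH",
                   beadname = "BB", stringsAsFactors = FALSE),
        data.frame(chain = ch, resnum = 71L, resname = "LEU",
                   beadname = "CA", stringsAsFactors = FALSE),
        data.frame(chain = ch, resnum = 2433:2462,
                   resname = ifelse(2433:2462 == 2444, "TYR",
                             ifelse(2433:2462 == 2450, "VAL",
                             ifelse(2433:2462 == 2449, "LEU",
                             ifelse(2433:2462 == 2454, "PHE", "POR")))),
                   beadname = "BB", stringsAsFactors = FALSE)
      )
    }))
    prot_rows$species <- "protein"
    prot_rows$leaflet <- "none"
    n_prot <- nrow(prot_rows)

    # lipids: PIP2 walkers first (lower leaflet), then bulk species
    lip_species <- character(0)
    lip_leaflet <- character(0)
    if (n_pip2 > 0) {
      lip_species <- c(lip_species, rep("PIP2", n_pip2))
      lip_leaflet <- c(lip_leaflet, rep("lower", n_pip2))
    }
    for (leaf in c("lower", "upper")) {
      cc <- counts[[leaf]]
      cc <- cc[setdiff(names(cc), "PIP2")]
      lip_species <- c(lip_species, rep(names(cc), cc))
      lip_leaflet <- c(lip_leaflet, rep(leaf, sum(cc)))
    }
    n_lip <- length(lip_species)
    lip_rows <- data.frame(
      chain = NA_character_, resnum = seq_len(n_lip) + 3000L,
      resname = lip_species, beadname = headgroup_beadname(lip_species),
      species = lip_species, leaflet = lip_leaflet, stringsAsFactors = FALSE)
    topology <- channel_topology(rbind(prot_rows, lip_rows))

    # --- static per-chain landmarks -----------------------------------
    u <- cbind(cos(phi), sin(phi))
    site_phi <- phi - 60 * pi / 180
    r_hs <- 11
    site_xy <- cbind(c0[1] + r_hs * cos(site_phi),
                     c0[2] + r_hs * sin(site_phi))
    site_z <- cz + dome_height(site_xy[, 1], site_xy[, 2], dome$depth,
                               dome$sigma, dome$trilobate, center = c0)
    thu6_xy <- cbind(c0[1] + 8 * u[, 1], c0[2] + 8 * u[, 2])
    # helix lay directions (unit, in-plane)
    lay_dir <- function(from, to) {
      v <- to - from
      v / sqrt(sum(v^2))
    }

    # --- bulk lipid diffusion (vectorised over frames) ----------------
    leaflet_z_off <- c(lower = -2, upper = 2)
    if (n_lip - n_pip2 > 0) {
      nb <- n_lip - n_pip2
      x0 <- stats::runif(nb, 0, box[1])
      y0 <- stats::runif(nb, 0, box[2])
      stepx <- matrix(stats::rnorm(n * nb, 0, p$lipid_step_sd), n, nb)
      stepy <- matrix(stats::rnorm(n * nb, 0, p$lipid_step_sd), n, nb)
      stepx[1, ] <- 0; stepy[1, ] <- 0
      bulk_x <- (sweep(apply(stepx, 2, cumsum), 2, x0, "+")) %% box[1]
      bulk_y <- (sweep(apply(stepy, 2, cumsum), 2, y0, "+")) %% box[2]
      if (n == 1) { bulk_x <- matrix(bulk_x, 1); bulk_y <- matrix(bulk_y, 1) }
    } else {
      bulk_x <- bulk_y <- matrix(0, n, 0)
    }
    bulk_leaf <- lip_leaflet[seq.int(n_pip2 + 1, length.out = n_lip - n_pip2)]

    # --- PIP2 walker placements ---------------------------------------
    # anchored: within 1.5 nm of the SH tip of the owning pair; bulk: far
    # annulus (> 2.5 nm from every SH bead), so the measured pool equals
    # the latent pool exactly.
    pip2_owner <- if (n_pip2 > 0) {
      c(rep(1:3, each = n_pp), rep(0L, n_pip2_bulk_only))
    } else integer(0)

    # --- assemble frames ----------------------------------------------
    blade_height_gt <- matrix(0, n, 3)
    frames <- vector("list", n)
    sh_res <- 176:203; lh_res <- 1912:1951
    pore_res <- 2433:2462
    marker_res <- c(top = 2444L, middle = 2450L, bottom = 2454L)
    # pore COG z offset: marker beads replace helix beads at fixed z levels
    helix_z <- seq(1, -1, length.out = length(pore_res))
    repl <- match(c(marker_res, 2449L), pore_res)
    h0ref <- h0 + (sum(c(1, 0, -1, 0)) - sum(helix_z[repl])) / length(pore_res)
    for (t in seq_len(n)) {
      coords <- matrix(0, n_prot + n_lip, 3)
      off <- 0L
      thu1_store <- matrix(0, 3, 3)
      for (cix in 1:3) {
        sol <- solve_blade_xy(blade_d[t, cix], blade_th[t, cix], u[cix, ],
                              c0, cz, dome, h0ref)
        thu1 <- sol$thu1
        thu9 <- c0 + 3 * u[cix, ]
        thu6 <- c0 + 8 * u[cix, ]
        # THU2..5 along THU6 -> THU1; THU7,8 along THU6 -> THU9
        fr15 <- (6 - (2:5)) / 5          # fractions for THU2..THU5
        thu_xy <- rbind(
          thu1,
          t(sapply(fr15, function(f) thu6 + f * (thu1 - thu6))),
          thu6,
          thu6 + (1 / 3) * (thu9 - thu6),
          thu6 + (2 / 3) * (thu9 - thu6),
          thu9)
        thu_z <- cz + dome_height(thu_xy[, 1], thu_xy[, 2], dome$depth,
                                  dome$sigma, dome$trilobate, center = c0)
        thu1_store[cix, ] <- c(thu_xy[1, ], thu_z[1])
        blade_height_gt[t, cix] <- abs(thu_z[1] - (cz + h0ref))
        coords[off + 1:9, ] <- cbind(thu_xy, thu_z)
        off <- off + 9L
        # SH of chain cix lives at site cix, laid toward its own THU6
        e_sh <- lay_dir(site_xy[cix, ], thu6_xy[cix, ])
        d_hs <- tipd[t, cix]
        sh_xy <- cbind(site_xy[cix, 1] + (d_hs + 0.1 * (seq_along(sh_res) - 1)) * e_sh[1],
                       site_xy[cix, 2] + (d_hs + 0.1 * (seq_along(sh_res) - 1)) * e_sh[2])
        coords[off + seq_along(sh_res), ] <-
          cbind(sh_xy, rep(site_z[cix], length(sh_res)))
        off <- off + length(sh_res)
        # LH of chain cix lives at site pred(cix), tip exactly on the site
        jp <- pred[cix]
        e_lh <- lay_dir(site_xy[jp, ], thu6_xy[cix, ])
        lh_xy <- cbind(site_xy[jp, 1] + 0.1 * (seq_along(lh_res) - 1) * e_lh[1],
                       site_xy[jp, 2] + 0.1 * (seq_along(lh_res) - 1) * e_lh[2])
        coords[off + seq_along(lh_res), ] <-
          cbind(lh_xy, rep(site_z[jp], length(lh_res)))
        off <- off + length(lh_res)
        # L71 just beyond THU1
        l71 <- thu1 + 0.3 * sol$w
        coords[off + 1L, ] <- c(l71, thu1_store[cix, 3])
        off <- off + 1L
        # pore inner helix: vertical line at radius 1, markers on triangles
        pz <- cz + h0 + seq(1, -1, length.out = length(pore_res))
        px <- c0[1] + 1.0 * u[cix, 1] + numeric(length(pore_res))
        py <- c0[2] + 1.0 * u[cix, 2] + numeric(length(pore_res))
        pc <- cbind(px, py, pz)
        for (lv in seq_along(marker_res)) {
          rr <- sides[t, lv] / sqrt(3)
          zlv <- cz + h0 + c(1, 0, -1)[lv]
          mi <- which(pore_res == marker_res[lv])
          pc[mi, ] <- c(c0 + rr * u[cix, ], zlv)
          if (names(marker_res)[lv] == "middle") {
            # L2449 adjacent to V2450 (tangential 0.15 nm offset)
            tj <- c(-u[cix, 2], u[cix, 1])
            ai <- which(pore_res == 2449L)
            pc[ai, ] <- c(c0 + rr * u[cix, ] + 0.15 * tj, zlv)
          }
        }
        coords[off + seq_along(pore_res), ] <- pc
        off <- off + length(pore_res)
      }
      # PIP2 walkers
      if (n_pip2 > 0) {
        for (j in 1:3) {
          idx <- which(pip2_owner == j)
          if (!length(idx)) next
          npj <- pool[t, j]
          e_sh <- lay_dir(site_xy[j, ], thu6_xy[j, ])
          tip <- site_xy[j, ] + tipd[t, j] * e_sh
          for (m in seq_along(idx)) {
            row <- n_prot + idx[m]
            if (m <= npj) {
              rad <- stats::runif(1, 0.3, 1.4)
              ang <- stats::runif(1, 0, 2 * pi)
              coords[row, ] <- c(tip[1] + rad * cos(ang),
                                 tip[2] + rad * sin(ang), site_z[j])
            } else {
              rad <- stats::runif(1, r_hs + 7, min(box[1:2]) / 2 - 2)
              ang <- stats::runif(1, 0, 2 * pi)
              xx <- (c0[1] + rad * cos(ang)) %% box[1]
              yy <- (c0[2] + rad * sin(ang)) %% box[2]
              zz <- cz + leaflet_z_off["lower"] +
                dome_height(xx, yy, dome$depth, dome$sigma,
                            dome$trilobate, center = c0)
              coords[row, ] <- c(xx, yy, zz)
            }
          }
        }
        bulk_only <- which(pip2_owner == 0L)
        for (m in bulk_only) {
          rad <- stats::runif(1, r_hs + 7, min(box[1:2]) / 2 - 2)
          ang <- stats::runif(1, 0, 2 * pi)
          xx <- (c0[1] + rad * cos(ang)) %% box[1]
          yy <- (c0[2] + rad * sin(ang)) %% box[2]
          coords[n_prot + m, ] <- c(xx, yy, cz + leaflet_z_off["lower"] +
            dome_height(xx, yy, dome$depth, dome$sigma, dome$trilobate,
                        center = c0))
        }
      }
      # bulk lipids ride the dome surface of their leaflet
      if (ncol(bulk_x) > 0) {
        zz <- cz + leaflet_z_off[bulk_leaf] +
          dome_height(bulk_x[t, ], bulk_y[t, ], dome$depth, dome$sigma,
                      dome$trilobate, center = c0)
        coords[n_prot + n_pip2 + seq_len(ncol(bulk_x)), ] <-
          cbind(bulk_x[t, ], bulk_y[t, ], zz)
      }
      frames[[t]] <- new_frame(coords, box, time = (t - 1) * p$dt * 1000)
    }

    mismatch <- mean((tipd <= 1.5) != bound)
    gt <- structure(list(
      bound = bound, tip_distance = tipd, pool = pool,
      blade_distance = blade_d, blade_angle = blade_th,
      blade_height = blade_height_gt,
      pore_sides = sides, dome = dome,
      state_rule_mismatch = mismatch, params = p), class = "ground_truth")
    list(trajectory = new_trajectory(topology, frames,
                                     source_label = sprintf("synthetic-%d", seed)),
         ground_truth = gt)
  })
}

#' Synthetic handshake-mode series with known labels
#'
#' Generates distance + PIP2-pool series typical of the three handshake
#' modes, for validating mode segmentation: `"stable"` (one long bound
#' dwell), `"release"` (a long bound dwell, a pool collapse, then a
#' terminal unbound run), and `"unstable"` (rapid bound/unbound
#' alternation at a modest pool).
#'
#' @param mode one of `"stable"`, `"release"`, `"unstable"`.
#' @param n_frames series length (defaults sized so dwell scales are at
#'   least five times the segmentation thresholds).
#' @param seed optional seed.
#' @param bound_frames bound dwell length for `"release"`.
#' @param dwell mean dwell (frames) for `"unstable"` alternation.
#' @return list with numeric `distance`, `pool` and character `label`
#'   (per-frame ground-truth mode).
#' @export
simulate_mode_series <- function(mode = c("stable", "release", "unstable"),
                                 n_frames = NULL, seed = NULL,
                                 bound_frames = 1000L, dwell = 50L) {
  mode <- match.arg(mode)
  if (is.null(n_frames)) {
    n_frames <- switch(mode, stable = 1500L, release = 3500L,
                       unstable = 2000L)
  }
  with_seed(seed, {
    n <- n_frames
    if (mode == "stable") {
      d <- 1 + stats::rnorm(n, 0, 0.1)
      pool <- pmax(0, round(6 + ou_series(n, 0, 100, 1.2)))
      label <- rep("stable", n)
    } else if (mode == "release") {
      nb <- min(bound_frames, n - 1L)
      d <- c(1 + stats::rnorm(nb, 0, 0.1),
             ou_series(n - nb, 4.5, 30, 0.4, x0 = 2.5))
      d[(nb + 1):n] <- pmax(d[(nb + 1):n], 2.2)   # never re-enter bound band
      decay_start <- max(1L, nb - 200L)
      pool <- c(rep(6, decay_start - 1),
                round(seq(6, 0, length.out = nb - decay_start + 1)),
                rep(0, n - nb)) + pmax(0, round(stats::rnorm(n, 0, 0.3)))
      label <- c(rep("stable", nb), rep("release", n - nb))
    } else {
      d <- numeric(0); label <- character(0)
      b <- TRUE
      while (length(d) < n) {
        len <- 1L + stats::rgeom(1, 1 / dwell)
        seg <- if (b) 1 + stats::rnorm(len, 0, 0.1)
               else 3.5 + stats::rnorm(len, 0, 0.3)
        d <- c(d, seg)
        label <- c(label, rep("unstable", len))
        b <- !b
      }
      d <- d[seq_len(n)]; label <- label[seq_len(n)]
      pool <- pmax(0, round(2 + ou_series(n, 0, 50, 0.8)))
    }
    list(distance = d, pool = as.numeric(pool[seq_len(n)]), label = label)
  })
}

#' Simulate an outside-out patch pressure-response table
#'
#' Forward Boltzmann model with additive Gaussian noise:
#' `I(p) = Imin + (Imax - Imin) / (1 + exp((p - p50)/dp)) + N(0, noise_sd)`.
#' The default pressure protocol is 0-120 mmHg in 15-mmHg steps.
#'
#' @param Imin,Imax asymptotic currents (pA).
#' @param p50 half-activation pressure (mmHg).
#' @param dp Boltzmann coefficient (mmHg, may be negative).
#' @param pressures pressure protocol (mmHg).
#' @param noise_sd additive noise sd.
#' @param n_replicates rows per pressure.
#' @param seed optional seed.
#' @return data.frame with `pressure_mmHg`, `replicate`, `response`.
#' @export
simulate_pressure_response <- function(Imin = 0, Imax = -500, p50 = 60,
                                       dp = -10,
                                       pressures = seq(0, 120, by = 15),
                                       noise_sd = 0, n_replicates = 1L,
                                       seed = NULL) {
  if (dp == 0) abort_config("dp must be non-zero")
  if (!length(pressures)) abort_config("pressures must be non-empty")
  with_seed(seed, {
    grid <- expand.grid(pressure_mmHg = pressures,
                        replicate = seq_len(n_replicates))
    mu <- Imin + (Imax - Imin) / (1 + exp((grid$pressure_mmHg - p50) / dp))
    grid$response <- mu + stats::rnorm(nrow(grid), 0, noise_sd)
    grid[order(grid$replicate, grid$pressure_mmHg), ]
  })
}

#' Simulate an agonist dose-response table
#'
#' Forward Hill model
#' `R(d) = Rmin + (Rmax - Rmin) d^HC / (EC50^HC + d^HC) + N(0, noise_sd)`.
#' The default panel is the seven-point 0.03-30 uM dose ladder.
#'
#' @param Rmin,Rmax response asymptotes.
#' @param EC50 mid-point dose (> 0, uM).
#' @param HC Hill coefficient (> 0).
#' @param doses dose panel (uM, all > 0).
#' @param noise_sd additive noise sd.
#' @param n_replicates rows per dose.
#' @param seed optional seed.
#' @return data.frame with `dose_uM`, `replicate`, `response`.
#' @export
simulate_dose_response <- function(Rmin = 0, Rmax = 1, EC50 = 1, HC = 2,
                                   doses = c(0.03, 0.1, 0.3, 1, 3, 10, 30),
                                   noise_sd = 0, n_replicates = 1L,
                                   seed = NULL) {
  if (EC50 <= 0 || HC <= 0) abort_config("EC50 and HC must be > 0")
  if (!length(doses) || any(doses <= 0)) {
    abort_config("doses must be non-empty and positive")
  }
  with_seed(seed, {
    grid <- expand.grid(dose_uM = doses, replicate = seq_len(n_replicates))
    mu <- Rmin + (Rmax - Rmin) * grid$dose_uM^HC / (EC50^HC + grid$dose_uM^HC)
    grid$response <- mu + stats::rnorm(nrow(grid), 0, noise_sd)
    grid[order(grid$replicate, grid$dose_uM), ]
  })
}
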