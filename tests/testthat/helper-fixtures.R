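# Fixtures and independent oracles used across the suite.

# a bare topology of n unlabelled beads
toy_topology <- function(n, chain = NA_character_, resnum = seq_len(n),
                         resname = "BEA", beadname = "BB",
                         species = "protein", leaflet = "none") {
  channel_topology(data.frame(
    chain = rep_len(chain, n), resnum = rep_len(resnum, n),
    resname = rep_len(resname, n), beadname = rep_len(beadname, n),
    species = rep_len(species, n), leaflet = rep_len(leaflet, n),
    stringsAsFactors = FALSE))
}

toy_trajectory <- function(coords_list, box = c(10, 10, 10),
                           topology = NULL) {
  if (is.matrix(coords_list)) coords_list <- list(coords_list)
  if (is.null(topology)) topology <- toy_topology(nrow(coords_list[[1]]))
  frames <- lapply(seq_along(coords_list), function(i) {
    new_frame(coords_list[[i]], box, time = i - 1)
  })
  new_trajectory(topology, frames)
}

# brute-force minimum-image distance: wrap both points into the primary
# cell, then minimise over all 27 periodic images
brute_min_image <- function(a, b, box) {
  a <- a %% box; b <- b %% box
  shifts <- as.matrix(expand.grid(i = -1:1, j = -1:1, k = -1:1))
  min(apply(shifts, 1, function(s) {
    sqrt(sum((b + s * box - a)^2))
  }))
}

# triangle area from vertex coordinates via the cross product
cross_product_area <- function(A, B, C) {
  u <- B - A; v <- C - A
  cr <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  0.5 * sqrt(sum(cr^2))
}

# rotation matrix about z (degrees)
rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

# a small synthetic run cached per session (600 frames, 200 lipids)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_channel(channel_sim_params(n_frames = 600L),
                                 membrane_spec(n_lipids = 200L), seed = 42L)
    }
    cache
  }
})
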