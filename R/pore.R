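# Pore geometry: marker-residue triangle areas (Heron's formula) and voxel
# degree-of-buriedness cavity volumes.

#' Triangle area by Heron's formula
#'
#' `area = sqrt(s (s-a)(s-b)(s-c))` with `s` the semiperimeter. A slightly
#' negative radicand from rounding (|eps| < 1e-9 relative) is clamped to
#' zero; genuinely degenerate side triples (triangle inequality violated)
#' give area 0.
#'
#' @param a,b,c side lengths (vectorised).
#' @return Areas in the squared unit of the sides.
#' @export
heron_area <- function(a, b, c) {
  s <- (a + b + c) / 2
  rad <- s * (s - a) * (s - b) * (s - c)
  rad[rad < 0] <- 0
  sqrt(rad)
}

#' Pore cross-section triangle at a marker level
#'
#' Side lengths are the pairwise minimum-image distances between the
#' centres of geometry of the level's marker residue on each chain (top
#' Y2444, middle V2450, bottom F2454); the area follows from Heron's
#' formula. Residue overrides support the short-helix-mutant convention of
#' using L2449 in place of V2450 on the rotated chain
#' (`residue_overrides = c(C = 2449)` at the middle level).
#'
#' @param trajectory a `trajectory` (all frames are measured).
#' @param level `"top"`, `"middle"` or `"bottom"`.
#' @param residue_overrides optional named vector mapping chain id to a
#'   replacement marker residue number.
#' @param scheme selection scheme.
#' @return data.frame with per-frame `a`, `b`, `c`, `s`, `area`, `level`.
#' @export
pore_triangle <- function(trajectory, level = c("top", "middle", "bottom"),
                          residue_overrides = NULL,
                          scheme = selection_scheme()) {
  level <- match.arg(level)
  top <- trajectory$topology
  marker <- switch(level, top = scheme$pore_top, middle = scheme$pore_middle,
                   bottom = scheme$pore_bottom)
  chains <- top$chain_order
  res_of <- stats::setNames(rep(marker, 3), chains)
  if (!is.null(residue_overrides)) {
    for (ch in names(residue_overrides)) {
      if (!ch %in% chains) abort_config(sprintf("unknown chain '%s'", ch))
      res_of[ch] <- residue_overrides[[ch]]
    }
  }
  idx <- lapply(chains, function(ch) {
    select_beads(top, chain = ch, resnum = res_of[[ch]])
  })
  n <- n_frames(trajectory)
  sides <- matrix(NA_real_, n, 3)
  for (t in seq_len(n)) {
    f <- trajectory$frames[[t]]
    p <- lapply(idx, function(ix) center_of_geometry(f, ix))
    sides[t, ] <- c(min_image_dist(p[[1]], p[[2]], f$box),
                    min_image_dist(p[[2]], p[[3]], f$box),
                    min_image_dist(p[[3]], p[[1]], f$box))
  }
  data.frame(frame = seq_len(n), level = level,
             a = sides[, 1], b = sides[, 2], c = sides[, 3],
             s = rowSums(sides) / 2,
             area = heron_area(sides[, 1], sides[, 2], sides[, 3]))
}

# cumulative "any occupied before me" along one axis of a 3D logical array,
# in both directions; used for the degree of buriedness.
axis_enclosure <- function(occ, axis) {
  d <- dim(occ)
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  a <- aperm(occ, perm)
  m <- matrix(a, nrow = dim(a)[1])
  n1 <- nrow(m)
  cum_fwd <- matrix(apply(m, 2, cummax), nrow = n1)
  below <- rbind(FALSE, cum_fwd[-n1, , drop = FALSE] > 0)
  cum_bwd <- matrix(apply(m[n1:1, , drop = FALSE], 2, cummax),
                    nrow = n1)[n1:1, , drop = FALSE]
  above <- rbind(cum_bwd[-1, , drop = FALSE] > 0, FALSE)
  inv <- order(perm)
  list(neg = aperm(array(below, dim(a)), inv),
       pos = aperm(array(above, dim(a)), inv))
}

#' Cavity detection on a voxel occupancy grid
#'
#' Given a logical 3D occupancy array, computes each empty voxel's degree
#' of buriedness (the number of the six axis-aligned directions along which
#' a protein-occupied voxel is encountered), keeps empty voxels with degree
#' >= `dim_threshold`, and retains the 6-connected component containing the
#' seed voxel.
#'
#' @param occ logical 3D array (TRUE = protein-occupied).
#' @param spacing voxel edge length in Angstrom.
#' @param dim_threshold minimum degree of buriedness (default 3).
#' @param seed_voxel integer length-3 voxel index; `NULL` snaps the grid
#'   centre to the nearest cavity voxel.
#' @return list with `voxels` (n x 3 indices), `volume_A3`, `volume_nm3`,
#'   `degree` array, `spacing`, `dim_threshold`, `seed_voxel`.
#' @export
cavity_from_occupancy <- function(occ, spacing = 1.4, dim_threshold = 3,
                                  seed_voxel = NULL) {
  if (length(dim(occ)) != 3L) abort("occupancy must be a 3D array")
  stopifnot_scalar_num(spacing, "spacing", positive = TRUE)
  deg <- array(0L, dim(occ))
  for (ax in 1:3) {
    enc <- axis_enclosure(occ, ax)
    deg <- deg + enc$neg + enc$pos
  }
  cavity <- !occ & deg >= dim_threshold
  empty_result <- list(voxels = matrix(integer(0), 0, 3), volume_A3 = 0,
                       volume_nm3 = 0, degree = deg, spacing = spacing,
                       dim_threshold = dim_threshold, seed_voxel = seed_voxel)
  if (!any(cavity)) {
    warning("no cavity voxels at this buriedness threshold")
    return(empty_result)
  }
  cav_idx <- which(cavity, arr.ind = TRUE)
  if (is.null(seed_voxel)) {
    ctr <- (dim(occ) + 1) / 2
    d2 <- rowSums(sweep(cav_idx, 2, ctr)^2)
    seed_voxel <- cav_idx[which.min(d2), ]
  } else {
    seed_voxel <- as.integer(seed_voxel)
    if (!cavity[seed_voxel[1], seed_voxel[2], seed_voxel[3]]) {
      warning("seed voxel is not a cavity voxel: returning an empty cavity")
      return(empty_result)
    }
  }
  # 6-connected flood fill from the seed
  dims <- dim(occ)
  lin <- function(i, j, k) i + dims[1] * ((j - 1) + dims[2] * (k - 1))
  in_comp <- array(FALSE, dims)
  queue <- matrix(seed_voxel, 1, 3)
  in_comp[seed_voxel[1], seed_voxel[2], seed_voxel[3]] <- TRUE
  nbr <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
               c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  while (nrow(queue)) {
    cur <- queue[nrow(queue), ]
    queue <- queue[-nrow(queue), , drop = FALSE]
    for (q in 1:6) {
      nx <- cur + nbr[q, ]
      if (any(nx < 1) || any(nx > dims)) next
      if (cavity[nx[1], nx[2], nx[3]] && !in_comp[nx[1], nx[2], nx[3]]) {
        in_comp[nx[1], nx[2], nx[3]] <- TRUE
        queue <- rbind(queue, nx)
      }
    }
  }
  vox <- which(in_comp, arr.ind = TRUE)
  vol <- nrow(vox) * spacing^3
  list(voxels = vox, volume_A3 = vol, volume_nm3 = vol / 1000,
       degree = deg, spacing = spacing, dim_threshold = dim_threshold,
       seed_voxel = seed_voxel)
}

#' Pore cavity volume by voxel degree of buriedness
#'
#' Voxelises the bounding box of the inner-pore selection (residues
#' 2433-2462 on every chain, plus two voxels of padding), marks a voxel
#' occupied when its centre lies within the van der Waals radius of any
#' selected bead, and measures the buried cavity with
#' [cavity_from_occupancy()].
#'
#' @param frame a `frame`.
#' @param topology the matching `channel_topology`.
#' @param residue_set residues defining the pore (default 2433-2462).
#' @param spacing voxel spacing in Angstrom (default 1.4).
#' @param dim_threshold degree-of-buriedness threshold (default 3).
#' @param vdw_radius bead van der Waals radius in nm (default 0.26, the
#'   regular coarse-grained bead; use 0.23 for small beads or an atomistic
#'   table via a per-bead vector).
#' @param seed_point optional length-3 point (nm) seeding the connected
#'   component; default is the selection's geometric centre.
#' @return A cavity result as from [cavity_from_occupancy()], plus
#'   `origin_nm` and the bead selection used.
#' @export
cavity_volume <- function(frame, topology, residue_set = 2433:2462,
                          spacing = 1.4, dim_threshold = 3,
                          vdw_radius = 0.26, seed_point = NULL) {
  idx <- select_beads(topology, resnum = residue_set)
  P <- frame$coords[idx, , drop = FALSE] * 10      # nm -> Angstrom
  radii <- rep_len(vdw_radius * 10, nrow(P))
  lo <- apply(P, 2, min) - 2 * spacing - max(radii)
  hi <- apply(P, 2, max) + 2 * spacing + max(radii)
  nvox <- pmax(ceiling((hi - lo) / spacing), 1L)
  centers <- lapply(1:3, function(k) lo[k] + (seq_len(nvox[k]) - 0.5) * spacing)
  occ <- array(FALSE, nvox)
  # occupancy: voxel centre within vdW radius of any bead; loop over beads,
  # touching only the local voxel block of each bead
  for (m in seq_len(nrow(P))) {
    rA <- radii[m]
    rng <- lapply(1:3, function(k) {
      which(abs(centers[[k]] - P[m, k]) <= rA)
    })
    if (!all(lengths(rng) > 0)) next
    dx <- centers[[1]][rng[[1]]] - P[m, 1]
    dy <- centers[[2]][rng[[2]]] - P[m, 2]
    dz <- centers[[3]][rng[[3]]] - P[m, 3]
    d2 <- outer(outer(dx^2, dy^2, "+"), dz^2, "+")
    occ[rng[[1]], rng[[2]], rng[[3]]] <-
      occ[rng[[1]], rng[[2]], rng[[3]]] | (d2 <= rA^2)
  }
  seed_voxel <- NULL
  if (!is.null(seed_point)) {
    sp <- seed_point * 10
    seed_voxel <- pmin(pmax(round((sp - lo) / spacing + 0.5), 1), nvox)
  }
  res <- cavity_from_occupancy(occ, spacing = spacing,
                               dim_threshold = dim_threshold,
                               seed_voxel = seed_voxel)
  res$origin_nm <- lo / 10
  res$selection <- idx
  res
}
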