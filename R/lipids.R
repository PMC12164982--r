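# Protein-lipid environment: contact profiles, density maps, PIP2 pools,
# leaflet height maps and dome depth.

headgroup_names <- function() {
  c(POPC = "PO4", POPE = "PO4", POPS = "PO4", DPSM = "PO4",
    CHOL = "ROH", PIP2 = "P1")
}

# per-lipid headgroup bead indices for one species
lipid_headgroups <- function(topology, species, allow_empty = FALSE) {
  bn <- headgroup_names()[[species]]
  idx <- select_beads(topology, species = species, beadname = bn,
                      allow_empty = TRUE)
  if (!length(idx)) {
    idx <- select_beads(topology, species = species, allow_empty = TRUE)
  }
  if (!length(idx) && !allow_empty) {
    abort(sprintf("species '%s' not present in topology", species))
  }
  split(idx, topology$beads$resnum[idx])
}

as_trajectory_list <- function(trajectories) {
  if (inherits(trajectories, "trajectory")) list(trajectories) else trajectories
}

#' Residue-lipid contact profile
#'
#' For each residue in `residue_set` (on every chain) and each frame, a
#' contact with a lipid is recorded when the minimum-image minimum bead
#' distance between the residue and that lipid's headgroup is <= `cutoff`.
#' Counts are normalised by the number of frames and the number of lipids
#' of the species, averaged across the three chains, and averaged across
#' replicate trajectories.
#'
#' @param trajectories a `trajectory` or list of them (replicates).
#' @param residue_set integer residue numbers to profile.
#' @param species lipid species name (e.g. `"PIP2"`).
#' @param cutoff contact cutoff in nm (default 0.6).
#' @return data.frame with `resnum` and `contacts` (per frame, per lipid,
#'   chain-averaged); attributes record the normalisation.
#' @export
residue_lipid_contacts <- function(trajectories, residue_set, species,
                                   cutoff = 0.6) {
  trajs <- as_trajectory_list(trajectories)
  per_traj <- lapply(trajs, function(traj) {
    top <- traj$topology
    heads <- lipid_headgroups(top, species)
    n_lipid <- length(heads)
    chains <- top$chain_order
    res_idx <- lapply(chains, function(ch) {
      lapply(residue_set, function(r) {
        select_beads(top, chain = ch, resnum = r, species = "protein",
                     allow_empty = TRUE)
      })
    })
    head_idx <- unlist(heads, use.names = FALSE)
    head_lipid <- rep(seq_along(heads), lengths(heads))
    counts <- matrix(0, length(residue_set), length(chains))
    for (t in seq_len(n_frames(traj))) {
      f <- traj$frames[[t]]
      H <- f$coords[head_idx, , drop = FALSE]
      for (ci in seq_along(chains)) {
        for (ri in seq_along(residue_set)) {
          ix <- res_idx[[ci]][[ri]]
          if (!length(ix)) next
          dm <- min_image_dist_matrix(f$coords[ix, , drop = FALSE], H, f$box)
          # min over the residue's beads per headgroup bead, then per lipid
          dmin <- apply(dm, 2, min)
          lip_min <- tapply(dmin, head_lipid, min)
          counts[ri, ci] <- counts[ri, ci] + sum(lip_min <= cutoff)
        }
      }
    }
    rowMeans(counts) / (n_frames(traj) * n_lipid)
  })
  contacts <- Reduce(`+`, per_traj) / length(per_traj)
  out <- data.frame(resnum = residue_set, contacts = contacts)
  attr(out, "normalization") <- list(species = species, cutoff = cutoff,
                                     n_replicates = length(trajs),
                                     chains_averaged = TRUE)
  out
}

#' Interhelix residue-pair contact map
#'
#' Contact frequency between every SH residue (176-203) and every LH
#' residue (1912-1951) of the clockwise-paired chain: fraction of frames
#' in which the minimum-image residue-residue bead distance is <= `cutoff`,
#' averaged over the three monomer pairs and over replicates.
#'
#' @param trajectories a `trajectory` or list of replicates.
#' @param cutoff contact cutoff (nm).
#' @param scheme selection scheme (SH/LH residue ranges).
#' @return data.frame with `sh_resnum`, `lh_resnum`, `frequency`.
#' @export
interhelix_contacts <- function(trajectories, cutoff = 0.6,
                                scheme = selection_scheme()) {
  trajs <- as_trajectory_list(trajectories)
  sh_res <- scheme$sh_residues; lh_res <- scheme$lh_residues
  per_traj <- lapply(trajs, function(traj) {
    top <- traj$topology
    pairing <- handshake_pairing(top)
    acc <- matrix(0, length(sh_res), length(lh_res))
    for (j in seq_len(nrow(pairing))) {
      sh_ix <- lapply(sh_res, function(r) {
        select_beads(top, chain = pairing$sh_chain[j], resnum = r)
      })
      lh_ix <- lapply(lh_res, function(r) {
        select_beads(top, chain = pairing$lh_chain[j], resnum = r)
      })
      sh_all <- unlist(sh_ix); lh_all <- unlist(lh_ix)
      sh_grp <- rep(seq_along(sh_ix), lengths(sh_ix))
      lh_grp <- rep(seq_along(lh_ix), lengths(lh_ix))
      for (t in seq_len(n_frames(traj))) {
        f <- traj$frames[[t]]
        dm <- min_image_dist_matrix(f$coords[sh_all, , drop = FALSE],
                                    f$coords[lh_all, , drop = FALSE], f$box)
        # residue-pair minima
        rp <- tapply(as.numeric(dm),
                     list(sh_grp[row(dm)], lh_grp[col(dm)]), min)
        acc <- acc + (rp <= cutoff)
      }
    }
    acc / (3 * n_frames(traj))
  })
  freq <- Reduce(`+`, per_traj) / length(per_traj)
  data.frame(sh_resnum = rep(sh_res, times = length(lh_res)),
             lh_resnum = rep(lh_res, each = length(sh_res)),
             frequency = as.numeric(freq))
}

new_spatial_map <- function(values, bin, origin, kind, mask = NULL) {
  structure(list(values = values, bin = bin, origin = origin, kind = kind,
                 mask = mask),
            class = "spatial_map")
}

#' @export
print.spatial_map <- function(x, ...) {
  cat(sprintf("spatial_map (%s): %d x %d bins of %.2f nm\n",
              x$kind, nrow(x$values), ncol(x$values), x$bin))
  invisible(x)
}

#' 2D lipid density map
#'
#' After superposing every frame onto the protein coordinates of the first
#' frame of the first trajectory, headgroup xy positions of the species are
#' binned; values are mean counts per bin per frame, so the map total
#' equals the mean number of lipids per frame. Replicates are concatenated.
#'
#' @param trajectories a `trajectory` or list of replicates.
#' @param species lipid species.
#' @param bin bin size (nm, default 0.1).
#' @param fit superpose frames onto the reference protein first (default
#'   TRUE; requires >= 3 protein beads).
#' @return A `spatial_map` of kind `"density"`.
#' @export
lipid_density_map <- function(trajectories, species, bin = 0.1, fit = TRUE) {
  trajs <- as_trajectory_list(trajectories)
  box <- trajs[[1]]$frames[[1]]$box
  nx <- ceiling(box[1] / bin); ny <- ceiling(box[2] / bin)
  acc <- matrix(0, nx, ny)
  total_frames <- 0L
  ref <- trajs[[1]]$frames[[1]]
  ref_fit <- select_beads(trajs[[1]]$topology, species = "protein",
                          allow_empty = TRUE)
  for (traj in trajs) {
    heads <- lipid_headgroups(traj$topology, species)
    hidx <- unlist(heads, use.names = FALSE)
    fit_idx <- select_beads(traj$topology, species = "protein",
                            allow_empty = TRUE)
    do_fit <- fit && length(fit_idx) >= 3 && length(ref_fit) == length(fit_idx)
    for (t in seq_len(n_frames(traj))) {
      f <- traj$frames[[t]]
      if (do_fit) f <- superpose(f, ref, fit_idx)
      xy <- f$coords[hidx, 1:2, drop = FALSE]
      ix <- floor((xy[, 1] %% box[1]) / bin) + 1L
      iy <- floor((xy[, 2] %% box[2]) / bin) + 1L
      ix <- pmin(ix, nx); iy <- pmin(iy, ny)
      tab <- table(factor(ix, levels = 1:nx), factor(iy, levels = 1:ny))
      acc <- acc + unclass(tab)
      total_frames <- total_frames + 1L
    }
  }
  new_spatial_map(acc / total_frames, bin, origin = c(0, 0), kind = "density")
}

#' PIP2 pool time series
#'
#' Per frame and per handshake pair, the number of distinct PIP2 lipids
#' whose headgroup lies within `cutoff` (minimum-image, inclusive) of any
#' bead of the pair's SH helix. Systems without PIP2 give an all-zero
#' series with a warning.
#'
#' @param trajectory a `trajectory`.
#' @param pairing pairing table (default from the topology).
#' @param cutoff pool cutoff in nm (default 2.5; 2.0 is the common
#'   alternative preset).
#' @param scheme selection scheme.
#' @return Integer matrix `(n_frames, 3)`.
#' @export
pip2_pool_series <- function(trajectory, pairing = NULL, cutoff = 2.5,
                             scheme = selection_scheme()) {
  top <- trajectory$topology
  if (is.null(pairing)) pairing <- handshake_pairing(top)
  heads <- lipid_headgroups(top, "PIP2", allow_empty = TRUE)
  out <- matrix(0L, n_frames(trajectory), nrow(pairing),
                dimnames = list(NULL, paste0("pair", pairing$pair)))
  if (!length(heads)) {
    warning("no PIP2 in topology: returning an all-zero pool series")
    return(out)
  }
  hidx <- unlist(heads, use.names = FALSE)
  hlip <- rep(seq_along(heads), lengths(heads))
  sh_idx <- lapply(pairing$sh_chain, function(ch) {
    select_beads(top, chain = ch, resnum = scheme$sh_residues)
  })
  for (t in seq_len(n_frames(trajectory))) {
    f <- trajectory$frames[[t]]
    H <- f$coords[hidx, , drop = FALSE]
    for (j in seq_len(nrow(pairing))) {
      dm <- min_image_dist_matrix(f$coords[sh_idx[[j]], , drop = FALSE],
                                  H, f$box)
      dmin <- apply(dm, 2, min)
      lip_min <- tapply(dmin, hlip, min)
      out[t, j] <- sum(lip_min <= cutoff)
    }
  }
  out
}

#' Leaflet height map
#'
#' Mean z of the phosphate headgroup beads of one leaflet per xy bin,
#' across all frames. Bins never visited are filled by nearest-neighbour
#' interpolation and flagged in the mask.
#'
#' @param trajectories a `trajectory` or list of replicates.
#' @param leaflet `"upper"` or `"lower"`.
#' @param bin bin size in nm (default 0.5).
#' @param scheme selection scheme (phosphate bead name).
#' @return A `spatial_map` of kind `"height"` with `mask` TRUE where bins
#'   were empty before interpolation.
#' @export
leaflet_height_map <- function(trajectories, leaflet, bin = 0.5,
                               scheme = selection_scheme()) {
  if (!leaflet %in% c("upper", "lower")) {
    abort("leaflet must be 'upper' or 'lower'")
  }
  trajs <- as_trajectory_list(trajectories)
  box <- trajs[[1]]$frames[[1]]$box
  nx <- ceiling(box[1] / bin); ny <- ceiling(box[2] / bin)
  zsum <- matrix(0, nx, ny); cnt <- matrix(0, nx, ny)
  for (traj in trajs) {
    idx <- select_beads(traj$topology, beadname = scheme$phosphate_beadname,
                        leaflet = leaflet, allow_empty = TRUE)
    if (!length(idx)) {
      abort(sprintf("no phosphate beads assigned to the %s leaflet", leaflet))
    }
    for (t in seq_len(n_frames(traj))) {
      f <- traj$frames[[t]]
      xy <- f$coords[idx, 1:2, drop = FALSE]
      z <- f$coords[idx, 3]
      ix <- pmin(floor((xy[, 1] %% box[1]) / bin) + 1L, nx)
      iy <- pmin(floor((xy[, 2] %% box[2]) / bin) + 1L, ny)
      lin <- cbind(ix, iy)
      for (m in seq_along(z)) {
        zsum[lin[m, 1], lin[m, 2]] <- zsum[lin[m, 1], lin[m, 2]] + z[m]
        cnt[lin[m, 1], lin[m, 2]] <- cnt[lin[m, 1], lin[m, 2]] + 1
      }
    }
  }
  if (all(cnt == 0)) abort("height map is entirely empty")
  vals <- zsum / cnt
  mask <- cnt == 0
  if (any(mask)) {
    filled <- which(!mask, arr.ind = TRUE)
    empty <- which(mask, arr.ind = TRUE)
    for (m in seq_len(nrow(empty))) {
      d2 <- (filled[, 1] - empty[m, 1])^2 + (filled[, 2] - empty[m, 2])^2
      nn <- filled[which.min(d2), , drop = FALSE]
      vals[empty[m, 1], empty[m, 2]] <- vals[nn[1], nn[2]]
    }
  }
  new_spatial_map(vals, bin, origin = c(0, 0), kind = "height", mask = mask)
}

#' Dome depth from a height map
#'
#' Depth = mean height over the far-field annulus (the outer 10% of the
#' radial range, measured from the map centre, using only bins that were
#' observed) minus the minimum observed height.
#'
#' @param height_map a `spatial_map` of kind `"height"`.
#' @return Depth in nm (>= 0 for a downward dome).
#' @export
dome_depth <- function(height_map) {
  if (!inherits(height_map, "spatial_map") || height_map$kind != "height") {
    abort("dome_depth needs a height-kind spatial_map")
  }
  v <- height_map$values
  mask <- height_map$mask
  if (is.null(mask)) mask <- matrix(FALSE, nrow(v), ncol(v))
  if (all(mask)) abort("height map is entirely empty")
  ctr <- c((nrow(v) + 1) / 2, (ncol(v) + 1) / 2)
  rr <- sqrt((row(v) - ctr[1])^2 + (col(v) - ctr[2])^2)
  rmax <- max(rr[!mask])
  far <- !mask & rr >= 0.9 * rmax
  if (!any(far)) far <- !mask & rr >= stats::quantile(rr[!mask], 0.9)
  mean(v[far]) - min(v[!mask])
}
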