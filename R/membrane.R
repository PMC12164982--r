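#' Membrane composition specification
#'
#' Per-leaflet mole percentages and a total lipid count. The default is the
#' endothelial composition used throughout the package: lower leaflet
#' POPC/POPE/POPS/CHOL/PIP2 = 50/20/5/20/5, upper leaflet
#' POPC/POPE/DPSM/CHOL = 55/20/5/20. A 0% PIP2 variant replaces PIP2 with
#' POPS (lower leaflet POPS 10%).
#'
#' @param lower,upper named numeric vectors of mole percentages (must each
#'   sum to 100).
#' @param n_lipids total lipid count across both leaflets (split evenly).
#' @param box_xy in-plane box dimensions `(Lx, Ly)` in nm.
#' @return A `membrane_spec`.
#' @export
membrane_spec <- function(lower = c(POPC = 50, POPE = 20, POPS = 5,
                                    CHOL = 20, PIP2 = 5),
                          upper = c(POPC = 55, POPE = 20, DPSM = 5,
                                    CHOL = 20),
                          n_lipids = 600L, box_xy = c(44, 44)) {
  for (leaf in list(lower = lower, upper = upper)) {
    if (abs(sum(leaf) - 100) > 1e-9) {
      abort_config(sprintf("leaflet percentages sum to %.6f, not 100", sum(leaf)))
    }
    if (any(leaf < 0)) abort_config("negative mole percentage")
  }
  stopifnot_scalar_num(n_lipids, "n_lipids", positive = TRUE)
  structure(list(lower = lower, upper = upper,
                 n_lipids = as.integer(n_lipids),
                 box_xy = as.numeric(box_xy)),
            class = "membrane_spec")
}

#' @rdname membrane_spec
#' @export
membrane_spec_no_pip2 <- function(n_lipids = 600L, box_xy = c(44, 44)) {
  membrane_spec(lower = c(POPC = 50, POPE = 20, POPS = 10, CHOL = 20, PIP2 = 0),
                n_lipids = n_lipids, box_xy = box_xy)
}

#' Largest-remainder apportionment
#'
#' Apportions `n` counts to categories proportional to `percent` (summing
#' to 100) with the largest-remainder (Hamilton) rule, which conserves the
#' total exactly. Ties are broken by category order.
#'
#' @param percent named numeric vector of percentages.
#' @param n total count to apportion.
#' @return Named integer vector summing exactly to `n`.
#' @export
apportion_largest_remainder <- function(percent, n) {
  if (abs(sum(percent) - 100) > 1e-9) {
    abort_config("percentages must sum to 100")
  }
  q <- percent * n / 100
  base <- floor(q)
  left <- as.integer(round(n - sum(base)))
  counts <- base
  if (left > 0L) {
    rem <- q - base
    take <- order(-rem, seq_along(rem))[seq_len(left)]
    counts[take] <- counts[take] + 1
  }
  stats::setNames(as.integer(counts), names(percent))
}

headgroup_beadname <- function(species) {
  ifelse(species == "CHOL", "ROH", ifelse(species == "PIP2", "P1", "PO4"))
}

#' Build a flat membrane of headgroup beads
#'
#' Places one headgroup bead per lipid on a jittered 2D lattice at the
#' leaflet heights +/- 2 nm, with per-leaflet species counts given by the
#' largest-remainder apportionment of the composition.
#'
#' @param spec a [membrane_spec()].
#' @param seed integer seed.
#' @param leaflet_height absolute z of each leaflet plane (nm).
#' @param box_z box height (nm).
#' @return list with `topology` (a `channel_topology`) and `frame`.
#' @export
build_membrane <- function(spec, seed = 1L, leaflet_height = 2, box_z = 24) {
  if (!inherits(spec, "membrane_spec")) abort_config("spec must be a membrane_spec")
  n_low <- spec$n_lipids %/% 2L + spec$n_lipids %% 2L
  n_up  <- spec$n_lipids %/% 2L
  with_seed(seed, {
    place_leaflet <- function(pct, n, z) {
      counts <- apportion_largest_remainder(pct, n)
      species <- rep(names(counts), counts)
      species <- sample(species)           # mix species across the lattice
      side <- ceiling(sqrt(n))
      g <- expand.grid(ix = seq_len(side), iy = seq_len(side))[seq_len(n), ]
      dx <- spec$box_xy[1] / side
      dy <- spec$box_xy[2] / side
      x <- (g$ix - 0.5) * dx + stats::runif(n, -0.2, 0.2) * dx
      y <- (g$iy - 0.5) * dy + stats::runif(n, -0.2, 0.2) * dy
      list(coords = cbind(x %% spec$box_xy[1], y %% spec$box_xy[2], rep(z, n)),
           species = species)
    }
    lo <- place_leaflet(spec$lower, n_low, box_z / 2 - leaflet_height)
    up <- place_leaflet(spec$upper, n_up,  box_z / 2 + leaflet_height)
    species <- c(lo$species, up$species)
    beads <- data.frame(
      chain = NA_character_,
      resnum = seq_along(species),
      resname = species,
      beadname = headgroup_beadname(species),
      species = species,
      leaflet = c(rep("lower", n_low), rep("upper", n_up)),
      stringsAsFactors = FALSE)
    list(topology = channel_topology(beads),
         frame = new_frame(rbind(lo$coords, up$coords),
                           c(spec$box_xy, box_z), time = 0))
  })
}

#' Per-leaflet species counts implied by a membrane spec
#' @param spec a [membrane_spec()].
#' @return list with integer vectors `lower` and `upper`.
#' @export
membrane_counts <- function(spec) {
  n_low <- spec$n_lipids %/% 2L + spec$n_lipids %% 2L
  n_up  <- spec$n_lipids %/% 2L
  list(lower = apportion_largest_remainder(spec$lower, n_low),
       upper = apportion_largest_remainder(spec$upper, n_up))
}
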