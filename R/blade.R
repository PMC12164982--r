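# Blade conformation metrics: tip-to-pore distance, vertex angle, height,
# conditional 2D histograms, compact/extended classification, projected
# area.

pore_cog_indices <- function(topology, scheme = selection_scheme()) {
  select_beads(topology, resnum = scheme$pore_inner)
}

thu_indices <- function(topology, chain, k, scheme = selection_scheme()) {
  select_beads(topology, chain = chain, resname = scheme$thu_resnames[k])
}

#' Blade tip-to-pore distance
#'
#' 3D minimum-image distance between the centre of geometry of the
#' N-terminal THU (THU1) of each chain and the centre of geometry of the
#' inner-pore selection (residues 2433-2462 over all chains).
#'
#' @param trajectory a `trajectory`.
#' @param scheme selection scheme.
#' @return Matrix `(n_frames, 3)`, one column per chain.
#' @export
blade_distance <- function(trajectory, scheme = selection_scheme()) {
  top <- trajectory$topology
  pore <- pore_cog_indices(top, scheme)
  thu1 <- lapply(top$chain_order, function(ch) thu_indices(top, ch, 1, scheme))
  out <- matrix(NA_real_, n_frames(trajectory), 3,
                dimnames = list(NULL, top$chain_order))
  for (t in seq_len(n_frames(trajectory))) {
    f <- trajectory$frames[[t]]
    pc <- center_of_geometry(f, pore)
    for (c_ in 1:3) {
      out[t, c_] <- min_image_dist(center_of_geometry(f, thu1[[c_]]), pc, f$box)
    }
  }
  out
}

#' Blade vertex angle
#'
#' Angle at the THU6 vertex between the xy-projected arms THU1-THU6 and
#' THU9-THU6 (degrees); a straight blade gives 180. Frames where a
#' projected arm collapses to zero length are returned as `NA` with a
#' warning.
#'
#' @param trajectory a `trajectory`.
#' @param scheme selection scheme.
#' @return Matrix `(n_frames, 3)` of angles in degrees.
#' @export
blade_angle <- function(trajectory, scheme = selection_scheme()) {
  top <- trajectory$topology
  sel <- lapply(top$chain_order, function(ch) {
    list(t1 = thu_indices(top, ch, 1, scheme),
         t6 = thu_indices(top, ch, 6, scheme),
         t9 = thu_indices(top, ch, 9, scheme))
  })
  out <- matrix(NA_real_, n_frames(trajectory), 3,
                dimnames = list(NULL, top$chain_order))
  degenerate <- 0L
  for (t in seq_len(n_frames(trajectory))) {
    f <- trajectory$frames[[t]]
    for (c_ in 1:3) {
      v6 <- center_of_geometry(f, sel[[c_]]$t6)
      a <- min_image_wrap(center_of_geometry(f, sel[[c_]]$t1) - v6, f$box)[1:2]
      b <- min_image_wrap(center_of_geometry(f, sel[[c_]]$t9) - v6, f$box)[1:2]
      na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
      if (na < 1e-9 || nb < 1e-9) {
        degenerate <- degenerate + 1L
        next
      }
      cosang <- sum(a * b) / (na * nb)
      out[t, c_] <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    }
  }
  if (degenerate > 0L) {
    warning(sprintf("%d blade-angle frames had a degenerate xy projection (NA)",
                    degenerate))
  }
  out
}

#' Blade height
#'
#' Absolute z separation between the THU1 centre of geometry and the
#' inner-pore centre of geometry, per chain per frame.
#'
#' @param trajectory a `trajectory`.
#' @param scheme selection scheme.
#' @return Matrix `(n_frames, 3)`.
#' @export
blade_height <- function(trajectory, scheme = selection_scheme()) {
  top <- trajectory$topology
  pore <- pore_cog_indices(top, scheme)
  thu1 <- lapply(top$chain_order, function(ch) thu_indices(top, ch, 1, scheme))
  out <- matrix(NA_real_, n_frames(trajectory), 3,
                dimnames = list(NULL, top$chain_order))
  for (t in seq_len(n_frames(trajectory))) {
    f <- trajectory$frames[[t]]
    zp <- center_of_geometry(f, pore)[3]
    for (c_ in 1:3) {
      out[t, c_] <- abs(center_of_geometry(f, thu1[[c_]])[3] - zp)
    }
  }
  out
}

#' Handshake-conditioned 2D conformational histogram
#'
#' Density-normalised 2D histogram of (blade distance, blade angle) over
#' the frames whose handshake count equals `k`. The density integrates to 1
#' (sum(density) * bin_d * bin_theta == 1) for non-empty conditions.
#'
#' @param distances,angles matrices `(n_frames, 3)` from [blade_distance()]
#'   and [blade_angle()]; the three chains are pooled.
#' @param counts integer per-frame handshake counts.
#' @param k handshake count condition (0-3), or `NULL` for the
#'   unconditional histogram over all frames.
#' @param bin_d,bin_theta bin widths (nm, degrees).
#' @param d_range,theta_range optional fixed ranges so that histograms for
#'   different `k` share bins.
#' @return A `conformation_histogram`: list with `density` matrix,
#'   `d_breaks`, `theta_breaks`, `k`, `n_frames_used`.
#' @export
conformation_histogram <- function(distances, angles, counts, k,
                                   bin_d = 0.25, bin_theta = 2,
                                   d_range = NULL, theta_range = NULL) {
  distances <- as.matrix(distances); angles <- as.matrix(angles)
  if (nrow(distances) != length(counts) || !all(dim(distances) == dim(angles))) {
    abort("distances, angles and counts are not aligned")
  }
  if (is.null(d_range)) {
    d_range <- c(floor(min(distances) / bin_d) * bin_d,
                 ceiling(max(distances) / bin_d) * bin_d + bin_d)
  }
  if (is.null(theta_range)) {
    theta_range <- c(floor(min(angles) / bin_theta) * bin_theta,
                     ceiling(max(angles) / bin_theta) * bin_theta + bin_theta)
  }
  d_breaks <- seq(d_range[1], d_range[2], by = bin_d)
  t_breaks <- seq(theta_range[1], theta_range[2], by = bin_theta)
  sel <- if (is.null(k)) rep(TRUE, length(counts)) else counts == k
  dens <- matrix(0, length(d_breaks) - 1, length(t_breaks) - 1)
  nsel <- sum(sel)
  if (nsel == 0L) {
    warning(sprintf("no frames with handshake count %s: empty histogram",
                    format(k)))
  } else {
    dv <- as.numeric(distances[sel, ]); tv <- as.numeric(angles[sel, ])
    ok <- is.finite(dv) & is.finite(tv)
    di <- findInterval(dv[ok], d_breaks, rightmost.closed = TRUE)
    ti <- findInterval(tv[ok], t_breaks, rightmost.closed = TRUE)
    keep <- di >= 1 & di <= nrow(dens) & ti >= 1 & ti <= ncol(dens)
    tab <- table(factor(di[keep], levels = seq_len(nrow(dens))),
                 factor(ti[keep], levels = seq_len(ncol(dens))))
    dens <- unclass(tab) / (sum(keep) * bin_d * bin_theta)
  }
  structure(list(density = dens, d_breaks = d_breaks, theta_breaks = t_breaks,
                 bin_d = bin_d, bin_theta = bin_theta, k = k,
                 n_frames_used = nsel),
            class = "conformation_histogram")
}

#' Compact / extended / intermediate blade classification
#'
#' Compact: distance < 13 nm and angle < 100 degrees. Extended: distance
#' > 13 nm. Anything else is intermediate.
#'
#' @param distance,angle numeric (vectorised), nm and degrees.
#' @return Character vector of labels.
#' @export
classify_conformation <- function(distance, angle) {
  if (any(!is.finite(distance)) || any(!is.finite(angle))) {
    abort("distance and angle must be finite")
  }
  ifelse(distance > 13, "extended",
         ifelse(distance < 13 & angle < 100, "compact", "intermediate"))
}

#' Projected area and in-plane radius
#'
#' Pairwise minimum-image distances between the L71 markers of the three
#' chains; the in-plane radius is the circumradius of the equilateral
#' triangle with the mean side, `r_b = d_mean / sqrt(3)`, and the projected
#' area is `pi * r_b^2`.
#'
#' @param trajectory a `trajectory`.
#' @param scheme selection scheme.
#' @return data.frame with per-frame `d12`, `d23`, `d31`, `d_mean`, `r_b`,
#'   `area`.
#' @export
projected_area <- function(trajectory, scheme = selection_scheme()) {
  top <- trajectory$topology
  l71 <- lapply(top$chain_order, function(ch) {
    select_beads(top, chain = ch, resnum = scheme$area_marker)
  })
  n <- n_frames(trajectory)
  d <- matrix(NA_real_, n, 3)
  for (t in seq_len(n)) {
    f <- trajectory$frames[[t]]
    p <- lapply(l71, function(ix) center_of_geometry(f, ix))
    d[t, ] <- c(min_image_dist(p[[1]], p[[2]], f$box),
                min_image_dist(p[[2]], p[[3]], f$box),
                min_image_dist(p[[3]], p[[1]], f$box))
  }
  d_mean <- rowMeans(d)
  r_b <- d_mean / sqrt(3)
  data.frame(frame = seq_len(n), d12 = d[, 1], d23 = d[, 2], d31 = d[, 3],
             d_mean = d_mean, r_b = r_b, area = pi * r_b^2)
}
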