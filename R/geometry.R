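#' Minimum-image displacement and distance
#'
#' Orthorhombic minimum-image convention: each displacement component is
#' wrapped into `(-L/2, L/2]`.
#'
#' @param frame a `frame`.
#' @param index_a,index_b bead indices (length-1). For groups use
#'   [center_of_geometry()] first.
#' @return list with `vec` (displacement b - a, nm) and `dist` (nm).
#' @export
min_image_vector <- function(frame, index_a, index_b) {
  a <- frame$coords[index_a, , drop = TRUE]
  b <- frame$coords[index_b, , drop = TRUE]
  v <- min_image_wrap(b - a, frame$box)
  list(vec = v, dist = sqrt(sum(v^2)))
}

# wrap displacement components into (-L/2, L/2]
min_image_wrap <- function(d, box) {
  if (any(box <= 0)) abort("box dimensions must be positive")
  w <- d - box * round(d / box)
  low <- w <= -box / 2
  w[low] <- w[low] + box[low]
  w
}

# min-image distance between two points (length-3 vectors)
min_image_dist <- function(a, b, box) {
  v <- min_image_wrap(b - a, box)
  sqrt(sum(v^2))
}

# pairwise min-image distance matrix between coordinate sets A (n x 3) and
# B (m x 3); vectorised per dimension.
min_image_dist_matrix <- function(A, B, box) {
  if (any(box <= 0)) abort("box dimensions must be positive")
  A <- matrix(A, ncol = 3); B <- matrix(B, ncol = 3)
  d2 <- matrix(0, nrow(A), nrow(B))
  for (k in 1:3) {
    dk <- outer(A[, k], B[, k], "-")
    dk <- dk - box[k] * round(dk / box[k])
    d2 <- d2 + dk^2
  }
  sqrt(d2)
}

#' Center of geometry of a bead selection
#'
#' Unweighted mean of the selected coordinates. Selections are assumed
#' whole (not split across the periodic boundary); the synthetic generator
#' guarantees whole molecules and real input should be centred beforehand.
#'
#' @param frame a `frame`.
#' @param index_set non-empty integer bead indices.
#' @return Length-3 numeric (nm).
#' @export
center_of_geometry <- function(frame, index_set) {
  if (!length(index_set)) abort("center_of_geometry: empty selection")
  colMeans(frame$coords[index_set, , drop = FALSE])
}

#' Least-squares rigid-body superposition
#'
#' Kabsch superposition of `frame` onto `reference_frame` using the fit
#' selection; the recovered rotation + translation is applied to all beads.
#'
#' @param frame,reference_frame `frame` objects with equal bead counts.
#' @param fit_index_set at least three non-collinear bead indices.
#' @return The transformed `frame`, with attributes `rmsd` (of the fit
#'   selection, nm), `rotation` and `translation`.
#' @export
superpose <- function(frame, reference_frame, fit_index_set) {
  if (length(fit_index_set) < 3L) {
    abort("superpose needs at least 3 fit beads")
  }
  P <- frame$coords[fit_index_set, , drop = FALSE]
  Q <- reference_frame$coords[fit_index_set, , drop = FALSE]
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  sv <- svd(crossprod(Pc, Qc))
  # collinear fit set: second singular value of the covariance vanishes
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1e-300)) {
    abort("superpose: fit selection is (near-)collinear")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  out <- frame
  out$coords <- sweep(frame$coords, 2, cp) %*% t(R)
  out$coords <- sweep(out$coords, 2, cq, FUN = "+")
  fitted <- out$coords[fit_index_set, , drop = FALSE]
  attr(out, "rmsd") <- sqrt(mean(rowSums((fitted - Q)^2)))
  attr(out, "rotation") <- R
  attr(out, "translation") <- cq - as.numeric(R %*% cp)
  out
}
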