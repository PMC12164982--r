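#' Frames and trajectories
#'
#' A `frame` holds an N x 3 coordinate matrix in nanometres, the
#' orthorhombic box lengths `(Lx, Ly, Lz)` in nm and a time stamp in ps.
#' A `trajectory` couples an ordered list of frames with a
#' [channel_topology()].
#'
#' @param coords numeric N x 3 matrix (nm).
#' @param box numeric length-3 vector of box lengths (nm), all > 0.
#' @param time time in ps.
#' @return `new_frame()` returns a `frame`; `new_trajectory()` a
#'   `trajectory`.
#' @export
new_frame <- function(coords, box, time = 0) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) abort("frame coordinates must be an N x 3 matrix")
  if (length(box) < 3L || any(!is.finite(box[1:3])) || any(box[1:3] <= 0)) {
    abort("box must have three positive components")
  }
  structure(list(coords = coords, box = as.numeric(box[1:3]),
                 time = as.numeric(time)),
            class = "frame")
}

#' @rdname new_frame
#' @param topology a `channel_topology` whose bead count matches every frame.
#' @param frames list of `frame` objects with non-decreasing time.
#' @param source_label replicate identifier carried through to outputs.
#' @export
new_trajectory <- function(topology, frames, source_label = "run") {
  if (!inherits(topology, "channel_topology")) {
    abort("topology must be a channel_topology")
  }
  if (!length(frames)) abort("a trajectory needs at least one frame")
  nb <- n_beads(topology)
  for (i in seq_along(frames)) {
    if (!inherits(frames[[i]], "frame")) abort("frames must be frame objects")
    if (nrow(frames[[i]]$coords) != nb) {
      abort(sprintf("frame %d has %d beads but topology has %d",
                    i, nrow(frames[[i]]$coords), nb))
    }
  }
  times <- vapply(frames, function(f) f$time, numeric(1))
  if (is.unsorted(times)) abort("frame times must be non-decreasing")
  structure(list(topology = topology, frames = frames,
                 source_label = source_label),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory '%s': %d frames x %d beads, box (%s) nm\n",
              x$source_label, length(x$frames), n_beads(x$topology),
              paste(format(x$frames[[1]]$box, digits = 4), collapse = ", ")))
  invisible(x)
}

#' @rdname new_frame
#' @param trajectory a `trajectory`.
#' @export
n_frames <- function(trajectory) length(trajectory$frames)

#' Extract the frames with a given handshake count
#'
#' @param trajectory a `trajectory`.
#' @param series a `handshake_series` (see [classify_handshakes()]).
#' @param k handshake count in `0:3`.
#' @return A `trajectory` containing only the matching frames (order
#'   preserved); empty selections return a zero-frame structure with a
#'   warning rather than an error.
#' @export
frames_by_count <- function(trajectory, series, k) {
  if (!k %in% 0:3) abort("k must be one of 0, 1, 2, 3")
  idx <- which(series$count == k)
  if (!length(idx)) {
    warning(sprintf("no frames with handshake count %d", k))
    out <- trajectory
    out$frames <- list()
    return(out)
  }
  out <- trajectory
  out$frames <- trajectory$frames[idx]
  out
}

#' Subset a trajectory by frame indices
#' @param trajectory a `trajectory`.
#' @param idx integer frame indices.
#' @export
subset_frames <- function(trajectory, idx) {
  if (!length(idx)) abort("frame index set is empty")
  out <- trajectory
  out$frames <- trajectory$frames[idx]
  out
}
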