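# Handshake detection and classification.
#
# A handshake is the transient contact between the short helix (SH) tip,
# residue 176, of one blade and the long helix (LH) tip, residue 1912, of
# the clockwise-neighbouring blade; tip separation <= 1.5 nm (inclusive)
# defines the bound state.

#' Per-pair handshake tip distance series
#'
#' Minimum-image distance between the centres of geometry of the two tip
#' residues (SH tip 176, LH tip 1912 of the clockwise neighbour), per frame
#' and per pair.
#'
#' @param trajectory a `trajectory`.
#' @param pairing a pairing table from [handshake_pairing()] (default:
#'   derived from the topology's chain order).
#' @param scheme selection scheme (see [selection_scheme()]).
#' @return Numeric matrix `(n_frames, 3)`.
#' @export
tip_distance_series <- function(trajectory, pairing = NULL,
                                scheme = selection_scheme()) {
  top <- trajectory$topology
  if (is.null(pairing)) pairing <- handshake_pairing(top)
  sh_idx <- lapply(pairing$sh_chain, function(ch) {
    select_beads(top, chain = ch, resnum = scheme$sh_tip)
  })
  lh_idx <- lapply(pairing$lh_chain, function(ch) {
    select_beads(top, chain = ch, resnum = scheme$lh_tip)
  })
  out <- matrix(NA_real_, n_frames(trajectory), nrow(pairing))
  for (t in seq_len(n_frames(trajectory))) {
    f <- trajectory$frames[[t]]
    for (j in seq_len(nrow(pairing))) {
      a <- center_of_geometry(f, sh_idx[[j]])
      b <- center_of_geometry(f, lh_idx[[j]])
      out[t, j] <- min_image_dist(a, b, f$box)
    }
  }
  colnames(out) <- paste0("pair", pairing$pair)
  out
}

#' Classify handshake states from tip distances
#'
#' Bound if distance <= cutoff (inclusive). The per-frame count is the
#' number of bound pairs (0-3).
#'
#' @param distance_series matrix `(n_frames, n_pairs)` of tip distances (nm).
#' @param cutoff handshake distance cutoff (nm, default 1.5).
#' @return A `handshake_series`: list with `distance`, logical `bound`,
#'   integer `count`, and `cutoff`.
#' @export
classify_handshakes <- function(distance_series, cutoff = 1.5) {
  d <- as.matrix(distance_series)
  if (any(!is.finite(d))) abort("distances must be finite")
  stopifnot_scalar_num(cutoff, "cutoff", positive = TRUE)
  bound <- d <= cutoff
  structure(list(distance = d, bound = bound,
                 count = as.integer(rowSums(bound)), cutoff = cutoff),
            class = "handshake_series")
}

#' @export
print.handshake_series <- function(x, ...) {
  cat(sprintf("handshake_series: %d frames, cutoff %.2f nm\n",
              nrow(x$distance), x$cutoff))
  print(handshake_frequencies(x))
  invisible(x)
}

#' Frequency of the 0/1/2/3 handshake conformations
#'
#' @param series a `handshake_series`.
#' @return Named numeric vector of length 4 summing to 1.
#' @export
handshake_frequencies <- function(series) {
  if (!length(series$count)) abort("series has no frames")
  k <- factor(series$count, levels = 0:3)
  freq <- as.numeric(table(k)) / length(series$count)
  stats::setNames(freq, paste0("n", 0:3))
}

#' Probability-density histogram of tip distances
#'
#' @param series a `handshake_series` or a numeric vector/matrix of
#'   distances.
#' @param bin_width bin width in nm (default 0.1).
#' @return data.frame with `mid`, `lower`, `upper`, `density` (integrates
#'   to 1).
#' @export
distance_histogram <- function(series, bin_width = 0.1) {
  stopifnot_scalar_num(bin_width, "bin_width", positive = TRUE)
  d <- if (inherits(series, "handshake_series")) series$distance else series
  d <- as.numeric(d)
  breaks <- seq(floor(min(d) / bin_width) * bin_width,
                ceiling(max(d) / bin_width + 1) * bin_width, by = bin_width)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  data.frame(mid = h$mids, lower = utils::head(h$breaks, -1),
             upper = h$breaks[-1], density = h$density)
}

#' Mode segmentation parameters
#'
#' Hysteresis and dwell thresholds for [classify_modes()]. Defaults:
#' bind at <= 1.5 nm, unbind only above 2.0 nm, stable episodes need a
#' bound dwell of at least 200 frames, unstable regions need at least 3
#' transitions within a 500-frame window, release is a terminal unbound
#' run of at least 500 frames following a bound episode.
#'
#' @param bind_cutoff,unbind_cutoff hysteresis distances (nm).
#' @param stable_min_dwell,unstable_min_transitions,unstable_window,release_min_unbound
#'   dwell/transition thresholds in frames.
#' @return A named list.
#' @export
mode_params <- function(bind_cutoff = 1.5, unbind_cutoff = 2.0,
                        stable_min_dwell = 200L,
                        unstable_min_transitions = 3L,
                        unstable_window = 500L,
                        release_min_unbound = 500L) {
  if (unbind_cutoff < bind_cutoff) {
    abort_config("unbind_cutoff must be >= bind_cutoff")
  }
  as.list(environment())
}

# hysteretic bound-state sequence from a distance series
hysteretic_state <- function(d, bind_cutoff, unbind_cutoff) {
  n <- length(d)
  s <- logical(n)
  s[1] <- d[1] <= bind_cutoff
  for (t in seq_len(n)[-1]) {
    s[t] <- if (s[t - 1]) d[t] <= unbind_cutoff else d[t] <= bind_cutoff
  }
  s
}

#' Segment a handshake distance series into mode episodes
#'
#' Applies hysteretic bound/unbound segmentation then labels episodes:
#' `stable` (long bound dwells), `unstable` (regions of rapid
#' binding/unbinding), and `release` (a terminal unbound run following a
#' bound episode). Each episode is annotated with the mean PIP2 pool.
#'
#' @param distance numeric vector (one pair) or matrix (pairs in columns).
#' @param pool optional aligned PIP2 pool series (same shape).
#' @param params a [mode_params()] list.
#' @return data.frame with `pair`, `start`, `end`, `label`, `mean_pool`.
#' @export
classify_modes <- function(distance, pool = NULL, params = mode_params()) {
  d <- as.matrix(distance)
  if (!is.null(pool)) {
    pool <- as.matrix(pool)
    if (!all(dim(pool) == dim(d))) {
      abort("pool series is not aligned with the distance series")
    }
  }
  out <- lapply(seq_len(ncol(d)), function(j) {
    ep <- classify_modes_one(d[, j], if (is.null(pool)) NULL else pool[, j],
                             params)
    if (nrow(ep)) ep$pair <- j
    ep
  })
  out <- do.call(rbind, out)
  if (is.null(out) || !nrow(out)) {
    return(data.frame(pair = integer(0), start = integer(0),
                      end = integer(0), label = character(0),
                      mean_pool = numeric(0)))
  }
  out[, c("pair", "start", "end", "label", "mean_pool")]
}

classify_modes_one <- function(d, pool, params) {
  n <- length(d)
  s <- hysteretic_state(d, params$bind_cutoff, params$unbind_cutoff)
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nruns <- length(r$lengths)
  # transition times: frame index at which the state changes (start of run 2..)
  tt <- starts[-1]
  # dense transition clusters -> unstable
  dense_tr <- rep(FALSE, length(tt))
  m <- params$unstable_min_transitions
  if (length(tt) >= m) {
    for (i in seq_len(length(tt) - m + 1L)) {
      if (tt[i + m - 1L] - tt[i] <= params$unstable_window) {
        dense_tr[i:(i + m - 1L)] <- TRUE
      }
    }
  }
  run_label <- rep(NA_character_, nruns)
  # a run is in an unstable region if it is bordered by a dense transition
  if (any(dense_tr)) {
    for (i in seq_len(nruns)) {
      left  <- if (i > 1L) dense_tr[i - 1L] else FALSE
      right <- if (i < nruns) dense_tr[i] else FALSE
      if (left || right) run_label[i] <- "unstable"
    }
  }
  # stable bound dwells (long dwells are never part of a dense cluster span)
  for (i in seq_len(nruns)) {
    if (r$values[i] && r$lengths[i] >= params$stable_min_dwell) {
      run_label[i] <- "stable"
    }
  }
  # terminal release
  if (!r$values[nruns] && r$lengths[nruns] >= params$release_min_unbound &&
      any(r$values[seq_len(nruns - 1L)])) {
    run_label[nruns] <- "release"
  }
  # merge consecutive runs with the same label into episodes
  eps <- list()
  i <- 1L
  while (i <= nruns) {
    if (is.na(run_label[i])) { i <- i + 1L; next }
    j <- i
    while (j < nruns && identical(run_label[j + 1L], run_label[i])) j <- j + 1L
    eps[[length(eps) + 1L]] <- data.frame(
      start = starts[i], end = ends[j], label = run_label[i],
      stringsAsFactors = FALSE)
    i <- j + 1L
  }
  if (!length(eps)) {
    return(data.frame(start = integer(0), end = integer(0),
                      label = character(0), mean_pool = numeric(0)))
  }
  eps <- do.call(rbind, eps)
  eps$mean_pool <- if (is.null(pool)) NA_real_ else
    vapply(seq_len(nrow(eps)),
           function(k) mean(pool[eps$start[k]:eps$end[k]]), numeric(1))
  eps
}

#' Per-frame mode labels from an episode table
#'
#' @param episodes output of [classify_modes()] (one pair).
#' @param n_frames series length.
#' @return Character vector of length `n_frames` (`NA` outside episodes).
#' @export
mode_frame_labels <- function(episodes, n_frames) {
  lab <- rep(NA_character_, n_frames)
  for (k in seq_len(nrow(episodes))) {
    lab[episodes$start[k]:episodes$end[k]] <- episodes$label[k]
  }
  lab
}

#' Contrast PIP2 pool between stable handshaking and pre-release windows
#'
#' For one pair: mean pool over frames inside stable episodes versus mean
#' pool in the `window` frames immediately preceding each handshake release
#' event (a bound-to-unbound transition of the hysteretic state).
#'
#' @param distance,pool aligned numeric vectors.
#' @param params a [mode_params()].
#' @param window pre-release window length in frames.
#' @return list with `stable_mean`, `prerelease_mean` (either may be `NA`
#'   when the corresponding condition never occurs).
#' @export
pool_mode_contrast <- function(distance, pool, params = mode_params(),
                               window = 50L) {
  s <- hysteretic_state(distance, params$bind_cutoff, params$unbind_cutoff)
  eps <- classify_modes(distance, pool, params)
  stable <- eps[eps$label == "stable", , drop = FALSE]
  stable_frames <- unlist(lapply(seq_len(nrow(stable)), function(k) {
    stable$start[k]:stable$end[k]
  }))
  rel <- which(diff(s) == -1) + 1L   # first unbound frame of each release
  pre_frames <- unlist(lapply(rel, function(t0) {
    seq(max(1L, t0 - window), t0 - 1L)
  }))
  pre_frames <- setdiff(pre_frames, integer(0))
  list(stable_mean = if (length(stable_frames))
         mean(pool[setdiff(stable_frames, pre_frames)]) else NA_real_,
       prerelease_mean = if (length(pre_frames))
         mean(pool[pre_frames]) else NA_real_)
}

#' Arginine/lysine content of a helix span
#'
#' Counts arginines and lysines in a one-letter amino-acid sequence span
#' and returns a per-position charge mask (+1 for R/K, -1 for D/E, 0
#' otherwise). The handshake helices of human PIEZO1 are arginine-rich
#' (six in one helix, nine in the other, no lysines), a feature this
#' profile quantifies for any ortholog sequence.
#'
#' @param sequence one-letter amino-acid string.
#' @param span integer range of positions (default: full sequence). An
#'   empty span gives zero counts.
#' @return list with `R`, `K` counts and `charge_mask`.
#' @export
helix_charge_profile <- function(sequence, span = NULL) {
  seq_chars <- strsplit(toupper(sequence), "")[[1]]
  valid <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  bad <- setdiff(unique(seq_chars), valid)
  if (length(bad)) {
    abort(sprintf("non-amino-acid character(s) in sequence: %s",
                  paste(bad, collapse = ", ")))
  }
  if (is.null(span)) span <- seq_along(seq_chars)
  if (length(span) && (min(span) < 1 || max(span) > length(seq_chars))) {
    abort("span is outside the sequence")
  }
  sub <- seq_chars[span]
  mask <- ifelse(sub %in% c("R", "K"), 1L, ifelse(sub %in% c("D", "E"), -1L, 0L))
  list(R = sum(sub == "R"), K = sum(sub == "K"),
       charge_mask = stats::setNames(mask, span))
}
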