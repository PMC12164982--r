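# Coordinate file I/O.
#
# GRO is fixed-column: resnum %5d, resname %-5s, atomname %5s, atomnum %5d,
# x/y/z %8.3f (nm); multi-frame files are concatenated blocks each ending in
# a box line of >= 3 floats. PDB multi-model files use MODEL/ENDMDL as
# frames and CRYST1 as the box; coordinates are converted A -> nm on read.

species_from_resname <- function(resname) {
  lipids <- c("POPC", "POPE", "POPS", "CHOL", "PIP2", "DPSM")
  ifelse(resname %in% lipids, resname,
         ifelse(resname %in% c("W", "SOL", "HOH", "WAT"), "solvent",
                ifelse(resname %in% c("NA", "CL", "ION", "NA+", "CL-", "CA"),
                       "ion", "protein")))
}

parse_gro_numeric <- function(txt, lineno, what) {
  x <- suppressWarnings(as.numeric(txt))
  if (any(is.na(x))) {
    abort(sprintf("GRO parse error at line %d: bad %s field '%s'",
                  lineno[which(is.na(x))[1]], what, txt[which(is.na(x))[1]]))
  }
  x
}

#' Read a (multi-frame) GRO file
#'
#' @param path GRO file path.
#' @param topology optional `channel_topology` (or path to a topology CSV
#'   sidecar) supplying chain/species/leaflet annotation. Without it a bare
#'   topology is built from the GRO labels (no chains, species guessed from
#'   residue names).
#' @param chain_order used when building a bare topology.
#' @return A `trajectory` with coordinates in nm.
#' @export
read_gro <- function(path, topology = NULL, chain_order = c("A", "B", "C")) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  frames <- list()
  labels <- NULL
  i <- 1L
  nb <- NA_integer_
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    if (i + 1L > length(lines)) {
      abort(sprintf("GRO parse error at line %d: truncated frame header", i))
    }
    title <- lines[i]
    n <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(n) || n < 1L) {
      abort(sprintf("GRO parse error at line %d: bad atom count '%s'",
                    i + 1L, lines[i + 1L]))
    }
    if (!is.na(nb) && n != nb) {
      abort(sprintf("inconsistent bead count across frames: %d then %d", nb, n))
    }
    nb <- n
    if (i + 1L + n + 1L > length(lines)) {
      abort(sprintf("GRO parse error: frame starting at line %d is truncated", i))
    }
    atom_lines <- lines[(i + 2L):(i + 1L + n)]
    linenos <- (i + 2L):(i + 1L + n)
    if (any(nchar(atom_lines) < 44L)) {
      bad <- linenos[which(nchar(atom_lines) < 44L)[1]]
      abort(sprintf("GRO parse error at line %d: line shorter than 44 columns", bad))
    }
    resnum  <- parse_gro_numeric(substr(atom_lines, 1, 5), linenos, "residue number")
    resname <- trimws(substr(atom_lines, 6, 10))
    atname  <- trimws(substr(atom_lines, 11, 15))
    x <- parse_gro_numeric(substr(atom_lines, 21, 28), linenos, "x")
    y <- parse_gro_numeric(substr(atom_lines, 29, 36), linenos, "y")
    z <- parse_gro_numeric(substr(atom_lines, 37, 44), linenos, "z")
    boxv <- suppressWarnings(as.numeric(strsplit(trimws(lines[i + 2L + n]),
                                                 "\\s+")[[1]]))
    if (length(boxv) < 3L || any(is.na(boxv[1:3]))) {
      abort(sprintf("GRO parse error at line %d: bad box line", i + 2L + n))
    }
    if (length(boxv) > 3L && any(abs(boxv[-(1:3)]) > 1e-9)) {
      abort("triclinic boxes are not supported")
    }
    tm <- regmatches(title, regexec("t=\\s*([0-9eE+.-]+)", title))[[1]]
    time <- if (length(tm) == 2L) as.numeric(tm[2]) else length(frames)
    frames[[length(frames) + 1L]] <- new_frame(cbind(x, y, z), boxv[1:3], time)
    if (is.null(labels)) {
      labels <- data.frame(resnum = as.integer(resnum), resname = resname,
                           beadname = atname, stringsAsFactors = FALSE)
    }
    i <- i + n + 3L
    while (i <= length(lines) && !nzchar(trimws(lines[i]))) i <- i + 1L
  }
  if (!length(frames)) abort("no frames found in GRO file")
  if (is.character(topology)) topology <- read_topology_csv(topology, chain_order)
  if (is.null(topology)) {
    topology <- channel_topology(
      data.frame(chain = NA_character_, resnum = labels$resnum,
                 resname = labels$resname, beadname = labels$beadname,
                 species = species_from_resname(labels$resname),
                 leaflet = "none", stringsAsFactors = FALSE),
      chain_order = chain_order)
  } else if (n_beads(topology) != nb) {
    abort(sprintf("topology has %d beads but GRO frames have %d",
                  n_beads(topology), nb))
  }
  new_trajectory(topology, frames, source_label = basename(path))
}

#' Write a trajectory as a (multi-frame) GRO file
#'
#' Residue and atom numbers are wrapped modulo 100000 to fit the 5-column
#' fields. Coordinates are printed at the GRO 3-decimal precision.
#'
#' @param trajectory a `trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gro <- function(trajectory, path) {
  top <- trajectory$topology$beads
  resnum <- top$resnum %% 100000L
  atomnum <- seq_len(nrow(top)) %% 100000L
  con <- file(path, "w")
  on.exit(close(con))
  for (f in trajectory$frames) {
    if (any(!is.finite(f$coords))) {
      abort("write_gro: non-finite coordinate")
    }
    writeLines(sprintf("piezotraj t= %.3f", f$time), con)
    writeLines(sprintf("%5d", nrow(top)), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       resnum, substr(top$resname, 1, 5),
                       substr(top$beadname, 1, 5), atomnum,
                       f$coords[, 1], f$coords[, 2], f$coords[, 3]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", f$box[1], f$box[2], f$box[3]), con)
  }
  invisible(path)
}

#' Read a (multi-model) PDB file as a trajectory
#'
#' MODEL/ENDMDL blocks become frames; a file with no MODEL records is a
#' single frame. Coordinates are converted from Angstrom to nm; the box is
#' taken from CRYST1 (also converted) unless `box_nm` overrides it.
#'
#' @param path PDB file path.
#' @param topology optional `channel_topology` or topology CSV path.
#' @param box_nm optional length-3 box override in nm (required when the
#'   file has no CRYST1 record).
#' @param chain_order used when building a bare topology.
#' @return A `trajectory` with coordinates in nm.
#' @export
read_pdb <- function(path, topology = NULL, box_nm = NULL,
                     chain_order = c("A", "B", "C")) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) abort("PDB contains no ATOM/HETATM records")
  cryst <- lines[startsWith(rec, "CRYST1")]
  box <- box_nm
  if (is.null(box)) {
    if (length(cryst)) {
      box <- c(as.numeric(substr(cryst[1], 7, 15)),
               as.numeric(substr(cryst[1], 16, 24)),
               as.numeric(substr(cryst[1], 25, 33))) / 10
    } else {
      abort("PDB has no CRYST1 record and no box override was supplied")
    }
  }
  model_id <- cumsum(startsWith(rec, "MODEL "))
  if (max(model_id) == 0L) model_id <- model_id + 1L
  model_of_atoms <- model_id[is_atom]
  al <- lines[is_atom]
  atname  <- trimws(substr(al, 13, 16))
  resname <- trimws(substr(al, 18, 20))
  chain   <- trimws(substr(al, 22, 22))
  resnum  <- as.integer(substr(al, 23, 26))
  xyz <- cbind(as.numeric(substr(al, 31, 38)),
               as.numeric(substr(al, 39, 46)),
               as.numeric(substr(al, 47, 54))) / 10
  if (any(is.na(xyz))) abort("PDB parse error: bad coordinate field")
  ids <- sort(unique(model_of_atoms))
  nb <- sum(model_of_atoms == ids[1])
  frames <- lapply(seq_along(ids), function(j) {
    sel <- model_of_atoms == ids[j]
    if (sum(sel) != nb) abort("inconsistent atom count across MODEL blocks")
    new_frame(xyz[sel, , drop = FALSE], box, time = j - 1)
  })
  if (is.character(topology)) topology <- read_topology_csv(topology, chain_order)
  if (is.null(topology)) {
    first <- model_of_atoms == ids[1]
    chain1 <- chain[first]
    chain1[chain1 == ""] <- NA_character_
    topology <- channel_topology(
      data.frame(chain = chain1, resnum = resnum[first],
                 resname = resname[first], beadname = atname[first],
                 species = species_from_resname(resname[first]),
                 leaflet = "none", stringsAsFactors = FALSE),
      chain_order = chain_order)
  }
  new_trajectory(topology, frames, source_label = basename(path))
}
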