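#' Channel topology: bead annotations and named selections
#'
#' A `channel_topology` annotates every bead of a trajectory with chain,
#' residue number/name, bead name, lipid/protein species and leaflet, and
#' records the cyclic chain order that defines "clockwise" for the
#' interblade handshake pairing.
#'
#' @param beads data.frame with columns `chain` (character, `NA` for
#'   non-protein beads), `resnum` (integer >= 1), `resname`, `beadname`,
#'   `species` (one of `"protein"`, `"POPC"`, `"POPE"`, `"POPS"`, `"CHOL"`,
#'   `"PIP2"`, `"DPSM"`, `"solvent"`, `"ion"`), and `leaflet` (`"upper"`,
#'   `"lower"` or `"none"`).
#' @param chain_order character vector of the three chain identifiers in
#'   clockwise order as viewed from the extracellular (+z) side.
#' @return An object of class `channel_topology`.
#' @export
channel_topology <- function(beads, chain_order = c("A", "B", "C")) {
  required <- c("chain", "resnum", "resname", "beadname", "species", "leaflet")
  missing_cols <- setdiff(required, names(beads))
  if (length(missing_cols)) {
    abort(sprintf("topology is missing columns: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  beads <- as.data.frame(beads, stringsAsFactors = FALSE)
  beads$resnum <- as.integer(beads$resnum)
  if (any(beads$resnum < 1L, na.rm = TRUE)) {
    abort("residue numbers must be >= 1")
  }
  bad <- beads$species == "protein" & beads$leaflet != "none"
  if (any(bad, na.rm = TRUE)) {
    abort("protein beads must have leaflet = 'none'")
  }
  structure(list(beads = beads, chain_order = chain_order),
            class = "channel_topology")
}

#' @export
print.channel_topology <- function(x, ...) {
  cat(sprintf("channel_topology: %d beads, chains [%s]\n",
              nrow(x$beads), paste(x$chain_order, collapse = ", ")))
  cat("species:", paste(sprintf("%s=%d", names(table(x$beads$species)),
                                as.integer(table(x$beads$species))),
                        collapse = " "), "\n")
  invisible(x)
}

n_beads <- function(topology) nrow(topology$beads)

#' Select bead indices from a topology
#'
#' All filters are combined with AND; `NULL` means "no constraint".
#'
#' @param topology a `channel_topology`.
#' @param chain,resnum,resname,beadname,species,leaflet optional filters.
#' @param allow_empty if `FALSE` (default) an empty selection is an error.
#' @return Integer vector of bead indices (1-based).
#' @export
select_beads <- function(topology, chain = NULL, resnum = NULL,
                         resname = NULL, beadname = NULL, species = NULL,
                         leaflet = NULL, allow_empty = FALSE) {
  b <- topology$beads
  keep <- rep(TRUE, nrow(b))
  if (!is.null(chain))    keep <- keep & !is.na(b$chain) & b$chain %in% chain
  if (!is.null(resnum))   keep <- keep & b$resnum %in% resnum
  if (!is.null(resname))  keep <- keep & b$resname %in% resname
  if (!is.null(beadname)) keep <- keep & b$beadname %in% beadname
  if (!is.null(species))  keep <- keep & b$species %in% species
  if (!is.null(leaflet))  keep <- keep & b$leaflet %in% leaflet
  idx <- which(keep)
  if (!length(idx) && !allow_empty) {
    abort(paste0("selection is empty (chain=", paste(chain, collapse = ","),
                 " resnum=", paste(range(resnum), collapse = ":"),
                 " resname=", paste(resname, collapse = ","),
                 " species=", paste(species, collapse = ","), ")"))
  }
  idx
}

#' Canonical residue/selection scheme for the trimeric channel
#'
#' Residue numbering follows human PIEZO1: short handshake helix (SH)
#' 176-203 with tip 176, long helix (LH) 1912-1951 with tip 1912, inner
#' pore helix 2433-2462 with level markers Y2444 (top), V2450 (middle,
#' L2449 as the rotated substitute), F2454 (bottom), and the blade area
#' marker L71. Blade transmembrane helical units are labelled by residue
#' name `THU1` ... `THU9`.
#'
#' @return A named list of residue numbers / name conventions that analysis
#'   functions use to resolve selections; override entries to adapt the
#'   pipeline to other numbering schemes.
#' @export
selection_scheme <- function() {
  list(
    sh_residues   = 176:203,
    lh_residues   = 1912:1951,
    sh_tip        = 176L,
    lh_tip        = 1912L,
    pore_inner    = 2433:2462,
    pore_top      = 2444L,
    pore_middle   = 2450L,
    pore_middle_alt = 2449L,
    pore_bottom   = 2454L,
    area_marker   = 71L,
    thu_resnames  = paste0("THU", 1:9),
    phosphate_beadname = "PO4"
  )
}

#' Clockwise handshake pairing
#'
#' Each handshake pair joins the SH tip of one chain to the LH tip of its
#' clockwise neighbour (viewed from the extracellular, +z side).
#'
#' @param topology a `channel_topology`.
#' @return data.frame with columns `pair`, `sh_chain`, `lh_chain`.
#' @export
handshake_pairing <- function(topology) {
  ord <- topology$chain_order
  if (length(ord) != 3L) abort("chain_order must name exactly three chains")
  data.frame(pair = 1:3,
             sh_chain = ord,
             lh_chain = ord[c(2L, 3L, 1L)],
             stringsAsFactors = FALSE)
}

#' Read / write the topology annotation sidecar
#'
#' CSV columns: `index`, `chain`, `resnum`, `resname`, `beadname`,
#' `species`, `leaflet`. Rows must be ordered by `index`.
#'
#' @param path file path.
#' @param chain_order passed to [channel_topology()].
#' @return `read_topology_csv()` returns a `channel_topology`.
#' @export
read_topology_csv <- function(path, chain_order = c("A", "B", "C")) {
  if (!file.exists(path)) abort(sprintf("topology file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(chain = "character"))
  if (!"index" %in% names(df)) abort("topology CSV must have an 'index' column")
  df <- df[order(df$index), , drop = FALSE]
  if (!identical(as.integer(df$index), seq_len(nrow(df)))) {
    abort("topology CSV 'index' must be 1..n without gaps")
  }
  df$chain[df$chain %in% c("", "NA")] <- NA_character_
  channel_topology(df[, c("chain", "resnum", "resname", "beadname",
                          "species", "leaflet")],
                   chain_order = chain_order)
}

#' @rdname read_topology_csv
#' @param topology a `channel_topology` to write.
#' @export
write_topology_csv <- function(topology, path) {
  df <- topology$beads
  out <- cbind(index = seq_len(nrow(df)), df)
  out$chain[is.na(out$chain)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
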