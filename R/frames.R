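#' Coarse-grained coordinate frame set
#'
#' Container for one or more monolayer coordinate frames: per-particle
#' positions (nm), an orthorhombic box per frame (nm), and a constant
#' particle table (residue name, bead name, residue index).
#'
#' @param frames list of frames; each frame is a list with `xyz`
#'   (n x 3 numeric matrix, nm) and `box` (length-3 edge lengths, nm).
#' @param atoms data.frame with columns `resname`, `bead`, `resid`
#'   (one row per particle, same order as `xyz` rows).
#' @return object of class `frame_set`.
#' @export
frame_set <- function(frames, atoms) {
  if (length(frames) == 0L) abort_input("no frames")
  n <- nrow(atoms)
  for (f in frames) {
    if (!is.matrix(f$xyz) || ncol(f$xyz) != 3L || nrow(f$xyz) != n) {
      abort_input("every frame must have an n x 3 coordinate matrix matching the particle table")
    }
    if (length(f$box) != 3L || any(f$box <= 0)) {
      abort_input("box edges must be 3 positive lengths")
    }
  }
  structure(list(frames = frames, atoms = atoms), class = "frame_set")
}

#' @export
print.frame_set <- function(x, ...) {
  cat(sprintf("frame_set: %d frame(s), %d particles, %d residues\n",
              length(x$frames), nrow(x$atoms), length(unique(x$atoms$resid))))
  invisible(x)
}

#' Number of frames in a frame set
#' @param fs a [frame_set()].
#' @export
n_frames <- function(fs) length(fs$frames)

#' Select particles by residue and/or bead name
#'
#' @param fs a [frame_set()].
#' @param resname character vector of residue names to keep (NULL = all).
#' @param bead character vector of bead names to keep (NULL = all).
#' @param resid integer vector of residue indices to keep (NULL = all).
#' @return integer particle indices (rows of the particle table).
#' @export
select_beads <- function(fs, resname = NULL, bead = NULL, resid = NULL) {
  keep <- rep(TRUE, nrow(fs$atoms))
  if (!is.null(resname)) keep <- keep & fs$atoms$resname %in% resname
  if (!is.null(bead))    keep <- keep & fs$atoms$bead %in% bead
  if (!is.null(resid))   keep <- keep & fs$atoms$resid %in% resid
  which(keep)
}

#' Acyl-chain bead topology for the order-parameter calculation
#'
#' For each lipid species, the ordered bead names of the sn-1 and sn-2
#' chains; consecutive names define the bonds whose tilt is measured.
#' Defaults follow MARTINI four-bead tails with the unsaturated bead (D)
#' on the sn-1 chain of POPC and POPG.
#'
#' @param species named list; each element is a list with character vectors
#'   `sn1` and `sn2`.
#' @return object of class `chain_topology`.
#' @export
chain_topology <- function(species = default_chain_topology()) {
  structure(species, class = "chain_topology")
}

#' @rdname chain_topology
#' @export
default_chain_topology <- function() {
  sat <- c("C1", "C2", "C3", "C4")
  uns <- c("C1", "D2", "C3", "C4")
  list(
    DPPC = list(sn1 = paste0(sat, "A"), sn2 = paste0(sat, "B")),
    POPC = list(sn1 = paste0(uns, "A"), sn2 = paste0(sat, "B")),
    POPG = list(sn1 = paste0(uns, "A"), sn2 = paste0(sat, "B"))
  )
}
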