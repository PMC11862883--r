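# Readers and writers: delimited tables, GRO / PDB / XYZ coordinate files.
# Internal canonical units: nm for coordinates, Angstrom^2 for APL, mN/m
# for pressures/tensions/moduli, V for potentials, bar for input pressure
# tensors. Units are never guessed from file contents.

#' Read a delimited numeric table
#'
#' Delimiter is auto-detected among comma, tab, and whitespace; an optional
#' single header line is detected by non-numeric first-row cells. Cells
#' must be numeric; a parse failure reports the offending row and column.
#'
#' @param path file path.
#' @param n_cols expected number of columns (NULL = any).
#' @return data.frame of numeric columns (header names kept when present).
#' @export
read_table_auto <- function(path, n_cols = NULL) {
  if (!file.exists(path)) abort_input(paste("file not found:", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort_input(paste("empty file:", path))
  sep <- if (grepl(",", lines[1L], fixed = TRUE)) "," else
    if (grepl("\t", lines[1L], fixed = TRUE)) "\t" else ""
  split_row <- function(ln) {
    if (sep == "") strsplit(trimws(ln), "[ \t]+")[[1L]] else
      trimws(strsplit(ln, sep, fixed = TRUE)[[1L]])
  }
  first <- split_row(lines[1L])
  has_header <- any(is.na(suppressWarnings(as.numeric(first))))
  header <- if (has_header) first else NULL
  data_lines <- if (has_header) lines[-1L] else lines
  rows <- lapply(data_lines, split_row)
  ncol_file <- length(rows[[1L]])
  if (!is.null(n_cols) && ncol_file < n_cols) {
    abort_input(sprintf("expected %d columns, found %d", n_cols, ncol_file))
  }
  out <- matrix(NA_real_, length(rows), ncol_file)
  for (i in seq_along(rows)) {
    if (length(rows[[i]]) != ncol_file) {
      abort_input(sprintf("row %d has %d fields, expected %d",
                          i + has_header, length(rows[[i]]), ncol_file))
    }
    v <- suppressWarnings(as.numeric(rows[[i]]))
    if (any(is.na(v))) {
      abort_input(sprintf("non-numeric cell at row %d, column %d",
                          i + has_header, which(is.na(v))[1L]))
    }
    out[i, ] <- v
  }
  out <- as.data.frame(out)
  names(out) <- if (!is.null(header)) make.names(header) else
    paste0("V", seq_len(ncol_file))
  out
}

#' Read coordinate frames from GRO, PDB or XYZ files
#'
#' Coordinates are stored in nm internally (PDB Angstrom are converted;
#' XYZ units are declared by the caller). Residue and bead names are kept
#' verbatim. Multi-frame files (concatenated GRO blocks, PDB MODELs,
#' stacked XYZ blocks) are supported; the particle count must be constant.
#' XYZ carries no box, so a sidecar file (one "lx ly lz" line per frame,
#' same units as the coordinates) is required.
#'
#' @param path coordinate file; format from the extension (.gro/.pdb/.xyz)
#'   unless `format` is given.
#' @param format "gro", "pdb" or "xyz".
#' @param box_sidecar path to the XYZ box file; defaults to `path` with a
#'   ".box" extension appended.
#' @param xyz_unit "nm" or "angstrom" for XYZ input.
#' @return a [frame_set()].
#' @export
read_frames <- function(path, format = NULL, box_sidecar = NULL,
                        xyz_unit = c("nm", "angstrom")) {
  if (!file.exists(path)) abort_input(paste("file not found:", path))
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  switch(format,
         gro = read_gro(path),
         pdb = read_pdb_frames(path),
         xyz = read_xyz(path, box_sidecar, match.arg(xyz_unit)),
         abort_input(paste("unsupported coordinate format:", format)))
}

read_gro <- function(path) {
  lines <- readLines(path, warn = FALSE)
  frames <- list(); atoms <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    natoms <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(natoms) || i + 1L + natoms + 1L > length(lines)) {
      abort_input("truncated or malformed GRO file")
    }
    at <- lines[(i + 2L):(i + 1L + natoms)]
    resid <- as.integer(substr(at, 1L, 5L))
    resname <- trimws(substr(at, 6L, 10L))
    bead <- trimws(substr(at, 11L, 15L))
    xyz <- cbind(as.numeric(substr(at, 21L, 28L)),
                 as.numeric(substr(at, 29L, 36L)),
                 as.numeric(substr(at, 37L, 44L)))
    if (any(is.na(xyz))) abort_input("non-numeric coordinates in GRO file")
    box <- as.numeric(strsplit(trimws(lines[i + 2L + natoms]), "[ \t]+")[[1L]])[1:3]
    tab <- data.frame(resname = resname, bead = bead, resid = resid,
                      stringsAsFactors = FALSE)
    if (is.null(atoms)) atoms <- tab
    else if (nrow(tab) != nrow(atoms)) {
      abort_input("inconsistent particle counts across GRO frames")
    }
    frames[[length(frames) + 1L]] <- list(xyz = xyz, box = box)
    i <- i + 3L + natoms
  }
  if (length(frames) == 0L) abort_input("no frames in GRO file")
  frame_set(frames, atoms)
}

read_pdb_frames <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    abort_input("PDB reading requires the bio3d package")
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  a <- pdb$atom
  atoms <- data.frame(resname = trimws(a$resid), bead = trimws(a$elety),
                      resid = a$resno, stringsAsFactors = FALSE)
  box <- rep(10, 3)
  lines <- readLines(path, warn = FALSE)
  cr <- grep("^CRYST1", lines, value = TRUE)
  if (length(cr) > 0L) {
    box <- as.numeric(c(substr(cr[1L], 7, 15), substr(cr[1L], 16, 24),
                        substr(cr[1L], 25, 33)))
  }
  xyz_all <- pdb$xyz
  if (is.null(dim(xyz_all))) xyz_all <- matrix(xyz_all, nrow = 1L)
  frames <- lapply(seq_len(nrow(xyz_all)), function(f) {
    list(xyz = matrix(xyz_all[f, ], ncol = 3L, byrow = TRUE) / 10,  # A -> nm
         box = box / 10)
  })
  frame_set(frames, atoms)
}

read_xyz <- function(path, box_sidecar = NULL, unit = "nm") {
  if (is.null(box_sidecar)) box_sidecar <- paste0(path, ".box")
  if (!file.exists(box_sidecar)) {
    abort_input(paste("XYZ box sidecar not found:", box_sidecar))
  }
  scale <- if (unit == "angstrom") 0.1 else 1
  boxes <- as.matrix(read_table_auto(box_sidecar, n_cols = 3L)) * scale
  lines <- readLines(path, warn = FALSE)
  frames <- list(); atoms <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    natoms <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(natoms) || i + 1L + natoms > length(lines)) {
      abort_input("truncated or malformed XYZ file")
    }
    rows <- strsplit(trimws(lines[(i + 2L):(i + 1L + natoms)]), "[ \t]+")
    bead <- vapply(rows, `[`, character(1), 1L)
    xyz <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3))) * scale
    if (any(is.na(xyz))) abort_input("non-numeric coordinates in XYZ file")
    tab <- data.frame(resname = "UNK", bead = bead,
                      resid = seq_len(natoms), stringsAsFactors = FALSE)
    if (is.null(atoms)) atoms <- tab
    else if (nrow(tab) != nrow(atoms)) {
      abort_input("inconsistent particle counts across XYZ frames")
    }
    frames[[length(frames) + 1L]] <-
      list(xyz = xyz,
           box = unname(boxes[min(length(frames) + 1L, nrow(boxes)), ]))
    i <- i + 2L + natoms
  }
  if (length(frames) == 0L) abort_input("no frames in XYZ file")
  frame_set(frames, atoms)
}

#' Write a frame set as a (multi-frame) GRO file
#'
#' @param fs a [frame_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_frames <- function(fs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in fs$frames) {
    writeLines("monolayer scene", con)
    writeLines(sprintf("%5d", nrow(fs$atoms)), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       fs$atoms$resid %% 100000L, fs$atoms$resname,
                       fs$atoms$bead, seq_len(nrow(fs$atoms)) %% 100000L,
                       fr$xyz[, 1L], fr$xyz[, 2L], fr$xyz[, 3L]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", fr$box[1L], fr$box[2L], fr$box[3L]), con)
  }
  invisible(path)
}
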