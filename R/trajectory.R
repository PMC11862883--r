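#' Second-Legendre chain order parameters
#'
#' For every consecutive-bead bond of each chain in the topology,
#' P2 = (3 <cos^2 theta> - 1) / 2 with theta the angle between the bond
#' vector and the monolayer normal. The molecular average is taken per
#' frame; the reported value is the frame mean and the standard deviation
#' over frames. P2 = 1 means perfect alignment with the normal, -0.5
#' complete anti-alignment (bond in the monolayer plane), 0 isotropy.
#'
#' @param fs a [frame_set()].
#' @param topo a [chain_topology()].
#' @param normal monolayer normal (default z axis); normalized internally.
#' @return data.frame with columns `species`, `chain`, `bond`, `p2`, `sd`,
#'   `n_frames`.
#' @export
order_parameter <- function(fs, topo = chain_topology(), normal = c(0, 0, 1)) {
  normal <- normal / sqrt(sum(normal^2))
  key <- paste(fs$atoms$resid, fs$atoms$bead)
  out <- list()
  for (sp in names(topo)) {
    resids <- unique(fs$atoms$resid[fs$atoms$resname == sp])
    if (length(resids) == 0L) next
    for (chain in c("sn1", "sn2")) {
      beads <- topo[[sp]][[chain]]
      for (b in seq_len(length(beads) - 1L)) {
        i1 <- match(paste(resids, beads[b]), key)
        i2 <- match(paste(resids, beads[b + 1L]), key)
        bad <- resids[is.na(i1) | is.na(i2)]
        if (length(bad) > 0L) {
          abort_input(sprintf(
            "topology error: %s %s bond %s-%s unresolved for residues %s",
            sp, chain, beads[b], beads[b + 1L],
            paste(utils::head(bad, 5L), collapse = ", ")))
        }
        p2f <- vapply(fs$frames, function(fr) {
          v <- fr$xyz[i2, , drop = FALSE] - fr$xyz[i1, , drop = FALSE]
          cosang <- as.vector(v %*% normal) / sqrt(rowSums(v^2))
          mean((3 * cosang^2 - 1) / 2)
        }, numeric(1))
        out[[length(out) + 1L]] <- data.frame(
          species = sp, chain = chain,
          bond = paste(beads[b], beads[b + 1L], sep = "-"),
          p2 = mean(p2f),
          sd = if (length(p2f) > 1L) stats::sd(p2f) else 0,
          n_frames = length(p2f))
      }
    }
  }
  if (length(out) == 0L) abort_input("no topology species present in frame set")
  do.call(rbind, out)
}

#' Pressure-tensor time series
#'
#' @param t time, ps.
#' @param pxx,pyy,pzz diagonal pressure-tensor components, bar.
#' @param lz box height along the interface normal, nm.
#' @return object of class `pressure_series`.
#' @export
pressure_series <- function(t, pxx, pyy, pzz, lz) {
  n <- length(t)
  lz <- rep_len(lz, n)
  if (any(lengths(list(pxx, pyy, pzz)) != n)) abort_input("length mismatch")
  if (any(lz <= 0)) abort_input("lz must be > 0")
  if (any(!is.finite(c(pxx, pyy, pzz)))) abort_input("pressures must be finite")
  structure(data.frame(t = t, pxx = pxx, pyy = pyy, pzz = pzz, lz = lz),
            class = c("pressure_series", "data.frame"))
}

#' Surface tension from the diagonal pressure tensor
#'
#' gamma = (Lz / n_interfaces) <Pzz - (Pxx + Pyy)/2>, converted bar -> Pa
#' and nm -> m and reported in mN/m. The uncertainty is the standard error
#' of block means (block averaging).
#'
#' @param series a [pressure_series()].
#' @param n_interfaces number of interfaces in the slab (a symmetric
#'   double-monolayer system has 2).
#' @param n_blocks number of blocks for the error estimate.
#' @return list with `gamma` (mN/m), `se` (block standard error, mN/m;
#'   `NA` when the series is shorter than `n_blocks`), `n_blocks`.
#' @export
surface_tension <- function(series, n_interfaces = 2L, n_blocks = 5L) {
  if (n_interfaces < 1L) abort_input("n_interfaces must be >= 1")
  if (nrow(series) == 0L) abort_input("empty pressure series")
  # per-sample gamma: bar*nm = 1e5 Pa * 1e-9 m = 1e-4 N/m = 0.1 mN/m
  g <- series$lz * (series$pzz - (series$pxx + series$pyy) / 2) *
    0.1 / n_interfaces
  se <- NA_real_
  if (length(g) >= n_blocks) {
    blk <- split(g, cut(seq_along(g), n_blocks, labels = FALSE))
    bm <- vapply(blk, mean, numeric(1))
    se <- stats::sd(bm) / sqrt(n_blocks)
  }
  list(gamma = mean(g), se = se, n_blocks = n_blocks)
}

#' Number-density profile along a box axis
#'
#' Histogram of bead positions along the chosen axis, normalized by slab
#' volume and frame count, for one or more selections.
#'
#' @param fs a [frame_set()].
#' @param selections named list of integer particle-index vectors (from
#'   [select_beads()]).
#' @param axis 1, 2 or 3 (x, y, z).
#' @param bin bin width, nm (> 0).
#' @return data.frame with `coord` (bin center, nm), `selection`,
#'   `density` (nm^-3).
#' @export
density_profile <- function(fs, selections, axis = 3L, bin = 0.1) {
  if (bin <= 0) abort_input("bin must be > 0")
  if (length(selections) == 0L || any(lengths(selections) == 0L)) {
    abort_input("selections must be nonempty")
  }
  lo <- min(vapply(fs$frames, function(fr) min(fr$xyz[, axis]), numeric(1)))
  hi <- max(vapply(fs$frames, function(fr) max(fr$xyz[, axis]), numeric(1)))
  breaks <- seq(lo - bin / 2, hi + bin, by = bin)
  # cross-section area orthogonal to the axis, averaged over frames
  other <- setdiff(1:3, axis)
  area <- mean(vapply(fs$frames, function(fr) prod(fr$box[other]), numeric(1)))
  out <- list()
  for (nm in names(selections)) {
    idx <- selections[[nm]]
    counts <- 0
    for (fr in fs$frames) {
      counts <- counts + graphics::hist(fr$xyz[idx, axis], breaks = breaks,
                              plot = FALSE)$counts
    }
    out[[nm]] <- data.frame(
      coord = (breaks[-length(breaks)] + breaks[-1L]) / 2,
      selection = nm,
      density = counts / (area * bin * length(fs$frames)))
  }
  do.call(rbind, out)
}

#' Mean roughness Ra of a height profile
#'
#' Ra = mean |z_i - mean(z)|, the arithmetic average deviation used for
#' AFM line sections.
#'
#' @param heights ordered height samples (any consistent length unit).
#' @return Ra in the same unit.
#' @export
roughness_ra <- function(heights) {
  if (length(heights) < 2L) abort_input("need at least 2 height samples")
  mean(abs(heights - mean(heights)))
}
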