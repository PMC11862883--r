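# Monolayer defect detection: pores in the lateral plane and
# out-of-plane collapse of the head-group layer.

#' Detect pores in a monolayer frame
#'
#' Lipid beads are projected onto the x-y plane and an occupancy grid is
#' built: a cell is occupied when any bead lies within `footprint` of its
#' center (periodic in both directions). Connected components of empty
#' cells (4-connectivity, periodic) with area at least `min_area` are
#' reported as pores.
#'
#' The raw grid area of an empty component underestimates the true open
#' area by a boundary ring: the occupancy dilation reaches `footprint`
#' beyond the bead centers, while the physical film edge lies about half a
#' molecular spacing beyond the outermost bead centers. A corrected
#' estimate dilates each component back by `footprint - film_spacing / 2`
#' via the Steiner formula, area + perimeter x r + pi r^2 (the staircase
#' perimeter is scaled by pi/4 to remove grid bias), and is reported as
#' `area` alongside `area_raw`.
#'
#' @param fs a [frame_set()].
#' @param lipid_selection integer particle indices to treat as film
#'   material.
#' @param frame frame number to analyze.
#' @param grid_cell target grid cell size, nm (> 0).
#' @param min_area minimum raw component area to count as a pore, nm^2.
#' @param footprint bead footprint radius, nm; should be at least half the
#'   typical in-plane bead spacing so an intact film has no spurious holes.
#' @param film_spacing typical in-plane molecular spacing of the film, nm
#'   (e.g. sqrt(APL)); 0 treats the film edge as the bead centers
#'   themselves, appropriate for densely sampled films.
#' @return list with `n_pores` and `pores` (data.frame: `area_raw`,
#'   `area`, `n_cells`).
#' @export
detect_pores <- function(fs, lipid_selection, frame = 1L, grid_cell = 0.2,
                         min_area = 1.0, footprint = 0.5, film_spacing = 0) {
  if (grid_cell <= 0) abort_input("grid_cell must be > 0")
  if (length(lipid_selection) == 0L) abort_input("lipid selection is empty")
  fr <- fs$frames[[frame]]
  box <- fr$box
  nx <- max(2L, round(box[1L] / grid_cell))
  ny <- max(2L, round(box[2L] / grid_cell))
  cx <- box[1L] / nx
  cy <- box[2L] / ny
  x <- fr$xyz[lipid_selection, 1L] %% box[1L]
  y <- fr$xyz[lipid_selection, 2L] %% box[2L]
  occ <- matrix(FALSE, nx, ny)
  # mark all cells whose center lies within `footprint` of a bead
  kx <- ceiling(footprint / cx)
  ky <- ceiling(footprint / cy)
  ci <- floor(x / cx)                      # 0-based bead cell
  cj <- floor(y / cy)
  for (di in -kx:kx) {
    for (dj in -ky:ky) {
      ii <- (ci + di) %% nx
      jj <- (cj + dj) %% ny
      ccx <- (ii + 0.5) * cx
      ccy <- (jj + 0.5) * cy
      dx <- ccx - x; dx <- dx - box[1L] * round(dx / box[1L])
      dy <- ccy - y; dy <- dy - box[2L] * round(dy / box[2L])
      hit <- dx * dx + dy * dy <= footprint^2
      if (any(hit)) occ[cbind(ii[hit] + 1L, jj[hit] + 1L)] <- TRUE
    }
  }
  comp <- label_components(!occ, periodic = TRUE)
  cell_area <- cx * cy
  r_c <- max(footprint - film_spacing / 2, 0)
  pores <- list()
  for (lab in seq_len(comp$n)) {
    cells <- which(comp$labels == lab)
    raw <- length(cells) * cell_area
    if (raw < min_area) next
    per <- component_perimeter(comp$labels == lab, cx, cy) * pi / 4
    pores[[length(pores) + 1L]] <- data.frame(
      area_raw = raw,
      area = raw + per * r_c + pi * r_c^2,
      n_cells = length(cells))
  }
  pores <- if (length(pores)) do.call(rbind, pores) else
    data.frame(area_raw = numeric(0), area = numeric(0), n_cells = integer(0))
  list(n_pores = nrow(pores), pores = pores)
}

# Label connected components of TRUE cells in a logical matrix
# (4-connectivity, optionally periodic). Returns integer labels (0 for
# FALSE cells) and the component count.
label_components <- function(mask, periodic = TRUE) {
  nx <- nrow(mask); ny <- ncol(mask)
  labels <- matrix(0L, nx, ny)
  n <- 0L
  wrap <- function(i, m) if (periodic) ((i - 1L) %% m) + 1L else i
  for (start in which(mask)) {
    if (labels[start] != 0L) next
    n <- n + 1L
    queue <- start
    labels[start] <- n
    while (length(queue) > 0L) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      i <- ((cur - 1L) %% nx) + 1L
      j <- ((cur - 1L) %/% nx) + 1L
      for (nb in list(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L), c(i, j + 1L))) {
        ii <- nb[1L]; jj <- nb[2L]
        if (!periodic && (ii < 1L || ii > nx || jj < 1L || jj > ny)) next
        ii <- wrap(ii, nx); jj <- wrap(jj, ny)
        if (mask[ii, jj] && labels[ii, jj] == 0L) {
          labels[ii, jj] <- n
          queue <- c(queue, (jj - 1L) * nx + ii)
        }
      }
    }
  }
  list(labels = labels, n = n)
}

# Staircase perimeter of a component: boundary edge count times edge
# length (periodic neighbors).
component_perimeter <- function(mask, cx, cy) {
  nx <- nrow(mask); ny <- ncol(mask)
  right <- mask[c(2:nx, 1L), , drop = FALSE]
  up <- mask[, c(2:ny, 1L), drop = FALSE]
  # vertical edges have length cy, horizontal edges length cx
  sum(mask != right) * cy + sum(mask != up) * cx
}

#' Detect out-of-plane collapse from head-group z-spread
#'
#' The z-spread of the head-bead layer is measured per frame as the
#' interdecile range (q90 - q10). A frame is flagged as collapsed when the
#' spread exceeds `spread_threshold`; by default the threshold is 3 times
#' the first frame's spread (the flat-monolayer baseline). The bimodality
#' coefficient of the z distribution is reported as a secondary indicator
#' (values above ~0.555 suggest two layers).
#'
#' @param fs a [frame_set()].
#' @param head_selection integer particle indices of head beads.
#' @param spread_threshold absolute threshold in nm, or `NULL` for
#'   3 x baseline.
#' @return data.frame with `frame`, `spread` (nm), `collapsed`,
#'   `bimodality`; the threshold used is attached as attribute
#'   `threshold`.
#' @export
detect_collapse_3d <- function(fs, head_selection, spread_threshold = NULL) {
  if (length(head_selection) == 0L) abort_input("head selection is empty")
  spread <- vapply(fs$frames, function(fr) {
    # empirical (type 1) deciles: a displaced subpopulation sitting exactly
    # at the decile boundary still registers
    q <- stats::quantile(fr$xyz[head_selection, 3L], c(0.1, 0.9),
                         names = FALSE, type = 1)
    q[2L] - q[1L]
  }, numeric(1))
  if (is.null(spread_threshold)) spread_threshold <- 3 * spread[1L]
  bimod <- vapply(fs$frames, function(fr) {
    z <- fr$xyz[head_selection, 3L]
    n <- length(z)
    m <- mean(z); s <- stats::sd(z)
    if (s == 0 || n < 4L) return(NA_real_)
    g1 <- mean((z - m)^3) / s^3
    g2 <- mean((z - m)^4) / s^4 - 3
    (g1^2 + 1) / (g2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
  }, numeric(1))
  structure(data.frame(frame = seq_along(fs$frames), spread = spread,
                       collapsed = spread > spread_threshold,
                       bimodality = bimod),
            threshold = spread_threshold)
}
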