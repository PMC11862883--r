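# Pair statistics: radial distribution functions and drug clustering.

# Histogram of minimum-image pair distances between particle sets i and j
# in one frame, accumulated in chunks so no n_i x n_j matrix is ever
# materialized. With `self = TRUE` (i and j the same set) every unordered
# pair is counted once. Distances of exactly zero are excluded.
pair_dist_hist <- function(xyz, box, i, j, breaks, self = FALSE,
                           lateral = FALSE) {
  counts <- numeric(length(breaks) - 1L)
  r_max <- breaks[length(breaks)]
  chunk <- max(1L, floor(2e6 / max(length(j), 1L)))
  for (start in seq(1L, length(i), by = chunk)) {
    ii <- i[start:min(length(i), start + chunk - 1L)]
    d1 <- rep(xyz[ii, 1L], times = length(j)) - rep(xyz[j, 1L], each = length(ii))
    d1 <- d1 - box[1L] * round(d1 / box[1L])
    d2 <- rep(xyz[ii, 2L], times = length(j)) - rep(xyz[j, 2L], each = length(ii))
    d2 <- d2 - box[2L] * round(d2 / box[2L])
    r2 <- d1 * d1 + d2 * d2
    if (!lateral) {
      d3 <- rep(xyz[ii, 3L], times = length(j)) - rep(xyz[j, 3L], each = length(ii))
      d3 <- d3 - box[3L] * round(d3 / box[3L])
      r2 <- r2 + d3 * d3
    }
    r <- sqrt(r2[r2 > 0 & r2 <= r_max^2])
    if (length(r) > 0L) {
      counts <- counts + graphics::hist(r, breaks = breaks, plot = FALSE)$counts
    }
  }
  if (self) counts / 2 else counts
}

#' Radial distribution function between two bead selections
#'
#' Distance-histogram g(r) with minimum-image periodicity in an
#' orthorhombic box, normalized by the ideal-gas shell count at the mean
#' pair density. The default is the three-dimensional (spherical) g(r); a
#' two-dimensional lateral mode (distances and shell areas in the x-y
#' plane) is available since monolayer pair structure is often reported
#' laterally.
#'
#' @param fs a [frame_set()].
#' @param group_a,group_b integer particle indices (see [select_beads()]);
#'   identical selections give the self-RDF, otherwise the selections must
#'   be disjoint.
#' @param r_max cutoff distance, nm (must not exceed half the smallest
#'   relevant box edge).
#' @param n_bins number of histogram bins on (0, r_max].
#' @param mode "3d" (spherical) or "2d" (lateral).
#' @return object of class `rdf_result`: list with `r` (bin centers, nm),
#'   `g`, `counts` (summed pair counts per bin, for oracle checks),
#'   `mode`, `r_max`.
#' @export
rdf <- function(fs, group_a, group_b = group_a, r_max = 1.0, n_bins = 50L,
                mode = c("3d", "2d")) {
  mode <- match.arg(mode)
  if (length(group_a) == 0L || length(group_b) == 0L) {
    abort_input("selections must be nonempty")
  }
  self <- length(group_a) == length(group_b) &&
    all(sort(group_a) == sort(group_b))
  if (!self && length(intersect(group_a, group_b)) > 0L) {
    abort_input("selections must be identical or disjoint")
  }
  dims <- if (mode == "2d") 1:2 else 1:3
  min_edge <- min(vapply(fs$frames, function(fr) min(fr$box[dims]), numeric(1)))
  if (r_max > min_edge / 2) {
    abort_input("r_max exceeds half the smallest box edge")
  }
  breaks <- seq(0, r_max, length.out = n_bins + 1L)
  shell <- if (mode == "3d") 4 / 3 * pi * diff(breaks^3) else pi * diff(breaks^2)
  counts <- numeric(n_bins)
  ideal <- numeric(n_bins)
  for (fr in fs$frames) {
    counts <- counts + pair_dist_hist(fr$xyz, fr$box, group_a, group_b,
                                      breaks, self = self,
                                      lateral = mode == "2d")
    vol <- prod(fr$box[dims])
    n_pairs <- if (self) {
      length(group_a) * (length(group_a) - 1) / 2
    } else {
      length(group_a) * length(group_b)
    }
    ideal <- ideal + n_pairs * shell / vol
  }
  structure(list(r = (breaks[-1L] + breaks[-length(breaks)]) / 2,
                 g = ifelse(ideal > 0, counts / ideal, 0),
                 counts = counts, mode = mode, r_max = r_max),
            class = "rdf_result")
}

#' Drug aggregation: single-linkage clusters under a distance cutoff
#'
#' Two drug molecules belong to the same cluster when any bead pair between
#' them lies within `cutoff` (minimum-image); clusters are the connected
#' components of that relation (single linkage).
#'
#' @param fs a [frame_set()].
#' @param drug_selection integer particle indices of the drug beads.
#' @param cutoff linkage distance, nm (> 0).
#' @return list with one element per frame, each a list with `sizes`
#'   (cluster sizes, decreasing), `n_clusters`, and `largest_fraction`
#'   (largest cluster size / number of molecules).
#' @export
drug_clusters <- function(fs, drug_selection, cutoff) {
  if (cutoff <= 0) abort_input("cutoff must be > 0")
  if (length(drug_selection) == 0L) abort_input("drug selection is empty")
  mol <- fs$atoms$resid[drug_selection]
  mols <- sort(unique(mol))
  n_mol <- length(mols)
  mol_id <- match(mol, mols)
  n <- length(drug_selection)
  lapply(fs$frames, function(fr) {
    if (n_mol == 1L) {
      return(list(sizes = 1L, n_clusters = 1L, largest_fraction = 1))
    }
    xyz <- fr$xyz[drug_selection, , drop = FALSE]
    # bead pairs within cutoff -> molecule adjacency, chunked over rows
    parent <- seq_len(n_mol)
    find <- function(a) {
      while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }
      a
    }
    chunk <- max(1L, floor(2e6 / n))
    for (start in seq(1L, n, by = chunk)) {
      rows <- start:min(n, start + chunk - 1L)
      d1 <- rep(xyz[rows, 1L], times = n) - rep(xyz[, 1L], each = length(rows))
      d1 <- d1 - fr$box[1L] * round(d1 / fr$box[1L])
      d2 <- rep(xyz[rows, 2L], times = n) - rep(xyz[, 2L], each = length(rows))
      d2 <- d2 - fr$box[2L] * round(d2 / fr$box[2L])
      d3 <- rep(xyz[rows, 3L], times = n) - rep(xyz[, 3L], each = length(rows))
      d3 <- d3 - fr$box[3L] * round(d3 / fr$box[3L])
      hit <- which(d1 * d1 + d2 * d2 + d3 * d3 <= cutoff^2)
      if (length(hit) == 0L) next
      a_mol <- mol_id[rows[(hit - 1L) %% length(rows) + 1L]]
      b_mol <- mol_id[(hit - 1L) %/% length(rows) + 1L]
      keep <- a_mol != b_mol
      for (k in which(keep)) {
        ra <- find(a_mol[k]); rb <- find(b_mol[k])
        if (ra != rb) parent[ra] <- rb
      }
    }
    roots <- vapply(seq_len(n_mol), find, integer(1))
    sizes <- sort(as.integer(table(roots)), decreasing = TRUE)
    list(sizes = sizes, n_clusters = length(sizes),
         largest_fraction = sizes[1L] / n_mol)
  })
}
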