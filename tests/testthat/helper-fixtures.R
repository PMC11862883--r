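# Shared fixtures: a reduced lung-surfactant composition for fast scenes,
# and an O(n^2) brute-force pair-count oracle independent of the rdf code.

small_lung_composition <- function(total = 200L) {
  monolayer_composition(rbind(
    lipid_species("DPPC", 734.04, 0.60),
    lipid_species("POPC", 760.08, 0.20),
    lipid_species("POPG", 770.99, 0.10),
    lipid_species("CHOL", 386.65, 0.10)
  ), total_molecules = total, n_leaflets = 2L)
}

lipid_resnames <- c("DPPC", "POPC", "POPG", "CHOL")

# brute-force minimum-image pair histogram (plain double loop)
brute_pair_counts <- function(xyz, box, ia, ib, breaks, self = FALSE,
                              lateral = FALSE) {
  counts <- numeric(length(breaks) - 1L)
  r_max <- max(breaks)
  dims <- if (lateral) 1:2 else 1:3
  for (p in seq_along(ia)) {
    for (q in seq_along(ib)) {
      if (self && q <= p) next
      r2 <- 0
      for (k in dims) {
        d <- xyz[ia[p], k] - xyz[ib[q], k]
        d <- d - box[k] * round(d / box[k])
        r2 <- r2 + d * d
      }
      r <- sqrt(r2)
      if (r > 0 && r <= r_max) {
        bin <- findInterval(r, breaks, left.open = TRUE)
        counts[bin] <- counts[bin] + 1
      }
    }
  }
  counts
}
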