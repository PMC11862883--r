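test_that("rdf pair counts equal brute-force enumeration on small frames", {
  set.seed(31)
  for (rep_i in 1:3) {
    n <- 50
    xyz <- cbind(runif(n, 0, 4), runif(n, 0, 4), runif(n, 0, 4))
    fs <- frame_set(list(list(xyz = xyz, box = c(4, 4, 4))),
                    data.frame(resname = "P", bead = "B", resid = seq_len(n)))
    breaks <- seq(0, 1, length.out = 21)

    # self-RDF, 3d and lateral
    for (mode in c("3d", "2d")) {
      got <- rdf(fs, seq_len(n), seq_len(n), r_max = 1, n_bins = 20,
                 mode = mode)
      want <- brute_pair_counts(xyz, c(4, 4, 4), seq_len(n), seq_len(n),
                                breaks, self = TRUE, lateral = mode == "2d")
      expect_equal(got$counts, want)
    }

    # cross-RDF on disjoint halves
    ia <- 1:25; ib <- 26:50
    got <- rdf(fs, ia, ib, r_max = 1, n_bins = 20)
    want <- brute_pair_counts(xyz, c(4, 4, 4), ia, ib, breaks)
    expect_equal(got$counts, want)
  }
})

test_that("a fixed pair occupies exactly the bin of its separation", {
  fs <- frame_set(list(list(xyz = rbind(c(1, 1, 1), c(1.5, 1, 1)),
                            box = c(5, 5, 5))),
                  data.frame(resname = "P", bead = "B", resid = 1:2))
  r2 <- rdf(fs, 1L, 2L, r_max = 1, n_bins = 20)
  expect_equal(which(r2$counts > 0), 10L)   # bin (0.45, 0.5]
  expect_equal(sum(r2$counts), 1)
})

test_that("uniform random particles give g(r) near 1 and input checks hold", {
  set.seed(32)
  n <- 4000
  fs <- frame_set(list(list(xyz = matrix(runif(3 * n, 0, 10), ncol = 3),
                            box = c(10, 10, 10))),
                  data.frame(resname = "G", bead = "B", resid = seq_len(n)))
  r <- rdf(fs, seq_len(n), seq_len(n), r_max = 1, n_bins = 4)
  expect_true(all(abs(r$g - 1) < 0.1))

  expect_error(rdf(fs, seq_len(n), seq_len(n), r_max = 6), "half the smallest")
  expect_error(rdf(fs, integer(0), 1:3), "nonempty")
  expect_error(rdf(fs, 1:10, 5:20), "identical or disjoint")
})

test_that("single-linkage clustering recovers planted aggregates", {
  comp <- small_lung_composition()

  # all far apart -> singletons
  far <- gen_scene(apl = 60, composition = comp, seed = 41,
                   drug = list(count = 6L, mode = "aggregated",
                               cluster_sizes = rep(1L, 6)))
  cl_far <- drug_clusters(far, select_beads(far, resname = "MF"), cutoff = 0.6)
  expect_equal(cl_far[[1]]$sizes, rep(1L, 6))

  planted <- gen_scene(apl = 60, composition = comp, seed = 42,
                       drug = list(count = 10L, mode = "aggregated",
                                   cluster_sizes = c(5L, 3L, 2L)))
  cl <- drug_clusters(planted, select_beads(planted, resname = "MF"),
                      cutoff = 0.8)
  expect_equal(cl[[1]]$sizes, c(5L, 3L, 2L))
  expect_equal(cl[[1]]$largest_fraction, 0.5)

  # chain transitivity: one cluster of 6 in a row
  row6 <- gen_scene(apl = 60, composition = comp, seed = 43,
                    drug = list(count = 6L, mode = "aggregated",
                                cluster_sizes = 6L))
  cl6 <- drug_clusters(row6, select_beads(row6, resname = "MF"), cutoff = 0.8)
  expect_equal(cl6[[1]]$sizes, 6L)

  expect_error(drug_clusters(planted, integer(0), 0.5), "empty")
  expect_error(drug_clusters(planted, 1:4, 0), "> 0")
})

test_that("cluster sizes are invariant to particle ordering", {
  comp <- small_lung_composition()
  sc <- gen_scene(apl = 60, composition = comp, seed = 44,
                  drug = list(count = 9L, mode = "aggregated",
                              cluster_sizes = c(4L, 4L, 1L)))
  sel <- select_beads(sc, resname = "MF")
  ref <- drug_clusters(sc, sel, cutoff = 0.8)[[1]]$sizes

  set.seed(45)
  perm <- sample(nrow(sc$atoms))
  shuffled <- frame_set(list(list(xyz = sc$frames[[1]]$xyz[perm, ],
                                  box = sc$frames[[1]]$box)),
                        sc$atoms[perm, ])
  sel2 <- select_beads(shuffled, resname = "MF")
  expect_equal(drug_clusters(shuffled, sel2, cutoff = 0.8)[[1]]$sizes, ref)
})
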