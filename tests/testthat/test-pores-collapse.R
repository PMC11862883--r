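# Dense uniform film with excised disks: a geometric oracle where the true
# open area is the disk area.
dense_film <- function(seed, disks, n = 8000, L = 20) {
  set.seed(seed)
  xyz <- cbind(runif(n, 0, L), runif(n, 0, L), 4)
  keep <- rep(TRUE, n)
  for (k in seq_len(nrow(disks))) {
    keep <- keep & (xyz[, 1] - disks$x[k])^2 +
      (xyz[, 2] - disks$y[k])^2 > disks$r[k]^2
  }
  frame_set(list(list(xyz = xyz[keep, ], box = c(L, L, 12))),
            data.frame(resname = "F", bead = "B", resid = seq_len(sum(keep))))
}

test_that("an intact film has no pores; excised disks are found and measured", {
  sc <- gen_scene(apl = 49, composition = lung_surfactant_composition(),
                  seed = 51)
  lip <- select_beads(sc, resname = lipid_resnames)
  expect_equal(detect_pores(sc, lip)$n_pores, 0L)

  # dense-film geometric oracle: one disk of radius 2 -> area 4 pi within
  # one ring of grid cells (2 pi R * cell)
  spacing <- 1 / sqrt(8000 / 400)
  one <- dense_film(52, data.frame(x = 10, y = 10, r = 2))
  p1 <- detect_pores(one, seq_len(nrow(one$atoms)), grid_cell = 0.2,
                     footprint = 0.25, film_spacing = spacing)
  expect_equal(p1$n_pores, 1L)
  expect_equal(p1$pores$area, 4 * pi, tolerance = 2 * pi * 2 * 0.2 / (4 * pi))

  two <- dense_film(53, data.frame(x = c(5, 15), y = c(5, 15), r = c(2, 1.5)))
  p2 <- detect_pores(two, seq_len(nrow(two$atoms)), grid_cell = 0.2,
                     footprint = 0.25, film_spacing = spacing)
  expect_equal(p2$n_pores, 2L)

  expect_error(detect_pores(sc, lip, grid_cell = 0), "> 0")
  expect_error(detect_pores(sc, integer(0)), "empty")
})

test_that("pore area estimates tighten toward the disk area as the grid refines", {
  spacing <- 1 / sqrt(8000 / 400)
  film <- dense_film(54, data.frame(x = 10, y = 10, r = 2))
  for (cell in c(0.4, 0.2, 0.1)) {
    p <- detect_pores(film, seq_len(nrow(film$atoms)), grid_cell = cell,
                      footprint = 0.25, film_spacing = spacing)
    expect_equal(p$n_pores, 1L)
    expect_equal(p$pores$area, 4 * pi,
                 tolerance = 2 * pi * 2 * cell / (4 * pi))
  }
})

test_that("scene pores planted by the generator are recovered", {
  sc <- gen_scene(apl = 49, composition = lung_surfactant_composition(),
                  seed = 55, pores = data.frame(x = 8, y = 8, radius = 2))
  lip <- select_beads(sc, resname = lipid_resnames)
  truth <- attr(sc, "ground_truth")$pores
  p <- detect_pores(sc, lip, grid_cell = 0.2, film_spacing = sqrt(49) / 10)
  expect_equal(p$n_pores, 1L)
  expect_equal(p$pores$area, truth$area,
               tolerance = 2 * pi * truth$radius * 0.2 / truth$area)
})

test_that("collapse flags respond to head-group displacement, not flat films", {
  comp <- small_lung_composition()
  flat <- gen_scene(apl = 60, composition = comp, seed = 61, n_frames = 2)
  heads <- select_beads(flat, bead = "PO4")
  cf <- detect_collapse_3d(flat, heads)
  expect_false(any(cf$collapsed))

  # exactly 10% of heads displaced 3 nm below the plane -> collapsed
  set.seed(63)
  z <- rnorm(100, 4, 0.1)
  z[1:10] <- z[1:10] - 3
  built <- frame_set(list(list(xyz = cbind(runif(100, 0, 10),
                                           runif(100, 0, 10), z),
                               box = c(10, 10, 12))),
                     data.frame(resname = "L", bead = "PO4", resid = 1:100))
  cb <- detect_collapse_3d(built, 1:100, spread_threshold = 1)
  expect_true(all(cb$collapsed))
  expect_gt(cb$spread[1], 1)

  fallen <- gen_scene(apl = 60, composition = comp, seed = 62,
                      collapse = list(fraction = 0.15, displacement = 3))
  hf <- select_beads(fallen, bead = "PO4")
  cc <- detect_collapse_3d(fallen, hf, spread_threshold = 1)
  expect_true(all(cc$collapsed))
  expect_gt(cc$spread[1], 1)

  never <- detect_collapse_3d(fallen, hf, spread_threshold = Inf)
  expect_false(any(never$collapsed))

  expect_error(detect_collapse_3d(flat, integer(0)), "empty")
})
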