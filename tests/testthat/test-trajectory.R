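test_that("order parameter hits its exact limits on delta-tilt scenes", {
  comp <- small_lung_composition()
  up <- gen_scene(apl = 60, tilt = list(type = "delta", theta = 0),
                  composition = comp, seed = 1)
  expect_equal(order_parameter(up)$p2, rep(1, 18), tolerance = 1e-12)

  flat <- gen_scene(apl = 60, tilt = list(type = "delta", theta = 90),
                    composition = comp, seed = 1)
  expect_equal(order_parameter(flat)$p2, rep(-0.5, 18), tolerance = 1e-12)

  # P2(60 deg) = (3 cos^2 60 - 1)/2 = -0.125
  mid <- gen_scene(apl = 60, tilt = list(type = "delta", theta = 60),
                   composition = comp, seed = 2)
  expect_equal(order_parameter(mid)$p2, rep(-0.125, 18), tolerance = 1e-12)
})

test_that("isotropically oriented bonds give a vanishing order parameter", {
  set.seed(11)
  n <- 1e5
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  start <- matrix(runif(3 * n, 0, 50), ncol = 3)
  xyz <- matrix(NA_real_, 2 * n, 3)
  xyz[seq(1, 2 * n, by = 2), ] <- start
  xyz[seq(2, 2 * n, by = 2), ] <- start + 0.47 * u
  atoms <- data.frame(resname = "ISO",
                      bead = rep(c("B1", "B2"), n),
                      resid = rep(seq_len(n), each = 2))
  fs <- frame_set(list(list(xyz = xyz, box = c(60, 60, 60))), atoms)
  topo <- chain_topology(list(ISO = list(sn1 = c("B1", "B2"),
                                         sn2 = c("B1", "B2"))))
  p2 <- order_parameter(fs, topo)$p2
  expect_true(all(abs(p2) < 0.01))
})

test_that("order parameter is invariant to rigid translation and in-plane rotation", {
  sc <- gen_scene(apl = 60, tilt = list(type = "gaussian", theta = 25, sd = 8),
                  composition = small_lung_composition(), seed = 5)
  ref <- order_parameter(sc)$p2

  shift <- sc
  shift$frames[[1]]$xyz <- sweep(shift$frames[[1]]$xyz, 2, c(1.3, -0.7, 2.1), "+")
  expect_equal(order_parameter(shift)$p2, ref, tolerance = 1e-12)

  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rotated <- sc
  rotated$frames[[1]]$xyz <- sc$frames[[1]]$xyz %*% rot
  expect_equal(order_parameter(rotated)$p2, ref, tolerance = 1e-10)
})

test_that("unresolvable topology beads raise a topology error naming them", {
  sc <- gen_scene(apl = 60, composition = small_lung_composition(), seed = 3)
  bad <- chain_topology(list(DPPC = list(sn1 = c("C1A", "C9A"),
                                         sn2 = c("C1B", "C2B"))))
  expect_error(order_parameter(sc, bad), "C9A")
})

test_that("surface tension converts the pressure anisotropy correctly", {
  n <- 50
  iso_t <- pressure_series(1:n, rep(100, n), rep(100, n), rep(100, n), 20)
  expect_equal(surface_tension(iso_t)$gamma, 0)

  # 100 bar anisotropy, Lz 20 nm, 2 interfaces -> (10 nm)(10^7 Pa) = 100 mN/m
  aniso <- pressure_series(1:n, rep(0, n), rep(0, n), rep(100, n), 20)
  expect_equal(surface_tension(aniso)$gamma, 100)

  flipped <- pressure_series(1:n, rep(0, n), rep(0, n), rep(-100, n), 20)
  expect_equal(surface_tension(flipped)$gamma, -100)

  # linear in anisotropy and in Lz
  zero <- rep(0, n)
  expect_equal(surface_tension(pressure_series(1:n, zero, zero, rep(50, n), 20))$gamma, 50)
  expect_equal(surface_tension(pressure_series(1:n, zero, zero, rep(100, n), 10))$gamma, 50)

  expect_error(surface_tension(aniso, n_interfaces = 0), ">= 1")
})

test_that("density profile localizes selections and recovers uniformity", {
  set.seed(21)
  n <- 4000
  fs <- frame_set(list(list(xyz = cbind(runif(n, 0, 10), runif(n, 0, 10),
                                        runif(n, 0, 10)),
                            box = c(10, 10, 10))),
                  data.frame(resname = "U", bead = "B", resid = seq_len(n)))
  prof <- density_profile(fs, list(all = seq_len(n)), axis = 3, bin = 1)
  inner <- prof$density[prof$coord > 1 & prof$coord < 9]
  expect_equal(inner, rep(mean(inner), length(inner)), tolerance = 0.2)

  one <- frame_set(list(list(xyz = cbind(rep(1, 10), rep(1, 10), rep(5, 10)),
                             box = c(10, 10, 10))),
                   data.frame(resname = "U", bead = "B", resid = 1:10))
  p1 <- density_profile(one, list(s = 1:10), axis = 3, bin = 0.5)
  expect_equal(sum(p1$density > 0), 1L)

  # dispersed drugs sit around the head-bead plane
  sc <- gen_scene(apl = 60, composition = small_lung_composition(), seed = 9,
                  drug = list(count = 30L, mode = "dispersed"))
  prof2 <- density_profile(sc, list(head = select_beads(sc, bead = "PO4"),
                                    drug = select_beads(sc, resname = "MF")),
                           axis = 3, bin = 0.25)
  mode_of <- function(sel) {
    d <- prof2[prof2$selection == sel, ]
    d$coord[which.max(d$density)]
  }
  expect_lt(abs(mode_of("head") - mode_of("drug")), 0.25 + 1e-9)

  expect_error(density_profile(sc, list(), bin = 0.1), "nonempty")
  expect_error(density_profile(sc, list(a = 1:3), bin = 0), "> 0")
})

test_that("mean roughness matches closed forms", {
  expect_equal(roughness_ra(rep(3.2, 50)), 0)
  h <- 0.7
  expect_equal(roughness_ra(rep(c(h, -h), 100)), h)
  x <- seq(0, 2 * pi, length.out = 20001)[-20001]
  a <- 1.5
  expect_equal(roughness_ra(a * sin(x)), 2 * a / pi, tolerance = 0.01)
  expect_error(roughness_ra(1), "at least 2")
})
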