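# Ground-truth generators. Every generator returns a regular analysis
# substrate with a `ground_truth` attribute recording the parameters it
# embeds, so each analysis operation can be tested for parameter recovery
# without molecular dynamics runs or instrument data.

#' Generate a piecewise-phase compression isotherm
#'
#' The pressure is zero above the lift-off area; below it, each segment
#' prescribes a constant compression modulus Cs^-1, so within a segment
#' dpi/dA = -Cs^-1 / A and the pressure grows by Cs^-1 ln(A1/A2) (the
#' curve and its slope are continuous across segment boundaries). The
#' pressure is capped at the collapse plateau. Defaults emulate a
#' lung-surfactant mixture: lift-off 86 A^2, a soft liquid-expanded
#' segment, an intermediate LE-LC segment with Cs^-1 below 100 mN/m, and
#' collapse at 42 mN/m.
#'
#' @param lift_off_apl lift-off area, Angstrom^2.
#' @param segments data.frame with columns `apl_from`, `apl_to`, `cs_inv`
#'   (contiguous, decreasing APL; `apl_from` of the first segment is the
#'   lift-off area).
#' @param collapse_pi collapse plateau pressure, mN/m (> 0); `Inf` for no
#'   collapse.
#' @param apl_min,apl_max grid limits, Angstrom^2.
#' @param n number of samples.
#' @param noise_sd Gaussian pressure noise, mN/m.
#' @param seed integer seed (RNG state is restored afterwards).
#' @return an [isotherm()] with attribute `ground_truth`.
#' @export
gen_isotherm <- function(lift_off_apl = 86,
                         segments = data.frame(
                           apl_from = c(86, 70, 50),
                           apl_to = c(70, 50, 38),
                           cs_inv = c(25, 75, 90)),
                         collapse_pi = 42,
                         apl_min = 38, apl_max = 110, n = 400L,
                         noise_sd = 0, seed = NULL) {
  if (collapse_pi <= 0) abort_input("collapse_pi must be > 0")
  if (nrow(segments) > 0L) {
    if (any(segments$apl_from <= segments$apl_to)) {
      abort_input("segments must have apl_from > apl_to")
    }
    if (nrow(segments) > 1L &&
        any(abs(segments$apl_to[-nrow(segments)] -
                segments$apl_from[-1L]) > 1e-9)) {
      abort_input("segments must be contiguous")
    }
    if (abs(segments$apl_from[1L] - lift_off_apl) > 1e-9) {
      abort_input("first segment must start at the lift-off area")
    }
  }
  apl <- seq(apl_max, apl_min, length.out = n)     # compression order
  pi_clean <- vapply(apl, function(a) {
    if (a >= lift_off_apl || nrow(segments) == 0L) return(0)
    p <- 0
    for (s in seq_len(nrow(segments))) {
      hi <- segments$apl_from[s]; lo <- segments$apl_to[s]
      if (a >= hi) break
      p <- p + segments$cs_inv[s] * log(hi / max(a, lo))
      if (a >= lo) break
    }
    min(p, collapse_pi)
  }, numeric(1))
  pi_obs <- with_seed(seed, pi_clean + stats::rnorm(n, 0, noise_sd))
  iso <- isotherm(apl, pi_obs, label = "synthetic")
  attr(iso, "ground_truth") <- list(
    lift_off_apl = lift_off_apl, segments = segments,
    collapse_pi = collapse_pi, noise_sd = noise_sd, seed = seed)
  iso
}

# Bead architecture used by gen_scene. Head/backbone stack plus two
# four-bead chains per phospholipid; cholesterol is a short rod; the drug
# is a compact four-bead unit.
scene_beads <- function(resname) {
  switch(resname,
    DPPC = ,
    POPC = c("NC3", "PO4", "GL1", "GL2"),
    POPG = c("GL0", "PO4", "GL1", "GL2"),
    CHOL = c("ROH", "R1", "R2", "C1"),
    MF = c("MF1", "MF2", "MF3", "MF4"),
    abort_input(paste("unknown scene species:", resname)))
}

#' Generate a coarse-grained monolayer scene
#'
#' Lipids are placed on a jittered square lattice at the prescribed area
#' per lipid, with head/backbone beads stacked at the interface plane and
#' both acyl chains extended as straight bead rods tilted by a prescribed
#' angle from the monolayer normal (delta or Gaussian tilt distribution,
#' random azimuth per chain). Drug molecules are placed dispersed under the
#' head groups, aggregated into prescribed cluster sizes, or airborne above
#' the film; pore disks are excised; a fraction of lipids can be displaced
#' below the film to mimic collapse protrusions. Scenes are geometric
#' fixtures with exact ground truth, not equilibrium ensembles.
#'
#' @param composition a [monolayer_composition()]; one leaflet is built
#'   (per-leaflet counts = counts / n_leaflets).
#' @param apl area per lipid, Angstrom^2.
#' @param tilt list: `type` ("delta" or "gaussian"), `theta` (degrees from
#'   the z normal), `sd` (degrees, Gaussian only).
#' @param drug list: `count`, `mode` ("dispersed", "aggregated",
#'   "airborne"), `cluster_sizes` (integer vector, aggregated mode; must
#'   sum to `count`), `spacing` (intra-cluster molecule spacing, nm).
#' @param pores data.frame with `x`, `y`, `radius` (nm): lipids whose
#'   lattice site falls inside a disk are removed.
#' @param collapse list: `fraction` of lipids displaced, `displacement`
#'   (nm, downward).
#' @param n_frames number of frames (jitter and tilt re-sampled per frame).
#' @param jitter lateral lattice jitter half-width, nm.
#' @param z_noise Gaussian noise on each lipid's interface height, nm
#'   (gives flat films a realistic nonzero head-group z-spread).
#' @param bond_length chain bead spacing, nm.
#' @param seed integer seed.
#' @return a [frame_set()] with attribute `ground_truth` (expected P2 for
#'   delta tilt, cluster sizes, pore areas, collapse fraction, box, apl).
#' @export
gen_scene <- function(composition = lung_surfactant_composition(),
                      apl = 49,
                      tilt = list(type = "delta", theta = 0, sd = 0),
                      drug = list(count = 0L, mode = "dispersed",
                                  cluster_sizes = NULL, spacing = 0.35),
                      pores = NULL,
                      collapse = list(fraction = 0, displacement = 3),
                      n_frames = 1L, jitter = 0.03, z_noise = 0.1,
                      bond_length = 0.47, seed = NULL) {
  n_lip <- sum(composition$count) / composition$n_leaflets
  if (n_lip != round(n_lip)) abort_input("counts not divisible into one leaflet")
  n_lip <- as.integer(n_lip)
  per_species <- composition$count / composition$n_leaflets
  if (any(abs(per_species - round(per_species)) > 0)) {
    abort_input("per-species counts must divide evenly across leaflets")
  }
  per_species <- as.integer(round(per_species))
  edge_nm <- box_for_apl(apl, n_lip) / 10
  n_side <- ceiling(sqrt(n_lip))
  spacing <- edge_nm / n_side
  if (spacing < 0.3) abort_input("over-packed scene: lattice spacing < 0.3 nm")
  if (jitter >= spacing / 2) abort_input("jitter must be below half the lattice spacing")
  z0 <- 4                                   # interface plane, nm
  lz <- 12
  box <- c(edge_nm, edge_nm, lz)
  drug <- utils::modifyList(list(count = 0L, mode = "dispersed",
                                 cluster_sizes = NULL, spacing = 0.35), drug)
  collapse <- utils::modifyList(list(fraction = 0, displacement = 3), collapse)
  if (drug$mode == "aggregated") {
    if (is.null(drug$cluster_sizes)) abort_input("aggregated mode needs cluster_sizes")
    if (sum(drug$cluster_sizes) != drug$count) {
      abort_input("cluster_sizes must sum to the drug count")
    }
  }

  # lattice sites, species assignment, pore excision (frame-independent)
  site <- expand.grid(ix = seq_len(n_side) - 1L, iy = seq_len(n_side) - 1L)
  extra <- nrow(site) - n_lip
  if (extra > 0L) {
    # drop surplus lattice sites evenly so no contiguous vacancy strip forms
    drop_idx <- unique(round(seq(1L, nrow(site), length.out = extra)))
    site <- site[-drop_idx, , drop = FALSE][seq_len(n_lip), , drop = FALSE]
  }
  sx <- (site$ix + 0.5) * spacing
  sy <- (site$iy + 0.5) * spacing
  resname <- rep(composition$species$name, per_species)
  keep <- rep(TRUE, n_lip)
  pore_truth <- NULL
  if (!is.null(pores) && nrow(pores) > 0L) {
    for (k in seq_len(nrow(pores))) {
      dx <- sx - pores$x[k]; dx <- dx - edge_nm * round(dx / edge_nm)
      dy <- sy - pores$y[k]; dy <- dy - edge_nm * round(dy / edge_nm)
      keep <- keep & (dx^2 + dy^2 > pores$radius[k]^2)
    }
    pore_truth <- data.frame(x = pores$x, y = pores$y, radius = pores$radius,
                             area = pi * pores$radius^2)
  }
  sx <- sx[keep]; sy <- sy[keep]; resname <- resname[keep]
  n_kept <- length(sx)

  # particle table (constant across frames)
  atoms <- list(); resid0 <- 0L
  chains <- default_chain_topology()
  for (i in seq_len(n_kept)) {
    rn <- resname[i]
    beads <- scene_beads(rn)
    if (rn %in% names(chains)) {
      beads <- c(beads, chains[[rn]]$sn1, chains[[rn]]$sn2)
    }
    atoms[[i]] <- data.frame(resname = rn, bead = beads,
                             resid = resid0 + i)
  }
  resid_drug0 <- n_kept
  if (drug$count > 0L) {
    for (m in seq_len(drug$count)) {
      atoms[[n_kept + m]] <- data.frame(resname = "MF", bead = scene_beads("MF"),
                                        resid = resid_drug0 + m)
    }
  }
  atoms <- do.call(rbind, atoms)

  frames <- with_seed(seed, {
    lapply(seq_len(n_frames), function(f) {
      xyz <- matrix(NA_real_, nrow(atoms), 3L)
      row <- 0L
      collapsed_idx <- if (collapse$fraction > 0) {
        sample.int(n_kept, floor(collapse$fraction * n_kept))
      } else integer(0)
      for (i in seq_len(n_kept)) {
        x <- (sx[i] + stats::runif(1, -jitter, jitter)) %% edge_nm
        y <- (sy[i] + stats::runif(1, -jitter, jitter)) %% edge_nm
        rn <- resname[i]
        dz <- if (i %in% collapsed_idx) -collapse$displacement else 0
        stack_z <- z0 + dz + stats::rnorm(1, 0, z_noise)
        if (rn == "CHOL") {
          # short rod along +z from the interface
          p <- cbind(x, y, stack_z + c(0, 0.3, 0.6, 0.9))
        } else if (rn %in% names(chains)) {
          head_beads <- cbind(x, y, stack_z + c(0.3, 0, -0.2, -0.2))
          head_beads[4L, 1L] <- (x + 0.15) %% edge_nm   # GL2 offset
          chain_pts <- function() {
            th <- if (tilt$type == "delta") tilt$theta else
              stats::rnorm(1, tilt$theta, tilt$sd)
            th <- th * pi / 180
            phi <- stats::runif(1, 0, 2 * pi)
            u <- c(sin(th) * cos(phi), sin(th) * sin(phi), cos(th))
            start <- c(x, y, stack_z + 0.2)
            t(sapply(0:3, function(k) start + k * bond_length * u))
          }
          p <- rbind(head_beads, chain_pts(), chain_pts())
        }
        xyz[row + seq_len(nrow(p)), ] <- p
        row <- row + nrow(p)
      }
      if (drug$count > 0L) {
        centers <- switch(drug$mode,
          dispersed = cbind(stats::runif(drug$count, 0, edge_nm),
                            stats::runif(drug$count, 0, edge_nm),
                            z0 + stats::rnorm(drug$count, 0, 0.2)),
          airborne = cbind(stats::runif(drug$count, 0, edge_nm),
                           stats::runif(drug$count, 0, edge_nm),
                           z0 + 4),
          aggregated = {
            # clusters on a coarse k x k grid; molecules within a cluster on
            # a compact sub-grid with `spacing`, so single linkage connects a
            # cluster while cluster-cluster gaps stay well above any
            # reasonable cutoff
            ncl <- length(drug$cluster_sizes)
            k <- ceiling(sqrt(ncl))
            cell <- edge_nm / k
            ext <- (ceiling(sqrt(max(drug$cluster_sizes))) - 1) * drug$spacing
            if (cell < ext + 1.2) abort_input("aggregated clusters do not fit the box")
            do.call(rbind, lapply(seq_len(ncl), function(ci) {
              gx <- ((ci - 1L) %% k + 0.5) * cell
              gy <- ((ci - 1L) %/% k + 0.5) * cell
              m <- drug$cluster_sizes[ci]
              mside <- ceiling(sqrt(m))
              off <- seq_len(m) - 1L
              cbind(gx + (off %% mside) * drug$spacing - ext / 2,
                    gy + (off %/% mside) * drug$spacing - ext / 2,
                    z0 - 0.6)
            }))
          },
          abort_input(paste("unknown drug mode:", drug$mode)))
        for (m in seq_len(drug$count)) {
          c0 <- centers[m, ]
          p <- rbind(c0,
                     c0 + c(0.12, 0, 0),
                     c0 + c(0, 0.12, 0),
                     c0 + c(0, 0, 0.12))
          p[, 1L] <- p[, 1L] %% edge_nm
          p[, 2L] <- p[, 2L] %% edge_nm
          xyz[row + 1:4, ] <- p
          row <- row + 4L
        }
      }
      list(xyz = xyz, box = box)
    })
  })

  fs <- frame_set(frames, atoms)
  theta_rad <- tilt$theta * pi / 180
  attr(fs, "ground_truth") <- list(
    apl = apl, box = box, n_lipids = n_kept,
    tilt = tilt,
    expected_p2 = if (tilt$type == "delta") (3 * cos(theta_rad)^2 - 1) / 2 else NA_real_,
    drug = drug,
    cluster_sizes = if (drug$mode == "aggregated") sort(drug$cluster_sizes, decreasing = TRUE) else NULL,
    pores = pore_truth,
    collapse = collapse,
    seed = seed)
  fs
}

#' Generate a pressure-tensor time series with a prescribed surface tension
#'
#' The tensor anisotropy is set so that the surface-tension estimator's
#' expectation equals `gamma_target`; Gaussian noise is added to each
#' diagonal component.
#'
#' @param gamma_target target surface tension, mN/m.
#' @param lz box height, nm.
#' @param n_interfaces interface count used by the estimator.
#' @param noise_sd per-component Gaussian noise, bar.
#' @param n number of samples (>= 1).
#' @param dt sample spacing, ps.
#' @param seed integer seed.
#' @return a [pressure_series()] with attribute `ground_truth`.
#' @export
gen_pressure_series <- function(gamma_target, lz = 20, n_interfaces = 2L,
                                noise_sd = 0, n = 1000L, dt = 10, seed = NULL) {
  if (n < 1L) abort_input("n must be >= 1")
  dp <- gamma_target * n_interfaces / (0.1 * lz)   # bar
  with_seed(seed, {
    pxx <- stats::rnorm(n, 0, noise_sd)
    pyy <- stats::rnorm(n, 0, noise_sd)
    pzz <- stats::rnorm(n, dp, noise_sd)
    ps <- pressure_series(t = seq(0, by = dt, length.out = n),
                          pxx = pxx, pyy = pyy, pzz = pzz, lz = lz)
    attr(ps, "ground_truth") <- list(gamma = gamma_target, lz = lz,
                                     n_interfaces = n_interfaces,
                                     noise_sd = noise_sd, seed = seed)
    ps
  })
}

#' Generate a surface-potential isotherm with a prescribed critical area
#'
#' Sigmoidal potential rise during compression,
#' dV(A) = dv_max / (1 + exp((A - critical_apl) / width)), whose maximum
#' slope sits at `critical_apl`.
#'
#' @param critical_apl inflection area, Angstrom^2.
#' @param dv_max plateau potential, V.
#' @param width sigmoid width, Angstrom^2.
#' @param apl_min,apl_max,n grid specification.
#' @param noise_sd Gaussian noise, V.
#' @param seed integer seed.
#' @return a [potential_isotherm()] with attribute `ground_truth`.
#' @export
gen_potential_curve <- function(critical_apl = 85, dv_max = 0.4, width = 3,
                                apl_min = 40, apl_max = 140, n = 300L,
                                noise_sd = 0, seed = NULL) {
  apl <- seq(apl_max, apl_min, length.out = n)
  dv <- dv_max / (1 + exp((apl - critical_apl) / width))
  dv <- with_seed(seed, dv + stats::rnorm(n, 0, noise_sd))
  iso <- potential_isotherm(apl, dv, label = "synthetic")
  attr(iso, "ground_truth") <- list(critical_apl = critical_apl,
                                    dv_max = dv_max, width = width,
                                    noise_sd = noise_sd, seed = seed)
  iso
}

#' Generate a constant-pressure relaxation trace
#'
#' @param k decay constant, 1/s.
#' @param type "exp" for A/A0 = exp(-k t), "linear" for 1 - k t.
#' @param t_max horizon, s.
#' @param dt sample spacing, s.
#' @param noise_sd Gaussian noise on A/A0.
#' @param setpoint_pi holding pressure, mN/m.
#' @param seed integer seed.
#' @return a [relaxation_trace()] with attribute `ground_truth`.
#' @export
gen_relaxation <- function(k = 0.01, type = c("exp", "linear"),
                           t_max = 600, dt = 1, noise_sd = 0,
                           setpoint_pi = 30, seed = NULL) {
  type <- match.arg(type)
  t <- seq(0, t_max, by = dt)
  r <- if (type == "exp") exp(-k * t) else pmax(1 - k * t, 1e-6)
  r <- with_seed(seed, r + stats::rnorm(length(t), 0, noise_sd))
  r[1L] <- 1
  tr <- relaxation_trace(t, pmin(pmax(r, 1e-6), 1.05), setpoint_pi)
  attr(tr, "ground_truth") <- list(k = k, type = type, noise_sd = noise_sd,
                                   seed = seed)
  tr
}
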