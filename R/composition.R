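#' Lipid species definition
#'
#' @param name character label, e.g. "DPPC".
#' @param mw molecular weight in g/mol (> 0).
#' @param mole_fraction dimensionless, in \[0, 1\].
#' @return a one-row data.frame with columns `name`, `mw`, `mole_fraction`.
#' @export
lipid_species <- function(name, mw, mole_fraction) {
  if (any(mw <= 0)) abort_input("molecular weight must be > 0")
  if (any(mole_fraction < 0 | mole_fraction > 1)) {
    abort_input("mole fractions must lie in [0, 1]")
  }
  data.frame(name = as.character(name), mw = as.numeric(mw),
             mole_fraction = as.numeric(mole_fraction),
             stringsAsFactors = FALSE)
}

#' Monolayer composition
#'
#' Describes a multi-species lipid (sub)phase: per-species mole fractions and
#' molecular weights, the total molecule count over all leaflets, and the
#' number of leaflets (a symmetric double-monolayer simulation slab has 2).
#'
#' @param species data.frame with columns `name`, `mw`, `mole_fraction`
#'   (rows can be built with [lipid_species()] and `rbind`).
#' @param total_molecules integer count of molecules across all leaflets.
#' @param n_leaflets 1 or 2.
#' @param counts optional explicit per-species integer counts summing to
#'   `total_molecules`; when omitted, counts are apportioned from the mole
#'   fractions by largest remainder. Explicit counts allow compositions
#'   whose realized counts deviate slightly from the nominal mole ratio.
#' @return object of class `monolayer_composition` with per-species integer
#'   counts.
#' @export
monolayer_composition <- function(species, total_molecules, n_leaflets = 2L,
                                  counts = NULL) {
  if (nrow(species) == 0L) abort_input("empty composition")
  if (any(species$mw <= 0)) abort_input("molecular weight must be > 0")
  if (abs(sum(species$mole_fraction) - 1) > 1e-9) {
    abort_input("mole fractions must sum to 1 (within 1e-9)")
  }
  total_molecules <- as.integer(total_molecules)
  n_leaflets <- as.integer(n_leaflets)
  if (!n_leaflets %in% c(1L, 2L)) abort_input("n_leaflets must be 1 or 2")
  if (total_molecules %% n_leaflets != 0L) {
    abort_input("total_molecules must be divisible by n_leaflets")
  }
  if (is.null(counts)) {
    raw <- species$mole_fraction * total_molecules
    counts <- floor(raw)
    rem <- total_molecules - sum(counts)
    if (rem > 0) {
      extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
      counts[extra] <- counts[extra] + 1L
    }
  } else {
    if (length(counts) != nrow(species)) abort_input("one count per species required")
    if (any(counts < 0) || any(counts != round(counts))) {
      abort_input("counts must be non-negative integers")
    }
    if (sum(counts) != total_molecules) {
      abort_input("counts must sum to total_molecules")
    }
  }
  structure(
    list(species = species, count = as.integer(counts),
         total_molecules = total_molecules, n_leaflets = n_leaflets),
    class = "monolayer_composition"
  )
}

#' @export
print.monolayer_composition <- function(x, ...) {
  cat(sprintf("Monolayer composition: %d molecules, %d leaflet(s)\n",
              x$total_molecules, x$n_leaflets))
  print(cbind(x$species, count = x$count))
  invisible(x)
}

#' The lung-surfactant model composition
#'
#' DPPC:POPC:POPG:CHOL at 60:20:10:10 mol%, 2032 molecules over two
#' leaflets (1016 per leaflet): DPPC 1224, POPC 408, POPG 200, CHOL 200.
#' POPG is the sodium salt (770.99 g/mol) as purchased; pass `popg_mw` to
#' use the free acid instead.
#'
#' @param popg_mw molecular weight used for POPG, g/mol.
#' @return a [monolayer_composition()].
#' @export
lung_surfactant_composition <- function(popg_mw = 770.99) {
  sp <- rbind(
    lipid_species("DPPC", 734.04, 0.60),
    lipid_species("POPC", 760.08, 0.20),
    lipid_species("POPG", popg_mw, 0.10),
    lipid_species("CHOL", 386.65, 0.10)
  )
  monolayer_composition(sp, total_molecules = 2032L, n_leaflets = 2L,
                        counts = c(1224L, 408L, 200L, 200L))
}

#' Drug specification
#'
#' @param name character label.
#' @param mw molecular weight g/mol; default is mometasone furoate, 521.40.
#' @param count integer molecule count (>= 0).
#' @param concentration_ww percent mass/mass (>= 0).
#' @export
drug_spec <- function(name = "MF", mw = 521.40, count = 0L,
                      concentration_ww = 0) {
  if (mw <= 0) abort_input("molecular weight must be > 0")
  if (count < 0) abort_input("drug count must be >= 0")
  if (concentration_ww < 0) abort_input("concentration must be >= 0")
  structure(list(name = name, mw = mw, count = as.integer(count),
                 concentration_ww = concentration_ww),
            class = "drug_spec")
}

#' Mass fractions of a composition
#'
#' Converts mole fractions to mass percentages, w_i = 100 x_i MW_i /
#' sum_j x_j MW_j. Returned both unrounded and rounded to the nearest
#' integer (round-half-to-even).
#'
#' @param composition a [monolayer_composition()].
#' @return data.frame with columns `name`, `mass_percent`,
#'   `mass_percent_rounded`.
#' @export
mass_fractions <- function(composition) {
  sp <- composition$species
  if (nrow(sp) == 0L) abort_input("empty composition")
  w <- sp$mole_fraction * sp$mw
  pct <- 100 * w / sum(w)
  data.frame(name = sp$name, mass_percent = pct,
             mass_percent_rounded = as.integer(round(pct)),
             stringsAsFactors = FALSE)
}

# Total lipid mass in g/mol-equivalents (sum N_i MW_i); masses enter the
# weight-percent formula only through this product, so Avogadro cancels.
lipid_mass_units <- function(composition) {
  sum(composition$count * composition$species$mw)
}

#' Drug weight-percent concentration for a given molecule count
#'
#' C \%w/w = 100 n MW_d / (n MW_d + sum_i N_i MW_i).
#'
#' @param composition a [monolayer_composition()].
#' @param drug a [drug_spec()].
#' @param count integer number of drug molecules.
#' @return percent w/w (numeric scalar).
#' @export
concentration_for_count <- function(composition, drug, count) {
  if (count < 0) abort_input("count must be >= 0")
  md <- count * drug$mw
  100 * md / (md + lipid_mass_units(composition))
}

#' Drug molecule count realizing a target weight concentration
#'
#' Inverts the weight-percent formula and rounds to the nearest integer
#' molecule; the achieved concentration (which differs from the target by
#' at most one molecule's quantization) is attached.
#'
#' @param composition a [monolayer_composition()].
#' @param drug a [drug_spec()].
#' @param concentration_ww target percent w/w, in \[0, 100).
#' @return integer count with attributes `achieved_ww` (percent realized by
#'   the integer count) and `rounding` ("nearest").
#' @export
drug_count_for_concentration <- function(composition, drug, concentration_ww) {
  if (concentration_ww < 0 || concentration_ww >= 100) {
    abort_input("concentration_ww must lie in [0, 100)")
  }
  m_lip <- lipid_mass_units(composition)
  n_real <- concentration_ww * m_lip / ((100 - concentration_ww) * drug$mw)
  n <- as.integer(round(n_real))
  structure(n,
            achieved_ww = concentration_for_count(composition, drug, n),
            rounding = "nearest")
}

#' Convert an inhaled dose to a molecule count
#'
#' count = dose\[ug\] 1e-6 / MW * N_A with N_A = 6.02214076e23 /mol.
#'
#' @param dose_ug dose in micrograms (>= 0).
#' @param drug a [drug_spec()] (only `mw` is used).
#' @return molecule count (numeric; typically astronomically large).
#' @export
dose_to_molecules <- function(dose_ug, drug = drug_spec()) {
  if (dose_ug < 0) abort_input("dose must be >= 0")
  dose_ug * 1e-6 / drug$mw * .AVOGADRO
}

#' Area per lipid from box geometry
#'
#' @param edge_x,edge_y box edges in Angstrom.
#' @param n_per_leaflet molecules in one leaflet (> 0).
#' @return list with `apl` (Angstrom^2, exact) and `apl_rounded`
#'   (round-half-to-even integer).
#' @export
apl_from_box <- function(edge_x, edge_y = edge_x, n_per_leaflet) {
  if (n_per_leaflet <= 0) abort_input("n_per_leaflet must be > 0")
  apl <- edge_x * edge_y / n_per_leaflet
  list(apl = apl, apl_rounded = as.integer(round(apl)))
}

#' Square box edge for a target area per lipid
#'
#' @param apl target area per lipid, Angstrom^2 (> 0); vectorized.
#' @param n_per_leaflet molecules in one leaflet (> 0).
#' @return edge length in Angstrom; `apl_from_box(edge, edge, n)` recovers
#'   `apl` exactly.
#' @export
box_for_apl <- function(apl, n_per_leaflet) {
  if (any(apl <= 0) || any(n_per_leaflet <= 0)) {
    abort_input("apl and n must be > 0")
  }
  sqrt(apl * n_per_leaflet)
}
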