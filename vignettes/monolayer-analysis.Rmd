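---
title: "Analysing drug-lung-surfactant monolayers: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing drug-lung-surfactant monolayers: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(monosurf)
```

## Scope and model system

`monosurf` analyses the interaction of a hydrophobic inhaled drug with a
lung-surfactant monolayer from two directions: Langmuir-trough observables
(surface pressure-area isotherms, surface-potential isotherms, relaxation
traces) and coarse-grained simulation observables (chain order parameters,
surface tension from the pressure tensor, radial distribution functions,
drug aggregation, pores, collapse). The reference system throughout is a
DPPC:POPC:POPG:CHOL 60:20:10:10 (mol) film — 2032 molecules over two
leaflets, 1016 per leaflet (DPPC 1224, POPC 408, POPG 200, CHOL 200) —
with mometasone furoate (MW 521.40 g/mol) as the drug, but every function
takes an arbitrary composition.

The package contains no molecular dynamics engine and no instrument
drivers. Every analysis is exercised against synthetic data with exact,
machine-readable ground truth (`gen_isotherm()`, `gen_scene()`,
`gen_pressure_series()`, `gen_potential_curve()`, `gen_relaxation()`), so
the whole pipeline is testable at desk scale. Experimentally measured
quantities — an 86 Å² lift-off area, a 42 mN/m collapse plateau, measured
roughness values, microsecond-scale simulated surface tensions — are *not*
reproducible from this package alone: they require lab data or long
coarse-grained runs. The generators embed curves with those landmark
shapes so that the detection code is exercised on realistic inputs; tests
against them validate the estimators, not the experiments.

## Composition and dosing arithmetic

Mass fractions follow from mole fractions as
$w_i = 100\, x_i M_i / \sum_j x_j M_j$. For the reference composition this
gives DPPC 62.2%, POPC 21.5%, POPG 10.9%, CHOL 5.46%. Cholesterol is often
quoted as 6% by mass alongside the other three rounded values; it actually
computes to ~5.5 and rounds to 5. `mass_fractions()` reports both the
exact and the (round-half-to-even) integer values and leaves the
discrepancy visible rather than forcing agreement.

The drug weight concentration uses
$C_{w/w} = 100\, n M_d / (n M_d + \sum_i N_i M_i)$; masses enter only as
count-molecular-weight products, so Avogadro's number cancels.
`drug_count_for_concentration()` inverts this and rounds to the nearest
whole molecule; the achieved concentration is attached so quantization is
never hidden. Dose-to-molecule conversion is
$n = d \cdot 10^{-6} / M \cdot N_A$ with $N_A = 6.02214076 \times 10^{23}$.

POPG defaults to the sodium-salt molecular weight (770.99 g/mol), matching
the commercially supplied material; the free-acid value can be passed
instead and moves the rounded mass percentages by less than one point.

Box geometry: a square box of edge $L$ (Å) holding $n$ molecules per
leaflet has APL $= L^2/n$. With 1016 per leaflet, 223.1 Å ↔ 49 Å² and
249.2 Å ↔ 61 Å²; a 220.0 Å box gives 47.6 Å² (rounding to 48, not 47),
which the composition driver flags as internally inconsistent with the
47 Å² label it sometimes carries.

## Isotherm analysis

**Compression modulus.** $C_s^{-1} = -A\, (\partial\pi/\partial A)$,
evaluated by smoothing $\pi(A)$ and central finite differences (one-sided
at the ends). Smoothing is a moving local polynomial least-squares fit
(window 11 points, degree 3 by default) rather than a classical
Savitzky-Golay convolution because isotherm grids need not be uniform; on
a uniform grid the two coincide. The window is a bias-variance dial: the
derivative of a noisy curve is noise-amplifying, and at the 0.1 mN/m
instrument accuracy a 11-15 point window keeps the modulus stable without
smearing phase boundaries. `window = 1` disables smoothing for clean or
pre-smoothed data.

**Phase classification.** Davies-Rideal bands on $C_s^{-1}$ (mN/m):
< 12.5 gaseous, 12.5-50 liquid-expanded, 50-100 intermediate LE-LC,
100-250 liquid-condensed, > 250 solid. Boundaries belong to the lower
band so classification is deterministic at ties.

**Lift-off.** "The pressure rises above zero" is not operational against
noise, so detection is two-stage: the onset is located where $\pi$ exceeds
the baseline (median over the largest-area decile) by 0.5 mN/m; the
reported lift-off then comes from a changepoint regression
$\pi(A) = b + C_s \ln(A_0/A)$ for $A < A_0$, $b$ otherwise, fitted over
the baseline and the first `rise_span` (default 5) mN/m of the rise. The
locally-constant-modulus form is exact for piecewise-modulus curves and a
good local model for real films; a raw interpolated threshold crossing is
systematically late on gently rising isotherms (by roughly
$0.5\,A_0/C_s^{-1}$ Å²) and is available as `method = "crossing"`.

**Collapse.** The first point, after the pressure passes half its maximum,
where $d\pi/dA$ changes sign or falls below a plateau tolerance
(0.02 mN/m/Å² by default). Monotone rising curves return no collapse.

**Relaxation.** For constant-pressure stability traces $A/A_0(t)$ the
metrics are the area loss at the horizon, the initial decay rate (least
squares over the first 10% of samples), and the exponential constant from
a log-linear fit restricted to $A/A_0 >$ 0.05 — the logarithm amplifies
noise without bound as the relative area approaches zero.

## Surface potential

The apparent dipole moment is $\mu_a = \Delta V \cdot A \cdot
\varepsilon_0$ per sample, with $A$ in m², $\varepsilon_0 =
8.8541878128 \times 10^{-12}$ F/m, reported in Debye
($1\,\mathrm{D} = 3.33564 \times 10^{-30}$ C·m). Only this
vacuum-permittivity form is computed: the film's own permittivity is
unknown, so no three-layer capacitor decomposition is attempted. The
critical area of the $\Delta V$ rise is the maximum-magnitude slope of the
smoothed curve (no numeric threshold exists for "sharp"), refined to
sub-grid precision by a parabolic fit through the peak and its neighbours.
A 15-point window suits curves sampled ~10 points per sigmoid width; the
criterion is max-slope rather than a threshold crossing, so symmetric
smoothing does not bias the location.

## Trajectory analysis

**Order parameters.** $P_2 = (3\langle\cos^2\theta\rangle - 1)/2$ for the
angle between each consecutive-bead bond of the sn-1/sn-2 chains and the
monolayer normal (z axis by default): +1 for bonds along the normal, -0.5
for bonds in the plane, 0 for isotropy — the stated range pins the second
Legendre polynomial uniquely. Averaging is over molecules within a frame,
then over frames; the across-frame standard deviation is reported. Bead
chains are configurable per species (`chain_topology()`); defaults follow
four-bead MARTINI-style tails with the unsaturated D-bead on the sn-1
chain of POPC and POPG.

**Surface tension.** $\gamma = (L_z / n_\mathrm{int})\,\langle P_{zz} -
(P_{xx}+P_{yy})/2\rangle$, bar and nm converted to give mN/m
($1\,\mathrm{bar \cdot nm} = 0.1$ mN/m). `n_interfaces` defaults to 2, the
symmetric double-monolayer slab geometry; set 1 for a single interface.
Uncertainty is the standard error of 5 block means. With few blocks that
estimate itself is noisy (4 degrees of freedom), which matters when using
it for significance statements.

**RDF.** Distance-histogram $g(r)$ with orthorhombic minimum-image
periodicity, normalized by ideal-gas shell counts at the box's mean pair
density, cutoff 1.0 nm by default. Both a 3D (spherical) and a 2D lateral
mode are provided — monolayer pair structure is reported both ways in the
literature and the choice is rarely stated, so neither is privileged. Raw
pair counts are returned so results can be checked against brute-force
enumeration. Triclinic boxes are rejected by design.

**Clustering.** Drug molecules are linked when any bead pair between them
is within the cutoff (single linkage via union-find); cluster sizes and
the largest-cluster fraction summarize aggregation per frame.

**Pores.** Film beads are projected on the x-y plane; a cell of the
occupancy grid counts as covered when a bead lies within the footprint
radius (default 0.5 nm — at least half the in-plane molecular spacing, or
an intact film shows spurious holes). Pores are periodic 4-connected empty
components above a minimum area. The raw grid area under-reports the open
area by a boundary ring, so a corrected area dilates each component back
by `footprint - film_spacing/2` using the Steiner formula
($A + P r + \pi r^2$), with the staircase perimeter scaled by $\pi/4$ to
remove the grid's Manhattan bias. `film_spacing` (e.g. $\sqrt{\mathrm{APL}}$)
expresses that the physical film edge sits about half a molecular spacing
beyond the outermost bead centers; at 0 the edge is taken at the bead
centers, appropriate for densely sampled films.

**Collapse (3D).** The interdecile range of head-bead z, with empirical
(type 1) quantiles so a displaced subpopulation sitting exactly at a
decile still registers. The default threshold is 3 times the first frame's
spread, assuming the trajectory starts from an intact film; pass an
absolute threshold otherwise. A bimodality coefficient of the z
distribution is reported as a secondary two-layer indicator.

**Roughness.** $R_a = \mathrm{mean}|z_i - \bar z|$ on a height profile,
the arithmetic roughness used for AFM line sections.

## The synthetic generators

`gen_isotherm()` integrates $d\pi/dA = -C_s^{-1}/A$ through contiguous
prescribed-modulus segments below the lift-off area and caps the pressure
at a collapse plateau; defaults (lift-off 86 Å², segments of 25/75/90
mN/m, collapse at 42 mN/m, so the modulus maximum falls in the 50-100
intermediate window) give the drug-free lung-surfactant curve shape.
Noise is Gaussian; 0.1 mN/m matches Wilhelmy-plate accuracy.

`gen_scene()` builds one leaflet on a jittered square lattice at the
requested APL (surplus lattice sites are dropped evenly, never as a
contiguous strip), stacks head/backbone beads at the interface plane with
0.1 nm height noise, and extends both chains as straight 4-bead rods
tilted by a delta or Gaussian angle with random azimuth. Drugs are placed
dispersed (Gaussian around the head plane), aggregated (compact sub-grids
of prescribed sizes on a coarse grid, so single linkage recovers the sizes
exactly for any cutoff between the intra-cluster spacing and the
inter-cluster gap), or airborne above the film. Pore disks excise lipids;
a collapse fraction displaces whole lipids downward. Scenes are geometric
fixtures with exact ground truth — not equilibrium ensembles: they carry
no thermal disorder beyond the prescribed distributions, no
area-dependent phase behaviour, and no drug-lipid energetics. Passing
tests on them demonstrates that the estimators recover known parameters,
not that the physics of real films is reproduced.

`gen_pressure_series()` inverts the tension estimator so its expectation
equals the target; `gen_potential_curve()` places a sigmoid inflection at
the prescribed critical area; `gen_relaxation()` produces exponential or
linear area decays. All generators take an explicit seed, use a private
RNG scope (the caller's stream is untouched), and are byte-identical
under the same seed.

## Problem sizes and numerical defaults

The test suite and the drivers run at deliberately modest sizes chosen to
keep statistical tolerances meaningful: isotherms of 400 points,
pressure series of 10⁴ samples, scenes of 100-1016 lipids per leaflet,
10⁵ bonds for the isotropy Monte-Carlo, pore grids of 0.1-0.4 nm cells.
Parameter-recovery tests run across ten seeds at the instrument noise
levels above. Key tolerances: recovery of a prescribed segment modulus to
±0.5 mN/m, collapse pressure to ±0.5 mN/m, lift-off to one grid step,
critical area to ±1 Å², relaxation constant to ±1×10⁻⁴ s⁻¹, planted pore
areas to one ring of grid cells, surface tension to three exact standard
errors of the injected noise.

## Known limitations

* Single-branch compression only; no hysteresis modelling of
  compression-expansion cycles.
* Orthorhombic minimum image only; triclinic trajectories must be wrapped
  upstream.
* The pore detector assumes the film is roughly normal to z and reports
  projected areas; strongly folded films violate the projection.
* The changepoint lift-off model assumes a locally constant modulus just
  above lift-off; curves with immediate strong curvature should use
  `method = "crossing"` with a tight threshold instead.
* Scene generators place straight chains; bond-angle disorder within a
  chain (gauche defects) is not emulated, so per-bond order-parameter
  *differences* along a chain are not exercised by synthetic data.
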