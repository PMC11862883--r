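# monosurf

Analysis toolkit for studies of inhaled-drug interaction with lung
surfactant monolayers, combining the two standard views of such systems:
Langmuir-trough observables and coarse-grained simulation observables.

The lung surfactant monolayer (LSM) is the DPPC-rich phospholipid/
cholesterol film at the alveolar air-water interface that lowers surface
tension during breathing. Delivering corticosteroids through it raises a
quantitative question: at what dose does the drug change the film's
mechanics? `monosurf` implements the measurements used to answer it, for
a DPPC:POPC:POPG:CHOL 60:20:10:10 (mol) model film and mometasone furoate
(MW 521.40 g/mol) by default, and for arbitrary compositions in general:

* **Isotherms** — surface pressure π = γ_w − γ; compression modulus
  Cs⁻¹ = −A(∂π/∂A); Davies-Rideal phase classification (gaseous / LE /
  intermediate LE-LC / LC / solid); lift-off and collapse detection;
  constant-π relaxation stability metrics.
* **Surface potential** — apparent dipole moment μ_a = ΔV·A·ε₀ (in
  Debye); critical-area detection of the ΔV rise.
* **Composition & dosing** — mole↔mass fractions; drug molecule count for
  a target % w/w, C = 100·n·MW_d/(n·MW_d + Σ N_i·MW_i); dose-to-molecule
  conversion via Avogadro's number; box-edge ↔ area-per-lipid geometry.
* **Trajectories** — P₂ = (3⟨cos²θ⟩−1)/2 chain order parameters per
  bonded bead pair; surface tension γ = (L_z/n)⟨P_zz − (P_xx+P_yy)/2⟩ with
  block-average errors; minimum-image RDFs (3D or lateral) with a 1.0 nm
  cutoff; single-linkage drug clustering; occupancy-grid pore detection;
  head-group z-spread collapse detection; density profiles; AFM-style Ra
  roughness.
* **Synthetic data** — generators for all of the above with exact,
  attached ground truth, so the full pipeline is testable without MD runs
  or instrument data. GRO/PDB/XYZ readers and JSON/CSV report writers
  round out the I/O.

## Worked example

```r
library(monosurf)

comp <- lung_surfactant_composition()
mass_fractions(comp)
#>   name mass_percent mass_percent_rounded
#> 1 DPPC    62.188861                   62
#> 2 POPC    21.465002                   21
#> 3 POPG    10.886552                   11
#> 4 CHOL     5.459585                    5

# molecules of mometasone furoate for 0.72 % w/w in this film
drug_count_for_concentration(comp, drug_spec(), 0.72)
#> [1] 20
#> attr(,"achieved_ww") 0.7189079

# a synthetic drug-free compression isotherm and its analysis
iso <- gen_isotherm(noise_sd = 0.1, seed = 20260919)
detect_lift_off(iso)               # 86.05 A^2
detect_collapse(iso, window = 11)  # pi 42.1 mN/m at 43.4 A^2
mc <- compression_modulus(iso, window = 15)
classify_phase(max(mc$cs_inv))     # "intermediate LE-LC" (98.1 mN/m)

# chain order in a coarse-grained monolayer scene
sc <- gen_scene(composition = comp, apl = 47,
                tilt = list(type = "gaussian", theta = 10, sd = 5), seed = 1)
head(order_parameter(sc), 3)
#>   species chain    bond       p2 sd n_frames
#> 1    DPPC   sn1 C1A-C2A 0.941582  0        1
#> 2    DPPC   sn1 C2A-C3A 0.941582  0        1
#> 3    DPPC   sn1 C3A-C4A 0.941582  0        1
```

The lift-off (86 Å²) and collapse (42 mN/m) values above are generator
ground truth recovered by the detectors; they are the landmark shape of a
drug-free lung-surfactant isotherm, not re-measurements of it.

## Analysis workflow

The `analysis/` scripts run the package end to end and write tables under
`results/`:

```sh
Rscript analysis/01_composition_dosing.R    # mass %, box/APL table, drug counts
Rscript analysis/02_isotherm_phase.R        # lift-off, Cs^-1, collapse, relaxation
Rscript analysis/03_surface_potential.R     # mu_a curve, critical area
Rscript analysis/04_monolayer_trajectories.R # P2, tension series, RDF, clusters, pores
```

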