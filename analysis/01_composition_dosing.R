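#!/usr/bin/env Rscript
# Composition and dosing arithmetic for the DPPC:POPC:POPG:CHOL 60:20:10:10
# lung-surfactant model: mass fractions, the box-edge <-> area-per-lipid
# table, drug molecule counts for the studied weight concentrations, and
# inhaled-dose molecule counts.

suppressMessages(library(monosurf))
dir.create("results", showWarnings = FALSE)

comp <- lung_surfactant_composition()
cat("Model composition (2032 molecules, 1016 per leaflet):\n")
print(comp)

mf <- mass_fractions(comp)
cat("\nMass fractions derived from 60:20:10:10 mol%:\n")
print(mf, digits = 4)
cat("Note: cholesterol computes to",
    sprintf("%.2f%%", mf$mass_percent[mf$name == "CHOL"]),
    "- it is usually quoted rounded up to 6%.\n")
write_report(mf, "results/mass_fractions.csv", format = "csv")

# box edge <-> area per lipid, 1016 molecules per leaflet
apls <- seq(47, 61, by = 2)
box_tab <- data.frame(
  apl_target = apls,
  edge_A = round(box_for_apl(apls, 1016), 1))
box_tab$apl_back <- vapply(box_tab$edge_A, function(e)
  apl_from_box(e, e, 1016)$apl, numeric(1))
box_tab$apl_rounded <- vapply(box_tab$edge_A, function(e)
  apl_from_box(e, e, 1016)$apl_rounded, integer(1))
cat("\nBox edges realizing each target area per lipid:\n")
print(box_tab, digits = 4)
check220 <- apl_from_box(220.0, 220.0, 1016)
cat(sprintf(paste0("A 220.0 A box with 1016 molecules per leaflet gives ",
                   "%.1f A^2 per lipid (rounds to %d, not 47).\n"),
            check220$apl, check220$apl_rounded))
write_report(box_tab, "results/box_apl_table.csv", format = "csv")

# drug counts for the studied weight concentrations
mf_drug <- drug_spec()
conc <- c(0, 0.72, 2.13, 4.18, 8.02, 14.84)
dose_tab <- data.frame(
  concentration_ww = conc,
  n_molecules = vapply(conc, function(cw)
    as.integer(drug_count_for_concentration(comp, mf_drug, cw)), integer(1)))
dose_tab$achieved_ww <- vapply(dose_tab$n_molecules, function(n)
  concentration_for_count(comp, mf_drug, n), numeric(1))
cat("\nMometasone furoate counts for the studied % w/w series:\n")
print(dose_tab, digits = 4)
write_report(dose_tab, "results/drug_counts.csv", format = "csv")

# inhaled doses: 100 ug (low) to 2000 ug (high)
doses <- c(100, 250, 500, 1000, 2000)
inhaled <- data.frame(dose_ug = doses,
                      molecules = vapply(doses, dose_to_molecules, numeric(1),
                                         drug = mf_drug))
cat("\nMolecule counts delivered per inhaled dose (MW 521.40 g/mol):\n")
print(inhaled)
write_report(inhaled, "results/inhaled_doses.csv", format = "csv")
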