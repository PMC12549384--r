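#!/usr/bin/env Rscript
# Material characterization: compressibility index from the bulk/tapped
# densities of the three model excipients, and the lumped permeation
# constant c = K*patm/(eta*L) each material presents to the suction-pressure
# model on both machines (rotary press L = 6 mm, compaction simulator
# L = 11 mm). Writes results/materials_characterization.csv.

suppressPackageStartupMessages(library(suctionfill))

mats <- fixture_materials()
air <- air_properties()

tab <- do.call(rbind, lapply(mats, function(m) {
  data.frame(
    material = m$name,
    x50_um = m$x50,
    rho_bulk_g_cm3 = m$rho_bulk,
    rho_tapped_g_cm3 = m$rho_tapped,
    ci_percent = compressibility_index(m$rho_bulk, m$rho_tapped),
    permeability_m2 = m$permeability,
    c_rotary_m_s = model_constant(m$permeability, 6e-3, air),
    c_simulator_m_s = model_constant(m$permeability, 11e-3, air)
  )
}))
rownames(tab) <- NULL

dir.create("results", showWarnings = FALSE)
write.csv(tab, "results/materials_characterization.csv", row.names = FALSE)

cat("Material characterization:\n")
print(tab, digits = 4)
cat("\nThe compressibility index separates the free flowing (DCP, ~15%),\n")
cat("easy flowing (MCC, ~22%) and cohesive (LAC, ~33%) excipients. LAC's\n")
cat("permeability is ~10x lower than the other two, so its permeation\n")
cat("constant c is ~10x smaller: the same punch velocity drives a much\n")
cat("larger stationary suction pressure through a lactose bed.\n")
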