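#!/usr/bin/env Rscript
# Synthetic die-filling study: generates tablet-weight datasets over the
# full turret x paddle design for a DCP-like (suction- and supply-robust)
# and a LAC-like (suction- and supply-limited) rotary-press scenario, runs
# them through the filling-yield pipeline and verifies that the pipeline
# recovers the generator's ground truth. Writes results/yield_grid_*.csv
# and results/yield_recovery.csv.

suppressPackageStartupMessages(library(suctionfill))
seed <- 20260930L

mats <- fixture_materials()
die <- die_geometry()
dir.create("results", showWarnings = FALSE)

scenarios <- list(
  dcp_like = synthetic_scenario(mats$DCP, "rotary_press", "conventional",
                                suction_sensitivity = 0.02,
                                supply_sensitivity = 0,
                                weight_rsd = 0.015, seed = seed),
  lac_like = synthetic_scenario(mats$LAC, "rotary_press", "conventional",
                                suction_sensitivity = 0.3,
                                supply_sensitivity = 0.4,
                                weight_rsd = 0.03, seed = seed + 1L)
)

recovery <- list()
for (nm in names(scenarios)) {
  template <- scenarios[[nm]]
  study <- generate_study(template)
  grid <- yield_grid(study$experiments, die, template$material)
  write.csv(grid, sprintf("results/yield_grid_%s.csv", nm),
            row.names = FALSE)
  write_weights(study$experiments, sprintf("results/weights_%s.csv", nm))
  truth <- vapply(study$experiments, function(e) attr(e, "mu_phi"),
                  numeric(1))
  recovery[[nm]] <- data.frame(
    scenario = nm,
    cells = nrow(grid),
    mean_phi_min = min(grid$mean_phi), mean_phi_max = max(grid$mean_phi),
    max_abs_phi_error = max(abs(grid$mean_phi - truth)),
    mean_phi_rsd = mean(grid$phi_rsd)
  )
  cat(sprintf("\n%s scenario (%s): %d cells\n", nm,
              template$material$name, nrow(grid)))
  print(head(grid[, c("turret_speed", "paddle_speed", "mean_phi",
                      "phi_rsd")], 7), digits = 3)
}

rec <- do.call(rbind, recovery)
write.csv(rec, "results/yield_recovery.csv", row.names = FALSE)
cat("\nGround-truth recovery:\n")
print(rec, digits = 3)
cat("\nThe DCP-like grid sits at phi ~ 1 everywhere (filling insensitive\n")
cat("to process settings), while the LAC-like grid rises with paddle\n")
cat("speed: powder supply limits die filling for the cohesive material,\n")
cat("as the yield pipeline recovers from the generated weights.\n")
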