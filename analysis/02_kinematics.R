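#!/usr/bin/env Rscript
# Lower-punch kinematics: pull-down times and linear velocities for the
# conventional (16 mm travel) and stearate (11.3 mm travel) fill cams over
# the turret-speed range, plus recovery of the stationary punch velocity
# from synthetic 2000 Hz instrumentation reports (10 noisy reports per
# simulated turret speed, as the instrumentation analysis prescribes).
# Writes results/pull_down_kinematics.csv and results/report_recovery.csv.

suppressPackageStartupMessages(library(suctionfill))
seed <- 20260930L

mats <- fixture_materials()
turret <- c(20, 30, 40, 50, 60)

## cam kinematics --------------------------------------------------------------
kin <- do.call(rbind, lapply(c("conventional", "stearate"), function(ck) {
  cam <- fill_cam(ck)
  tppd <- pull_down_time(cam$pull_down_angle, turret)
  data.frame(cam = ck, turret_speed_min = turret, t_ppd_s = tppd,
             v_ppd_m_s = linear_pull_down_velocity(cam$hppd, tppd))
}))
dir.create("results", showWarnings = FALSE)
write.csv(kin, "results/pull_down_kinematics.csv", row.names = FALSE)
cat("Pull-down kinematics (72 deg sector):\n")
print(kin, digits = 4)
cat("\nThe pull-down time is cam-independent (same angular sector); the\n")
cat("stearate cam's shorter travel reduces its linear velocity by the\n")
cat("factor 11.3/16 at every turret speed.\n\n")

## report analysis recovery ----------------------------------------------------
rec <- do.call(rbind, lapply(turret, function(nt) {
  sc <- synthetic_scenario(mats$MCC, "compaction_simulator", "conventional",
                           turret_speed = nt, velocity_noise = 0.01,
                           seed = seed + nt)
  reports <- lapply(1:10, function(j) generate_punch_report(sc, j))
  sm <- summarize_reports(reports)
  prof <- scenario_profile(sc)
  truth <- sc$velocity_factor * prof$hppd / prof$duration
  data.frame(
    turret_speed_min = nt,
    plateau_truth_m_s = truth,
    plateau_recovered_m_s = sm$stationary_velocity_mean,
    pooled_sd_m_s = sm$stationary_velocity_sd,
    rel_error_percent = 100 * abs(sm$stationary_velocity_mean - truth) / truth,
    pull_down_time_s = sm$pull_down_time
  )
}))
write.csv(rec, "results/report_recovery.csv", row.names = FALSE)
cat("Stationary-velocity recovery from 10 noisy reports per turret speed:\n")
print(rec, digits = 4)
cat(sprintf("\nWorst-case relative error %.3f%% — the inverse-variance\n",
            max(rec$rel_error_percent)))
cat("weighted mean recovers the generator's plateau well within 0.5%.\n")
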