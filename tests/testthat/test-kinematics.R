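test_that("pull-down time is the cam's fraction of one turret revolution", {
  expect_equal(pull_down_time(72, 60), 0.2)
  expect_equal(pull_down_time(72, 20), 0.6)
  # inverse proportionality in turret speed at fixed angle
  nts <- c(10, 25, 40, 80)
  expect_equal(pull_down_time(90, nts) * nts, rep(pull_down_time(90, 1), 4))
  expect_error(pull_down_time(0, 60), "degrees")
  expect_error(pull_down_time(400, 60), "degrees")
  expect_error(pull_down_time(72, 0), "positive")
})

test_that("linear pull-down velocity follows the height/time ratio and cam geometry", {
  expect_equal(linear_pull_down_velocity(0.016, 0.2), 0.08)
  expect_equal(linear_pull_down_velocity(0.0113, 0.2), 0.0565)
  # conventional vs stearate velocity ratio = ratio of pull-down heights
  conv <- fill_cam("conventional")
  ste <- fill_cam("stearate")
  tppd <- pull_down_time(72, 40)
  expect_equal(linear_pull_down_velocity(conv$hppd, tppd) /
                 linear_pull_down_velocity(ste$hppd, tppd),
               16 / 11.3, tolerance = 1e-12)
  expect_error(linear_pull_down_velocity(-1, 0.2), "positive")
})

test_that("fill cam geometry derives pull-down height and initial cavity", {
  conv <- fill_cam("conventional")
  expect_equal(conv$h0, 0)
  expect_equal(conv$hppd, 0.016)
  ste <- fill_cam("stearate")
  expect_equal(ste$h0, 4.7e-3)
  expect_equal(ste$hppd, 0.016 - 4.7e-3)
  expect_error(fill_cam("stearate", pre_pull_height = 0.017), "smaller")
})

test_that("rotary profile is a single constant phase reaching hppd", {
  cam <- fill_cam("conventional")
  mach <- machine_config("rotary_press", 60)
  prof <- build_rotary_profile(cam, mach)
  expect_equal(nrow(prof$phases), 1L)
  tt <- seq(0, prof$duration, length.out = 101)
  expect_true(all(abs(profile_velocity(prof, tt) -
                        profile_velocity(prof, 0)) < 1e-15))
  expect_equal(profile_displacement(prof, prof$duration), cam$hppd,
               tolerance = 1e-6 / cam$hppd)
  # doubling turret speed halves the duration and doubles the velocity
  prof2 <- build_rotary_profile(cam, machine_config("rotary_press", 120))
  expect_equal(prof2$duration, prof$duration / 2)
  expect_equal(profile_velocity(prof2, 0), 2 * profile_velocity(prof, 0))
  expect_equal(profile_displacement(prof2, prof2$duration), cam$hppd)
  expect_error(
    build_rotary_profile(cam, machine_config("compaction_simulator", 60)),
    "rotary_press"
  )
})

test_that("three-phase simulator profile meets its endpoint and integral constraints", {
  hppd <- 0.016
  for (pars in list(c(0.2, 0.12, 0.3, 0.3), c(0.6, 0.035, 0.2, 0.25),
                    c(0.2, 0.11, 0.35, 0.15))) {
    prof <- build_simulator_profile(hppd, pars[1], pars[2], pars[3], pars[4])
    expect_equal(profile_velocity(prof, 0), 0)
    expect_equal(profile_velocity(prof, prof$duration), 0,
                 tolerance = 1e-10)
    # continuity at the phase boundaries
    for (tb in prof$phases$t0[-1]) {
      expect_equal(profile_velocity(prof, tb - 1e-12),
                   profile_velocity(prof, tb), tolerance = 1e-6)
    }
    tt <- seq(0, prof$duration, length.out = 2001)
    v <- profile_velocity(prof, tt)
    expect_true(all(v >= -1e-12))
    expect_true(all(diff(profile_displacement(prof, tt)) >= -1e-15))
    # displacement reaches hppd within 1e-6 m; mean velocity = hppd/duration
    expect_lt(abs(profile_displacement(prof, prof$duration) - hppd), 1e-6)
    expect_equal(profile_displacement(prof, prof$duration) / prof$duration,
                 hppd / pars[1], tolerance = 1e-9)
    expect_gte(max(v), hppd / pars[1])
  }
})

test_that("simulator profile degenerates to the constant profile as ramps vanish", {
  hppd <- 0.016
  v_mean <- hppd / 0.2
  prof <- build_simulator_profile(hppd, 0.2, 1.01 * v_mean, 0.01, 0.01)
  tt <- seq(0, 0.2, length.out = 4001)
  v <- profile_velocity(prof, tt)
  expect_lt(max(v), 1.011 * v_mean)
  expect_equal(profile_displacement(prof, 0.2), hppd, tolerance = 1e-9)
  # infeasible: plateau below the mean velocity
  expect_error(build_simulator_profile(hppd, 0.2, 0.9 * v_mean, 0.3, 0.3),
               "exceed the mean")
  # infeasible: plateau too low for the phase split
  expect_error(build_simulator_profile(hppd, 0.2, 1.001 * v_mean, 0.3, 0.3),
               "infeasible")
})

test_that("report analysis recovers plateau, acceleration and deceleration of a noiseless profile", {
  prof <- build_simulator_profile(0.016, 0.2, 0.12, 0.3, 0.3)
  rep <- sample_profile_report(prof)
  # a threshold just below 1 isolates the exact plateau in noiseless data
  res <- analyze_report(rep, stationary_threshold = 0.999999)
  expect_equal(res$stationary_mean, 0.12, tolerance = 1e-12)
  expect_equal(res$stationary_sd, 0)
  expect_false(res$degenerate)
  expect_gt(res$acceleration, 0)
  expect_lt(res$deceleration, 0)
})

test_that("constant-velocity report is flagged as degenerate", {
  cam <- fill_cam("conventional")
  prof <- build_rotary_profile(cam, machine_config("rotary_press", 60))
  rep <- sample_profile_report(prof)
  res <- analyze_report(rep)
  expect_true(res$degenerate)
  expect_true(is.na(res$acceleration))
  expect_equal(res$stationary_mean, profile_velocity(prof, 0))
})

test_that("noisy plateau is recovered within the standard error of the window mean", {
  prof <- build_simulator_profile(0.016, 0.2, 0.12, 0.3, 0.3)
  time <- seq(0, prof$duration, by = 1 / 2000)
  set.seed(99)
  sigma <- 0.01 * 0.12
  rep <- punch_report(time, profile_displacement(prof, time),
                      profile_velocity(prof, time) + rnorm(length(time),
                                                           sd = sigma))
  res <- analyze_report(rep)
  expect_lt(abs(res$stationary_mean - 0.12),
            3 * sigma / sqrt(res$n_stationary) + 0.002 * 0.12)
})

test_that("inverse-variance weighting pools means and shrinks the pooled sd", {
  ws <- weighted_stats(c(10, 20), c(1, 2))
  expect_equal(ws$mean, 12.0)
  expect_equal(ws$sd, sqrt(1 / 1.25), tolerance = 1e-12)
  # equal sds reduce to the arithmetic mean with sd/sqrt(n)
  ws2 <- weighted_stats(c(1, 2, 3, 6), rep(0.5, 4))
  expect_equal(ws2$mean, 3)
  expect_equal(ws2$sd, 0.5 / 2)
  # identity for a single report
  ws3 <- weighted_stats(5, 0.3)
  expect_equal(ws3$mean, 5)
  expect_equal(ws3$sd, 0.3)
  expect_error(weighted_stats(numeric(0), numeric(0)), "empty")
  expect_error(weighted_stats(c(1, 2), c(1, 0)), "positive")
  expect_error(weighted_stats(c(1, 2), 1), "equal length")
})

test_that("report ensembles pool correctly and pooled sd scales as 1/sqrt(n)", {
  prof <- build_simulator_profile(0.016, 0.2, 0.12, 0.3, 0.3)
  time <- seq(0, prof$duration, by = 1 / 2000)
  make_rep <- function(seed) {
    set.seed(seed)
    punch_report(time, profile_displacement(prof, time),
                 profile_velocity(prof, time) +
                   rnorm(length(time), sd = 0.01 * 0.12))
  }
  reps <- lapply(1:10, make_rep)
  sm10 <- summarize_reports(reps)
  sm1 <- summarize_reports(reps[1])
  one <- analyze_report(reps[[1]])
  expect_equal(sm1$stationary_velocity_mean, one$stationary_mean)
  expect_equal(sm1$stationary_velocity_sd, one$stationary_sd)
  # roughly equal per-report sds: pooled sd drops like 1/sqrt(n)
  expect_equal(sm10$stationary_velocity_sd * sqrt(10),
               mean(sm10$per_report$stationary_sd), tolerance = 0.1)
  # pull-down time spans the moving part of the trace
  expect_equal(sm10$pull_down_time, prof$duration, tolerance = 2 / 2000)
})

test_that("punch report validation and CSV round-trip preserve the trace", {
  prof <- build_simulator_profile(0.016, 0.2, 0.12, 0.3, 0.3)
  rep <- sample_profile_report(prof, metadata = list(machine = "x", seed = 1))
  path <- tempfile(fileext = ".csv")
  write_punch_report(rep, path)
  back <- read_punch_report(path)
  expect_equal(back$velocity, rep$velocity, tolerance = 1e-12)
  expect_equal(back$displacement, rep$displacement, tolerance = 1e-12)
  expect_equal(back$sampling_rate, 2000)
  expect_error(punch_report(c(0, 0.1, 0.05), 1:3, 1:3), "increasing")
  expect_error(punch_report(c(0, 1e-3, 3e-3), 1:3, 1:3, 2000), "uniformly")
})
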