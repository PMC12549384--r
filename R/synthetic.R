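#' Fixture materials: the three model excipients
#'
#' Returns the bundled material table (DCP: free flowing, dense; MCC: easy
#' flowing, highly compressible; LAC: cohesive, low permeability) as
#' [powder_material()] objects, read from the package's `materials.csv`
#' fixture.
#'
#' @return Named list with elements `DCP`, `MCC`, `LAC`.
#' @export
#' @examples
#' fixture_materials()$LAC$permeability # 5.61e-13 m^2
fixture_materials <- function() {
  path <- system.file("extdata", "materials.csv", package = "suctionfill",
                      mustWork = TRUE)
  read_materials(path)
}

#' Synthetic study scenario
#'
#' Ground-truth parameter set from which punch reports and tablet weights are
#' generated. The velocity-profile parameters define the punch motion (on
#' the compaction simulator a three-phase profile whose stationary velocity
#' defaults to `velocity_factor` times the mean pull-down velocity; on the
#' rotary press a constant profile). The weight model draws tablet masses
#' around `mu_phi * theoretical mass`, where
#' `mu_phi = base_yield * s(dp_max) * g(supply)` with saturating links
#' `s(dp) = 1 - suction_sensitivity * exp(-dp / dp_scale)` and
#' `g(u) = 1 - supply_sensitivity * exp(-u / supply_scale)`; the supply
#' variable `u` is the number of paddle revolutions during the fill. Both
#' links are synthetic constructs for controllable ground truth, not fitted
#' models.
#'
#' @param material A [powder_material()].
#' @param machine,cam_kind Machine and cam identifiers.
#' @param turret_speed,paddle_speed Process speeds, 1/min.
#' @param velocity_factor Stationary velocity as a multiple of the mean
#'   pull-down velocity (simulator profiles only).
#' @param accel_fraction,decel_fraction Simulator profile phase fractions.
#' @param velocity_noise Gaussian velocity noise, as a fraction of the
#'   plateau velocity.
#' @param base_yield Yield with saturated suction and supply.
#' @param suction_sensitivity,supply_sensitivity Deficit fractions at zero
#'   suction pressure / zero supply, each in `[0, 1)`.
#' @param dp_scale Suction saturation scale, Pa.
#' @param supply_scale Supply saturation scale, paddle revolutions.
#' @param weight_rsd Relative standard deviation of tablet weights
#'   (fraction, e.g. 0.015 for 1.5%).
#' @param die A [die_geometry()].
#' @param air An [air_properties()] object.
#' @param seed Integer seed; fixed seed gives byte-identical outputs.
#' @return An object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(material,
                               machine = c("compaction_simulator",
                                           "rotary_press"),
                               cam_kind = c("conventional", "stearate"),
                               turret_speed = 20, paddle_speed = 30,
                               velocity_factor = 1.5,
                               accel_fraction = 0.3, decel_fraction = 0.3,
                               velocity_noise = 0.01,
                               base_yield = 1.0,
                               suction_sensitivity = 0,
                               supply_sensitivity = 0,
                               dp_scale = 5000,
                               supply_scale = 0.2,
                               weight_rsd = 0.015,
                               die = die_geometry(),
                               air = air_properties(),
                               seed = 1L) {
  machine <- match.arg(machine)
  cam_kind <- match.arg(cam_kind)
  stopifnot(inherits(material, "powder_material"),
            velocity_noise >= 0, weight_rsd >= 0,
            base_yield > 0,
            suction_sensitivity >= 0, suction_sensitivity < 1,
            supply_sensitivity >= 0, supply_sensitivity < 1,
            dp_scale > 0, supply_scale > 0)
  seed <- as.integer(seed)
  structure(
    list(material = material, machine = machine, cam_kind = cam_kind,
         turret_speed = turret_speed, paddle_speed = paddle_speed,
         velocity_factor = velocity_factor,
         accel_fraction = accel_fraction, decel_fraction = decel_fraction,
         velocity_noise = velocity_noise,
         base_yield = base_yield,
         suction_sensitivity = suction_sensitivity,
         supply_sensitivity = supply_sensitivity,
         dp_scale = dp_scale, supply_scale = supply_scale,
         weight_rsd = weight_rsd,
         die = die, air = air, seed = seed),
    class = "synthetic_scenario"
  )
}

#' Velocity profile and model spec of a synthetic scenario
#'
#' `scenario_profile()` builds the scenario's punch velocity profile;
#' `scenario_spec()` wraps the scenario into a [pressure_model_spec()].
#'
#' @param scenario A [synthetic_scenario()].
#' @param ... Passed on to [pressure_model_spec()] (e.g. tolerances).
#' @return A `velocity_profile` / `pressure_model_spec`.
#' @export
scenario_profile <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  cam <- fill_cam(scenario$cam_kind,
                  filling_height = scenario$die$filling_height)
  tppd <- pull_down_time(cam$pull_down_angle, scenario$turret_speed)
  if (scenario$machine == "rotary_press") {
    build_rotary_profile(cam, machine_config("rotary_press",
                                             scenario$turret_speed,
                                             scenario$paddle_speed,
                                             die = scenario$die))
  } else {
    build_simulator_profile(cam$hppd, tppd,
                            scenario$velocity_factor * cam$hppd / tppd,
                            scenario$accel_fraction, scenario$decel_fraction)
  }
}

#' @rdname scenario_profile
#' @export
scenario_spec <- function(scenario, ...) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  cam <- fill_cam(scenario$cam_kind,
                  filling_height = scenario$die$filling_height)
  machine <- machine_config(scenario$machine, scenario$turret_speed,
                            scenario$paddle_speed, die = scenario$die)
  pressure_model_spec(scenario$material, cam, machine, air = scenario$air,
                      profile = scenario_profile(scenario), ...)
}

#' Generate one synthetic punch instrumentation report
#'
#' Samples the scenario's velocity profile at the acquisition frequency,
#' adds independent Gaussian noise (sd = `velocity_noise` x plateau
#' velocity) to the velocity channel and keeps the displacement channel as
#' the noiseless integral (instrument-style smooth displacement). Output is
#' deterministic given `(seed, report_index)`.
#'
#' @param scenario A [synthetic_scenario()].
#' @param report_index Report number (distinct reports get independent
#'   noise).
#' @param sampling_rate Acquisition frequency, Hz (default 2000).
#' @return A [punch_report()].
#' @export
generate_punch_report <- function(scenario, report_index = 1L,
                                  sampling_rate = 2000) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  profile <- scenario_profile(scenario)
  time <- seq(0, profile$duration, by = 1 / sampling_rate)
  v <- profile_velocity(profile, time)
  h <- profile_displacement(profile, time)
  plateau <- max(v)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(scenario$seed + 7919L * as.integer(report_index))
  noise <- stats::rnorm(length(v), sd = scenario$velocity_noise * plateau)
  punch_report(time, h, v + noise, sampling_rate = sampling_rate,
               metadata = list(machine = scenario$machine,
                               cam = scenario$cam_kind,
                               material = scenario$material$name,
                               turret_speed = scenario$turret_speed,
                               seed = scenario$seed,
                               report_index = report_index))
}

# Save/restore the global RNG state so generators are reproducible without
# clobbering the caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate a synthetic tablet-weight experiment
#'
#' Draws `n` tablet weights as Gaussians around `mu_phi` times the
#' theoretical tablet mass, with the scenario's weight RSD. The ground-truth
#' mean yield `mu_phi` responds to the maximum suction pressure of the
#' scenario (via [solve_pressure()]) and to the powder supply (paddle
#' revolutions during the fill) through the scenario's saturating links; see
#' [synthetic_scenario()].
#'
#' @param scenario A [synthetic_scenario()].
#' @param n Number of tablets (>= 2).
#' @param dp_max Optional precomputed maximum differential pressure, Pa;
#'   `NULL` solves the scenario's pressure model.
#' @return A [filling_experiment()] with attributes `"mu_phi"` (ground
#'   truth) and `"dp_max"`.
#' @export
generate_tablet_weights <- function(scenario, n = 20L, dp_max = NULL) {
  stopifnot(inherits(scenario, "synthetic_scenario"), n >= 2L)
  if (is.null(dp_max)) {
    dp_max <- solve_pressure(scenario_spec(scenario))$max_delta_p
  }
  profile <- scenario_profile(scenario)
  supply <- scenario$paddle_speed / 60 * profile$duration
  s_link <- 1 - scenario$suction_sensitivity * exp(-dp_max / scenario$dp_scale)
  g_link <- 1 - scenario$supply_sensitivity * exp(-supply / scenario$supply_scale)
  mu_phi <- scenario$base_yield * s_link * g_link
  m_theory <- theoretical_tablet_mass(scenario$die,
                                      scenario$material$rho_bulk)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(scenario$seed + 104729L)
  mu_w <- mu_phi * m_theory
  weights <- stats::rnorm(n, mean = mu_w, sd = scenario$weight_rsd * mu_w)
  weights <- pmax(weights, 0.01 * mu_w) # guard against non-physical draws
  exp_obj <- filling_experiment(scenario$machine, scenario$cam_kind,
                                scenario$material$name,
                                scenario$turret_speed,
                                scenario$paddle_speed, weights)
  attr(exp_obj, "mu_phi") <- mu_phi
  attr(exp_obj, "dp_max") <- dp_max
  exp_obj
}

#' Full experimental design of the die-filling study
#'
#' The study grid: turret speeds 20-60 1/min in steps of 10 on both
#' machines; paddle speeds 5, 10, 20, 30, 40, 50, 60 on the rotary press and
#' the closest settable values 6, 9, 21, 30, 39, 51, 60 on the compaction
#' simulator (settable only in increments of 3).
#'
#' @param machine `"rotary_press"` or `"compaction_simulator"`.
#' @return Data frame with columns `turret_speed`, `paddle_speed`.
#' @export
study_design <- function(machine = c("rotary_press",
                                     "compaction_simulator")) {
  machine <- match.arg(machine)
  turret <- c(20, 30, 40, 50, 60)
  paddle <- if (machine == "rotary_press") {
    c(5, 10, 20, 30, 40, 50, 60)
  } else {
    c(6, 9, 21, 30, 39, 51, 60)
  }
  out <- expand.grid(paddle_speed = paddle, turret_speed = turret,
                     KEEP.OUT.ATTRS = FALSE)
  out[, c("turret_speed", "paddle_speed")]
}

#' Generate a full synthetic study
#'
#' Produces one tablet-weight experiment per design cell (n = 20 tablets on
#' the rotary press, n = 10 on the compaction simulator) and, on the
#' compaction simulator, `n_reports` punch instrumentation reports per
#' turret speed. Each cell's scenario derives from the template with the
#' cell's speeds and a cell-specific seed; the whole dataset is reproducible
#' from the template's seed. Pressure solves are cached per turret speed
#' (the weight model depends on paddle speed only through the supply link).
#'
#' @param template A [synthetic_scenario()] providing material, machine, cam
#'   and ground-truth parameters.
#' @param design Data frame with `turret_speed`, `paddle_speed`; defaults to
#'   the machine's [study_design()]. May be empty (zero rows).
#' @param n_reports Punch reports per simulator turret speed (default 10).
#' @return A list with `experiments` (list of [filling_experiment()]),
#'   `reports` (named by turret speed; empty for the rotary press) and
#'   `design`.
#' @export
generate_study <- function(template, design = NULL, n_reports = 10L) {
  stopifnot(inherits(template, "synthetic_scenario"))
  if (is.null(design)) design <- study_design(template$machine)
  stopifnot(all(c("turret_speed", "paddle_speed") %in% names(design)))
  n_tab <- if (template$machine == "rotary_press") 20L else 10L
  dp_cache <- new.env(parent = emptyenv())
  experiments <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    sc <- template
    sc$turret_speed <- design$turret_speed[i]
    sc$paddle_speed <- design$paddle_speed[i]
    sc$seed <- template$seed + 131L * i
    key <- as.character(sc$turret_speed)
    if (is.null(dp_cache[[key]])) {
      dp_cache[[key]] <- solve_pressure(scenario_spec(sc))$max_delta_p
    }
    experiments[[i]] <- generate_tablet_weights(sc, n = n_tab,
                                                dp_max = dp_cache[[key]])
  }
  reports <- list()
  if (template$machine == "compaction_simulator" && nrow(design) > 0) {
    for (nt in sort(unique(design$turret_speed))) {
      sc <- template
      sc$turret_speed <- nt
      reports[[as.character(nt)]] <- lapply(seq_len(n_reports), function(j) {
        generate_punch_report(sc, report_index = j)
      })
    }
  }
  list(experiments = experiments, reports = reports, design = design)
}
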