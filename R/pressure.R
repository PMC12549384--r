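#' Lumped permeation constant of the suction-pressure model
#'
#' Collapses the ideal-gas and Darcy factors of the in-die pressure balance
#' into a single velocity-scale constant
#' `c = R * T * K * rho_air / (eta_air * L * M_air)` (m/s). With an
#' ideal-gas-consistent air density (`rho_air = patm * M_air / (R * T)`,
#' the default of [air_properties()]) this reduces to
#' `c = K * patm / (eta_air * L)`. Large `c` means the bed re-equilibrates
#' easily and suction pressure stays low.
#'
#' @param permeability Bed permeability K, m^2 (> 0).
#' @param bed_height Powder bed height L, m (> 0).
#' @param air An [air_properties()] object.
#' @return The constant c, m/s.
#' @export
#' @examples
#' model_constant(5.20e-12, 6e-3, air_properties()) # ~4.88 m/s
model_constant <- function(permeability, bed_height, air = air_properties()) {
  stopifnot(inherits(air, "air_properties"))
  if (any(permeability <= 0) || any(bed_height <= 0)) {
    stop("permeability and bed_height must be positive", call. = FALSE)
  }
  air$gas_constant * air$temperature * permeability * air$density /
    (air$dynamic_viscosity * bed_height * air$molar_mass)
}

#' Stationary differential pressure under constant punch velocity
#'
#' The fixed point of the pressure balance: when the punch moves at constant
#' velocity `v`, the in-die pressure relaxes towards
#' `p* = c * patm / (c + v)`, i.e. a stationary differential pressure
#' `delta_p* = patm * v / (c + v)` at which Darcy inflow through the bed
#' balances the volume expansion below it.
#'
#' @param v Punch velocity, m/s (>= 0).
#' @param c Lumped permeation constant from [model_constant()], m/s (> 0).
#' @param patm Ambient pressure, Pa.
#' @return Stationary differential pressure, Pa.
#' @export
#' @examples
#' stationary_delta_p(0.15, 4.88, 101325)
stationary_delta_p <- function(v, c, patm = 101325) {
  if (any(v < 0)) stop("v must be non-negative", call. = FALSE)
  if (any(c <= 0)) stop("c must be positive", call. = FALSE)
  patm * v / (c + v)
}

#' Specification of one suction-pressure calculation
#'
#' Binds together everything one solve needs: the material (for K), the fill
#' cam (for the initial cavity height h0 and pull-down height), the machine
#' (for the bed height L and turret speed), the air properties, the punch
#' velocity profile, and solver settings. When `profile` is `NULL` it is
#' built from the cam and machine: a constant-velocity profile on the rotary
#' press, and a three-phase profile on the compaction simulator with a
#' stationary velocity of `velocity_factor` times the mean pull-down
#' velocity and the given phase fractions.
#'
#' @param material A [powder_material()].
#' @param cam A [fill_cam()].
#' @param machine A [machine_config()].
#' @param air An [air_properties()] object.
#' @param profile A `velocity_profile`, or `NULL` to build the machine
#'   default.
#' @param t_start Integration start time, s (default 1e-6; avoids the h0 = 0
#'   singularity of the conventional cam and is applied to both cams for
#'   uniformity).
#' @param n_output_points Number of evenly spaced output samples spanning
#'   the filling time (default 300).
#' @param rtol,atol Solver relative/absolute tolerances (defaults 1e-6,
#'   1e-8).
#' @param permeability Optional override of the material permeability, m^2.
#'   May be 0 to model an impermeable bed (the Boyle's-law limit); the
#'   lumped constant is then 0.
#' @param velocity_factor,accel_fraction,decel_fraction Parameters of the
#'   default simulator profile (ignored when `profile` is supplied or the
#'   machine is a rotary press).
#' @return An object of class `pressure_model_spec` with derived fields
#'   `c` (m/s), `h0` (m) and `profile`.
#' @export
pressure_model_spec <- function(material, cam, machine,
                                air = air_properties(),
                                profile = NULL,
                                t_start = 1e-6,
                                n_output_points = 300,
                                rtol = 1e-6, atol = 1e-8,
                                permeability = NULL,
                                velocity_factor = 1.5,
                                accel_fraction = 0.3,
                                decel_fraction = 0.3) {
  stopifnot(inherits(material, "powder_material"),
            inherits(cam, "fill_cam"),
            inherits(machine, "machine_config"),
            inherits(air, "air_properties"))
  stopifnot(t_start > 0, n_output_points >= 2, rtol > 0, atol > 0)
  K <- if (is.null(permeability)) material$permeability else permeability
  if (K < 0) stop("permeability must be non-negative", call. = FALSE)
  if (is.null(profile)) {
    if (machine$machine == "rotary_press") {
      profile <- build_rotary_profile(cam, machine)
    } else {
      tppd <- pull_down_time(cam$pull_down_angle, machine$turret_speed)
      v_mean <- cam$hppd / tppd
      profile <- build_simulator_profile(cam$hppd, tppd,
                                         velocity_factor * v_mean,
                                         accel_fraction, decel_fraction)
    }
  }
  stopifnot(inherits(profile, "velocity_profile"))
  if (profile$duration <= t_start) {
    stop("profile duration must exceed t_start", call. = FALSE)
  }
  cc <- if (K > 0) model_constant(K, machine$bed_height, air) else 0
  structure(
    list(
      material = material, cam = cam, machine = machine, air = air,
      profile = profile, t_start = t_start,
      n_output_points = as.integer(n_output_points),
      rtol = rtol, atol = atol,
      permeability = K, c = cc, h0 = cam$h0
    ),
    class = "pressure_model_spec"
  )
}

#' Right-hand side of the in-die pressure balance
#'
#' `dp/dt = (c * (patm - p) - p * v(t)) / (h0 + h(t))`: Darcy inflow through
#' the powder bed replenishes the expanding cavity while the punch motion
#' rarefies it. `h(t)` is the displacement induced by the spec's velocity
#' profile and `h0` the initial cavity height of the cam.
#'
#' @param t Time, s (>= the spec's `t_start`).
#' @param p In-die absolute pressure, Pa.
#' @param spec A [pressure_model_spec()].
#' @return dp/dt, Pa/s.
#' @export
pressure_rhs <- function(t, p, spec) {
  stopifnot(inherits(spec, "pressure_model_spec"))
  h <- spec$h0 + profile_displacement(spec$profile, t)
  if (any(h <= 0)) {
    stop("cavity height h0 + h(t) must be positive (singular at t = 0 for ",
         "the conventional cam; start at t_start > 0)", call. = FALSE)
  }
  v <- profile_velocity(spec$profile, t)
  (spec$c * (spec$air$ambient_pressure - p) - p * v) / h
}

#' Solve the suction-pressure model
#'
#' Integrates the in-die pressure balance from ambient pressure at `t_start`
#' to the end of the punch pull-down with the implicit Runge-Kutta method of
#' the Radau IIA family (order 5) as provided by [deSolve::radau()], and
#' samples the solution at `n_output_points` evenly spaced times spanning
#' `[t_start, filling time]`.
#'
#' @param spec A [pressure_model_spec()].
#' @return An object of class `pressure_curve`: a list with `time` (s),
#'   `pressure` (Pa), `delta_p` (`patm - p`, Pa), `max_delta_p`,
#'   `stationary_delta_p` (analytic fixed point, `NA` unless the profile is
#'   a single constant phase), `rise_time` (first time with
#'   `delta_p >= 0.9 * max_delta_p`) and `spec`.
#' @export
#' @examples
#' mat <- fixture_materials()$DCP
#' spec <- pressure_model_spec(mat, fill_cam("conventional"),
#'                             machine_config("rotary_press", 60))
#' curve <- solve_pressure(spec)
#' curve$max_delta_p
solve_pressure <- function(spec) {
  stopifnot(inherits(spec, "pressure_model_spec"))
  patm <- spec$air$ambient_pressure
  times <- seq(spec$t_start, spec$profile$duration,
               length.out = spec$n_output_points)
  rhs <- function(t, y, parms) {
    h <- spec$h0 + profile_displacement(spec$profile, t)
    v <- profile_velocity(spec$profile, t)
    list((spec$c * (patm - y[1]) - y[1] * v) / h)
  }
  sol <- deSolve::radau(y = c(p = patm), times = times, func = rhs,
                        parms = NULL, rtol = spec$rtol, atol = spec$atol)
  if (attr(sol, "istate")[1] < 0) {
    stop("Radau solver failed to converge; istate = ",
         attr(sol, "istate")[1], call. = FALSE)
  }
  p <- sol[, "p"]
  delta_p <- patm - p
  slack <- max(spec$rtol * patm, spec$atol) * 10
  if (any(delta_p < -slack) || any(delta_p > patm + slack)) {
    stop("solution violates 0 <= delta_p <= patm", call. = FALSE)
  }
  constant_v <- nrow(spec$profile$phases) == 1L &&
    spec$profile$phases$c1[1] == 0 && spec$profile$phases$c2[1] == 0
  stat_dp <- if (constant_v && spec$c > 0) {
    stationary_delta_p(spec$profile$phases$c0[1], spec$c, patm)
  } else {
    NA_real_
  }
  max_dp <- max(delta_p)
  rise_time <- times[which(delta_p >= 0.9 * max_dp)[1]]
  structure(
    list(time = as.numeric(times), pressure = as.numeric(p),
         delta_p = as.numeric(delta_p),
         max_delta_p = max_dp, stationary_delta_p = stat_dp,
         rise_time = rise_time, spec = spec),
    class = "pressure_curve"
  )
}

#' @export
print.pressure_curve <- function(x, ...) {
  cat(sprintf("Pressure curve: %s, %s cam, %s, nt = %g/min\n",
              x$spec$material$name, x$spec$cam$kind,
              x$spec$machine$machine, x$spec$machine$turret_speed))
  cat(sprintf("  %d points over [%.2g, %.4g] s\n",
              length(x$time), x$time[1], x$time[length(x$time)]))
  cat(sprintf("  max delta_p = %.4g Pa (rise time %.4g s)\n",
              x$max_delta_p, x$rise_time))
  if (!is.na(x$stationary_delta_p)) {
    cat(sprintf("  analytic stationary delta_p = %.4g Pa\n",
                x$stationary_delta_p))
  }
  invisible(x)
}

#' Solver convergence error against a tight-tolerance reference
#'
#' Solves the spec twice — at its own tolerances and at the (tighter)
#' reference tolerances — and returns the relative error in the maximum
#' differential pressure, `|max_dp - max_dp_ref| / max_dp_ref`.
#'
#' @param spec A [pressure_model_spec()].
#' @param ref_rtol,ref_atol Reference tolerances (defaults 1e-12, 1e-14);
#'   must not be looser than the spec's.
#' @return Relative error, dimensionless.
#' @export
convergence_error <- function(spec, ref_rtol = 1e-12, ref_atol = 1e-14) {
  stopifnot(inherits(spec, "pressure_model_spec"))
  if (ref_rtol > spec$rtol || ref_atol > spec$atol) {
    stop("reference tolerances must be at least as tight as the spec's",
         call. = FALSE)
  }
  ref_spec <- spec
  ref_spec$rtol <- ref_rtol
  ref_spec$atol <- ref_atol
  dp <- solve_pressure(spec)$max_delta_p
  dp_ref <- solve_pressure(ref_spec)$max_delta_p
  abs(dp - dp_ref) / dp_ref
}

#' Explicit fixed-step oracle integrator for the pressure balance
#'
#' A deliberately simple forward-Euler integrator used as an independent
#' cross-check of [solve_pressure()]. The step is capped at half the local
#' stability limit `(h0 + h) / (c + v)` — near t = 0 the conventional cam's
#' vanishing cavity makes the balance arbitrarily stiff, so a literal fixed
#' step cannot remain stable there; away from that region (and for stearate
#' cams throughout) the nominal step `dt` is used unchanged.
#'
#' @param spec A [pressure_model_spec()].
#' @param dt Nominal step, s (default 1e-6).
#' @return A list with `max_delta_p` and the final `delta_p`.
#' @export
euler_pressure <- function(spec, dt = 1e-6) {
  stopifnot(inherits(spec, "pressure_model_spec"), dt > 0)
  patm <- spec$air$ambient_pressure
  cc <- spec$c
  h0 <- spec$h0
  ph <- spec$profile$phases
  ph_t0 <- ph$t0; ph_t1 <- ph$t1
  ph_c0 <- ph$c0; ph_c1 <- ph$c1; ph_c2 <- ph$c2
  ph_h <- ph$h_start
  t_end <- spec$profile$duration
  # scalar phase-wise evaluation, advancing the phase index with t
  i <- 1L
  n_ph <- nrow(ph)
  t <- spec$t_start
  p <- patm
  max_dp <- 0
  eps <- .Machine$double.eps
  while (t < t_end) {
    while (i < n_ph && t >= ph_t1[i]) i <- i + 1L
    tau <- t - ph_t0[i]
    v <- ph_c0[i] + ph_c1[i] * tau + ph_c2[i] * tau^2
    h <- h0 + ph_h[i] + ph_c0[i] * tau + ph_c1[i] * tau^2 / 2 +
      ph_c2[i] * tau^3 / 3
    step <- min(dt, 0.5 * h / (cc + v + eps), t_end - t)
    p <- p + step * (cc * (patm - p) - p * v) / h
    t <- t + step
    dp <- patm - p
    if (dp > max_dp) max_dp <- dp
  }
  list(max_delta_p = max_dp, final_delta_p = patm - p)
}

#' Compare suction-pressure scenarios
#'
#' Solves each spec and tabulates the maximum differential pressure, the
#' analytic stationary value (constant-velocity profiles only) and the rise
#' time (first time at 90% of the maximum), together with pairwise ratios of
#' the maxima.
#'
#' @param specs List of [pressure_model_spec()] objects (>= 2).
#' @param labels Optional character labels; defaults to
#'   material/machine/cam/turret-speed tags.
#' @return A data frame (one row per scenario) with attribute
#'   `"ratio_matrix"` holding the pairwise max-delta-p ratios.
#' @export
compare_scenarios <- function(specs, labels = NULL) {
  stopifnot(length(specs) >= 2L)
  curves <- lapply(specs, solve_pressure)
  if (is.null(labels)) {
    labels <- vapply(specs, function(s) {
      paste(s$material$name, s$machine$machine, s$cam$kind,
            paste0("nt", s$machine$turret_speed), sep = "/")
    }, character(1))
  }
  out <- data.frame(
    scenario = labels,
    max_delta_p = vapply(curves, `[[`, numeric(1), "max_delta_p"),
    stationary_delta_p = vapply(curves, `[[`, numeric(1),
                                "stationary_delta_p"),
    rise_time = vapply(curves, `[[`, numeric(1), "rise_time"),
    stringsAsFactors = FALSE
  )
  ratios <- outer(out$max_delta_p, out$max_delta_p, "/")
  dimnames(ratios) <- list(labels, labels)
  attr(out, "ratio_matrix") <- ratios
  out
}
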