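#' Punch pull-down time from the cam sector and turret speed
#'
#' The pull-down occupies an angular sector `theta_ppd` of the die table, so
#' at turret speed `nt` (1/min) the pull-down lasts the corresponding
#' fraction of one revolution: `t_ppd = theta_ppd / 360 * 60 / nt` seconds.
#'
#' @param theta_ppd Pull-down angle, degrees, in (0, 360].
#' @param turret_speed Turret speed nt, 1/min.
#' @return Pull-down time, s.
#' @export
#' @examples
#' pull_down_time(72, 60) # 0.2 s
pull_down_time <- function(theta_ppd, turret_speed) {
  if (any(theta_ppd <= 0) || any(theta_ppd > 360)) {
    stop("theta_ppd must be in (0, 360] degrees", call. = FALSE)
  }
  if (any(turret_speed <= 0)) {
    stop("turret_speed must be positive", call. = FALSE)
  }
  theta_ppd / 360 * 60 / turret_speed
}

#' Linear punch pull-down velocity
#'
#' `v_ppd = h_ppd / t_ppd`: the constant velocity with which a cam-guided
#' punch traverses the effective pull-down height in the pull-down time.
#'
#' @param hppd Effective pull-down height under the powder bed, m.
#' @param tppd Pull-down time, s.
#' @return Velocity, m/s.
#' @export
#' @examples
#' linear_pull_down_velocity(0.016, 0.2) # 0.08 m/s
linear_pull_down_velocity <- function(hppd, tppd) {
  if (any(hppd <= 0) || any(tppd <= 0)) {
    stop("hppd and tppd must be positive", call. = FALSE)
  }
  hppd / tppd
}

# Internal constructor: a piecewise-quadratic velocity profile.
# phases: data.frame(t0, t1, c0, c1, c2, h_start) with
#   v(t) = c0 + c1*(t - t0) + c2*(t - t0)^2   on [t0, t1]
#   h(t) = h_start + c0*tau + c1*tau^2/2 + c2*tau^3/3,  tau = t - t0
new_velocity_profile <- function(phases, hppd, kind) {
  stopifnot(is.data.frame(phases), nrow(phases) >= 1L)
  structure(
    list(
      phases = phases,
      duration = phases$t1[nrow(phases)],
      hppd = hppd,
      kind = kind
    ),
    class = "velocity_profile"
  )
}

#' Evaluate a velocity profile
#'
#' `profile_velocity()` returns the punch velocity v(t) (m/s) and
#' `profile_displacement()` the induced displacement h(t) (m, measured
#' downward-positive from the punch's position at t = 0, obtained as the
#' exact integral of the piecewise-quadratic velocity). Times outside
#' `[0, duration]` are clamped: v = 0 and h is held at its boundary value.
#'
#' @param profile A `velocity_profile` from [build_rotary_profile()] or
#'   [build_simulator_profile()].
#' @param t Time(s), s.
#' @return Numeric vector of velocities (m/s) or displacements (m).
#' @export
profile_velocity <- function(profile, t) {
  stopifnot(inherits(profile, "velocity_profile"))
  ph <- profile$phases
  idx <- findInterval(t, ph$t0)
  out <- numeric(length(t))
  inside <- idx >= 1L & t <= profile$duration & t >= 0
  i <- idx[inside]
  tau <- t[inside] - ph$t0[i]
  out[inside] <- ph$c0[i] + ph$c1[i] * tau + ph$c2[i] * tau^2
  out
}

#' @rdname profile_velocity
#' @export
profile_displacement <- function(profile, t) {
  stopifnot(inherits(profile, "velocity_profile"))
  ph <- profile$phases
  tc <- pmin(pmax(t, 0), profile$duration)
  idx <- pmax(findInterval(tc, ph$t0), 1L)
  tau <- tc - ph$t0[idx]
  ph$h_start[idx] + ph$c0[idx] * tau + ph$c1[idx] * tau^2 / 2 +
    ph$c2[idx] * tau^3 / 3
}

#' @export
print.velocity_profile <- function(x, ...) {
  cat(sprintf("Velocity profile (%s): %d phase(s), duration %.4g s, hppd %.4g m\n",
              x$kind, nrow(x$phases), x$duration, x$hppd))
  cat(sprintf("  mean velocity %.4g m/s, max velocity %.4g m/s\n",
              x$hppd / x$duration,
              max(profile_velocity(x, seq(0, x$duration, length.out = 512)))))
  invisible(x)
}

#' Constant-velocity pull-down profile for the rotary press
#'
#' On a rotary press the turret guides the punch down a linear cam slope, so
#' the pull-down velocity is constant: a single phase of duration
#' `pull_down_time(theta_ppd, nt)` at `hppd / t_ppd`.
#'
#' @param cam A [fill_cam()].
#' @param machine A [machine_config()] with `machine = "rotary_press"`.
#' @return A `velocity_profile` with one constant phase.
#' @export
#' @examples
#' prof <- build_rotary_profile(fill_cam("conventional"),
#'                              machine_config("rotary_press", 60))
#' profile_displacement(prof, prof$duration) # = hppd
build_rotary_profile <- function(cam, machine) {
  stopifnot(inherits(cam, "fill_cam"), inherits(machine, "machine_config"))
  if (machine$machine != "rotary_press") {
    stop("build_rotary_profile() requires a rotary_press machine_config",
         call. = FALSE)
  }
  tppd <- pull_down_time(cam$pull_down_angle, machine$turret_speed)
  v <- linear_pull_down_velocity(cam$hppd, tppd)
  phases <- data.frame(t0 = 0, t1 = tppd, c0 = v, c1 = 0, c2 = 0, h_start = 0)
  new_velocity_profile(phases, hppd = cam$hppd, kind = "rotary_constant")
}

#' Three-phase pull-down profile for the compaction simulator
#'
#' On a compaction simulator the punch is accelerated from rest to a
#' stationary velocity and decelerated back to rest to hit the target filling
#' height exactly. Acceleration and deceleration phases are second-degree
#' polynomials in time chosen so that v(0) = 0, v is continuous at the phase
#' boundaries, v(end) = 0, and the total displacement equals `hppd`; the
#' time-averaged velocity therefore equals `hppd / target_duration`.
#'
#' Given the phase split, feasibility requires the per-phase fill factor
#' `gamma = (hppd - v_s * t_stationary) / (v_s * (t_accel + t_decel))`
#' to lie in `[1/3, 2/3]` (the range attainable by a monotone quadratic
#' ramp); outside that range the constraint set is infeasible and an error is
#' raised. In particular `stationary_velocity` must exceed the mean velocity
#' `hppd / target_duration`.
#'
#' @param hppd Effective pull-down height, m.
#' @param target_duration Total pull-down duration, s.
#' @param stationary_velocity Plateau velocity v_s, m/s.
#' @param accel_fraction,decel_fraction Fractions of the duration spent
#'   accelerating / decelerating, each in (0, 1), sum < 1.
#' @return A `velocity_profile` with three phases.
#' @export
#' @examples
#' prof <- build_simulator_profile(0.016, 0.2, 0.12, 0.3, 0.3)
#' profile_displacement(prof, 0.2) # 0.016
build_simulator_profile <- function(hppd, target_duration, stationary_velocity,
                                    accel_fraction = 0.3,
                                    decel_fraction = 0.3) {
  stopifnot(hppd > 0, target_duration > 0, stationary_velocity > 0)
  if (!(accel_fraction > 0 && decel_fraction > 0 &&
        accel_fraction + decel_fraction < 1)) {
    stop("accel/decel fractions must be in (0,1) with sum < 1", call. = FALSE)
  }
  v_mean <- hppd / target_duration
  if (stationary_velocity <= v_mean) {
    stop("stationary_velocity must exceed the mean velocity hppd/duration (",
         signif(v_mean, 4), " m/s)", call. = FALSE)
  }
  t_a <- accel_fraction * target_duration
  t_d <- decel_fraction * target_duration
  t_s <- target_duration - t_a - t_d
  v_s <- stationary_velocity
  gamma <- (hppd - v_s * t_s) / (v_s * (t_a + t_d))
  tol <- 1e-9
  if (gamma < 1 / 3 - tol || gamma > 2 / 3 + tol) {
    stop("infeasible profile: ramp fill factor ", signif(gamma, 4),
         " outside [1/3, 2/3]; adjust stationary_velocity or phase fractions",
         call. = FALSE)
  }
  gamma <- min(max(gamma, 1 / 3), 2 / 3)
  # accelerating ramp v(tau) = b*tau + a*tau^2 with v(t_a) = v_s and
  # integral gamma*v_s*t_a; the decelerating ramp is its time mirror
  a_a <- 6 * v_s * (0.5 - gamma) / t_a^2
  b_a <- v_s * (6 * gamma - 2) / t_a
  a_d <- 6 * v_s * (0.5 - gamma) / t_d^2
  b_d <- v_s * (6 * gamma - 2) / t_d
  h_a <- gamma * v_s * t_a
  phases <- data.frame(
    t0 = c(0, t_a, t_a + t_s),
    t1 = c(t_a, t_a + t_s, target_duration),
    c0 = c(0, v_s, v_s),
    c1 = c(b_a, 0, -(b_d + 2 * a_d * t_d)),
    c2 = c(a_a, 0, a_d),
    h_start = c(0, h_a, h_a + v_s * t_s)
  )
  new_velocity_profile(phases, hppd = hppd, kind = "simulator_three_phase")
}

#' Punch instrumentation report
#'
#' A time series of lower-punch displacement and velocity as produced by the
#' compaction-simulator instrumentation, sampled uniformly (2000 Hz by
#' default). Displacement is downward-positive from the punch position at the
#' start of the report.
#'
#' @param time Sample times, s, strictly increasing and uniformly spaced.
#' @param displacement Punch displacement, m.
#' @param velocity Punch velocity, m/s.
#' @param sampling_rate Acquisition frequency, Hz.
#' @param metadata Optional named list (machine, cam, turret speed, seed ...)
#'   carried through to CSV export.
#' @return An object of class `punch_report`.
#' @export
punch_report <- function(time, displacement, velocity, sampling_rate = 2000,
                         metadata = list()) {
  stopifnot(length(time) == length(displacement),
            length(time) == length(velocity), length(time) >= 2L)
  dt <- diff(time)
  if (any(dt <= 0)) stop("time must be strictly increasing", call. = FALSE)
  if (max(abs(dt - 1 / sampling_rate)) > 1e-6 / sampling_rate) {
    stop("time must be uniformly spaced at the stated sampling rate",
         call. = FALSE)
  }
  structure(
    list(time = time, displacement = displacement, velocity = velocity,
         sampling_rate = sampling_rate, metadata = metadata),
    class = "punch_report"
  )
}

#' Analyze one punch instrumentation report
#'
#' Detects the stationary (plateau) window as the maximal contiguous run of
#' samples with velocity at or above `stationary_threshold` times the peak
#' velocity, and reports the mean and standard deviation of the velocity over
#' that window. The acceleration (deceleration) is the slope of an ordinary
#' least-squares line fitted to velocity versus time on the segment before
#' (after) the window; segments with fewer than 3 samples are flagged and
#' yield `NA` slopes.
#'
#' @param report A [punch_report()].
#' @param stationary_threshold Plateau detection threshold as a fraction of
#'   the maximum velocity (default 0.95).
#' @return A list with `stationary_mean`, `stationary_sd`, `n_stationary`,
#'   `acceleration`, `deceleration` (m/s^2), `window` (index range) and
#'   `degenerate` (TRUE when an acceleration or deceleration segment is too
#'   short to fit, e.g. a constant-velocity report).
#' @export
analyze_report <- function(report, stationary_threshold = 0.95) {
  stopifnot(inherits(report, "punch_report"))
  if (!(stationary_threshold > 0 && stationary_threshold < 1)) {
    stop("stationary_threshold must be in (0, 1)", call. = FALSE)
  }
  v <- report$velocity
  t <- report$time
  vmax <- max(v)
  if (vmax <= 0) stop("report contains no positive velocity", call. = FALSE)
  in_plateau <- v >= stationary_threshold * vmax
  if (!any(in_plateau)) stop("empty stationary window", call. = FALSE)
  runs <- rle(in_plateau)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  best <- keep[which.max(runs$lengths[keep])]
  w0 <- starts[best]
  w1 <- ends[best]
  window <- w0:w1
  ols_slope <- function(idx) {
    if (length(idx) < 3L) return(NA_real_)
    stats::cov(t[idx], v[idx]) / stats::var(t[idx])
  }
  pre <- seq_len(w0 - 1L)
  post <- if (w1 < length(v)) (w1 + 1L):length(v) else integer(0)
  accel <- ols_slope(pre)
  decel <- ols_slope(post)
  list(
    stationary_mean = mean(v[window]),
    stationary_sd = stats::sd(v[window]),
    n_stationary = length(window),
    acceleration = accel,
    deceleration = decel,
    window = c(w0, w1),
    degenerate = is.na(accel) || is.na(decel)
  )
}

#' Inverse-variance weighted mean and standard deviation
#'
#' Pools per-report means with inverse-variance weights:
#' `mu_w = sum(mu_i / sd_i^2) / sum(1 / sd_i^2)` and
#' `sd_w = sqrt(1 / sum(1 / sd_i^2))`. With equal per-report standard
#' deviations this reduces to the arithmetic mean with `sd_w = sd / sqrt(n)`.
#'
#' @param means Per-report means.
#' @param sds Per-report standard deviations, all > 0, same length.
#' @return A list with `mean` and `sd`.
#' @export
#' @examples
#' weighted_stats(c(10, 20), c(1, 2)) # mean 12, sd ~0.894
weighted_stats <- function(means, sds) {
  if (length(means) == 0L) stop("empty input", call. = FALSE)
  if (length(means) != length(sds)) {
    stop("means and sds must have equal length", call. = FALSE)
  }
  if (any(sds <= 0)) stop("all sds must be positive", call. = FALSE)
  w <- 1 / sds^2
  list(mean = sum(means * w) / sum(w), sd = sqrt(1 / sum(w)))
}

#' Summarize an ensemble of punch reports
#'
#' Applies [analyze_report()] to each report and pools the per-report
#' stationary velocities with [weighted_stats()]. The pull-down time is the
#' mean over reports of the span between the first and last sample at which
#' the displacement changes.
#'
#' @param reports List of [punch_report()] objects (>= 1).
#' @param stationary_threshold Passed to [analyze_report()].
#' @return A list of class `kinematics_summary`: `pull_down_time` (s),
#'   `stationary_velocity_mean`, `stationary_velocity_sd` (m/s, pooled),
#'   `acceleration`, `deceleration` (m/s^2, means over reports),
#'   `n_reports`, and `per_report` (data frame of per-report results).
#' @export
summarize_reports <- function(reports, stationary_threshold = 0.95) {
  stopifnot(length(reports) >= 1L)
  per <- lapply(reports, analyze_report,
                stationary_threshold = stationary_threshold)
  moving_span <- function(r) {
    dh <- abs(diff(r$displacement))
    moving <- which(dh > .Machine$double.eps * max(1, abs(r$displacement)))
    if (length(moving) == 0L) return(NA_real_)
    r$time[max(moving) + 1L] - r$time[min(moving)]
  }
  spans <- vapply(reports, moving_span, numeric(1))
  pooled <- weighted_stats(
    vapply(per, `[[`, numeric(1), "stationary_mean"),
    vapply(per, `[[`, numeric(1), "stationary_sd")
  )
  per_df <- data.frame(
    report = seq_along(per),
    stationary_mean = vapply(per, `[[`, numeric(1), "stationary_mean"),
    stationary_sd = vapply(per, `[[`, numeric(1), "stationary_sd"),
    acceleration = vapply(per, `[[`, numeric(1), "acceleration"),
    deceleration = vapply(per, `[[`, numeric(1), "deceleration")
  )
  structure(
    list(
      pull_down_time = mean(spans, na.rm = TRUE),
      stationary_velocity_mean = pooled$mean,
      stationary_velocity_sd = pooled$sd,
      acceleration = mean(per_df$acceleration, na.rm = TRUE),
      deceleration = mean(per_df$deceleration, na.rm = TRUE),
      n_reports = length(reports),
      per_report = per_df
    ),
    class = "kinematics_summary"
  )
}

#' @export
print.kinematics_summary <- function(x, ...) {
  cat(sprintf("Kinematics summary over %d report(s):\n", x$n_reports))
  cat(sprintf("  pull-down time: %.4g s\n", x$pull_down_time))
  cat(sprintf("  stationary velocity: %.4g +/- %.2g m/s (inverse-variance pooled)\n",
              x$stationary_velocity_mean, x$stationary_velocity_sd))
  cat(sprintf("  acceleration: %.4g m/s^2, deceleration: %.4g m/s^2\n",
              x$acceleration, x$deceleration))
  invisible(x)
}
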