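test_that("lumped permeation constant collapses to K*patm/(eta*L) for ideal-gas air", {
  air <- air_properties()
  K <- 5.20e-12
  L <- 6e-3
  c1 <- model_constant(K, L, air)
  expect_equal(c1, K * air$ambient_pressure / (air$dynamic_viscosity * L),
               tolerance = 1e-12)
  expect_equal(c1, 4.8786, tolerance = 1e-4)
  # linear in K, inverse in L; equal K/L ratios give equal c
  expect_equal(model_constant(2 * K, L, air), 2 * c1)
  expect_equal(model_constant(K, 2 * L, air), c1 / 2)
  expect_equal(model_constant(3 * K, 3 * L, air), c1, tolerance = 1e-12)
  expect_error(model_constant(0, L, air), "positive")
  expect_error(model_constant(K, -1, air), "positive")
})

test_that("air properties enforce ideal-gas self-consistency", {
  air <- air_properties()
  rho_ideal <- air$ambient_pressure * air$molar_mass /
    (air$gas_constant * air$temperature)
  expect_equal(air$density, rho_ideal)
  expect_equal(air$density, 1.2, tolerance = 0.01)
  expect_error(air_properties(density = 2.0), "inconsistent")
  expect_silent(air_properties(density = rho_ideal * 1.005))
})

test_that("stationary differential pressure is the fixed point patm*v/(c+v)", {
  expect_equal(stationary_delta_p(0, 5), 0)
  # perfectly permeable bed: delta_p vanishes
  expect_lt(stationary_delta_p(0.15, 1e9), 1e-3)
  expect_equal(stationary_delta_p(0.15, 4.878611, 101325),
               101325 * 0.15 / (4.878611 + 0.15), tolerance = 1e-12)
  # monotone increasing in v
  v <- seq(0.01, 1, length.out = 20)
  expect_true(all(diff(stationary_delta_p(v, 2)) > 0))
  expect_error(stationary_delta_p(-0.1, 1), "non-negative")
  expect_error(stationary_delta_p(0.1, 0), "positive")
})

test_that("pressure balance right-hand side has the correct equilibria and signs", {
  mats <- test_materials()
  spec <- rotary_spec(mats$DCP, "stearate", 60)
  patm <- spec$air$ambient_pressure
  # no punch motion at ambient pressure: equilibrium (evaluate past the
  # profile where v = 0)
  spec_still <- spec
  expect_equal(pressure_rhs(spec$profile$duration + 1, patm, spec_still), 0)
  # at ambient pressure with the punch moving, pressure must fall
  t0 <- spec$t_start
  v0 <- profile_velocity(spec$profile, t0)
  h <- spec$h0 + profile_displacement(spec$profile, t0)
  expect_equal(pressure_rhs(t0, patm, spec), -patm * v0 / h)
  expect_lt(pressure_rhs(t0, patm, spec), 0)
  # the constant-velocity fixed point zeroes the numerator
  p_star <- spec$c * patm / (spec$c + v0)
  expect_equal(pressure_rhs(t0, p_star, spec), 0, tolerance = 1e-9)
})

test_that("solver output meets the curve contract", {
  mats <- test_materials()
  spec <- rotary_spec(mats$MCC, "conventional", 60)
  curve <- solve_pressure(spec)
  patm <- spec$air$ambient_pressure
  expect_length(curve$time, 300)
  expect_equal(curve$time[1], spec$t_start)
  expect_equal(curve$time[300], spec$profile$duration)
  # evenly spaced output grid
  expect_true(all(abs(diff(diff(curve$time))) < 1e-12))
  # pressure starts at ambient and delta_p stays inside [0, patm]
  expect_lt(abs(curve$delta_p[1]), spec$rtol * patm)
  expect_true(all(curve$delta_p >= -1e-6 * patm))
  expect_true(all(curve$delta_p <= patm))
  # constant v: delta_p nondecreasing and bounded by the fixed point
  # (up to the solver's own tolerance once the fixed point is reached)
  expect_true(all(diff(curve$delta_p) >= -spec$rtol * patm))
  expect_true(all(curve$delta_p <=
                    curve$stationary_delta_p + spec$rtol * patm))
  # long-horizon convergence to the analytic fixed point
  expect_equal(curve$delta_p[300], curve$stationary_delta_p,
               tolerance = 1e-4)
})

test_that("impermeable-bed solution follows Boyle's law along the whole curve", {
  mats <- test_materials()
  for (nt in c(20, 60)) {
    spec <- pressure_model_spec(mats$DCP, fill_cam("stearate"),
                                machine_config("rotary_press", nt),
                                permeability = 0)
    curve <- solve_pressure(spec)
    patm <- spec$air$ambient_pressure
    h <- spec$h0 + profile_displacement(spec$profile, curve$time)
    # conserved: p*(h0+h) anchored at the integration start
    const0 <- patm * (spec$h0 +
                        profile_displacement(spec$profile, spec$t_start))
    expect_lt(max(abs(curve$pressure * h - const0)) / const0, spec$rtol)
    # the anchor differs from patm*h0 only by the t_start expansion offset
    # v * t_start / h0 (largest at the fastest turret speed tested)
    expect_lt(abs(const0 - patm * spec$h0) / (patm * spec$h0), 2e-5)
  }
})

test_that("explicit-step oracle agrees with the stiff solver on max delta_p", {
  mats <- test_materials()
  specs <- list(
    rotary_spec(mats$DCP, "conventional", 60),
    rotary_spec(mats$LAC, "stearate", 20),
    simulator_spec(mats$MCC, "conventional", 60)
  )
  for (spec in specs) {
    ode <- solve_pressure(spec)$max_delta_p
    euler <- euler_pressure(spec, dt = 1e-6)$max_delta_p
    expect_lt(abs(euler - ode) / ode, 0.005)
  }
})

test_that("co-scaling permeability and bed height leaves the solution unchanged", {
  mats <- test_materials()
  base <- rotary_spec(mats$MCC, "conventional", 40)
  mach_scaled <- machine_config("rotary_press", 40, bed_height = 3 * 6e-3)
  scaled <- pressure_model_spec(mats$MCC, fill_cam("conventional"),
                                mach_scaled,
                                permeability = 3 * mats$MCC$permeability)
  expect_equal(scaled$c, base$c, tolerance = 1e-12)
  expect_equal(solve_pressure(scaled)$max_delta_p,
               solve_pressure(base)$max_delta_p, tolerance = 1e-6)
})

test_that("stearate cam with full 16 mm travel reproduces the conventional stationary delta_p", {
  mats <- test_materials()
  conv <- rotary_spec(mats$MCC, "conventional", 40)
  # same travel distance (hppd = 16 mm) but with the stearate air pocket
  cam_full <- fill_cam("stearate", pre_pull_height = 4.7e-3,
                       filling_height = 16e-3 + 4.7e-3)
  expect_equal(cam_full$hppd, 16e-3)
  ste_full <- pressure_model_spec(mats$MCC, cam_full,
                                  machine_config("rotary_press", 40))
  c_conv <- solve_pressure(conv)
  c_ste <- solve_pressure(ste_full)
  expect_equal(c_ste$stationary_delta_p, c_conv$stationary_delta_p,
               tolerance = 1e-9)
  # and both curves actually reach it
  expect_equal(c_ste$delta_p[300], c_conv$delta_p[300], tolerance = 0.01)
})

test_that("mass balance: d(n)/dt along the solution equals the Darcy inflow", {
  mats <- test_materials()
  spec <- rotary_spec(mats$LAC, "stearate", 20)
  curve <- solve_pressure(spec)
  air <- spec$air
  A <- spec$machine$die$area
  h <- spec$h0 + profile_displacement(spec$profile, curve$time)
  V <- A * h
  n_mol <- curve$pressure * V / (air$gas_constant * air$temperature)
  dndt_num <- diff(n_mol) / diff(curve$time)
  t_mid <- (curve$time[-1] + curve$time[-300]) / 2
  p_mid <- (curve$pressure[-1] + curve$pressure[-300]) / 2
  dndt_darcy <- spec$permeability * A * air$density /
    (air$dynamic_viscosity * spec$machine$bed_height * air$molar_mass) *
    (air$ambient_pressure - p_mid)
  scale <- max(abs(dndt_darcy))
  expect_lt(max(abs(dndt_num - dndt_darcy)) / scale, 0.02)
})

test_that("scenario comparison ranks cams and materials as the physics dictates", {
  mats <- test_materials()
  specs <- list(
    conv = rotary_spec(mats$MCC, "conventional", 40),
    ste = rotary_spec(mats$MCC, "stearate", 40),
    lac_ste = rotary_spec(mats$LAC, "stearate", 40)
  )
  tab <- compare_scenarios(specs, labels = names(specs))
  expect_equal(nrow(tab), 3)
  # stearate cam: lower max delta_p, slower buildup (its air pocket makes
  # the relaxation time resolvable; the conventional rotary buildup is
  # quasi-instantaneous)
  expect_lt(tab$max_delta_p[tab$scenario == "ste"],
            tab$max_delta_p[tab$scenario == "conv"])
  expect_gt(tab$rise_time[tab$scenario == "ste"],
            tab$rise_time[tab$scenario == "conv"])
  # low-permeability material: slower buildup at matched cam and speed
  expect_gt(tab$rise_time[tab$scenario == "lac_ste"],
            tab$rise_time[tab$scenario == "ste"])
  ratios <- attr(tab, "ratio_matrix")
  expect_equal(unname(diag(ratios)), rep(1, 3))
  # identical specs give ratio 1
  tab2 <- compare_scenarios(list(specs$conv, specs$conv))
  expect_equal(unname(attr(tab2, "ratio_matrix")[1, 2]), 1)
})

test_that("solver error against the tight reference shrinks as tolerances tighten", {
  mats <- test_materials()
  make <- function(rt) {
    pressure_model_spec(mats$LAC, fill_cam("stearate"),
                        machine_config("compaction_simulator", 20),
                        rtol = rt, atol = rt * 1e-2)
  }
  errs <- vapply(c(1e-4, 1e-6, 1e-8), function(rt) {
    convergence_error(make(rt))
  }, numeric(1))
  expect_lte(errs[2], errs[1] + 1e-12)
  expect_lte(errs[3], errs[2] + 1e-12)
  # self-comparison is exact up to floating-point noise
  spec <- make(1e-12)
  expect_lt(convergence_error(spec, 1e-12, 1e-14), 1e-9)
  expect_error(convergence_error(make(1e-8), ref_rtol = 1e-4), "tight")
})

test_that("pressure curves export and re-import with their provenance metadata", {
  mats <- test_materials()
  spec <- rotary_spec(mats$DCP, "conventional", 60)
  curve <- solve_pressure(spec)
  path <- tempfile(fileext = ".csv")
  write_pressure_curve(curve, path)
  back <- read_pressure_curve(path)
  expect_equal(back$delta_p_pa, curve$delta_p, tolerance = 1e-9)
  meta <- attr(back, "metadata")
  expect_equal(meta$material, "DCP")
  expect_equal(as.numeric(meta$rtol), spec$rtol)
  # re-solving from the recorded configuration reproduces the curve
  again <- solve_pressure(spec)
  expect_identical(again$delta_p, curve$delta_p)
})
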