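#' Powder material constants
#'
#' Container for the material constants of one excipient blend: particle-size
#' quantiles, bulk/tapped/particle densities and the air permeability of the
#' powder bed at 1 kPa normal stress. Densities are stored in g/cm^3 as
#' conventionally tabulated; computations that need SI convert internally.
#'
#' @param name Material name (e.g. `"DCP"`).
#' @param x10,x50,x90 Particle-size distribution quantiles, um.
#' @param rho_bulk Bulk density, g/cm^3.
#' @param rho_tapped Tapped density, g/cm^3.
#' @param rho_particle Particle (true) density, g/cm^3.
#' @param permeability Darcy air permeability K at 1 kPa normal stress, m^2.
#' @param ffc Optional flow function coefficient (dimensionless).
#'
#' @return An object of class `powder_material`.
#' @export
#' @examples
#' dcp <- powder_material("DCP", 70.2, 167.0, 292.3,
#'                        rho_bulk = 0.738, rho_tapped = 0.870,
#'                        rho_particle = 2.838, permeability = 5.20e-12)
powder_material <- function(name, x10, x50, x90,
                            rho_bulk, rho_tapped, rho_particle,
                            permeability, ffc = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!(rho_bulk > 0 && rho_bulk <= rho_tapped && rho_tapped <= rho_particle)) {
    stop("densities must satisfy 0 < rho_bulk <= rho_tapped <= rho_particle",
         call. = FALSE)
  }
  if (!is.finite(permeability) || permeability <= 0) {
    stop("permeability must be positive", call. = FALSE)
  }
  if (!(x10 <= x50 && x50 <= x90)) {
    stop("particle sizes must satisfy x10 <= x50 <= x90", call. = FALSE)
  }
  structure(
    list(
      name = name, x10 = x10, x50 = x50, x90 = x90,
      rho_bulk = rho_bulk, rho_tapped = rho_tapped,
      rho_particle = rho_particle,
      permeability = permeability, ffc = ffc
    ),
    class = "powder_material"
  )
}

#' @export
print.powder_material <- function(x, ...) {
  cat(sprintf("Powder material '%s'\n", x$name))
  cat(sprintf("  x10/x50/x90: %.1f / %.1f / %.1f um\n", x$x10, x$x50, x$x90))
  cat(sprintf("  rho_b/rho_t/rho_s: %.3f / %.3f / %.3f g/cm^3 (CI = %.1f%%)\n",
              x$rho_bulk, x$rho_tapped, x$rho_particle,
              compressibility_index(x$rho_bulk, x$rho_tapped)))
  cat(sprintf("  K = %.3g m^2\n", x$permeability))
  invisible(x)
}

#' Flow function coefficient from a shear-cell measurement
#'
#' Ratio of the consolidation stress to the unconfined yield strength,
#' `ffc = sigma1 / sigma0`, the standard ring-shear flowability measure.
#'
#' @param sigma1 Consolidation stress, kPa.
#' @param sigma0 Unconfined yield strength, kPa. Must be strictly positive.
#'
#' @return The dimensionless flow function coefficient.
#' @export
#' @examples
#' flow_function_coefficient(8, 2) # 4
flow_function_coefficient <- function(sigma1, sigma0) {
  stopifnot(is.numeric(sigma1), is.numeric(sigma0))
  if (any(sigma1 <= 0)) stop("sigma1 must be positive", call. = FALSE)
  if (any(sigma0 <= 0)) {
    stop("sigma0 must be positive (non-physical yield strength)", call. = FALSE)
  }
  sigma1 / sigma0
}

#' Jenike flowability class from the flow function coefficient
#'
#' Maps ffc onto the Jenike classes: very cohesive (ffc < 2), cohesive
#' (2-4), easy flowing (4-10), free flowing (> 10).
#'
#' @param ffc Flow function coefficient(s), dimensionless, > 0.
#' @return Character vector of class labels.
#' @export
#' @examples
#' classify_flowability(c(1.5, 3, 6, 25))
classify_flowability <- function(ffc) {
  stopifnot(is.numeric(ffc))
  if (any(!is.finite(ffc)) || any(ffc <= 0)) {
    stop("ffc must be positive and finite", call. = FALSE)
  }
  labels <- c("very cohesive", "cohesive", "easy flowing", "free flowing")
  labels[findInterval(ffc, c(2, 4, 10)) + 1L]
}

#' Carr compressibility index
#'
#' `CI = (rho_tapped - rho_bulk) / rho_tapped * 100`, in percent.
#'
#' @param rho_bulk Bulk density, g/cm^3 (any unit consistent with
#'   `rho_tapped`).
#' @param rho_tapped Tapped density, same unit.
#' @return Compressibility index, percent.
#' @export
#' @examples
#' compressibility_index(0.738, 0.870) # ~15.2
compressibility_index <- function(rho_bulk, rho_tapped) {
  stopifnot(is.numeric(rho_bulk), is.numeric(rho_tapped))
  if (any(rho_bulk <= 0)) stop("rho_bulk must be positive", call. = FALSE)
  if (any(rho_bulk > rho_tapped)) {
    stop("rho_bulk must not exceed rho_tapped", call. = FALSE)
  }
  (rho_tapped - rho_bulk) / rho_tapped * 100
}

#' Darcy volume flow through a powder bed
#'
#' Air volume flow driven through a bed of permeability `K`, cross-section
#' `A` and height `L` by a pressure difference `delta_p`:
#' `Q = K * A / (eta * L) * delta_p`.
#'
#' @param permeability Bed permeability K, m^2.
#' @param area Bed cross-sectional area, m^2.
#' @param viscosity Dynamic viscosity of air, Pa s.
#' @param bed_height Bed height L, m.
#' @param delta_p Pressure difference across the bed, Pa (>= 0).
#' @return Volume flow, m^3/s.
#' @export
#' @examples
#' darcy_volume_flow(1e-12, 1e-4, 1.8e-5, 0.01, 1000) # 5.556e-7
darcy_volume_flow <- function(permeability, area, viscosity, bed_height,
                              delta_p) {
  if (any(c(permeability, area, viscosity, bed_height) <= 0)) {
    stop("permeability, area, viscosity and bed_height must be positive",
         call. = FALSE)
  }
  if (any(delta_p < 0)) stop("delta_p must be non-negative", call. = FALSE)
  permeability * area / (viscosity * bed_height) * delta_p
}

#' Permeability from a Darcy flow measurement
#'
#' Inverts Darcy's law: `K = Q * eta * L / (A * delta_p)`. Exact inverse of
#' [darcy_volume_flow()].
#'
#' @param flow Measured volume flow Q, m^3/s.
#' @param area Bed cross-sectional area, m^2.
#' @param viscosity Dynamic viscosity, Pa s.
#' @param bed_height Bed height L, m.
#' @param delta_p Measured pressure difference, Pa (> 0).
#' @return Permeability K, m^2.
#' @export
#' @examples
#' permeability_from_darcy(5.556e-7, 1e-4, 1.8e-5, 0.01, 1000) # ~1e-12
permeability_from_darcy <- function(flow, area, viscosity, bed_height,
                                    delta_p) {
  if (any(c(flow, area, viscosity, bed_height, delta_p) <= 0)) {
    stop("all arguments must be positive (zero delta_p is not invertible)",
         call. = FALSE)
  }
  flow * viscosity * bed_height / (area * delta_p)
}

#' Permeability from the powder-rheometer two-flow protocol
#'
#' The rheometer protocol applies two volume flows to the same bed and
#' records the resulting pressure differences. Each pair gives a per-flow
#' Darcy estimate; the reported permeability is their mean.
#'
#' @param flows Applied volume flows, m^3/s.
#' @param delta_ps Resulting pressure differences, Pa (same length).
#' @inheritParams permeability_from_darcy
#' @return Mean permeability estimate, m^2.
#' @export
permeability_from_flows <- function(flows, delta_ps, area, viscosity,
                                    bed_height) {
  stopifnot(length(flows) == length(delta_ps), length(flows) >= 1L)
  mean(permeability_from_darcy(flows, area, viscosity, bed_height, delta_ps))
}

#' Read a material table from a delimited fixture file
#'
#' Reads a CSV with columns `name, x10_um, x50_um, x90_um, rho_bulk_g_cm3,
#' rho_tapped_g_cm3, rho_particle_g_cm3, permeability_m2` (unit-suffixed to
#' guard against unit mix-ups) into a list of [powder_material()] objects.
#'
#' @param path Path to the CSV file. Lines starting with `#` are comments.
#' @return Named list of `powder_material` objects.
#' @export
read_materials <- function(path) {
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  needed <- c("name", "x10_um", "x50_um", "x90_um", "rho_bulk_g_cm3",
              "rho_tapped_g_cm3", "rho_particle_g_cm3", "permeability_m2")
  missing <- setdiff(needed, names(tab))
  if (length(missing) > 0) {
    stop("material table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  mats <- lapply(seq_len(nrow(tab)), function(i) {
    powder_material(
      name = tab$name[i],
      x10 = tab$x10_um[i], x50 = tab$x50_um[i], x90 = tab$x90_um[i],
      rho_bulk = tab$rho_bulk_g_cm3[i],
      rho_tapped = tab$rho_tapped_g_cm3[i],
      rho_particle = tab$rho_particle_g_cm3[i],
      permeability = tab$permeability_m2[i]
    )
  })
  names(mats) <- tab$name
  mats
}
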