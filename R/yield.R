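#' Theoretical tablet mass at bulk density
#'
#' Mass of a powder volume given by the die cross-section and dosing height
#' at bulk density: `m = pi * rdie^2 * hd * rho_bulk`. With the die in metres
#' and the density in g/cm^3 the result is returned in mg.
#'
#' @param die A [die_geometry()].
#' @param rho_bulk Bulk density, g/cm^3.
#' @return Theoretical tablet mass, mg.
#' @export
#' @examples
#' theoretical_tablet_mass(die_geometry(), 0.738) # ~727.7 mg
theoretical_tablet_mass <- function(die, rho_bulk) {
  stopifnot(inherits(die, "die_geometry"))
  if (any(rho_bulk <= 0)) stop("rho_bulk must be positive", call. = FALSE)
  # m^3 * (g/cm^3 -> kg/m^3) -> kg -> mg
  die$area * die$dosing_height * (rho_bulk * 1000) * 1e6
}

#' Filling yield of a tablet
#'
#' Dimensionless, material-independent measure of the degree of die filling:
#' the tablet mass divided by the theoretical mass of the dosing volume at
#' bulk density, `phi = mt / (pi * rdie^2 * hd * rho_bulk)`. `phi > 1`
#' indicates overfilling (in-die densification beyond bulk density). The
#' bulk density is used as reference because the actual in-die density
#' during filling is unknown.
#'
#' @param mt Tablet mass(es), mg.
#' @param die A [die_geometry()].
#' @param rho_bulk Bulk density, g/cm^3.
#' @return Filling yield(s), dimensionless.
#' @export
#' @examples
#' filling_yield(727.7, die_geometry(), 0.738) # ~1.0
filling_yield <- function(mt, die, rho_bulk) {
  if (any(mt <= 0)) stop("tablet mass must be positive", call. = FALSE)
  mt / theoretical_tablet_mass(die, rho_bulk)
}

#' One die-filling experiment cell
#'
#' Tablet weights collected at one (machine, cam, material, turret speed,
#' paddle speed) combination.
#'
#' @param machine `"rotary_press"` or `"compaction_simulator"`.
#' @param cam_kind `"conventional"` or `"stearate"`.
#' @param material_name Material name.
#' @param turret_speed,paddle_speed Process speeds, 1/min.
#' @param weights Tablet masses, mg (all > 0, length >= 2 for dispersion
#'   statistics).
#' @return An object of class `filling_experiment`.
#' @export
filling_experiment <- function(machine, cam_kind, material_name,
                               turret_speed, paddle_speed, weights) {
  machine <- match.arg(machine, c("rotary_press", "compaction_simulator"))
  cam_kind <- match.arg(cam_kind, c("conventional", "stearate"))
  stopifnot(turret_speed > 0, paddle_speed >= 0)
  if (any(weights <= 0)) stop("all weights must be positive", call. = FALSE)
  structure(
    list(machine = machine, cam_kind = cam_kind,
         material_name = material_name,
         turret_speed = turret_speed, paddle_speed = paddle_speed,
         weights = weights),
    class = "filling_experiment"
  )
}

#' Summarize one die-filling experiment
#'
#' Computes the mean filling yield over the cell's tablet weights, the
#' relative standard deviation of the weights (percent, the pharmacopoeial
#' weight-variation convention) and an overfill flag (`mean_phi > 1`).
#'
#' @param experiment A [filling_experiment()] with >= 2 weights.
#' @param die A [die_geometry()].
#' @param material A [powder_material()] providing the bulk density.
#' @return A list of class `yield_summary`: `mean_phi`, `phi_rsd` (percent),
#'   `n`, `overfill`, plus the cell's identifying fields.
#' @export
summarize_experiment <- function(experiment, die, material) {
  stopifnot(inherits(experiment, "filling_experiment"),
            inherits(die, "die_geometry"),
            inherits(material, "powder_material"))
  w <- experiment$weights
  if (length(w) < 2L) {
    stop("at least 2 weights are required for dispersion statistics",
         call. = FALSE)
  }
  phi <- filling_yield(w, die, material$rho_bulk)
  mean_phi <- mean(phi)
  structure(
    list(
      machine = experiment$machine, cam_kind = experiment$cam_kind,
      material_name = experiment$material_name,
      turret_speed = experiment$turret_speed,
      paddle_speed = experiment$paddle_speed,
      mean_phi = mean_phi,
      phi_rsd = 100 * stats::sd(w) / mean(w),
      n = length(w),
      overfill = mean_phi > 1
    ),
    class = "yield_summary"
  )
}

#' Yield grid over a (turret speed x paddle speed) design
#'
#' Summarizes a set of experiments sharing machine, cam and material into a
#' long-format grid keyed by (turret_speed, paddle_speed). Duplicate cells
#' are an error; the full cross of observed speeds is returned with missing
#' cells flagged (`NA` summaries, `missing = TRUE`).
#'
#' @param experiments List of [filling_experiment()] objects sharing
#'   machine, cam and material.
#' @param die A [die_geometry()].
#' @param material A [powder_material()].
#' @return A long-format data frame with columns `machine, cam_kind,
#'   material, turret_speed, paddle_speed, mean_phi, phi_rsd, n, overfill,
#'   missing`, ordered by turret then paddle speed.
#' @export
yield_grid <- function(experiments, die, material) {
  stopifnot(length(experiments) >= 1L)
  ids <- unique(t(vapply(experiments, function(e) {
    c(e$machine, e$cam_kind, e$material_name)
  }, character(3))))
  if (nrow(ids) != 1L) {
    stop("experiments must share machine, cam and material", call. = FALSE)
  }
  key <- vapply(experiments, function(e) {
    paste(e$turret_speed, e$paddle_speed, sep = "_")
  }, character(1))
  if (anyDuplicated(key)) {
    stop("duplicate (turret_speed, paddle_speed) cell(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  summaries <- lapply(experiments, summarize_experiment, die = die,
                      material = material)
  turret <- sort(unique(vapply(experiments, `[[`, numeric(1), "turret_speed")))
  paddle <- sort(unique(vapply(experiments, `[[`, numeric(1), "paddle_speed")))
  grid <- expand.grid(paddle_speed = paddle, turret_speed = turret,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("turret_speed", "paddle_speed")]
  gk <- paste(grid$turret_speed, grid$paddle_speed, sep = "_")
  pos <- match(gk, key)
  grab <- function(field, default = NA_real_) {
    vapply(pos, function(i) {
      if (is.na(i)) default else summaries[[i]][[field]]
    }, default)
  }
  data.frame(
    machine = ids[1, 1], cam_kind = ids[1, 2], material = ids[1, 3],
    turret_speed = grid$turret_speed, paddle_speed = grid$paddle_speed,
    mean_phi = grab("mean_phi"),
    phi_rsd = grab("phi_rsd"),
    n = grab("n", NA_integer_),
    overfill = grab("overfill", NA),
    missing = is.na(pos),
    stringsAsFactors = FALSE
  )
}

#' Read/write tablet-weight tables
#'
#' The tablet-weight CSV has columns `machine, cam, material,
#' turret_speed_min, paddle_speed_min, tablet_index, weight_mg`; one row per
#' tablet. `read_weights()` groups rows into [filling_experiment()] objects.
#'
#' @param experiments List of [filling_experiment()] objects.
#' @param path File path.
#' @return `read_weights()` returns a list of `filling_experiment` objects;
#'   `write_weights()` returns `path` invisibly.
#' @export
write_weights <- function(experiments, path) {
  rows <- do.call(rbind, lapply(experiments, function(e) {
    data.frame(
      machine = e$machine, cam = e$cam_kind, material = e$material_name,
      turret_speed_min = e$turret_speed, paddle_speed_min = e$paddle_speed,
      tablet_index = seq_along(e$weights), weight_mg = e$weights,
      stringsAsFactors = FALSE
    )
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  needed <- c("machine", "cam", "material", "turret_speed_min",
              "paddle_speed_min", "tablet_index", "weight_mg")
  missing <- setdiff(needed, names(tab))
  if (length(missing) > 0) {
    stop("weight table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  key <- interaction(tab$machine, tab$cam, tab$material,
                     tab$turret_speed_min, tab$paddle_speed_min, drop = TRUE)
  lapply(split(tab, key), function(g) {
    filling_experiment(g$machine[1], g$cam[1], g$material[1],
                       g$turret_speed_min[1], g$paddle_speed_min[1],
                       g$weight_mg[order(g$tablet_index)])
  })
}
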