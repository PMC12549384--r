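#' Die geometry
#'
#' Geometry of one die of the tooling: radius, dosing height and filling
#' height. Defaults are the 9 mm round flat-faced EU-D tooling with 16 mm
#' filling and 15.5 mm dosing height. All lengths in metres.
#'
#' @param radius Die radius, m.
#' @param dosing_height Dosing height h_d, m.
#' @param filling_height Filling height h_f, m (>= dosing height).
#' @return An object of class `die_geometry` with derived `area` (m^2).
#' @export
#' @examples
#' die_geometry() # 9 mm tooling
die_geometry <- function(radius = 4.5e-3, dosing_height = 15.5e-3,
                         filling_height = 16e-3) {
  stopifnot(radius > 0, dosing_height > 0)
  if (dosing_height > filling_height) {
    stop("dosing_height must not exceed filling_height", call. = FALSE)
  }
  structure(
    list(
      radius = radius,
      dosing_height = dosing_height,
      filling_height = filling_height,
      area = pi * radius^2
    ),
    class = "die_geometry"
  )
}

#' Fill-cam geometry
#'
#' The fill cam guides the lower punch's pull-down under the feed frame. A
#' *conventional* cam starts with the punch flush with the die table
#' (pre-pull height 0, no initial air pocket); a *stearate* cam pre-pulls the
#' punch by `pre_pull_height` before it enters the filling zone, leaving an
#' initial air pocket of that height. Derived fields: the effective pull-down
#' height under the powder bed `hppd = filling_height - pre_pull_height` and
#' the initial cavity height `h0 = pre_pull_height`.
#'
#' @param kind `"conventional"` or `"stearate"`.
#' @param pre_pull_height Pre-pull height h_s, m. Defaults to 0 for the
#'   conventional cam and 4.7 mm for the stearate cam.
#' @param filling_height Filling height h_f, m.
#' @param pull_down_angle Angular sector of the die table occupied by punch
#'   pull-down, degrees. The default of 72 degrees is an assumption (the
#'   angle is machine-specific and not generally tabulated); all kinematic
#'   quantities are linear in it.
#' @return An object of class `fill_cam` with derived `hppd` and `h0`.
#' @export
#' @examples
#' fill_cam("stearate")$hppd # 11.3 mm
fill_cam <- function(kind = c("conventional", "stearate"),
                     pre_pull_height = NULL,
                     filling_height = 16e-3,
                     pull_down_angle = 72) {
  kind <- match.arg(kind)
  if (is.null(pre_pull_height)) {
    pre_pull_height <- if (kind == "stearate") 4.7e-3 else 0
  }
  stopifnot(pre_pull_height >= 0, filling_height > 0)
  if (pre_pull_height >= filling_height) {
    stop("pre_pull_height must be smaller than filling_height", call. = FALSE)
  }
  if (!(pull_down_angle > 0 && pull_down_angle <= 360)) {
    stop("pull_down_angle must be in (0, 360] degrees", call. = FALSE)
  }
  structure(
    list(
      kind = kind,
      pre_pull_height = pre_pull_height,
      filling_height = filling_height,
      pull_down_angle = pull_down_angle,
      hppd = filling_height - pre_pull_height,
      h0 = pre_pull_height
    ),
    class = "fill_cam"
  )
}

#' Machine configuration
#'
#' Process context of one tableting machine: machine type, turret and paddle
#' speeds, powder bed height above the die, and die geometry. The powder bed
#' height defaults to the feed-frame spoke height of the respective machine
#' (6 mm on the rotary press, 11 mm on the compaction simulator).
#'
#' @param machine `"rotary_press"` or `"compaction_simulator"`.
#' @param turret_speed Turret (or simulated turret) speed, 1/min.
#' @param paddle_speed Feed-frame paddle speed, 1/min.
#' @param bed_height Powder bed height L, m. `NULL` uses the machine default.
#' @param die A [die_geometry()] object.
#' @return An object of class `machine_config`.
#' @export
#' @examples
#' machine_config("rotary_press", turret_speed = 60, paddle_speed = 30)
machine_config <- function(machine = c("rotary_press", "compaction_simulator"),
                           turret_speed, paddle_speed = 0,
                           bed_height = NULL, die = die_geometry()) {
  machine <- match.arg(machine)
  if (is.null(bed_height)) {
    bed_height <- if (machine == "rotary_press") 6e-3 else 11e-3
  }
  stopifnot(turret_speed > 0, paddle_speed >= 0, bed_height > 0,
            inherits(die, "die_geometry"))
  structure(
    list(
      machine = machine,
      turret_speed = turret_speed,
      paddle_speed = paddle_speed,
      bed_height = bed_height,
      die = die
    ),
    class = "machine_config"
  )
}
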