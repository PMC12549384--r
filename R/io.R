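# Metadata-header CSV helpers: a block of "# key: value" lines, then a
# regular CSV table. Keeps every exported artifact self-describing.

write_meta_csv <- function(df, path, metadata = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(metadata)) {
    writeLines(sprintf("# %s: %s", k, format(metadata[[k]])), con)
  }
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_meta_csv <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  metadata <- list()
  for (ml in meta_lines) {
    m <- regmatches(ml, regexec("^#\\s*([^:]+):\\s*(.*)$", ml))[[1]]
    if (length(m) == 3L) metadata[[trimws(m[2])]] <- trimws(m[3])
  }
  df <- utils::read.csv(text = lines[!grepl("^#", lines)],
                        stringsAsFactors = FALSE)
  attr(df, "metadata") <- metadata
  df
}

#' Export / import a pressure curve as CSV
#'
#' Writes columns `time_s, pressure_pa, delta_p_pa` preceded by a metadata
#' header block (`# key: value` lines) recording material, machine, cam,
#' turret speed and solver tolerances, so any curve can be regenerated from
#' its header.
#'
#' @param curve A `pressure_curve` from [solve_pressure()].
#' @param path Output path.
#' @return `write_pressure_curve()` returns `path` invisibly;
#'   `read_pressure_curve()` returns a data frame with a `"metadata"`
#'   attribute.
#' @export
write_pressure_curve <- function(curve, path) {
  stopifnot(inherits(curve, "pressure_curve"))
  s <- curve$spec
  write_meta_csv(
    data.frame(time_s = curve$time, pressure_pa = curve$pressure,
               delta_p_pa = curve$delta_p),
    path,
    metadata = list(
      material = s$material$name,
      machine = s$machine$machine,
      cam = s$cam$kind,
      turret_speed_min = s$machine$turret_speed,
      bed_height_m = s$machine$bed_height,
      permeability_m2 = s$permeability,
      model_constant_m_s = s$c,
      rtol = s$rtol, atol = s$atol,
      t_start_s = s$t_start,
      n_points = s$n_output_points,
      package_version = as.character(utils::packageVersion("suctionfill"))
    )
  )
}

#' @rdname write_pressure_curve
#' @export
read_pressure_curve <- function(path) {
  read_meta_csv(path)
}

#' Export / import a punch instrumentation report as CSV
#'
#' Writes columns `time_s, displacement_m, velocity_m_s` with the report's
#' metadata (machine, cam, turret speed, seed, ...) as a `# key: value`
#' header block.
#'
#' @param report A [punch_report()].
#' @param path File path.
#' @return `write_punch_report()` returns `path` invisibly;
#'   `read_punch_report()` returns a [punch_report()].
#' @export
write_punch_report <- function(report, path) {
  stopifnot(inherits(report, "punch_report"))
  meta <- report$metadata
  meta$sampling_rate_hz <- report$sampling_rate
  write_meta_csv(
    data.frame(time_s = report$time, displacement_m = report$displacement,
               velocity_m_s = report$velocity),
    path, metadata = meta
  )
}

#' @rdname write_punch_report
#' @export
read_punch_report <- function(path) {
  df <- read_meta_csv(path)
  meta <- attr(df, "metadata")
  rate <- as.numeric(meta$sampling_rate_hz)
  if (length(rate) == 0 || is.na(rate)) rate <- 2000
  meta$sampling_rate_hz <- NULL
  punch_report(df$time_s, df$displacement_m, df$velocity_m_s,
               sampling_rate = rate, metadata = meta)
}
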