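# Ingestion of wheel-mounted IMU gyroscope traces and athlete/chair metadata.

#' Construct a gyroscope trace
#'
#' A `gyro_trace` holds a single-axis angular-rate time series from a
#' wheel-hub mounted IMU. The y (wheel) axis angular rate is stored in
#' degrees per second; time is in seconds, rebased so the first sample is
#' at 0 s.
#'
#' @param time Numeric vector of sample times in seconds, strictly
#'   increasing.
#' @param gyro_y Numeric vector of angular rates about the wheel axis in
#'   degrees per second, same length as `time`.
#' @param fs Nominal sampling frequency in Hz. If `NULL`, inferred from the
#'   median sample interval.
#' @param device_id Free-text device identifier.
#' @param dropped Count of invalid rows removed during ingestion.
#'
#' @return An object of class `gyro_trace`: a list with elements `time`,
#'   `gyro_y`, `fs`, `device_id`, `dropped`.
#' @export
gyro_trace <- function(time, gyro_y, fs = NULL, device_id = "unknown",
                       dropped = 0L) {
  time <- as.numeric(time)
  gyro_y <- as.numeric(gyro_y)
  if (length(time) != length(gyro_y)) {
    stop("`time` and `gyro_y` must have the same length", call. = FALSE)
  }
  keep <- is.finite(time) & is.finite(gyro_y)
  dropped <- dropped + sum(!keep)
  time <- time[keep]
  gyro_y <- gyro_y[keep]
  if (length(time) < 2L) {
    stop("gyro trace must contain at least 2 valid samples", call. = FALSE)
  }
  if (any(diff(time) <= 0)) {
    stop("`time` must be strictly increasing", call. = FALSE)
  }
  time <- time - time[1L]
  fs_inferred <- 1 / stats::median(diff(time))
  if (is.null(fs)) {
    fs <- fs_inferred
  } else {
    fs <- as.numeric(fs)
    if (fs <= 0) stop("`fs` must be positive", call. = FALSE)
    if (abs(fs_inferred - fs) / fs > 0.01) {
      warning(sprintf(
        "declared fs (%.3f Hz) deviates >1%% from inferred fs (%.3f Hz)",
        fs, fs_inferred
      ), call. = FALSE)
    }
  }
  structure(
    list(time = time, gyro_y = gyro_y, fs = fs,
         device_id = device_id, dropped = as.integer(dropped)),
    class = "gyro_trace"
  )
}

#' @export
print.gyro_trace <- function(x, ...) {
  cat(sprintf(
    "<gyro_trace> %d samples @ %.1f Hz, %.2f s, device '%s' (%d rows dropped)\n",
    length(x$time), x$fs, x$time[length(x$time)], x$device_id, x$dropped
  ))
  invisible(x)
}

#' Read a gyroscope CSV file
#'
#' Two dialects are supported. The canonical interchange dialect
#' (`"generic"`) has columns `time_s` and `gyro_y_dps`. The `"xsens_dot"`
#' dialect is a best-effort mapping of the vendor export: a timestamp
#' column (`SampleTimeFine` in microseconds, or `Timestamp`/`time` in
#' seconds) plus `Gyr_Y` in degrees per second.
#'
#' Rows containing non-finite values are dropped and counted; time is
#' rebased to start at 0 s. Sample values are never altered.
#'
#' @param path Path to a CSV file.
#' @param dialect `"generic"` (default) or `"xsens_dot"`.
#' @param fs Declared sampling frequency in Hz; inferred from the data when
#'   `NULL`.
#' @return A [gyro_trace()].
#' @export
read_gyro_csv <- function(path, dialect = c("generic", "xsens_dot"),
                          fs = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (dialect == "generic") {
    need <- c("time_s", "gyro_y_dps")
    if (!all(need %in% names(df))) {
      stop("generic dialect requires columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    time <- df$time_s
    gy <- df$gyro_y_dps
  } else {
    gcol <- intersect(c("Gyr_Y", "gyr_y"), names(df))
    tcol <- intersect(c("SampleTimeFine", "Timestamp", "time"), names(df))
    if (length(gcol) == 0L || length(tcol) == 0L) {
      stop("xsens_dot dialect requires a timestamp column and `Gyr_Y`",
           call. = FALSE)
    }
    time <- df[[tcol[1L]]]
    # SampleTimeFine counts microseconds
    if (tcol[1L] == "SampleTimeFine") time <- time / 1e6
    gy <- df[[gcol[1L]]]
  }
  gyro_trace(time, gy, fs = fs, device_id = basename(path))
}

#' Write a gyroscope trace as generic-dialect CSV
#'
#' Full-precision round-trip: re-reading the file with [read_gyro_csv()]
#' reproduces the trace values exactly.
#'
#' @param trace A [gyro_trace()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gyro_csv <- function(trace, path) {
  stopifnot(inherits(trace, "gyro_trace"))
  df <- data.frame(
    time_s = format(trace$time, digits = 17, scientific = FALSE, trim = TRUE),
    gyro_y_dps = format(trace$gyro_y, digits = 17, trim = TRUE)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct an athlete-and-chair system record
#'
#' Masses in kg, seated (chair) stature in m, wheel radius in m. When both
#' body and chair mass are given, the system mass must equal their sum
#' within 0.01 kg. A stature above 3 m is treated as centimetres entered by
#' mistake and divided by 100 with a warning.
#'
#' @param body_mass Body mass in kg (optional when `system_mass` given).
#' @param chair_mass Chair mass in kg (optional when `system_mass` given).
#' @param system_mass Total system mass in kg; computed from the parts when
#'   omitted.
#' @param stature Seated athlete-with-chair stature in m.
#' @param wheel_radius Drive-wheel radius in m, in `[0.1, 0.5]`.
#' @return An object of class `athlete_chair_system`.
#' @export
athlete_chair_system <- function(body_mass = NULL, chair_mass = NULL,
                                 system_mass = NULL, stature = NULL,
                                 wheel_radius = NULL) {
  if (is.null(stature) || is.null(wheel_radius)) {
    stop("`stature` and `wheel_radius` are required", call. = FALSE)
  }
  if (is.null(system_mass)) {
    if (is.null(body_mass) || is.null(chair_mass)) {
      stop("supply `system_mass` or both `body_mass` and `chair_mass`",
           call. = FALSE)
    }
    system_mass <- body_mass + chair_mass
  } else if (!is.null(body_mass) && !is.null(chair_mass) &&
             abs(system_mass - (body_mass + chair_mass)) > 0.01) {
    stop("`system_mass` differs from body + chair mass by more than 0.01 kg",
         call. = FALSE)
  }
  for (v in list(body_mass, chair_mass, system_mass, stature, wheel_radius)) {
    if (!is.null(v) && (!is.finite(v) || v <= 0)) {
      stop("masses, stature and wheel radius must be strictly positive",
           call. = FALSE)
    }
  }
  if (stature > 3) {
    warning(sprintf(
      "stature %.2f looks like centimetres; interpreting as %.4f m",
      stature, stature / 100
    ), call. = FALSE)
    stature <- stature / 100
  }
  if (wheel_radius < 0.1 || wheel_radius > 0.5) {
    stop("`wheel_radius` must lie in [0.1, 0.5] m", call. = FALSE)
  }
  structure(
    list(body_mass = body_mass, chair_mass = chair_mass,
         system_mass = system_mass, stature = stature,
         wheel_radius = wheel_radius),
    class = "athlete_chair_system"
  )
}

#' @export
print.athlete_chair_system <- function(x, ...) {
  cat(sprintf(
    "<athlete_chair_system> m = %.2f kg, stature = %.3f m, wheel radius = %.3f m\n",
    x$system_mass, x$stature, x$wheel_radius
  ))
  invisible(x)
}

#' Construct an environment-conditions record
#'
#' The `pressure` field is expressed in the resistive-force formula's own
#' units, in which 760 is the reference value (a mmHg convention); see
#' [pressure_from_hpa()] and [pressure_from_mmhg()] for explicit
#' converters. Indoor testing is the default, so wind velocity defaults
#' to 0.
#'
#' @param temperature Air temperature in degrees Celsius (> -273).
#' @param pressure Barometric pressure in formula units (reference 760).
#' @param wind_velocity Wind speed along the sprint direction in m/s.
#' @return An object of class `environment_conditions`.
#' @export
environment_conditions <- function(temperature = 20, pressure = 760,
                                   wind_velocity = 0) {
  if (!is.finite(temperature) || temperature <= -273) {
    stop("`temperature` must exceed -273 degrees C", call. = FALSE)
  }
  if (!is.finite(pressure) || pressure <= 0) {
    stop("`pressure` must be positive", call. = FALSE)
  }
  structure(
    list(temperature = temperature, pressure = pressure,
         wind_velocity = wind_velocity),
    class = "environment_conditions"
  )
}

#' Pressure unit converters
#'
#' The air-density formula divides pressure by a reference value of 760,
#' a millimetres-of-mercury convention. These helpers convert measured
#' pressure into those formula units.
#'
#' @param hpa Pressure in hectopascal (reference 1013.25 hPa).
#' @param mmhg Pressure in millimetres of mercury.
#' @return Pressure in formula units (760 = reference).
#' @export
pressure_from_hpa <- function(hpa) hpa / 1013.25 * 760

#' @rdname pressure_from_hpa
#' @export
pressure_from_mmhg <- function(mmhg) mmhg

#' Read athlete/chair and environment metadata
#'
#' Accepts a YAML file or a two-column `key,value` CSV. Recognised keys:
#' `body_mass_kg`, `chair_mass_kg`, `system_mass_kg`, `stature_m`,
#' `wheel_radius_m`, `temperature_c`, `pressure`, `wind_mps`. Missing
#' environment keys fall back to defaults (20 degrees C, pressure 760,
#' zero wind), which are reported via messages.
#'
#' @param path Path to a `.yml`/`.yaml` or `.csv` metadata file.
#' @return A list with elements `system` ([athlete_chair_system()]) and
#'   `env` ([environment_conditions()]).
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    kv <- yaml::read_yaml(path)
  } else {
    df <- utils::read.csv(path, header = TRUE,
                          colClasses = c("character", "numeric"))
    kv <- as.list(df[[2L]])
    names(kv) <- df[[1L]]
  }
  num <- function(key) if (is.null(kv[[key]])) NULL else as.numeric(kv[[key]])
  dflt <- function(key, value) {
    x <- num(key)
    if (is.null(x)) {
      message(sprintf("metadata: `%s` missing, using default %s", key, value))
      value
    } else x
  }
  system <- athlete_chair_system(
    body_mass = num("body_mass_kg"),
    chair_mass = num("chair_mass_kg"),
    system_mass = num("system_mass_kg"),
    stature = num("stature_m"),
    wheel_radius = num("wheel_radius_m")
  )
  env <- environment_conditions(
    temperature = dflt("temperature_c", 20),
    pressure = dflt("pressure", 760),
    wind_velocity = dflt("wind_mps", 0)
  )
  list(system = system, env = env)
}
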