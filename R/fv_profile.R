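# Force-velocity outcome measures from a net-force trace.
#
# A linear FV profile F(V) = F0 + slope * V is fitted by OLS over the
# full modelled trace (all points, unweighted). Outcomes:
#   F0      force-axis intercept (N)
#   V0      velocity-axis intercept, -F0/slope (m/s)
#   Pmax    F0 * V0 / 4 (W) -- apex of the parabola P = F * V on the line
#   FVslope slope normalized per kg of system mass (N s/m/kg)
#   DRF     slope of the ratio of force (%) against velocity (% s/m)

#' Ordinary least-squares force-velocity line
#'
#' Regresses net force on velocity over the whole modelled trace.
#'
#' @param trace A `force_trace` from [net_force_trace()].
#' @return List with `slope` (N s/m, negative on a real sprint),
#'   `intercept` (F0, N) and `r2` of the line.
#' @export
linear_fv_fit <- function(trace) {
  v <- trace$velocity
  f <- trace$fnet
  if (length(v) < 10L) stop("need at least 10 points", call. = FALSE)
  if (diff(range(v)) <= 0.5) {
    stop("velocity range too small for an FV fit (<= 0.5 m/s)",
         call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, v), f)
  co <- fit$coefficients
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((f - mean(f))^2)
  list(slope = unname(co[2L]), intercept = unname(co[1L]),
       r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_)
}

#' Decrease ratio of force (DRF)
#'
#' The ratio of force expresses the horizontal (propulsive) component as
#' a percentage of the total force the system supports:
#' `RF = 100 * Fnet / sqrt(Fnet^2 + (m g)^2)`. DRF is the OLS slope of
#' RF against velocity, in percent per m/s; more negative values mean a
#' steeper decline of mechanical effectiveness with speed.
#'
#' @param trace A `force_trace`.
#' @param system An [athlete_chair_system()]; its system mass sets the
#'   gravitational term.
#' @return DRF in % s/m.
#' @export
ratio_of_force_drf <- function(trace, system) {
  m <- system$system_mass
  rf <- 100 * trace$fnet / sqrt(trace$fnet^2 + (m * 9.81)^2)
  v <- trace$velocity
  if (diff(range(v)) <= 0) stop("degenerate velocity range", call. = FALSE)
  unname(stats::lm.fit(cbind(1, v), rf)$coefficients[2L])
}

#' Derive the five FV outcome measures from a force trace
#'
#' @param trace A `force_trace`.
#' @param system An [athlete_chair_system()].
#' @return An object of class `fv_profile`: list with `f0` (N), `v0`
#'   (m/s), `pmax` (W, = F0*V0/4), `pmax_inst` (W, max of the modelled
#'   instantaneous power, a diagnostic), `drf` (% s/m), `fv_slope`
#'   (N s/m per kg), `slope_abs` (N s/m), `line_r2`, `model_tag`,
#'   `system_mass`.
#' @export
derive_profile <- function(trace, system) {
  lf <- linear_fv_fit(trace)
  f0 <- lf$intercept
  slope <- lf$slope
  if (slope >= 0) {
    stop("FV slope is non-negative; trace is not a decelerating profile",
         call. = FALSE)
  }
  v0 <- -f0 / slope
  structure(
    list(f0 = f0, v0 = v0, pmax = f0 * v0 / 4,
         pmax_inst = max(trace$power),
         drf = ratio_of_force_drf(trace, system),
         fv_slope = slope / system$system_mass,
         slope_abs = slope, line_r2 = lf$r2,
         model_tag = trace$model_tag,
         system_mass = system$system_mass),
    class = "fv_profile"
  )
}

#' @export
print.fv_profile <- function(x, ...) {
  cat(sprintf(
    "<fv_profile> [%s] F0 = %.1f N, V0 = %.2f m/s, Pmax = %.1f W, DRF = %.2f, slope = %.3f N s/m/kg\n",
    x$model_tag, x$f0, x$v0, x$pmax, x$drf, x$fv_slope
  ))
  invisible(x)
}

#' Export an FV profile as a JSON record
#'
#' @param profile An `fv_profile`.
#' @param path Output path, or `NULL` to return the JSON string.
#' @return The JSON string, invisibly when written.
#' @export
profile_to_json <- function(profile, path = NULL) {
  js <- jsonlite::toJSON(unclass(profile), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
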