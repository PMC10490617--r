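# Resistive-force models.
#
# AF (air friction): aerodynamic drag k * (V - Vwind)^2 with k derived
# from estimated frontal surface area and air density -- the model used
# for able-bodied overground sprinting.
#
# CRF (chair rolling friction): a wheelchair-specific dynamic friction
# coefficient mu built from inertial, drag, gravitational and lift
# forces, with velocity-dependent drag/lift constants measured for rugby
# wheelchairs; F_R = mu * m * g.
#
# Resistive forces are treated as positive magnitudes and *added* to the
# inertial term in the net-force equation F_net = m * a + F_R.

GRAVITY <- 9.81

#' Estimated frontal surface area of the athlete-chair system
#'
#' Du Bois-type allometric estimate scaled to the seated athlete:
#' `SA = 0.2025 * H^0.725 * m^0.425 * 0.266`.
#'
#' @param stature Seated athlete-with-chair stature H in m.
#' @param mass System mass in kg.
#' @return Surface area in m^2.
#' @export
surface_area <- function(stature, mass) {
  stopifnot(stature > 0, mass > 0)
  0.2025 * stature^0.725 * mass^0.425 * 0.266
}

#' Air density from pressure and temperature
#'
#' `rho = 1.293 * (pressure / 760) * (273 / (273 + T))`, i.e. 1.293
#' kg/m^3 at reference pressure (760 formula units) and 0 degrees C.
#'
#' @param pressure Barometric pressure in formula units (reference 760;
#'   see [pressure_from_hpa()]).
#' @param temperature Air temperature in degrees Celsius.
#' @return Air density in kg/m^3.
#' @export
air_density <- function(pressure = 760, temperature = 20) {
  stopifnot(temperature > -273, pressure > 0)
  1.293 * (pressure / 760) * (273 / (273 + temperature))
}

#' Aerodynamic drag constant
#'
#' `k = 0.5 * rho * SA * 0.9` (drag coefficient 0.9).
#'
#' @param rho Air density in kg/m^3.
#' @param sa Frontal surface area in m^2.
#' @return Drag constant k in kg/m.
#' @export
af_drag_constant <- function(rho, sa) {
  stopifnot(rho >= 0, sa >= 0)
  0.5 * rho * sa * 0.9
}

#' Air-friction resistive force
#'
#' Drag magnitude `k * (V - Vwind)^2`, returned as a positive resistive
#' magnitude that enters the net-force equation with a plus sign.
#'
#' @param vt Translational velocity in m/s.
#' @param k Drag constant in kg/m.
#' @param vwind Wind velocity in m/s (default 0; indoor testing).
#' @return Resistive force in N.
#' @export
af_resistive_force <- function(vt, k, vwind = 0) {
  k * (vt - vwind)^2
}

#' Velocity-dependent drag constant of a rugby wheelchair
#'
#' `CD = 0.2955 / (Vt + 0.0762) + 0.1608`: strictly decreasing in
#' velocity with asymptote 0.1608.
#'
#' @param vt Translational velocity in m/s (>= 0).
#' @return Drag constant (dimensionless in the model's working units).
#' @export
crf_drag_constant <- function(vt) {
  0.2955 / (vt + 0.0762) + 0.1608
}

#' Velocity-dependent lift constant of a rugby wheelchair
#'
#' `CL = 0.2099 / (Vt + 0.1218) + 0.1666`: strictly decreasing in
#' velocity with asymptote 0.1666.
#'
#' @inheritParams crf_drag_constant
#' @return Lift constant.
#' @export
crf_lift_constant <- function(vt) {
  0.2099 / (vt + 0.1218) + 0.1666
}

#' Dynamic friction coefficient of the rolling-friction model
#'
#' Ratio of propulsion-opposing to normal-direction forces:
#' `mu = (m*a + CD(V)*V^2) / (m*g + CL(V)*V^2)`, combining inertial (FI)
#' and drag (FD) forces over gravitational (FG) and lift (FL) forces.
#'
#' @param at Translational acceleration in m/s^2.
#' @param vt Translational velocity in m/s.
#' @param mass System mass in kg.
#' @return Dynamic friction coefficient mu (dimensionless).
#' @export
dynamic_friction_mu <- function(at, vt, mass) {
  stopifnot(mass > 0)
  fi <- mass * at
  fd <- crf_drag_constant(vt) * vt^2
  fg <- mass * GRAVITY
  fl <- crf_lift_constant(vt) * vt^2
  (fi + fd) / (fg + fl)
}

#' Chair-rolling-friction resistive force
#'
#' `F_R = mu * m * g` with g = 9.81 m/s^2.
#'
#' @param mu Dynamic friction coefficient.
#' @param mass System mass in kg.
#' @return Resistive force in N.
#' @export
crf_resistive_force <- function(mu, mass) {
  stopifnot(mass > 0)
  mu * mass * GRAVITY
}

#' Net horizontal force trace under a resistive-force model
#'
#' Evaluates modelled velocity and acceleration on a time grid and adds
#' the resistive force of the chosen model to the inertial term:
#' `F_net = m * a(t) + F_R(t)`; power is `P = F_net * V`.
#'
#' Note that the published CRF formulation embeds the inertial term
#' `m * a` inside mu, so `mu * m * g` already contains `m * a` and the
#' net force at zero velocity is exactly `2 * m * a` -- double the AF
#' value. This reproduces the published computation; a strict free-body
#' reading would drop the inertial term from mu during propulsion, and
#' is available via `strict_freebody = TRUE` (off by default, and not
#' part of the standard model comparison).
#'
#' @param fit A `monoexp_fit`.
#' @param system An [athlete_chair_system()].
#' @param env An [environment_conditions()] (used by the AF model).
#' @param model `"AF"` or `"CRF"`.
#' @param t Time grid in seconds; defaults to 1000 uniform points over
#'   `[t0, t0 + t_end]` where `t_end` spans the fitted sprint.
#' @param t_end Grid end time in seconds past `t0` (default `6 * tau`).
#' @param strict_freebody For the CRF model only: exclude the inertial
#'   term from mu.
#' @return An object of class `force_trace`: list with vectors `time`,
#'   `velocity`, `acceleration`, `fr`, `fnet`, `power`, plus `model_tag`
#'   and `mass`.
#' @export
net_force_trace <- function(fit, system, env = environment_conditions(),
                            model = c("AF", "CRF"), t = NULL,
                            t_end = NULL, strict_freebody = FALSE) {
  model <- match.arg(model)
  m <- system$system_mass
  if (is.null(t)) {
    if (is.null(t_end)) t_end <- 6 * fit$tau
    t <- seq(fit$t0, fit$t0 + t_end, length.out = 1000L)
  }
  vt <- pmax(model_velocity(fit, t), 0)
  at <- model_acceleration(fit, t)
  if (model == "AF") {
    sa <- surface_area(system$stature, m)
    rho <- air_density(env$pressure, env$temperature)
    k <- af_drag_constant(rho, sa)
    fr <- af_resistive_force(vt, k, env$wind_velocity)
  } else {
    if (strict_freebody) {
      fd <- crf_drag_constant(vt) * vt^2
      fl <- crf_lift_constant(vt) * vt^2
      mu <- fd / (m * GRAVITY + fl)
    } else {
      mu <- dynamic_friction_mu(at, vt, m)
    }
    fr <- crf_resistive_force(mu, m)
  }
  fnet <- m * at + fr
  structure(
    list(time = t, velocity = vt, acceleration = at, fr = fr,
         fnet = fnet, power = fnet * vt, model_tag = model, mass = m),
    class = "force_trace"
  )
}

#' @export
print.force_trace <- function(x, ...) {
  cat(sprintf(
    "<force_trace> %s model, %d points, F: %.1f..%.1f N, peak P %.1f W\n",
    x$model_tag, length(x$time), min(x$fnet), max(x$fnet), max(x$power)
  ))
  invisible(x)
}

#' Export a force trace as CSV
#'
#' @param trace A `force_trace`.
#' @param path Output path; columns
#'   `t_s,v_mps,a_mps2,fr_n,fnet_n,p_w,model`.
#' @return `path`, invisibly.
#' @export
write_force_trace_csv <- function(trace, path) {
  utils::write.csv(
    data.frame(t_s = trace$time, v_mps = trace$velocity,
               a_mps2 = trace$acceleration, fr_n = trace$fr,
               fnet_n = trace$fnet, p_w = trace$power,
               model = trace$model_tag),
    path, row.names = FALSE
  )
  invisible(path)
}
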