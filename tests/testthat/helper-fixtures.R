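# Shared fixtures: a reference athlete/chair system matching published
# cohort means, and convenience wrappers around the synthetic generator.

ref_system <- function(wheel_radius = 0.3) {
  athlete_chair_system(body_mass = 69.51, chair_mass = 18.15,
                       stature = 1.1905, wheel_radius = wheel_radius)
}

noisefree_trace <- function(vmax = 4.6, tau = 1.2, wheel_radius = 0.3,
                            duration = 8, ...) {
  simulate_sprint(synthetic_sprint_config(
    vmax = vmax, tau = tau, wheel_radius = wheel_radius,
    duration = duration, gyro_noise_sd = 0, rest_noise_sd = 0, ...
  ))
}

# force trace following an exact linear FV profile F(V) = f0 * (1 - V/v0),
# on a uniform velocity grid; used as an independent construction for
# profile-level checks
linear_force_trace <- function(f0, v0, mass, model_tag = "AF",
                               n = 1000L, vmax = v0) {
  v <- seq(0, vmax, length.out = n)
  f <- f0 * (1 - v / v0)
  structure(
    list(time = seq_along(v), velocity = v,
         acceleration = rep(NA_real_, n), fr = rep(NA_real_, n),
         fnet = f, power = f * v, model_tag = model_tag, mass = mass),
    class = "force_trace"
  )
}
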