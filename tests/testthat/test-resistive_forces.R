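test_that("surface area follows the allometric closed form", {
  expect_equal(surface_area(1, 1), 0.2025 * 0.266)
  expect_equal(surface_area(1.1905, 87.66), 0.4091675, tolerance = 1e-6)
  # strictly increasing in both arguments
  expect_gt(surface_area(1.3, 87), surface_area(1.2, 87))
  expect_gt(surface_area(1.2, 95), surface_area(1.2, 87))
})

test_that("air density matches its reference constant and scalings", {
  expect_equal(air_density(760, 0), 1.293)
  expect_equal(air_density(760, 20), 1.293 * 273 / 293)
  expect_equal(air_density(380, 0), 1.293 / 2)
})

test_that("AF drag constant and resistive force", {
  expect_equal(af_drag_constant(1.293, 0.4), 0.5 * 1.293 * 0.4 * 0.9)
  expect_equal(af_drag_constant(1.2, 0), 0)
  expect_equal(af_resistive_force(0, 0.23), 0)
  expect_equal(af_resistive_force(4, 0.23), 3.68)
  # quadratic in relative velocity
  expect_equal(af_resistive_force(4, 0.23), 4 * af_resistive_force(2, 0.23))
  expect_equal(af_resistive_force(3, 0.23, vwind = 1),
               af_resistive_force(2, 0.23))
})

test_that("CRF drag and lift constants decay to their asymptotes", {
  expect_equal(crf_drag_constant(0), 0.2955 / 0.0762 + 0.1608)
  expect_equal(crf_lift_constant(0), 0.2099 / 0.1218 + 0.1666)
  expect_equal(crf_drag_constant(1e9), 0.1608, tolerance = 1e-8)
  expect_equal(crf_lift_constant(1e9), 0.1666, tolerance = 1e-8)
  v <- seq(0, 10, by = 0.1)
  expect_true(all(diff(crf_drag_constant(v)) < 0))
  expect_true(all(diff(crf_lift_constant(v)) < 0))
  # bounded between asymptote and the zero-velocity value
  expect_true(all(crf_drag_constant(v[-1]) > 0.1608 &
                    crf_drag_constant(v[-1]) <= crf_drag_constant(0)))
})

test_that("dynamic friction coefficient combines the four forces", {
  expect_equal(dynamic_friction_mu(0, 0, 87.66), 0)
  expect_equal(dynamic_friction_mu(1, 0, 50), 1 / 9.81)
  expect_equal(dynamic_friction_mu(1, 0, 123.4), 1 / 9.81)  # mass cancels
  # increasing in acceleration at fixed velocity
  expect_gt(dynamic_friction_mu(2, 3, 88), dynamic_friction_mu(1, 3, 88))
  # CRF force is mu * m * g, linear in mu
  expect_equal(crf_resistive_force(0, 88), 0)
  expect_equal(crf_resistive_force(1 / 9.81, 87.66), 87.66)
  expect_equal(crf_resistive_force(0.2, 88), 2 * crf_resistive_force(0.1, 88))
})

test_that("net force traces obey F = m a + F_R and the V->0 doubling", {
  sys <- ref_system()
  fit <- structure(list(vmax = 4.6, tau = 1.2, t0 = 0, rmse = 0, r2 = 1),
                   class = "monoexp_fit")
  af <- net_force_trace(fit, sys, model = "AF")
  crf <- net_force_trace(fit, sys, model = "CRF")
  m <- sys$system_mass
  expect_equal(af$fnet, m * af$acceleration + af$fr, tolerance = 1e-12)
  expect_equal(crf$fnet, m * crf$acceleration + crf$fr, tolerance = 1e-12)
  # at t = t0 velocity is zero: AF net force is m*Vmax/tau, CRF twice that
  expect_equal(af$fnet[1], m * 4.6 / 1.2, tolerance = 1e-9)
  expect_equal(crf$fnet[1], 2 * m * 4.6 / 1.2, tolerance = 1e-9)
  expect_equal(crf$fnet[1] / af$fnet[1], 2, tolerance = 1e-9)
  # CRF dominates AF pointwise for a still-air sprint
  expect_true(all(crf$fnet >= af$fnet))
  # resistive magnitudes are non-negative while accelerating forward
  expect_true(all(af$fr >= 0) && all(crf$fr >= 0))
  expect_equal(af$power, af$fnet * af$velocity)
})

test_that("strict free-body CRF variant drops the embedded inertia", {
  sys <- ref_system()
  fit <- list(vmax = 4.6, tau = 1.2, t0 = 0)
  strict <- net_force_trace(fit, sys, model = "CRF",
                            strict_freebody = TRUE)
  published <- net_force_trace(fit, sys, model = "CRF")
  m <- sys$system_mass
  expect_equal(strict$fnet[1], m * 4.6 / 1.2, tolerance = 1e-9)
  expect_true(all(strict$fnet <= published$fnet))
})

test_that("force trace exports all channels to CSV", {
  sys <- ref_system()
  tr <- net_force_trace(list(vmax = 4.6, tau = 1.2, t0 = 0), sys,
                        model = "CRF")
  path <- withr::local_tempfile(fileext = ".csv")
  write_force_trace_csv(tr, path)
  df <- read.csv(path)
  expect_named(df, c("t_s", "v_mps", "a_mps2", "fr_n", "fnet_n", "p_w",
                     "model"))
  expect_equal(unique(df$model), "CRF")
  expect_equal(nrow(df), 1000L)
})
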