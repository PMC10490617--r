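# drag-free force trace: F = m * a = m * (Vmax - V) / tau, exactly
# linear in V with slope -m/tau and intercept m*Vmax/tau
dragfree_trace <- function(vmax, tau, mass, t_end = 6 * tau) {
  t <- seq(0, t_end, length.out = 1000L)
  v <- vmax * (1 - exp(-t / tau))
  a <- (vmax / tau) * exp(-t / tau)
  structure(list(time = t, velocity = v, acceleration = a,
                 fr = rep(0, 1000L), fnet = mass * a, power = mass * a * v,
                 model_tag = "AF", mass = mass),
            class = "force_trace")
}

test_that("OLS recovers an exactly linear FV profile", {
  tr <- linear_force_trace(f0 = 300, v0 = 5, mass = 87.66)
  lf <- linear_fv_fit(tr)
  expect_equal(lf$slope, -60, tolerance = 1e-10)
  expect_equal(lf$intercept, 300, tolerance = 1e-10)
  expect_equal(lf$r2, 1, tolerance = 1e-12)
})

test_that("drag-free sprint yields slope -m/tau and F0 = m Vmax/tau", {
  m <- 87.66
  tr <- dragfree_trace(vmax = 4.8, tau = 1.7, mass = m)
  lf <- linear_fv_fit(tr)
  expect_equal(lf$slope, -m / 1.7, tolerance = 1e-6)
  expect_equal(lf$intercept, m * 4.8 / 1.7, tolerance = 1e-6)
  prof <- derive_profile(tr, ref_system())
  expect_equal(prof$v0, 4.8, tolerance = 1e-6)
  expect_equal(prof$f0, m * 4.8 / 1.7, tolerance = 1e-6)
})

test_that("profile outcomes follow their closed-form relations", {
  tr <- linear_force_trace(f0 = 300, v0 = 5, mass = 87.66)
  prof <- derive_profile(tr, ref_system())
  expect_equal(prof$v0, 5, tolerance = 1e-9)
  expect_equal(prof$pmax, 375, tolerance = 1e-6)
  expect_equal(prof$fv_slope, -60 / 87.66, tolerance = 1e-9)
  # Pmax identity against its own definition
  expect_equal(prof$pmax, prof$f0 * prof$v0 / 4, tolerance = 1e-9)
})

test_that("aerodynamic drag bends the FV curve only slightly", {
  sys <- ref_system()
  fit <- list(vmax = 4.8, tau = 1.7, t0 = 0)
  tr <- net_force_trace(fit, sys, model = "AF")
  lf <- linear_fv_fit(tr)
  expect_lt(lf$r2, 1)
  expect_gt(lf$r2, 0.95)
})

test_that("flat ratio of force gives zero DRF", {
  tr <- linear_force_trace(f0 = 200, v0 = 5, mass = 87.66)
  tr$fnet <- rep(150, length(tr$fnet))
  expect_equal(ratio_of_force_drf(tr, ref_system()), 0, tolerance = 1e-12)
})

test_that("DRF on published-cohort-like profiles lands near -6.8 / -3.3", {
  sys <- ref_system()
  crf_like <- linear_force_trace(f0 = 282.125, v0 = 4.631, mass = 87.66)
  af_like <- linear_force_trace(f0 = 139.102, v0 = 4.804, mass = 87.66)
  expect_equal(ratio_of_force_drf(crf_like, sys), -6.794, tolerance = 0.05)
  expect_equal(ratio_of_force_drf(af_like, sys), -3.309, tolerance = 0.05)
})

test_that("doubling mass doubles F0 and Pmax but leaves V0 fixed", {
  m <- 87.66
  base <- derive_profile(dragfree_trace(4.8, 1.7, m), ref_system())
  heavy_sys <- athlete_chair_system(system_mass = 2 * m, stature = 1.1905,
                                    wheel_radius = 0.3)
  heavy <- derive_profile(dragfree_trace(4.8, 1.7, 2 * m), heavy_sys)
  expect_equal(heavy$f0, 2 * base$f0, tolerance = 1e-9)
  expect_equal(heavy$pmax, 2 * base$pmax, tolerance = 1e-9)
  expect_equal(heavy$v0, base$v0, tolerance = 1e-9)
  # per-kg slope is mass-invariant in the drag-free case
  expect_equal(heavy$fv_slope, base$fv_slope, tolerance = 1e-9)
})

test_that("CRF exceeds AF in F0, |slope|, |DRF| but V0 stays close", {
  sys <- ref_system()
  fit <- list(vmax = 4.7, tau = 2.9, t0 = 0)
  af <- derive_profile(net_force_trace(fit, sys, model = "AF"), sys)
  crf <- derive_profile(net_force_trace(fit, sys, model = "CRF"), sys)
  expect_gt(crf$f0, af$f0)
  expect_gt(abs(crf$slope_abs), abs(af$slope_abs))
  expect_lt(crf$drf, af$drf)
  expect_lt(abs(crf$v0 - af$v0) / af$v0, 0.10)
  # per-kg slopes land in the published cohort band
  expect_true(af$fv_slope > -0.7 && af$fv_slope < -0.3)
  expect_true(crf$fv_slope > -0.75 && crf$fv_slope < -0.3)
})

test_that("instantaneous peak power stays near the F0 V0 / 4 apex", {
  sys <- ref_system()
  for (model in c("AF", "CRF")) {
    prof <- derive_profile(
      net_force_trace(list(vmax = 4.7, tau = 2.9, t0 = 0), sys,
                      model = model), sys)
    expect_lt(abs(prof$pmax_inst - prof$pmax) / prof$pmax, 0.15)
  }
})

test_that("degenerate traces are rejected", {
  tr <- linear_force_trace(f0 = 300, v0 = 5, mass = 87.66)
  tr$velocity <- rep(1, length(tr$velocity))
  expect_error(linear_fv_fit(tr), "range too small")
  rising <- linear_force_trace(f0 = 300, v0 = 5, mass = 87.66)
  rising$fnet <- rev(rising$fnet)
  expect_error(derive_profile(rising, ref_system()), "non-negative")
})
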