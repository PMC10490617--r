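test_that("generic CSV reads back values unchanged and infers fs", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,gyro_y_dps", "0.0,0", sprintf("%.10f,12", 1 / 60)),
             path)
  tr <- read_gyro_csv(path)
  expect_s3_class(tr, "gyro_trace")
  expect_length(tr$time, 2L)
  expect_equal(tr$gyro_y, c(0, 12))
  expect_equal(tr$fs, 60, tolerance = 1e-6)
})

test_that("gyro trace round-trips through generic CSV bit-for-bit", {
  tr <- noisefree_trace(duration = 2, tau = 0.8)
  tr$gyro_y <- tr$gyro_y + 0.123456789012345  # exercise full precision
  path <- withr::local_tempfile(fileext = ".csv")
  write_gyro_csv(tr, path)
  tr2 <- read_gyro_csv(path)
  expect_identical(tr2$gyro_y, tr$gyro_y)
  expect_identical(tr2$time, tr$time)
})

test_that("rows with missing values are dropped and counted", {
  path <- withr::local_tempfile(fileext = ".csv")
  t <- seq(0, by = 1 / 60, length.out = 100)
  g <- as.character(seq(0, 99))
  g[50] <- "NaN"
  writeLines(c("time_s,gyro_y_dps", paste(t, g, sep = ",")), path)
  tr <- read_gyro_csv(path)
  expect_length(tr$gyro_y, 99L)
  expect_identical(tr$dropped, 1L)
  # surviving samples are untouched
  expect_equal(tr$gyro_y, as.numeric(g[-50]))
})

test_that("malformed traces are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,gyro_y_dps", "0.5,1", "0.0,2", "0.25,3"), path)
  expect_error(read_gyro_csv(path), "strictly increasing")
  writeLines(c("a,b", "1,2"), path)
  expect_error(read_gyro_csv(path), "requires columns")
  writeLines(c("time_s,gyro_y_dps", "0.0,1"), path)
  expect_error(read_gyro_csv(path), "at least 2")
})

test_that("xsens dialect maps vendor columns and microsecond timestamps", {
  path <- withr::local_tempfile(fileext = ".csv")
  st <- round(seq(0, by = 1e6 / 60, length.out = 10))
  writeLines(c("SampleTimeFine,Gyr_X,Gyr_Y,Gyr_Z",
               paste(st, 1, seq(0, 90, by = 10), 2, sep = ",")), path)
  tr <- read_gyro_csv(path, dialect = "xsens_dot")
  expect_equal(tr$gyro_y, seq(0, 90, by = 10))
  expect_equal(tr$fs, 60, tolerance = 0.01)
})

test_that("declared fs deviating >1% from the data is a warning", {
  expect_warning(
    gyro_trace(seq(0, 1, by = 1 / 50), rep(0, 51), fs = 60),
    "deviates"
  )
  expect_silent(gyro_trace(seq(0, 1, by = 1 / 60), rep(0, 61), fs = 60))
})

test_that("athlete system validates masses and fixes stature units", {
  sys <- athlete_chair_system(body_mass = 69.51, chair_mass = 18.15,
                              stature = 1.1905, wheel_radius = 0.3)
  expect_equal(sys$system_mass, 87.66)
  expect_warning(
    sys2 <- athlete_chair_system(system_mass = 87.66, stature = 119.05,
                                 wheel_radius = 0.3),
    "centimetres"
  )
  expect_equal(sys2$stature, 1.1905)
  expect_error(
    athlete_chair_system(body_mass = -1, chair_mass = 18, stature = 1.2,
                         wheel_radius = 0.3),
    "positive"
  )
  expect_error(
    athlete_chair_system(body_mass = 70, chair_mass = 18, system_mass = 90,
                         stature = 1.2, wheel_radius = 0.3),
    "0.01 kg"
  )
  expect_error(
    athlete_chair_system(system_mass = 88, stature = 1.2, wheel_radius = 0.6),
    "0.1, 0.5"
  )
})

test_that("metadata reader applies and reports environment defaults", {
  path <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("body_mass_kg: 69.51", "chair_mass_kg: 18.15",
               "stature_m: 1.1905", "wheel_radius_m: 0.3"), path)
  msgs <- capture_messages(md <- read_metadata(path))
  expect_equal(md$system$system_mass, 87.66)
  expect_equal(md$env$wind_velocity, 0)
  expect_equal(md$env$pressure, 760)
  expect_equal(md$env$temperature, 20)
  expect_true(any(grepl("wind_mps", msgs)))

  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("key,value", "system_mass_kg,87.66", "stature_m,1.19",
               "wheel_radius_m,0.3", "temperature_c,25"), csv)
  md2 <- suppressMessages(read_metadata(csv))
  expect_equal(md2$env$temperature, 25)
})

test_that("pressure converters use their reference points", {
  expect_equal(pressure_from_hpa(1013.25), 760)
  expect_equal(pressure_from_mmhg(760), 760)
})
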