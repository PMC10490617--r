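# Gyroscope trace -> cleaned translational-velocity trace.
#
# Fixed pipeline order: onset detection on the raw gyro signal, then
# convert -> low-pass filter -> crop to peak -> resample to 1000 points.

#' Detect sprint onset in a gyroscope trace
#'
#' Onset is the first sample whose absolute angular rate exceeds the
#' threshold, indicating significant wheel rotation. The absolute value is
#' used because a hub mount on the opposite side of the chair negates the
#' whole trace.
#'
#' @param trace A [gyro_trace()].
#' @param threshold Angular-rate threshold in degrees per second
#'   (default 10).
#' @return The 1-based index of the onset sample.
#' @export
detect_onset <- function(trace, threshold = 10) {
  stopifnot(inherits(trace, "gyro_trace"))
  idx <- which(abs(trace$gyro_y) > threshold)
  if (length(idx) == 0L) {
    stop(sprintf("no sprint detected: no sample exceeds %g deg/s", threshold),
         call. = FALSE)
  }
  idx[1L]
}

#' Convert wheel angular rate to translational velocity
#'
#' Applies `omega = (pi/180) * gyro` followed by `V = omega * wheel_radius`.
#' If the trace's dominant sign is negative (sensor mounted on the opposite
#' hub), the whole series is sign-flipped so that forward motion is
#' positive.
#'
#' @param omega_dps Angular rate in degrees per second (vector).
#' @param wheel_radius Wheel radius in m, positive.
#' @param fix_orientation Flip the sign when the series sum is negative
#'   (default `TRUE`).
#' @return Translational velocity in m/s.
#' @export
angular_to_translational <- function(omega_dps, wheel_radius,
                                     fix_orientation = TRUE) {
  if (!is.finite(wheel_radius) || wheel_radius <= 0) {
    stop("`wheel_radius` must be positive", call. = FALSE)
  }
  v <- (pi / 180) * omega_dps * wheel_radius
  if (fix_orientation && sum(v) < 0) v <- -v
  v
}

# steady-state filter state for a unit-step input; scaling it by the
# first sample suppresses the start-up transient of an IIR filter
step_response_init <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, numeric(n - length(b))) / a[1]
  a <- c(a, numeric(n - length(a))) / a[1]
  comp <- rbind(-a[2:n], cbind(diag(n - 2L), 0))
  solve(diag(n - 1L) - t(comp), b[2:n] - a[2:n] * b[1])
}

# direct-form-II-transposed IIR filter with explicit initial state
iir_filter <- function(b, a, x, zi) {
  nf <- max(length(a), length(b))
  b <- c(b, numeric(nf - length(b))) / a[1]
  a <- c(a, numeric(nf - length(a))) / a[1]
  z <- zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    for (k in seq_len(nf - 2L)) {
      z[k] <- b[k + 1L] * xi + z[k + 1L] - a[k + 1L] * yi
    }
    z[nf - 1L] <- b[nf] * xi - a[nf] * yi
    y[i] <- yi
  }
  y
}

#' Zero-phase low-pass Butterworth filter for velocity traces
#'
#' 5th-order 4.5 Hz low-pass Butterworth, applied forward and backward
#' (zero phase) with odd-reflection end padding so that constants pass
#' unchanged (DC gain 1) and edge transients do not distort the plateau.
#'
#' @param v Numeric velocity series.
#' @param fs Sampling frequency in Hz; must exceed `2 * fc`.
#' @param order Filter order (default 5).
#' @param fc Cutoff frequency in Hz (default 4.5).
#' @return Filtered series of the same length.
#' @export
lowpass_velocity <- function(v, fs, order = 5, fc = 4.5) {
  if (fs <= 2 * fc) {
    stop("`fs` must exceed twice the cutoff frequency", call. = FALSE)
  }
  pad <- 3L * (order + 1L)
  n <- length(v)
  if (n <= pad) {
    stop(sprintf("series too short to filter: need > %d samples, have %d",
                 pad, n), call. = FALSE)
  }
  bf <- signal::butter(order, fc / (fs / 2), type = "low")
  zi <- step_response_init(bf$b, bf$a)
  # odd reflection about the end samples
  head_pad <- 2 * v[1L] - v[(pad + 1L):2L]
  tail_pad <- 2 * v[n] - v[(n - 1L):(n - pad)]
  xp <- c(head_pad, v, tail_pad)
  y <- iir_filter(bf$b, bf$a, xp, zi * xp[1L])
  y <- rev(iir_filter(bf$b, bf$a, rev(y), zi * y[length(y)]))
  y[(pad + 1L):(pad + n)]
}

#' Crop a velocity series at its peak
#'
#' Retains samples from the start through the global maximum inclusive;
#' ties are broken at the first maximum (earliest plateau attainment).
#'
#' @param v Numeric velocity series.
#' @return Indices `1:which.max(v)` of `v`, as a cropped series.
#' @export
crop_to_peak <- function(v) {
  if (length(v) == 0L) stop("empty velocity series", call. = FALSE)
  ipk <- which.max(v)
  if (ipk == 1L) {
    stop("degenerate sprint: maximum velocity at the first sample",
         call. = FALSE)
  }
  v[seq_len(ipk)]
}

#' Resample a cropped velocity trace onto 1000 uniform points
#'
#' Linear interpolation of velocity onto `n` uniformly spaced time points
#' spanning `[0, t_peak]`. The time axis stays in seconds, so the
#' acceleration time constant fitted downstream keeps its physical units;
#' normalization is over sample count only.
#'
#' @param t Time stamps in seconds, strictly increasing.
#' @param v Velocity in m/s, same length as `t`.
#' @param n Number of output samples (default 1000).
#' @param provenance Character vector of processing flags carried along.
#' @return A `sprint_kinematics` object: list with `time`, `velocity`,
#'   `n_samples`, `provenance`.
#' @export
time_normalize <- function(t, v, n = 1000L, provenance = character()) {
  stopifnot(length(t) == length(v), length(t) >= 2L)
  t <- t - t[1L]
  tt <- seq(0, t[length(t)], length.out = n)
  vv <- stats::approx(t, v, xout = tt)$y
  sprint_kinematics(tt, vv, provenance = c(provenance, "resampled"))
}

#' Construct a sprint-kinematics record
#'
#' @param time Time in seconds, rebased to 0 at sprint onset.
#' @param velocity Translational velocity in m/s.
#' @param provenance Character flags recording the processing applied
#'   (`"filtered"`, `"cropped"`, `"resampled"`, ...).
#' @return An object of class `sprint_kinematics`.
#' @export
sprint_kinematics <- function(time, velocity, provenance = character()) {
  stopifnot(length(time) == length(velocity))
  if (any(diff(time) <= 0)) {
    stop("`time` must be strictly increasing", call. = FALSE)
  }
  structure(
    list(time = as.numeric(time), velocity = as.numeric(velocity),
         n_samples = length(time), provenance = provenance),
    class = "sprint_kinematics"
  )
}

#' @export
print.sprint_kinematics <- function(x, ...) {
  cat(sprintf(
    "<sprint_kinematics> %d samples over %.2f s, peak %.2f m/s [%s]\n",
    x$n_samples, x$time[x$n_samples], max(x$velocity),
    paste(x$provenance, collapse = ",")
  ))
  invisible(x)
}

#' Run the full kinematic cleaning pipeline on a gyroscope trace
#'
#' Onset detection (absolute angular rate > `threshold`), conversion to
#' translational velocity with orientation fixing, zero-phase low-pass
#' filtering, cropping at peak velocity, and resampling to `n` points.
#'
#' @param trace A [gyro_trace()].
#' @param wheel_radius Wheel radius in m.
#' @param threshold Onset threshold in degrees per second (default 10).
#' @param n Resampled length (default 1000).
#' @param order,fc Butterworth filter order and cutoff (defaults 5, 4.5 Hz).
#' @return A [sprint_kinematics()] with time rebased to 0 at onset.
#' @export
process_sprint <- function(trace, wheel_radius, threshold = 10, n = 1000L,
                           order = 5, fc = 4.5) {
  i0 <- detect_onset(trace, threshold)
  t <- trace$time[i0:length(trace$time)]
  g <- trace$gyro_y[i0:length(trace$gyro_y)]
  v <- angular_to_translational(g, wheel_radius)
  v <- lowpass_velocity(v, trace$fs, order = order, fc = fc)
  vc <- crop_to_peak(v)
  time_normalize(t[seq_along(vc)], vc,
                 n = n, provenance = c("filtered", "cropped"))
}

#' Export a kinematics trace as CSV
#'
#' @param kin A [sprint_kinematics()].
#' @param path Output path; columns `t_s,v_mps`.
#' @return `path`, invisibly.
#' @export
write_kinematics_csv <- function(kin, path) {
  utils::write.csv(
    data.frame(t_s = kin$time, v_mps = kin$velocity),
    path, row.names = FALSE
  )
  invisible(path)
}
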