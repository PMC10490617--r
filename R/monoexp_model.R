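# Mono-exponential sprint velocity model:
#   V(t) = Vmax * (1 - exp(-(t - t0) / tau))
#   a(t) = (Vmax / tau) * exp(-(t - t0) / tau)
# tau is the acceleration time constant in seconds; t0 a small onset
# offset absorbing imperfect sprint-start detection.

#' Evaluate the mono-exponential velocity model
#'
#' @param fit A `monoexp_fit`, or a list with `vmax`, `tau`, `t0`.
#' @param t Time in seconds.
#' @return Modelled velocity in m/s.
#' @export
model_velocity <- function(fit, t) {
  fit$vmax * (1 - exp(-(t - fit$t0) / fit$tau))
}

#' Evaluate the mono-exponential acceleration model
#'
#' Satisfies the identity `a(t) * tau + V(t) = Vmax` for all t.
#'
#' @inheritParams model_velocity
#' @return Modelled acceleration in m/s^2.
#' @export
model_acceleration <- function(fit, t) {
  (fit$vmax / fit$tau) * exp(-(t - fit$t0) / fit$tau)
}

#' Goodness of fit between measured and modelled velocity
#'
#' @param measured Measured velocity series.
#' @param modelled Modelled velocity series, same length.
#' @return A list with `rmse` (m/s) and `r2` (1 - SS_res/SS_tot about the
#'   measured mean).
#' @export
goodness_of_fit <- function(measured, modelled) {
  stopifnot(length(measured) == length(modelled), length(measured) >= 2L)
  res <- measured - modelled
  ss_tot <- sum((measured - mean(measured))^2)
  if (ss_tot == 0) {
    stop("r2 undefined: measured series has zero variance", call. = FALSE)
  }
  list(rmse = sqrt(mean(res^2)), r2 = 1 - sum(res^2) / ss_tot)
}

#' Fit the mono-exponential sprint model to a velocity trace
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) on the resampled
#' velocity trace, uniform weighting. Initial values: `vmax` at the
#' observed maximum, `tau` at the time to reach 63.2% of it, `t0 = 0`.
#' Bounds: `vmax` in (0.5, 15], `tau` in (0.05, 10], `t0` in [-0.5, 0.5] s.
#' On failure the fit is retried up to 5 times from deterministically
#' perturbed starting values before an error is raised.
#'
#' @param kin A [sprint_kinematics()] (or any list with `time` and
#'   `velocity`).
#' @return An object of class `monoexp_fit`: list with `vmax`, `tau`,
#'   `t0`, `rmse`, `r2`, `n`.
#' @export
fit_monoexponential <- function(kin) {
  t <- kin$time
  v <- kin$velocity
  if (length(t) < 10L) {
    stop("need at least 10 samples to fit", call. = FALSE)
  }
  if (diff(range(v)) <= 0.5) {
    stop("velocity range too small to fit (<= 0.5 m/s)", call. = FALSE)
  }
  vmax0 <- max(v)
  i63 <- which(v >= 0.632 * vmax0)[1L]
  tau0 <- max(t[i63], 0.1)
  start0 <- c(vmax = vmax0, tau = tau0, t0 = 0)
  lower <- c(vmax = 0.5, tau = 0.05, t0 = -0.5)
  upper <- c(vmax = 15, tau = 10, t0 = 0.5)
  # fixed multiplicative jitters keep restarts deterministic
  jitter <- list(c(1, 1, 1), c(1.1, 0.8, 1), c(0.95, 1.25, 1),
                 c(1.05, 0.6, 1), c(0.9, 1.5, 1), c(1.2, 1, 1))
  fit <- NULL
  last_err <- NULL
  for (j in jitter) {
    start <- pmin(pmax(start0 * j, lower + 1e-6), upper)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        v ~ vmax * (1 - exp(-(t - t0) / tau)),
        start = as.list(start), lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-10)
      ),
      error = function(e) {
        last_err <<- conditionMessage(e)
        NULL
      }
    )
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    stop("mono-exponential fit failed after restarts: ", last_err,
         call. = FALSE)
  }
  p <- stats::coef(fit)
  out <- structure(
    list(vmax = unname(p["vmax"]), tau = unname(p["tau"]),
         t0 = unname(p["t0"]), rmse = NA_real_, r2 = NA_real_,
         n = length(t)),
    class = "monoexp_fit"
  )
  gof <- goodness_of_fit(v, model_velocity(out, t))
  out$rmse <- gof$rmse
  out$r2 <- gof$r2
  out
}

#' @export
print.monoexp_fit <- function(x, ...) {
  cat(sprintf(
    "<monoexp_fit> Vmax = %.3f m/s, tau = %.3f s, t0 = %+.3f s (rmse %.3f m/s, r2 %.4f)\n",
    x$vmax, x$tau, x$t0, x$rmse, x$r2
  ))
  invisible(x)
}

#' Export a fit as a JSON record
#'
#' @param fit A `monoexp_fit`.
#' @param path Output path, or `NULL` to return the JSON string.
#' @return The JSON string, invisibly when written to `path`.
#' @export
fit_to_json <- function(fit, path = NULL) {
  js <- jsonlite::toJSON(unclass(fit), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
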