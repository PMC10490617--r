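# End-to-end commands tying the modules together. These back the
# command-line wrapper in inst/cli/wheelfv.R but are ordinary R
# functions.

#' Simulate a cohort and write it to disk
#'
#' @param n Number of athletes.
#' @param dir Output directory.
#' @param seed Integer seed.
#' @param ... Passed to [simulate_cohort()].
#' @return Invisibly, the list returned by [simulate_cohort()].
#' @export
cmd_simulate <- function(n, dir, seed = 1L, ...) {
  if (n < 1) stop("`n` must be at least 1", call. = FALSE)
  cohort <- simulate_cohort(n, seed = seed, ...)
  write_cohort_csv(cohort, dir)
  message(sprintf("wrote %d traces + truth.csv to %s",
                  length(cohort$traces), dir))
  invisible(cohort)
}

#' Profile one sprint trace under one resistive-force model
#'
#' Runs the kinematic pipeline, fits the mono-exponential model,
#' evaluates the net-force trace and derives the FV profile.
#'
#' @param trace A [gyro_trace()].
#' @param system An [athlete_chair_system()].
#' @param env An [environment_conditions()].
#' @param model `"AF"` or `"CRF"`.
#' @return List with `kin`, `fit`, `force`, `profile`.
#' @export
profile_sprint <- function(trace, system, env = environment_conditions(),
                           model = c("AF", "CRF")) {
  model <- match.arg(model)
  kin <- process_sprint(trace, system$wheel_radius)
  fit <- fit_monoexponential(kin)
  force <- net_force_trace(fit, system, env, model = model)
  list(kin = kin, fit = fit, force = force,
       profile = derive_profile(force, system))
}

#' Profile a simulated or ingested cohort under one or both models
#'
#' Failures on individual traces are logged and skipped; an error is
#' raised only if every trace fails.
#'
#' @param cohort A list as returned by [simulate_cohort()] (elements
#'   `traces`, `truth`, `index`).
#' @param models Character vector, subset of `c("AF", "CRF")`.
#' @param env An [environment_conditions()].
#' @return A cohort tibble (see [cohort_table()]) with one row per
#'   trace x model.
#' @export
cmd_profile <- function(cohort, models = c("AF", "CRF"),
                        env = environment_conditions()) {
  models <- match.arg(models, c("AF", "CRF"), several.ok = TRUE)
  rows <- list()
  n_fail <- 0L
  for (i in seq_along(cohort$traces)) {
    a <- cohort$index$athlete[i]
    tr <- cohort$index$trial[i]
    truth <- cohort$truth[cohort$truth$athlete == a, ]
    system <- athlete_chair_system(
      body_mass = truth$body_mass, chair_mass = truth$chair_mass,
      stature = truth$stature, wheel_radius = truth$wheel_radius
    )
    res <- tryCatch({
      kin <- process_sprint(cohort$traces[[i]], system$wheel_radius)
      fit <- fit_monoexponential(kin)
      profs <- lapply(models, function(m) {
        derive_profile(net_force_trace(fit, system, env, model = m),
                       system)
      })
      cohort_table(profs, athlete = rep(a, length(profs)),
                   trial = rep(tr, length(profs)),
                   rmse = fit$rmse, r2 = fit$r2)
    }, error = function(e) {
      message(sprintf("trace %d (athlete %d trial %d) skipped: %s",
                      i, a, tr, conditionMessage(e)))
      NULL
    })
    if (is.null(res)) n_fail <- n_fail + 1L else rows[[length(rows) + 1L]] <- res
  }
  if (length(rows) == 0L) {
    stop("all traces failed to profile", call. = FALSE)
  }
  do.call(rbind, rows)
}

#' Compare resistive-force models over a cohort table
#'
#' @param table A cohort tibble containing both `"AF"` and `"CRF"` rows.
#' @param reference Optional tibble of reference rows (see
#'   [reference_values()]) to append, velocity-corrected to the cohort's
#'   mean CRF V0.
#' @return List with `summary` (mean +/- SEM tibble), `tests` (one
#'   paired-test result per metric) and, when requested, `reference`
#'   (corrected rows flagged best-effort).
#' @export
cmd_compare <- function(table, reference = NULL) {
  if (length(unique(table$model)) < 2L) {
    stop("model comparison needs both AF and CRF rows", call. = FALSE)
  }
  tests <- lapply(FV_METRICS, function(m) {
    tryCatch(paired_model_test(table, m),
             error = function(e) list(t = NA_real_, df = NA_real_,
                                      p = NA_real_, mean_diff = NA_real_,
                                      n = NA_integer_,
                                      degenerate = conditionMessage(e)))
  })
  names(tests) <- FV_METRICS
  out <- list(summary = summarize_cohort(table), tests = tests)
  if (!is.null(reference)) {
    target_v0 <- mean(table$v0[table$model == "CRF"])
    out$reference <- lapply(seq_len(nrow(reference)), function(i) {
      ref <- as.list(reference[i, ])
      if (is.na(ref$fv_slope)) return(NULL)
      c(list(source = ref$source),
        velocity_correct_reference(ref, target_v0))
    })
    out$reference <- Filter(Negate(is.null), out$reference)
  }
  out
}

#' Format a model-comparison result as a text report
#'
#' @param cmp Result of [cmd_compare()].
#' @return Character vector of report lines, invisibly; also printed.
#' @export
format_comparison <- function(cmp) {
  lines <- c("Force-velocity model comparison (mean +/- SEM)", "")
  s <- cmp$summary
  for (mod in unique(s$model)) {
    sub <- s[s$model == mod, ]
    lines <- c(lines, sprintf(
      "  %-3s %s", mod,
      paste(sprintf("%s = %.3f +/- %.3f", sub$metric, sub$mean, sub$sem),
            collapse = ", ")
    ))
  }
  lines <- c(lines, "", "Paired tests (CRF - AF):")
  for (m in names(cmp$tests)) {
    tst <- cmp$tests[[m]]
    lines <- c(lines, if (!is.null(tst$degenerate)) {
      sprintf("  %-8s degenerate (%s)", m, tst$degenerate)
    } else {
      sprintf("  %-8s diff = %+.3f, t(%d) = %.2f, p = %.3g%s",
              m, tst$mean_diff, tst$df, tst$t, tst$p,
              if (tst$p < 0.05) " *" else "")
    })
  }
  for (ref in cmp$reference) {
    lines <- c(lines, sprintf(
      "  ref %s (corrected, %s): F0 = %.1f N, V0 = %.2f m/s, Pmax = %.1f W",
      ref$source, ref$flag, ref$f0, ref$v0, ref$pmax
    ))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
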