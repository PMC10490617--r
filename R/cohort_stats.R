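# Cohort aggregation and model-comparison statistics.

FV_METRICS <- c("pmax", "f0", "drf", "v0", "fv_slope")

#' Assemble a cohort table from per-sprint FV profiles
#'
#' @param profiles A list of `fv_profile` objects.
#' @param athlete,trial Integer vectors aligned with `profiles`.
#' @param rmse,r2 Optional per-sprint velocity-fit goodness values.
#' @return A tibble with one row per sprint x model: columns `athlete`,
#'   `trial`, `model`, `pmax`, `f0`, `drf`, `v0`, `fv_slope`, `rmse`,
#'   `r2`.
#' @export
cohort_table <- function(profiles, athlete, trial,
                         rmse = NA_real_, r2 = NA_real_) {
  stopifnot(length(profiles) == length(athlete),
            length(profiles) == length(trial))
  tibble::tibble(
    athlete = athlete,
    trial = trial,
    model = vapply(profiles, `[[`, "", "model_tag"),
    pmax = vapply(profiles, `[[`, 0, "pmax"),
    f0 = vapply(profiles, `[[`, 0, "f0"),
    drf = vapply(profiles, `[[`, 0, "drf"),
    v0 = vapply(profiles, `[[`, 0, "v0"),
    fv_slope = vapply(profiles, `[[`, 0, "fv_slope"),
    rmse = rep_len(rmse, length(profiles)),
    r2 = rep_len(r2, length(profiles))
  )
}

#' Paired t-test between resistive-force models for one metric
#'
#' Per-athlete metric values (trials averaged within athlete and model)
#' are compared with a two-sided paired t-test on the CRF - AF
#' differences.
#'
#' @param table A cohort table (see [cohort_table()]) containing both
#'   model tags.
#' @param metric One of `"pmax"`, `"f0"`, `"drf"`, `"v0"`, `"fv_slope"`.
#' @return List with `t`, `df`, `p`, `mean_diff` (CRF - AF), `n` pairs.
#' @export
paired_model_test <- function(table, metric) {
  metric <- match.arg(metric, FV_METRICS)
  agg <- stats::aggregate(table[[metric]],
                          by = list(athlete = table$athlete,
                                    model = table$model),
                          FUN = mean)
  crf <- agg[agg$model == "CRF", ]
  af <- agg[agg$model == "AF", ]
  common <- intersect(crf$athlete, af$athlete)
  if (length(common) < 3L) {
    stop("need at least 3 complete athlete pairs", call. = FALSE)
  }
  d <- crf$x[match(common, crf$athlete)] - af$x[match(common, af$athlete)]
  if (stats::sd(d) == 0) {
    stop("paired test undefined: zero variance of differences",
         call. = FALSE)
  }
  ht <- stats::t.test(d)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_diff = mean(d), n = length(d))
}

#' Cohort summary: mean and SEM per metric per model
#'
#' SEM is the sample standard deviation (n - 1 denominator) divided by
#' `sqrt(n)`; with a single row it is reported as `NA`.
#'
#' @param table A cohort table.
#' @return A tibble with columns `model`, `metric`, `mean`, `sem`, `n`.
#' @export
summarize_cohort <- function(table) {
  stopifnot(nrow(table) > 0)
  out <- list()
  for (mod in unique(table$model)) {
    sub <- table[table$model == mod, ]
    for (met in FV_METRICS) {
      x <- sub[[met]]
      out[[length(out) + 1L]] <- tibble::tibble(
        model = mod, metric = met, mean = mean(x),
        sem = if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_,
        n = length(x)
      )
    }
  }
  do.call(rbind, out)
}

#' Published reference FV values for wheelchair sprint cohorts
#'
#' Mean and SEM of Pmax, F0, V0 and per-kg FV slope reported by two
#' recent wheelchair sprint studies (ergometer-based rugby athletes;
#' court-sprint basketball athletes), used for qualitative comparison
#' against profiles computed by this package.
#'
#' @return A tibble with columns `source`, `pmax`, `pmax_sem`, `f0`,
#'   `f0_sem`, `v0`, `v0_sem`, `fv_slope`, `fv_slope_sem`.
#' @export
reference_values <- function() {
  tibble::tibble(
    source = c("Janssen et al. (2023)", "Brassart et al. (2023)"),
    pmax = c(307.174, 277.6),
    pmax_sem = c(42.15, 25.15),
    f0 = c(256.056, 244),
    f0_sem = c(24.75, 16.37),
    v0 = c(4.700, 4.700),
    v0_sem = c(0.33, 0.15),
    fv_slope = c(-0.728, NA),
    fv_slope_sem = c(0.16, NA)
  )
}

#' Adjust reference FV values to a common maximum velocity
#'
#' Best-effort reconstruction of a velocity correction: the reference F0
#' is recomputed along the reference FV line at the target V0,
#' `F0_corr = -FVslope * m * V0_target`, and `Pmax_corr =
#' F0_corr * V0_target / 4`. This is a plausible along-the-line rule for
#' comparing cohorts tested at different resistances; it is labelled
#' best-effort because published adjustments of this kind do not state
#' an explicit formula.
#'
#' @param ref One row of [reference_values()] (or a list with `fv_slope`
#'   and `v0`).
#' @param target_v0 Target maximum velocity in m/s.
#' @param mass System mass in kg used to denormalize the per-kg slope.
#'   Defaults to the mass implied by the reference row itself
#'   (`f0 / (-fv_slope * v0)`), which makes correcting to the reference's
#'   own V0 a no-op.
#' @return List with `v0`, `f0`, `pmax`, `fv_slope` and
#'   `flag = "best-effort reconstruction"`.
#' @export
velocity_correct_reference <- function(ref, target_v0, mass = NULL) {
  if (is.null(ref$fv_slope) || is.na(ref$fv_slope)) {
    stop("reference has no FV slope; cannot correct", call. = FALSE)
  }
  if (is.null(mass)) mass <- ref$f0 / (-ref$fv_slope * ref$v0)
  f0 <- -ref$fv_slope * mass * target_v0
  list(v0 = target_v0, f0 = f0, pmax = f0 * target_v0 / 4,
       fv_slope = ref$fv_slope, flag = "best-effort reconstruction")
}
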