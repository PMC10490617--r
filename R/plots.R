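# Diagnostic figures. ggplot2 is suggested, not imported; each function
# checks for it at call time. Figures are artifacts only -- no numbers
# are ever read back from them.

require_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
}

#' Plot measured velocity against the fitted mono-exponential model
#'
#' @param kin A [sprint_kinematics()].
#' @param fit A `monoexp_fit`.
#' @return A ggplot object.
#' @export
plot_velocity_fit <- function(kin, fit) {
  require_ggplot()
  df <- data.frame(t = kin$time, measured = kin$velocity,
                   modelled = model_velocity(fit, kin$time))
  ggplot2::ggplot(df, ggplot2::aes(x = t)) +
    ggplot2::geom_line(ggplot2::aes(y = measured, colour = "measured")) +
    ggplot2::geom_line(ggplot2::aes(y = modelled, colour = "modelled")) +
    ggplot2::labs(x = "time (s)", y = "velocity (m/s)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot force-velocity lines for one or more force traces
#'
#' @param traces List of `force_trace` objects (e.g. AF and CRF for the
#'   same sprint).
#' @return A ggplot object.
#' @export
plot_fv_profiles <- function(traces) {
  require_ggplot()
  df <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(v = tr$velocity, f = tr$fnet, model = tr$model_tag)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = v, y = f, colour = model)) +
    ggplot2::geom_line() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linetype = "dashed", linewidth = 0.4) +
    ggplot2::labs(x = "velocity (m/s)", y = "net force (N)") +
    ggplot2::theme_minimal()
}

#' Distribution panels for cohort FV metrics by model
#'
#' @param table A cohort tibble (see [cohort_table()]).
#' @return A ggplot object faceted by metric.
#' @export
plot_metric_panels <- function(table) {
  require_ggplot()
  long <- do.call(rbind, lapply(FV_METRICS, function(m) {
    data.frame(metric = m, model = table$model, value = table[[m]])
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = model, y = value, fill = model)) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.5) +
    ggplot2::geom_jitter(width = 0.1, size = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
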