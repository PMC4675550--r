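# Round half away from zero, matching how the prediction tables are
# presented (base round() rounds half to even).
round_half_away <- function(x, digits) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Prediction configuration
#'
#' Settings for translating residual tumor volume into a regression
#' probability: the critical volume (the volume above which regression is
#' not expected; default 9 cm^3), the risk coefficient (default the cohort
#' calibration 0.152), and the output precision on the percent scale.
#'
#' @param critical_volume Positive critical tumor volume in cm^3.
#' @param gamma Positive risk coefficient.
#' @param output_precision Nonnegative integer decimal places for percent
#'   output (default 2).
#' @return An object of class `"prediction_config"`.
#' @examples
#' prediction_config()
#' prediction_config(critical_volume = 10, gamma = 0.3)
#' @export
prediction_config <- function(critical_volume = 9, gamma = 0.152,
                              output_precision = 2) {
  if (length(critical_volume) != 1L || !is.finite(critical_volume) ||
      critical_volume <= 0)
    stop("`critical_volume` must be a single positive number")
  if (length(gamma) != 1L || !is.finite(gamma) || gamma <= 0)
    stop("`gamma` must be a single positive number")
  if (output_precision < 0 || output_precision != round(output_precision))
    stop("`output_precision` must be a nonnegative integer")
  structure(list(critical_volume = critical_volume, gamma = gamma,
                 output_precision = as.integer(output_precision)),
            class = "prediction_config")
}

#' Predicted regression probability for a residual tumor volume
#'
#' Maps a residual tumor volume to the regression probability in percent:
#' `100 * beta_gamma(volume / critical_volume)`.  The volume-to-fraction
#' mapping is purely proportional (cell number tracks volume).  Volumes at
#' or above the critical volume return 0 with a warning — at that size the
#' model defines regression as no longer expected.
#'
#' @param volume_cm3 Positive residual tumor volume(s) in cm^3.
#' @param config A [prediction_config()] object.
#' @return Percent probabilities in `[0, 100]`, rounded half away from
#'   zero at `config$output_precision` decimals.
#' @examples
#' regression_probability(1)    # 88.16 % for 1 cm^3 of 9 cm^3
#' regression_probability(5)    # 42.64 %
#' @export
regression_probability <- function(volume_cm3, config = prediction_config()) {
  if (!inherits(config, "prediction_config"))
    stop("`config` must come from prediction_config()")
  if (any(!is.finite(volume_cm3)) || any(volume_cm3 <= 0))
    stop("`volume_cm3` must be positive")
  over <- volume_cm3 >= config$critical_volume
  if (any(over))
    warning("volume(s) ", paste(volume_cm3[over], collapse = ", "),
            " cm^3 reach the critical volume (", config$critical_volume,
            " cm^3); regression probability is 0 there")
  rho <- pmin(volume_cm3 / config$critical_volume, 1)
  round_half_away(100 * beta_asymptotic(config$gamma, rho),
                  config$output_precision)
}

#' Prediction table over a grid of residual volumes
#'
#' One row per residual volume: the volume, the residual fraction
#' `rho = volume / critical_volume`, and the regression probability in
#' percent.  The default grid (0.1, 0.5, 1, 2, ..., 8 cm^3) spans the
#' clinically relevant range below the 9 cm^3 critical volume.
#'
#' @param volumes Positive volumes in cm^3.
#' @param config A [prediction_config()] object.
#' @return A data frame with columns `volume_cm3`, `rho`,
#'   `regression_probability_pct`, strictly decreasing in volume.
#' @examples
#' prediction_table()
#' @export
prediction_table <- function(volumes = c(0.1, 0.5, 1:8),
                             config = prediction_config()) {
  if (length(volumes) < 1) stop("`volumes` must be nonempty")
  data.frame(volume_cm3 = volumes,
             rho = volumes / config$critical_volume,
             regression_probability_pct =
               regression_probability(volumes, config))
}

#' Linearity report: absence of an extent-of-resection threshold
#'
#' Quantifies how close the calibrated regression curve is to linear, and
#' contrasts it with a strongly nonlinear regime.  Reports (a) the maximal
#' deviation of `100 * beta_gamma` from its midpoint tangent in percentage
#' points, (b) the mean regression-probability gain per cm^3 of additional
#' resection across the whole-cm^3 volumes of the default grid, and (c)
#' the same two quantities for a comparison risk coefficient (default the
#' fictive high value 50, where the curve is threshold-like).
#'
#' @param gamma Positive risk coefficient of interest.
#' @param config A [prediction_config()] object (its `gamma` is ignored in
#'   favor of the `gamma` argument).
#' @param comparison_gamma Risk coefficient for the nonlinear contrast.
#' @return An object of class `"eor_linearity_report"`: list with `gamma`,
#'   `max_deviation_pct`, `avg_gain_per_cm3_pct`, and a `comparison` list
#'   with the same fields for `comparison_gamma`.
#' @examples
#' eor_linearity_report(0.152)
#' @export
eor_linearity_report <- function(gamma = 0.152,
                                 config = prediction_config(gamma = gamma),
                                 comparison_gamma = 50) {
  one <- function(g) {
    cfg <- prediction_config(critical_volume = config$critical_volume,
                             gamma = g,
                             output_precision = config$output_precision)
    vols <- seq_len(floor(config$critical_volume) - 1)  # whole cm^3 below N
    p <- 100 * beta_asymptotic(g, vols / config$critical_volume)
    list(gamma = g,
         max_deviation_pct = 100 *
           max_taylor_deviation(g)$max_observed_deviation,
         avg_gain_per_cm3_pct = mean(-diff(p)))
  }
  main <- one(gamma)
  structure(c(main, list(comparison = one(comparison_gamma))),
            class = "eor_linearity_report")
}

#' @export
print.eor_linearity_report <- function(x, ...) {
  cat("Extent-of-resection linearity report\n")
  cat(sprintf("  gamma = %-8g max |curve - tangent| = %5.2f pp, mean gain %5.2f pp per cm^3\n",
              x$gamma, x$max_deviation_pct, x$avg_gain_per_cm3_pct))
  y <- x$comparison
  cat(sprintf("  gamma = %-8g max |curve - tangent| = %5.2f pp, mean gain %5.2f pp per cm^3\n",
              y$gamma, y$max_deviation_pct, y$avg_gain_per_cm3_pct))
  invisible(x)
}
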