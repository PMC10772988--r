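#' Temperature features
#'
#' Following the Arrhenius form kcat = A * exp(-Ea / (R T)), both the absolute
#' temperature T and its reciprocal 1/T enter the model, each min-max
#' normalized with statistics fitted on the training set. All internal
#' temperature math is in Kelvin: 1/T only makes physical sense on an
#' absolute scale. Input tables carry degrees Celsius, as the source kinetics
#' databases do.
#'
#' @name temperature-features
NULL

CELSIUS_OFFSET <- 273.15

celsius_to_kelvin <- function(t_celsius) t_celsius + CELSIUS_OFFSET

#' Fit min-max normalization statistics for temperature features
#'
#' @param temps_celsius Numeric vector of temperatures in degrees Celsius
#'   (the training set's temperatures).
#' @return A `thermo_stats` object with `t_min`, `t_max` (K) and `invt_min`,
#'   `invt_max` (1/K).
#' @export
fit_thermo_stats <- function(temps_celsius) {
  stopifnot(is.numeric(temps_celsius), length(temps_celsius) >= 1)
  tk <- celsius_to_kelvin(temps_celsius)
  if (any(tk <= 0)) abort("Temperatures at or below 0 K are not physical")
  if (length(unique(tk)) < 2) {
    abort("Need at least two distinct temperatures to fit normalization statistics",
          class = "thermokcat_degenerate_range_error")
  }
  structure(list(
    t_min = min(tk), t_max = max(tk),
    invt_min = 1 / max(tk), invt_max = 1 / min(tk)
  ), class = "thermo_stats")
}

#' Normalized temperature features for one temperature
#'
#' Values outside the fitted range are not clipped (linear extrapolation);
#' a message flags extrapolation.
#'
#' @param t_celsius Temperature in degrees Celsius.
#' @param stats A fitted [fit_thermo_stats()] object.
#' @param quiet Suppress the extrapolation message.
#' @return A `thermo_features` list with `t_norm`, `invt_norm`, `t_kelvin`.
#' @export
normalize_temperature <- function(t_celsius, stats, quiet = FALSE) {
  stopifnot(inherits(stats, "thermo_stats"))
  tk <- celsius_to_kelvin(t_celsius)
  if (any(tk <= 0)) abort("Temperature at or below 0 K")
  t_norm <- (tk - stats$t_min) / (stats$t_max - stats$t_min)
  invt_norm <- (1 / tk - stats$invt_min) / (stats$invt_max - stats$invt_min)
  if (!quiet && any(tk < stats$t_min | tk > stats$t_max)) {
    message(sprintf(
      "normalize_temperature: extrapolating outside the fitted range [%.2f, %.2f] K",
      stats$t_min, stats$t_max))
  }
  structure(list(t_norm = t_norm, invt_norm = invt_norm, t_kelvin = tk),
            class = "thermo_features")
}

#' Invert the temperature normalization
#'
#' @param t_norm Normalized temperature value(s).
#' @param stats A fitted [fit_thermo_stats()] object.
#' @return Absolute temperature(s) in Kelvin.
#' @export
denormalize_temperature <- function(t_norm, stats) {
  stopifnot(inherits(stats, "thermo_stats"))
  t_norm * (stats$t_max - stats$t_min) + stats$t_min
}

#' @export
print.thermo_stats <- function(x, ...) {
  cat(sprintf("<thermo_stats: T in [%.2f, %.2f] K>\n", x$t_min, x$t_max))
  invisible(x)
}
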