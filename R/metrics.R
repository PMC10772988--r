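#' Regression metrics on the log10(kcat) scale
#'
#' RMSE is the root mean squared error, MAE the mean absolute error, and R2
#' the coefficient of determination `1 - SS_res / SS_tot` with `SS_tot`
#' taken about the target mean (not squared Pearson correlation). When the
#' targets have zero variance R2 is undefined and reported as `NA` with a
#' warning.
#'
#' @param predictions,targets Equal-length numeric vectors.
#' @return A one-row tibble with columns `rmse`, `mae`, `r2`.
#' @export
eval_metrics <- function(predictions, targets) {
  stopifnot(length(predictions) == length(targets), length(targets) > 0)
  err <- predictions - targets
  rmse <- sqrt(mean(err^2))
  mae <- mean(abs(err))
  ss_tot <- sum((targets - mean(targets))^2)
  r2 <- if (ss_tot == 0) {
    warn("Targets have zero variance; R2 is undefined")
    NA_real_
  } else {
    1 - sum(err^2) / ss_tot
  }
  tibble::tibble(rmse = rmse, mae = mae, r2 = r2)
}
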