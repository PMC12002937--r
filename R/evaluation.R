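#' Mean absolute error
#'
#' @param model model values at the observation times.
#' @param observed observed medians (same units and length).
#' @return Mean of absolute residuals, in the variable's units.
#' @export
mae <- function(model, observed) {
  if (length(model) != length(observed))
    stop("'model' and 'observed' must have equal length")
  if (length(model) == 0L) stop("need at least one data point")
  mean(abs(model - observed))
}

#' Normalized root mean square error
#'
#' RMSE divided by the spread of the observations: by default the
#' observed range (`max - min`), so values are comparable across
#' variables with different scales, or the observed mean with
#' `normalization = "mean"`.
#'
#' @inheritParams mae
#' @param normalization `"range"` (default) or `"mean"`.
#' @return Dimensionless NRMSE.
#' @export
nrmse <- function(model, observed, normalization = c("range", "mean")) {
  normalization <- match.arg(normalization)
  if (length(model) != length(observed))
    stop("'model' and 'observed' must have equal length")
  if (length(model) == 0L) stop("need at least one data point")
  denom <- switch(normalization,
                  range = diff(range(observed)),
                  mean = mean(observed))
  if (!is.finite(denom) || denom == 0)
    stop("degenerate observations: zero ", normalization,
         " makes NRMSE undefined")
  sqrt(mean((model - observed)^2)) / denom
}

#' Margin of error of a model trajectory
#'
#' Half-width of the 95% confidence ribbon, `1.96 * sigma / sqrt(n)`,
#' where `sigma` is the standard deviation of the model residuals and `n`
#' the number of time points with data. The constant 1.96 is the 97.5%
#' normal quantile.
#'
#' @param sigma residual standard deviation, >= 0.
#' @param n number of data points, >= 1.
#' @return Nonnegative half-width in the variable's units.
#' @examples
#' moeBand(1, 4)  # 0.98
#' @export
moeBand <- function(sigma, n) {
  stopifnot(is.numeric(sigma), sigma >= 0, n >= 1)
  1.96 * sigma / sqrt(n)
}

#' Goodness-of-fit report for one variable
#'
#' Bundles MAE, NRMSE, residual standard deviation, sample size and the
#' margin of error into one object; [confidenceBand()] applies the MOE as
#' a constant-width ribbon around a trajectory.
#'
#' @inheritParams mae
#' @param normalization passed to [nrmse()].
#' @return An object of class `osteo_metrics` with fields `mae`, `nrmse`,
#'   `sigma`, `n`, `moe`.
#' @export
metricReport <- function(model, observed, normalization = "range") {
  res <- model - observed
  sigma <- if (length(res) > 1L) stats::sd(res) else 0
  nr <- tryCatch(nrmse(model, observed, normalization),
                 error = function(e) NA_real_)
  structure(list(mae = mae(model, observed), nrmse = nr,
                 sigma = sigma, n = length(res),
                 moe = moeBand(sigma, length(res))),
            class = "osteo_metrics")
}

#' @export
print.osteo_metrics <- function(x, ...) {
  cat(sprintf("MAE %.4g | NRMSE %.4g | sigma %.4g | n %d | MOE %.4g\n",
              x$mae, x$nrmse, x$sigma, x$n, x$moe))
  invisible(x)
}

#' Constant-width confidence band around a trajectory
#'
#' @param trajectory an `osteo_trajectory` (or data frame with `time`).
#' @param variable trajectory column the band applies to.
#' @param moe half-width (from [moeBand()] or [metricReport()]).
#' @return Data frame `time`, `fit`, `lower`, `upper`.
#' @export
confidenceBand <- function(trajectory, variable, moe) {
  stopifnot(variable %in% names(trajectory), moe >= 0)
  y <- trajectory[[variable]]
  data.frame(time = trajectory$time, fit = y,
             lower = y - moe, upper = y + moe)
}

#' Flat metric summary across materials and variables
#'
#' Collects the stage-3 (and any other) metric reports of a staged fit
#' into one data frame suitable for CSV export.
#'
#' @param staged an `osteo_staged` object from [stagedWorkflow()].
#' @return Data frame `material`, `variable`, `mae`, `nrmse`, `n`, `moe`.
#' @export
metricSummary <- function(staged) {
  stopifnot(inherits(staged, "osteo_staged"))
  rows <- list()
  m <- staged$`Mg-5Gd`$metrics
  for (v in names(m))
    rows[[length(rows) + 1L]] <-
      data.frame(material = "Mg-5Gd", variable = v, mae = m[[v]]$mae,
                 nrmse = m[[v]]$nrmse, n = m[[v]]$n, moe = m[[v]]$moe)
  if (length(rows) == 0L)
    return(data.frame(material = character(), variable = character(),
                      mae = numeric(), nrmse = numeric(), n = integer(),
                      moe = numeric()))
  do.call(rbind, rows)
}
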