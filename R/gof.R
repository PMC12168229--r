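#' Goodness-of-fit battery for thin-layer model fits
#'
#' The statistic set conventional in the thin-layer drying literature,
#' computed on the moisture-ratio scale from observed and predicted
#' series of equal length N with `n_params` fitted coefficients:
#'
#' * `sse`  — residual sum of squares, sum((obs - pred)^2)
#' * `rmse` — sqrt(sse / N)
#' * `chi2` — reduced chi-square, sse / (N - n_params)
#' * `r2`   — coefficient of determination, 1 - sse / sum((obs - mean(obs))^2)
#' * `ef`   — modelling efficiency, 1 - sse / sum((obs - mean(pred))^2)
#' * `se`   — standard error of the residuals, sqrt(sse / (N - 1))
#' * `see`  — standard error of estimate, sqrt(sse / (N - n_params))
#' * `sd`   — sample standard deviation of the residuals
#'
#' `chi2 * (N - n_params) == rmse^2 * N` holds exactly for every input,
#' and `r2 == 1`, `ef == 1`, `rmse == 0` are all equivalent to `sse == 0`.
#'
#' @param observed observed moisture ratios.
#' @param predicted model-predicted moisture ratios, same length.
#' @param n_params number of fitted model parameters (< N).
#' @return An object of class `gof_stats`: a named list with the eight
#'   statistics plus `n_obs` and `n_params`.
#' @examples
#' gof_stats(c(1, .6, .3, .1), c(1, .58, .33, .09), n_params = 2)
#' @export
gof_stats <- function(observed, predicted, n_params) {
  n <- length(observed)
  if (length(predicted) != n)
    stop("observed and predicted lengths differ", call. = FALSE)
  if (n < 2L) stop("need at least two observations", call. = FALSE)
  if (n <= n_params)
    stop("need more observations than fitted parameters", call. = FALSE)
  res <- observed - predicted
  sse <- sum(res^2)
  sstot <- sum((observed - mean(observed))^2)
  sspred <- sum((observed - mean(predicted))^2)
  structure(list(
    r2   = 1 - sse / sstot,
    se   = sqrt(sse / (n - 1)),
    chi2 = sse / (n - n_params),
    rmse = sqrt(sse / n),
    ef   = 1 - sse / sspred,
    sse  = sse,
    see  = sqrt(sse / (n - n_params)),
    sd   = stats::sd(res),
    n_obs = n, n_params = n_params),
    class = "gof_stats")
}

#' @export
print.gof_stats <- function(x, digits = 5, ...) {
  cat(sprintf("gof: R2 %.5f  chi2 %.3g  RMSE %.3g  EF %.5f  SSE %.3g\n",
              x$r2, x$chi2, x$rmse, x$ef, x$sse))
  invisible(x)
}

#' @export
as.data.frame.gof_stats <- function(x, ...) {
  data.frame(r2 = x$r2, se = x$se, chi2 = x$chi2, rmse = x$rmse,
             ef = x$ef, sse = x$sse, see = x$see, sd = x$sd)
}
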