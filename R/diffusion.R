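#' Fickian slab moisture-ratio series
#'
#' Truncated series solution of Fick's second law for an infinite slab
#' with uniform initial moisture, symmetric transfer, negligible surface
#' resistance, constant diffusivity and negligible shrinkage:
#'
#'   MR(t) = (8 / pi^2) * sum_{j=0}^{n_terms-1}
#'           exp(-(2j+1)^2 pi^2 D_eff t / (4 L^2)) / (2j+1)^2
#'
#' With `n_terms = 1` this reduces to the one-term late-time asymptote
#' whose log-linear slope underlies the slope method ([estimate_deff()]).
#'
#' @param deff effective moisture diffusivity, m^2/s (> 0).
#' @param half_thickness half slice thickness L, m (> 0).
#' @param t time in seconds (>= 0); vectorised.
#' @param n_terms number of series terms (>= 1); 50 is ample for
#'   MR < 0.999, 200 resolves t = 0 to about 1e-4.
#' @return moisture ratio at each `t`.
#' @examples
#' fick_mr(5.46e-10, 0.002, c(0, 6000), n_terms = 200)
#' fick_mr(5.46e-10, 0.002, 0, n_terms = 1)  # 8 / pi^2
#' @export
fick_mr <- function(deff, half_thickness, t, n_terms = 50) {
  stopifnot(deff > 0, half_thickness > 0, n_terms >= 1)
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  j <- 0:(n_terms - 1)
  odd <- 2 * j + 1
  rate <- pi^2 * deff / (4 * half_thickness^2)
  mr <- vapply(t, function(tt)
    sum(exp(-odd^2 * rate * tt) / odd^2), numeric(1))
  (8 / pi^2) * mr
}

#' Effective moisture diffusivity by the slope method
#'
#' In the falling-rate period the slab series is dominated by its first
#' term, so ln MR is linear in time with slope -pi^2 D_eff / (4 L^2).
#' This fits ordinary least squares of ln MR on time (converted to
#' seconds internally, so `deff` lands in m^2/s) over a moisture-ratio
#' window, then converts the slope magnitude:
#'
#'   D_eff = 4 L^2 |slope| / pi^2
#'
#' By default only points with MR in \[0.02, 0.7\] enter the regression:
#' the one-term asymptote holds late in drying, and early points (where
#' higher terms still matter) bias the slope.  Set
#' `window = c(0, 1)` to use every positive-MR point.
#'
#' The estimate inherits the slab-solution assumptions: uniform initial
#' moisture, symmetric transfer, negligible surface resistance,
#' diffusion-only transport, constant D and negligible shrinkage.
#'
#' @param series a `moisture_series`, or a numeric vector of moisture
#'   ratios (then supply `times`).
#' @param half_thickness half slice thickness L in metres; defaults to
#'   the series' condition thickness / 2000.
#' @param window inclusive MR window `c(lo, hi)` selecting points for
#'   the regression.
#' @param times sampling times in minutes when `series` is a bare
#'   numeric vector.
#' @return An object of class `deff_fit`: `deff` (m^2/s), `slope`
#'   (1/s, magnitude), `r2`, `half_thickness`, `window`, `n_used`,
#'   `used` (indices of the points in the regression).
#' @examples
#' tt <- seq(0, 400, by = 10)
#' mr <- fick_mr(5.46e-10, 0.002, tt * 60, n_terms = 1)
#' estimate_deff(mr, times = tt, half_thickness = 0.002)
#' @export
estimate_deff <- function(series, half_thickness = NULL,
                          window = c(0.02, 0.7), times = NULL) {
  if (inherits(series, "moisture_series")) {
    mr <- series$mr; tmin <- series$times
    if (is.null(half_thickness))
      half_thickness <- half_thickness(series$condition)
  } else {
    mr <- as.numeric(series); tmin <- as.numeric(times)
    if (is.null(half_thickness))
      stop("half_thickness required for bare numeric input", call. = FALSE)
  }
  stopifnot(length(mr) == length(tmin), half_thickness > 0,
            length(window) == 2L, window[1] < window[2])
  # the slope method describes the falling-rate period: ignore any
  # late-time rise (possible in noisy or pathological series)
  declining <- seq_len(which.min(mr))
  use <- declining[is.finite(mr[declining]) & mr[declining] > 0 &
                   mr[declining] >= window[1] & mr[declining] <= window[2]]
  if (length(use) < 3L)
    stop(sprintf("slope method needs >= 3 points with MR in [%g, %g]; got %d",
                 window[1], window[2], length(use)), call. = FALSE)
  t_sec <- tmin[use] * 60          # the only minutes->seconds conversion
  fit <- stats::lm(log(mr[use]) ~ t_sec)
  slope <- -unname(stats::coef(fit)[2])
  if (slope <= 0)
    warning("non-negative ln MR slope: series is not drying in the window")
  r2 <- 1 - sum(stats::residuals(fit)^2) /
    sum((log(mr[use]) - mean(log(mr[use])))^2)
  structure(list(deff = 4 * half_thickness^2 * slope / pi^2,
                 slope = slope, r2 = r2,
                 half_thickness = half_thickness,
                 window = window, n_used = length(use), used = use),
            class = "deff_fit")
}

#' @export
print.deff_fit <- function(x, ...) {
  cat(sprintf(
    "Slope-method diffusivity: D_eff = %.3g m^2/s (%.3f x 1e-10)\n",
    x$deff, x$deff * 1e10))
  cat(sprintf("  slope %.4g 1/s, R2 %.4f, %d points, MR window [%g, %g], L = %g m\n",
              x$slope, x$r2, x$n_used, x$window[1], x$window[2],
              x$half_thickness))
  invisible(x)
}

#' @export
coef.deff_fit <- function(object, ...) {
  c(deff = object$deff, slope = object$slope)
}

#' Universal gas constant, J/(mol K)
#' @keywords internal
R_GAS <- 8.314

#' Arrhenius activation energy from diffusivities at several temperatures
#'
#' Fits ln D_eff = ln D_0 - E_a / (R T) by ordinary least squares of
#' ln(deff) on 1/T, with R = 8.314 J/(mol K).  The activation energy is
#' the negated slope times R, reported in kJ/mol; D_0 is the
#' exponentiated intercept.
#'
#' @param deff effective diffusivities, m^2/s (> 0).
#' @param temperature effective sample temperatures, K; at least two
#'   distinct values.
#' @return An object of class `arrhenius_fit`: `ea` (kJ/mol), `d0`
#'   (m^2/s), `r2`, `n`.
#' @examples
#' T <- c(310, 330, 350)
#' D <- 1e-5 * exp(-25000 / (8.314 * T))
#' fit_arrhenius(D, T)
#' @export
fit_arrhenius <- function(deff, temperature) {
  deff <- as.numeric(deff); temperature <- as.numeric(temperature)
  stopifnot(length(deff) == length(temperature))
  if (any(deff <= 0)) stop("all deff must be > 0", call. = FALSE)
  if (any(temperature <= 0)) stop("temperatures must be in K (> 0)",
                                  call. = FALSE)
  if (length(unique(temperature)) < 2L)
    stop("Arrhenius fit needs at least two distinct temperatures",
         call. = FALSE)
  inv_t <- 1 / temperature
  fit <- stats::lm(log(deff) ~ inv_t)
  cf <- stats::coef(fit)
  sstot <- sum((log(deff) - mean(log(deff)))^2)
  r2 <- if (sstot > 0) 1 - sum(stats::residuals(fit)^2) / sstot else 1
  structure(list(ea = -unname(cf[2]) * R_GAS / 1000,
                 d0 = exp(unname(cf[1])),
                 r2 = r2, n = length(deff)),
            class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("Arrhenius fit: Ea = %.3f kJ/mol, D0 = %.3g m^2/s, R2 = %.4f (n = %d)\n",
              x$ea, x$d0, x$r2, x$n))
  invisible(x)
}

#' @export
coef.arrhenius_fit <- function(object, ...) {
  c(ea = object$ea, d0 = object$d0)
}

#' Predict diffusivity from an Arrhenius fit
#'
#' @param object an `arrhenius_fit`.
#' @param newdata temperatures in K.
#' @param ... unused.
#' @return predicted D_eff in m^2/s.
#' @export
predict.arrhenius_fit <- function(object, newdata, ...) {
  object$d0 * exp(-object$ea * 1000 / (R_GAS * as.numeric(newdata)))
}
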