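#' The thin-layer model registry
#'
#' Eleven semi-empirical moisture-ratio models MR(t), t in minutes, as
#' used throughout the thin-layer drying literature:
#'
#' | name | form |
#' |------|------|
#' | `newton` | exp(-k t) |
#' | `page` | exp(-k t^n) |
#' | `modified_page` | exp(-(k t)^n) |
#' | `henderson_pabis` | a exp(-k t) |
#' | `modified_henderson_pabis` | a exp(-k t) + b exp(-g t) + c exp(-h t) |
#' | `logarithmic` | a exp(-k t) + c |
#' | `wang_singh` | 1 + a t + b t^2 |
#' | `verma` | a exp(-k t) + (1 - a) exp(-g t) |
#' | `thomson` | t = a ln MR + b (ln MR)^2 (inverse form) |
#' | `two_term` | a exp(-k0 t) + b exp(-k1 t) |
#' | `midilli` | a exp(-k t^n) + b t |
#'
#' The Thompson model is stated as time as a function of moisture ratio;
#' it is fitted in that inverse space and evaluated for MR(t) by solving
#' the quadratic in ln MR (see [evaluate_model()]).
#'
#' @return `thinlayer_models()`: character vector of registered model
#'   names, ordered as above.
#' @export
thinlayer_models <- function() names(tl_registry)

#' @rdname thinlayer_models
#' @param model a registered model name.
#' @return `thinlayer_params()`: ordered parameter names of `model`.
#' @export
thinlayer_params <- function(model) tl_get(model)$params

tl_get <- function(model) {
  m <- tl_registry[[model]]
  if (is.null(m))
    stop(sprintf("unknown thin-layer model '%s'; see thinlayer_models()",
                 model), call. = FALSE)
  m
}

# jitter types: "log" multiplies by 10^U(-1,1) preserving sign,
# "add" shifts uniformly by +/- width.  Used by the multistart machinery.
tl_par <- function(name, lower, upper, jitter = "log", width = NA_real_) {
  list(name = name, lower = lower, upper = upper,
       jitter = jitter, width = width)
}

RATE_LO <- 1e-8; RATE_HI <- 10

tl_registry <- list(
  newton = list(
    params = "k",
    spec = list(tl_par("k", RATE_LO, RATE_HI)),
    fn = function(t, p) exp(-p[["k"]] * t),
    init = function(k0) c(k = k0)),
  page = list(
    params = c("k", "n"),
    spec = list(tl_par("k", RATE_LO, RATE_HI), tl_par("n", 0.1, 5)),
    fn = function(t, p) exp(-p[["k"]] * t^p[["n"]]),
    init = function(k0) c(k = k0, n = 1)),
  modified_page = list(
    params = c("k", "n"),
    spec = list(tl_par("k", RATE_LO, RATE_HI), tl_par("n", 0.1, 5)),
    fn = function(t, p) exp(-(p[["k"]] * t)^p[["n"]]),
    init = function(k0) c(k = k0, n = 1)),
  henderson_pabis = list(
    params = c("a", "k"),
    spec = list(tl_par("a", -2, 2, "add", 0.3),
                tl_par("k", RATE_LO, RATE_HI)),
    fn = function(t, p) p[["a"]] * exp(-p[["k"]] * t),
    init = function(k0) c(a = 1, k = k0)),
  modified_henderson_pabis = list(
    params = c("a", "k", "b", "g", "c", "h"),
    spec = list(tl_par("a", -2, 2, "add", 0.3),
                tl_par("k", RATE_LO, RATE_HI),
                tl_par("b", -2, 2, "add", 0.3),
                tl_par("g", RATE_LO, RATE_HI),
                tl_par("c", -2, 2, "add", 0.3),
                tl_par("h", RATE_LO, RATE_HI)),
    fn = function(t, p) p[["a"]] * exp(-p[["k"]] * t) +
      p[["b"]] * exp(-p[["g"]] * t) + p[["c"]] * exp(-p[["h"]] * t),
    # staggered rates break the rank deficiency of three equal exponentials
    init = function(k0) c(a = 0.34, k = k0, b = 0.33, g = 3 * k0,
                          c = 0.33, h = k0 / 3)),
  logarithmic = list(
    params = c("a", "k", "c"),
    spec = list(tl_par("a", -2, 2, "add", 0.3),
                tl_par("k", RATE_LO, RATE_HI),
                tl_par("c", -2, 2, "add", 0.1)),
    fn = function(t, p) p[["a"]] * exp(-p[["k"]] * t) + p[["c"]],
    init = function(k0) c(a = 1, k = k0, c = 0)),
  wang_singh = list(
    params = c("a", "b"),
    spec = list(tl_par("a", -2, 2, "log"),
                tl_par("b", -2, 2, "add", 1e-4)),
    fn = function(t, p) 1 + p[["a"]] * t + p[["b"]] * t^2,
    init = function(k0) c(a = -k0, b = k0^2 / 4)),
  verma = list(
    params = c("a", "k", "g"),
    spec = list(tl_par("a", -2, 2, "add", 0.3),
                tl_par("k", RATE_LO, RATE_HI),
                tl_par("g", RATE_LO, RATE_HI)),
    fn = function(t, p) p[["a"]] * exp(-p[["k"]] * t) +
      (1 - p[["a"]]) * exp(-p[["g"]] * t),
    init = function(k0) c(a = 0.8, k = k0, g = 3 * k0)),
  thomson = list(
    params = c("a", "b"),
    spec = list(tl_par("a", -Inf, Inf), tl_par("b", -Inf, Inf)),
    fn = function(t, p) tl_thomson_mr(t, p[["a"]], p[["b"]]),
    init = function(k0) c(a = -1 / k0, b = 0),
    linear_inverse = TRUE),
  two_term = list(
    params = c("a", "k0", "b", "k1"),
    spec = list(tl_par("a", -2, 2, "add", 0.3),
                tl_par("k0", RATE_LO, RATE_HI),
                tl_par("b", -2, 2, "add", 0.3),
                tl_par("k1", RATE_LO, RATE_HI)),
    fn = function(t, p) p[["a"]] * exp(-p[["k0"]] * t) +
      p[["b"]] * exp(-p[["k1"]] * t),
    init = function(k0) c(a = 0.7, k0 = k0, b = 0.3, k1 = 3 * k0)),
  midilli = list(
    params = c("k", "a", "n", "b"),
    spec = list(tl_par("k", RATE_LO, RATE_HI),
                tl_par("a", -2, 2, "add", 0.3),
                tl_par("n", 0.1, 5),
                tl_par("b", -0.01, 0.01, "add", 0.001)),
    fn = function(t, p) p[["a"]] * exp(-p[["k"]] * t^p[["n"]]) +
      p[["b"]] * t,
    init = function(k0) c(k = k0, a = 1, n = 1, b = 0))
)

# MR(t) for the Thompson model: solve t = a u + b u^2, u = ln MR, taking
# the branch through u = 0 at t = 0.  Beyond the vertex of the parabola
# (discriminant < 0) MR is clamped at the vertex value.
tl_thomson_mr <- function(t, a, b) {
  if (abs(b) < 1e-300) return(exp(t / a))
  disc <- a^2 + 4 * b * t
  u_vertex <- -a / (2 * b)
  u <- ifelse(disc >= 0,
              (-a + sign(a) * sqrt(pmax(disc, 0))) / (2 * b),
              u_vertex)
  exp(u)
}

#' Evaluate a registered thin-layer model
#'
#' @param model model name; see [thinlayer_models()].
#' @param params named numeric vector of the model's parameters, or an
#'   unnamed vector in registry order.
#' @param t times in minutes (>= 0); vectorised.
#' @return predicted moisture ratio at each `t`.
#' @examples
#' evaluate_model("newton", c(k = 0.01), t = c(0, 100))
#' evaluate_model("midilli", c(k = 0.008, a = 0.999, n = 1.058, b = 4e-5), 0)
#' @export
evaluate_model <- function(model, params, t) {
  m <- tl_get(model)
  if (length(params) != length(m$params))
    stop(sprintf("model '%s' takes %d parameters (%s), got %d",
                 model, length(m$params),
                 paste(m$params, collapse = ", "), length(params)),
         call. = FALSE)
  if (is.null(names(params)) || !all(nzchar(names(params)))) {
    names(params) <- m$params
  } else if (!setequal(names(params), m$params)) {
    stop(sprintf("model '%s' parameters are %s", model,
                 paste(m$params, collapse = ", ")), call. = FALSE)
  }
  if (any(!is.finite(params))) stop("params must be finite", call. = FALSE)
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  m$fn(t, as.list(params[m$params]))
}

# log-linear pre-fit of -ln(MR) on t; the slope seeds every rate constant
tl_k_prefit <- function(times, mr) {
  ok <- is.finite(mr) & mr > 1e-6 & mr < 0.999
  if (sum(ok) >= 3) {
    sl <- tryCatch(stats::coef(stats::lm(-log(mr[ok]) ~ times[ok]))[2],
                   error = function(e) NA_real_)
  } else sl <- NA_real_
  if (!is.finite(sl) || sl <= 0) sl <- 1 / max(mean(times[-1]), 1)
  min(max(sl, 1e-6), 5)
}

tl_jitter <- function(init, spec) {
  vapply(seq_along(init), function(i) {
    s <- spec[[i]]; v <- init[i]
    v <- switch(s$jitter,
                log = {
                  base <- if (v == 0) 1e-3 else v
                  base * 10^stats::runif(1, -1, 1)
                },
                add = v + stats::runif(1, -s$width, s$width))
    lo <- s$lower; hi <- s$upper
    if (is.finite(lo)) v <- max(v, lo + 1e-9 * max(1, abs(lo)))
    if (is.finite(hi)) v <- min(v, hi - 1e-9 * max(1, abs(hi)))
    v
  }, numeric(1))
}

#' Fit one thin-layer model to a moisture series
#'
#' Bounded Levenberg-Marquardt least squares of the model's moisture
#' ratio against the observed one, minimising sum((MR_obs - MR_model)^2).
#' Rate constants are seeded from a log-linear pre-fit of -ln(MR) on t;
#' `multistart` restarts jitter the starting values (rates and exponents
#' log-uniformly over one decade either side, amplitudes additively)
#' under `seed`, and the restart with the lowest residual sum of squares
#' wins.  The Thompson model bypasses the optimiser: its inverse form is
#' linear in (ln MR, (ln MR)^2) and is solved by ordinary least squares,
#' with MR(t) recovered by inverting the quadratic.
#'
#' @param series a `moisture_series` (see [moisture_series()], [mr_series()]).
#' @param model model name, see [thinlayer_models()]; default the
#'   Midilli-Kucuk model.
#' @param init optional named vector of starting values overriding the
#'   defaults.
#' @param lower,upper optional named bound overrides.
#' @param multistart number of optimiser restarts (>= 1).
#' @param seed integer seed controlling the restart jitter.
#' @return An object of class `thinlayer_fit` with components
#'   `model`, `params` (named fitted values), `gof` ([gof_stats()]),
#'   `converged`, `n_obs`, `n_params`, `series`.
#' @seealso [fit_thinlayer_all()] to screen all eleven models.
#' @examples
#' cnd <- condition("demo", 1500, 0.3, 4)
#' tt <- seq(0, 400, by = 10)
#' s <- mr_series(tt, exp(-0.01 * tt), cnd)
#' fit <- fit_thinlayer(s, "newton")
#' coef(fit)
#' @export
fit_thinlayer <- function(series, model = "midilli", init = NULL,
                          lower = NULL, upper = NULL,
                          multistart = 8, seed = 1) {
  stopifnot(inherits(series, "moisture_series"), multistart >= 1)
  m <- tl_get(model)
  npar <- length(m$params)
  t_obs <- series$times; mr_obs <- series$mr
  if (length(t_obs) <= npar)
    stop(sprintf("model '%s' has %d parameters but the series has only %d points",
                 model, npar, length(t_obs)), call. = FALSE)

  if (isTRUE(m$linear_inverse)) {
    fit <- tl_fit_thomson(t_obs, mr_obs)
  } else {
    fit <- tl_fit_lm(m, t_obs, mr_obs, init, lower, upper,
                     multistart, seed)
  }

  pred <- m$fn(t_obs, as.list(fit$params))
  gof <- if (all(is.finite(pred))) gof_stats(mr_obs, pred, npar) else NULL
  structure(list(model = model, params = fit$params,
                 gof = gof,
                 converged = fit$converged && !is.null(gof),
                 n_obs = length(t_obs), n_params = npar,
                 series = series),
            class = "thinlayer_fit")
}

tl_fit_lm <- function(m, t_obs, mr_obs, init, lower, upper,
                      multistart, seed) {
  k0 <- tl_k_prefit(t_obs, mr_obs)
  base <- m$init(k0)
  if (!is.null(init)) base[names(init)] <- init
  lo <- vapply(m$spec, `[[`, numeric(1), "lower")
  hi <- vapply(m$spec, `[[`, numeric(1), "upper")
  names(lo) <- names(hi) <- m$params
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper
  base <- pmin(pmax(base, lo + 1e-9), hi - 1e-9)

  resid_fn <- function(p) {
    names(p) <- m$params
    r <- mr_obs - m$fn(t_obs, as.list(p))
    r[!is.finite(r)] <- 1e6
    r
  }
  ctl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                    ptol = 1e-15, gtol = 0)
  best <- NULL
  starts <- vector("list", multistart)
  starts[[1]] <- base
  if (multistart > 1) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    for (i in 2:multistart) starts[[i]] <- stats::setNames(tl_jitter(base, m$spec), m$params)
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
      rm(".Random.seed", envir = globalenv())
  }
  for (st in starts) {
    rv <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = lo, upper = hi,
                         fn = resid_fn, control = ctl),
      error = function(e) NULL)
    if (is.null(rv)) next
    dev <- sum(rv$fvec^2)
    if (is.null(best) || dev < best$dev)
      best <- list(dev = dev,
                   params = stats::setNames(as.numeric(rv$par), m$params),
                   converged = rv$info %in% 1:4 && all(is.finite(rv$par)))
  }
  if (is.null(best))
    best <- list(params = base, converged = FALSE)
  best
}

tl_fit_thomson <- function(t_obs, mr_obs) {
  ok <- mr_obs > 0
  if (sum(ok) < 3)
    return(list(params = c(a = NA_real_, b = NA_real_), converged = FALSE))
  u <- log(mr_obs[ok]); tt <- t_obs[ok]
  cf <- tryCatch(stats::coef(stats::lm(tt ~ 0 + u + I(u^2))),
                 error = function(e) c(NA_real_, NA_real_))
  list(params = c(a = unname(cf[1]), b = unname(cf[2])),
       converged = all(is.finite(cf)))
}

#' @export
print.thinlayer_fit <- function(x, ...) {
  cat(sprintf("Thin-layer fit: %s (%s)\n", x$model,
              if (x$converged) "converged" else "NOT converged"))
  cat("  params:", paste(sprintf("%s = %.6g", names(x$params), x$params),
                         collapse = ", "), "\n")
  if (!is.null(x$gof))
    cat(sprintf("  R2 %.5f  chi2 %.3g  RMSE %.4g  (n = %d)\n",
                x$gof$r2, x$gof$chi2, x$gof$rmse, x$n_obs))
  invisible(x)
}

#' @export
coef.thinlayer_fit <- function(object, ...) object$params

#' @export
fitted.thinlayer_fit <- function(object, ...) {
  evaluate_model(object$model, object$params, object$series$times)
}

#' @export
residuals.thinlayer_fit <- function(object, ...) {
  object$series$mr - fitted(object)
}

#' Predict moisture ratio from a thin-layer fit
#'
#' @param object a `thinlayer_fit`.
#' @param newdata times in minutes at which to predict; defaults to the
#'   fitted series' times.
#' @param ... unused.
#' @return predicted moisture ratios.
#' @export
predict.thinlayer_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$series$times else as.numeric(newdata)
  evaluate_model(object$model, object$params, t)
}

#' @export
summary.thinlayer_fit <- function(object, ...) {
  out <- list(fit = object,
              stats = if (is.null(object$gof)) NULL
                      else as.data.frame(object$gof))
  class(out) <- "summary.thinlayer_fit"
  out
}

#' @export
print.summary.thinlayer_fit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$stats)) {
    cat("\nFit statistics (MR scale):\n")
    print(x$stats, row.names = FALSE, digits = 5)
  }
  invisible(x)
}

#' @export
plot.thinlayer_fit <- function(x, ...) {
  s <- x$series
  graphics::plot(s$times, s$mr, xlab = "time (min)",
                 ylab = "moisture ratio",
                 main = sprintf("%s fit, %s", x$model, s$condition$id), ...)
  tg <- seq(0, max(s$times), length.out = 200)
  graphics::lines(tg, predict(x, tg), col = 2)
  invisible(x)
}

#' Simulate noisy moisture-ratio curves from a fitted model
#'
#' @param object a `thinlayer_fit`.
#' @param nsim number of replicate curves.
#' @param seed integer seed, or NULL to leave the RNG state alone.
#' @param noise_sd additive Gaussian noise on the MR scale.
#' @param ... unused.
#' @return data.frame of `nsim` simulated MR columns over the fitted times.
#' @export
simulate.thinlayer_fit <- function(object, nsim = 1, seed = NULL,
                                   noise_sd = 0.005, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  out <- as.data.frame(replicate(
    nsim, pmax(mu + stats::rnorm(length(mu), 0, noise_sd), 1e-4)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Fit and rank all registered thin-layer models
#'
#' Fits every model in [thinlayer_models()] to the series and ranks the
#' converged fits by ascending reduced chi-square, breaking ties by
#' ascending RMSE then descending R-squared — the selection rule used
#' throughout the thin-layer drying literature (lowest chi2 and RMSE,
#' highest R2 wins).  Unconverged fits sort to the tail.
#'
#' @inheritParams fit_thinlayer
#' @param models subset of model names to fit (default: all eleven).
#' @return An object of class `thinlayer_screen`: list with `fits`
#'   (named list of `thinlayer_fit`), `ranking` (model names, best
#'   first) and `table` (one row per model in ranked order with
#'   parameters counts and the full statistic battery).
#' @examples
#' cnd <- condition("demo", 1500, 0.3, 4)
#' tt <- seq(0, 400, by = 25)
#' s <- mr_series(tt, exp(-0.01 * tt), cnd)
#' scr <- fit_thinlayer_all(s, multistart = 2)
#' head(scr$table, 3)
#' @export
fit_thinlayer_all <- function(series, models = thinlayer_models(),
                              multistart = 8, seed = 1) {
  fits <- lapply(models, function(mn)
    fit_thinlayer(series, mn, multistart = multistart, seed = seed))
  names(fits) <- models
  key <- data.frame(
    model = models,
    converged = vapply(fits, `[[`, logical(1), "converged"),
    chi2 = vapply(fits, function(f)
      if (is.null(f$gof)) Inf else f$gof$chi2, numeric(1)),
    rmse = vapply(fits, function(f)
      if (is.null(f$gof)) Inf else f$gof$rmse, numeric(1)),
    r2 = vapply(fits, function(f)
      if (is.null(f$gof)) -Inf else f$gof$r2, numeric(1)))
  ord <- order(!key$converged, key$chi2, key$rmse, -key$r2)
  ranking <- models[ord]
  tab <- do.call(rbind, lapply(ranking, function(mn) {
    f <- fits[[mn]]
    st <- if (is.null(f$gof))
      data.frame(r2 = NA, se = NA, chi2 = NA, rmse = NA, ef = NA,
                 sse = NA, see = NA, sd = NA)
    else as.data.frame(f$gof)
    cbind(data.frame(model = mn, n_params = f$n_params,
                     converged = f$converged), st)
  }))
  structure(list(fits = fits, ranking = ranking, table = tab,
                 condition = series$condition),
            class = "thinlayer_screen")
}

#' @export
print.thinlayer_screen <- function(x, ...) {
  cat(sprintf("Thin-layer model screen (%s): best model '%s'\n",
              x$condition$id, x$ranking[1]))
  print(utils::head(x$table[, c("model", "n_params", "r2", "chi2", "rmse")],
                    5), row.names = FALSE, digits = 5)
  invisible(x)
}

#' @export
summary.thinlayer_screen <- function(object, ...) {
  cat(sprintf("Thin-layer model screen for condition '%s'\n\n",
              object$condition$id))
  print(object$table, row.names = FALSE, digits = 5)
  invisible(object$table)
}
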