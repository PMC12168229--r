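#' Specify a rational-polynomial response surface
#'
#' Response surfaces linking a drying response (drying time, colour
#' difference, shrinkage, rehydration, thin-layer constants, ...) to the
#' process variables (infrared power I, airflow V, thickness Th) as a
#' ratio of two polynomials in the — optionally log-transformed —
#' variables:
#'
#'   y = N(x) / D(x),  D(x) = 1 + sum(d_j g_j(x))
#'
#' The denominator's constant term is fixed at 1 (the standard
#' identifiability normalisation).  Terms are written as character
#' strings over the variable names: `"1"` (constant), `"V"`, `"V^2"`,
#' `"I:V"` (interaction), `"I^2:V"` etc.  A variable listed in
#' `transforms` as `"log"` enters every term as its natural logarithm.
#'
#' @param response name of the response column.
#' @param numerator character vector of numerator terms (include `"1"`
#'   for an intercept).
#' @param denominator character vector of denominator terms beyond the
#'   fixed constant 1; empty for a plain polynomial model.
#' @param transforms named character vector mapping variable names to
#'   `"linear"` (default) or `"log"`.
#' @return An object of class `surface_template`.
#' @examples
#' surface_template("drying_time",
#'   numerator   = c("1", "V", "I"),
#'   denominator = c("V", "I", "I^2"),
#'   transforms  = c(I = "log"))
#' @export
surface_template <- function(response, numerator,
                             denominator = character(),
                             transforms = character()) {
  stopifnot(is.character(numerator), length(numerator) >= 1)
  parse_terms <- function(x) lapply(x, rs_parse_term)
  structure(list(response = response,
                 numerator = parse_terms(numerator),
                 denominator = parse_terms(denominator),
                 numerator_labels = numerator,
                 denominator_labels = as.character(denominator),
                 transforms = transforms),
            class = "surface_template")
}

# "I^2:V" -> named power vector c(I = 2, V = 1); "1" -> empty vector
rs_parse_term <- function(label) {
  label <- gsub(" ", "", label)
  if (label == "1") return(stats::setNames(numeric(0), character(0)))
  parts <- strsplit(label, ":", fixed = TRUE)[[1]]
  pw <- numeric(0)
  for (p in parts) {
    bits <- strsplit(p, "^", fixed = TRUE)[[1]]
    v <- bits[1]
    e <- if (length(bits) > 1) as.numeric(bits[2]) else 1
    pw[v] <- (if (v %in% names(pw)) pw[v] else 0) + e
  }
  pw
}

rs_basis <- function(terms, data, transforms) {
  n <- nrow(data)
  cols <- vapply(terms, function(pw) {
    if (length(pw) == 0) return(rep(1, n))
    val <- rep(1, n)
    for (v in names(pw)) {
      if (is.null(data[[v]]))
        stop(sprintf("variable '%s' not found in data", v), call. = FALSE)
      x <- data[[v]]
      if (identical(transforms[[v]], "log")) {
        if (any(x <= 0))
          stop(sprintf("log transform of '%s' needs positive values", v),
               call. = FALSE)
        x <- log(x)
      }
      val <- val * x^pw[[v]]
    }
    val
  }, numeric(n))
  matrix(cols, nrow = n)
}

#' Fit a rational response surface
#'
#' Least-squares fit of a [surface_template()] to observed
#' (conditions, response) data.  The rational form is first linearised —
#' multiplying through by the denominator gives a system linear in all
#' coefficients, `y = F n - (y * G) d` — and solved directly; the linear
#' solution then seeds a Levenberg-Marquardt polish of the true residual
#' `y - N/D`.  Plain polynomial templates (empty denominator) reduce to
#' one ordinary least-squares solve.
#'
#' @param data data.frame containing the template's variables and
#'   response column.
#' @param template a [surface_template()].
#' @return An object of class `rational_surface`: the template,
#'   `coef_num` / `coef_den` (named by term label), `r2`, `n_obs`, and
#'   the per-variable training ranges used for extrapolation warnings.
#' @examples
#' d <- expand.grid(I = c(1500, 3500, 5500), V = c(0.3, 0.7, 1.0))
#' d$y <- 2 + 0.001 * d$I - 0.5 * d$V
#' fs <- fit_surface(d, surface_template("y", c("1", "I", "V")))
#' coef(fs)
#' @export
fit_surface <- function(data, template) {
  stopifnot(inherits(template, "surface_template"))
  y <- data[[template$response]]
  if (is.null(y))
    stop(sprintf("response column '%s' not found", template$response),
         call. = FALSE)
  Fm <- rs_basis(template$numerator, data, as.list(template$transforms))
  Gm <- if (length(template$denominator))
    rs_basis(template$denominator, data, as.list(template$transforms))
  else NULL
  p <- ncol(Fm) + if (is.null(Gm)) 0L else ncol(Gm)
  n <- length(y)
  if (n < p + 1)
    stop(sprintf("need more data points (%d) than coefficients (%d)",
                 n, p), call. = FALSE)
  if (n < 2 * p)
    warning(sprintf(
      "only %d points for %d coefficients; fit may be poorly determined",
      n, p))

  X <- if (is.null(Gm)) Fm else cbind(Fm, -y * Gm)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    labs <- c(template$numerator_labels,
              if (!is.null(Gm)) paste0("den:", template$denominator_labels))
    bad <- labs[setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])]
    stop(sprintf("rank-deficient design; collinear terms: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  beta <- qr.coef(qrX, y)

  nn <- ncol(Fm)
  cn <- beta[seq_len(nn)]
  cd <- if (is.null(Gm)) numeric(0) else beta[-seq_len(nn)]

  if (!is.null(Gm)) {   # polish the true (non-linearised) residual
    resid_fn <- function(th) {
      num <- Fm %*% th[seq_len(nn)]
      den <- 1 + Gm %*% th[-seq_len(nn)]
      r <- y - num / den
      r[!is.finite(r)] <- 1e6
      r
    }
    pol <- tryCatch(
      minpack.lm::nls.lm(par = c(cn, cd), fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (!is.null(pol)) {
      cn <- pol$par[seq_len(nn)]
      cd <- pol$par[-seq_len(nn)]
    }
  }
  names(cn) <- template$numerator_labels
  names(cd) <- template$denominator_labels

  vars <- unique(unlist(lapply(c(template$numerator, template$denominator),
                               names)))
  ranges <- lapply(stats::setNames(vars, vars),
                   function(v) range(data[[v]]))

  obj <- structure(list(template = template, coef_num = cn, coef_den = cd,
                        r2 = NA_real_, n_obs = n, ranges = ranges),
                   class = "rational_surface")
  pred <- evaluate_surface(obj, data, warn_extrapolation = FALSE)
  sse <- sum((y - pred)^2)
  obj$r2 <- 1 - sse / sum((y - mean(y))^2)
  obj
}

#' Evaluate a fitted rational surface
#'
#' @param surface a `rational_surface`.
#' @param newdata data.frame with the surface's variables.
#' @param warn_extrapolation warn when any variable lies outside its
#'   training range (default TRUE).
#' @return predicted response values.
#' @export
evaluate_surface <- function(surface, newdata, warn_extrapolation = TRUE) {
  stopifnot(inherits(surface, "rational_surface"))
  tpl <- surface$template
  if (warn_extrapolation) {
    for (v in names(surface$ranges)) {
      r <- surface$ranges[[v]]
      if (any(newdata[[v]] < r[1] | newdata[[v]] > r[2]))
        warning(sprintf(
          "'%s' outside the fitted range [%g, %g]: extrapolating", v,
          r[1], r[2]))
    }
  }
  Fm <- rs_basis(tpl$numerator, newdata, as.list(tpl$transforms))
  num <- drop(Fm %*% surface$coef_num)
  if (length(surface$coef_den)) {
    Gm <- rs_basis(tpl$denominator, newdata, as.list(tpl$transforms))
    den <- drop(1 + Gm %*% surface$coef_den)
    if (any(abs(den) < 1e-9))
      stop("surface denominator vanishes at a requested point",
           call. = FALSE)
    num / den
  } else num
}

#' @export
predict.rational_surface <- function(object, newdata, ...) {
  evaluate_surface(object, newdata, ...)
}

#' @export
coef.rational_surface <- function(object, ...) {
  c(stats::setNames(object$coef_num,
                    paste0("num:", names(object$coef_num))),
    stats::setNames(object$coef_den,
                    if (length(object$coef_den))
                      paste0("den:", names(object$coef_den))
                    else character(0)))
}

#' @export
print.rational_surface <- function(x, ...) {
  tpl <- x$template
  cat(sprintf("Rational surface for '%s' (R2 = %.4f, n = %d)\n",
              tpl$response, x$r2, x$n_obs))
  cat("  numerator:  ",
      paste(sprintf("%+.4g*%s", x$coef_num, names(x$coef_num)),
            collapse = " "), "\n")
  if (length(x$coef_den))
    cat("  denominator: 1",
        paste(sprintf("%+.4g*%s", x$coef_den, names(x$coef_den)),
              collapse = " "), "\n")
  invisible(x)
}
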