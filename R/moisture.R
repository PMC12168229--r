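#' Dry-basis moisture content from wet and dry mass
#'
#' Moisture per unit dry matter: `(wet_mass - dry_mass) / dry_mass`
#' (kg water / kg dry matter).
#'
#' @param wet_mass sample mass including water, g.
#' @param dry_mass bone-dry matter mass, g (> 0, and not above `wet_mass`).
#' @return dry-basis moisture content, kg/kg.
#' @examples
#' mc_dry_basis(500, 71)  # a 500 g load at 85.8% wet basis
#' @export
mc_dry_basis <- function(wet_mass, dry_mass) {
  if (any(dry_mass <= 0))
    stop("dry_mass must be strictly positive", call. = FALSE)
  if (any(wet_mass < dry_mass))
    stop("wet_mass must be >= dry_mass", call. = FALSE)
  (wet_mass - dry_mass) / dry_mass
}

#' Wet-basis / dry-basis moisture conversions
#'
#' `wb_to_db()` maps a wet-basis fraction x to x / (1 - x) kg/kg;
#' `db_to_wb()` is its inverse d / (1 + d).  The two are mutual inverses
#' on \[0, 1).
#'
#' @param mc_wb wet-basis moisture fraction in \[0, 1).
#' @param mc_db dry-basis moisture content, kg/kg, >= 0.
#' @return the converted moisture measure.
#' @examples
#' wb_to_db(0.858)          # 6.042 kg/kg
#' db_to_wb(wb_to_db(0.5))  # 0.5
#' @export
wb_to_db <- function(mc_wb) {
  if (any(mc_wb < 0 | mc_wb >= 1))
    stop("wet-basis moisture must lie in [0, 1)", call. = FALSE)
  mc_wb / (1 - mc_wb)
}

#' @rdname wb_to_db
#' @export
db_to_wb <- function(mc_db) {
  if (any(mc_db < 0))
    stop("dry-basis moisture must be >= 0", call. = FALSE)
  mc_db / (1 + mc_db)
}

#' Moisture ratio
#'
#' Normalised moisture `(m_t - m_e) / (m_i - m_e)`, decaying from 1
#' towards 0 during drying.  The equilibrium moisture content `m_e` is
#' negligible for high-moisture tissue dried to low water activity and
#' defaults to 0, in which case the ratio reduces to `m_t / m_i`.
#'
#' @param m_t moisture content at time t (dry basis, kg/kg).
#' @param m_i initial moisture content (dry basis, kg/kg).
#' @param m_e equilibrium moisture content (dry basis, kg/kg), default 0.
#' @return dimensionless moisture ratio.
#' @export
moisture_ratio <- function(m_t, m_i, m_e = 0) {
  if (any(m_i <= m_e))
    stop("initial moisture must exceed equilibrium moisture",
         call. = FALSE)
  (m_t - m_e) / (m_i - m_e)
}

#' Moisture series: times, dry-basis moisture and moisture ratio
#'
#' Converts a [drying_curve()] into the analysis-ready series: dry-basis
#' moisture content and moisture ratio at each sampling time.  For a mass
#' curve the dry-matter mass is inferred from the initial wet-basis
#' moisture; for a moisture curve the values are taken as-is.
#'
#' @param curve a [drying_curve()].
#' @param initial_mc_wb initial wet-basis moisture fraction, used only
#'   for `value_kind = "mass"` curves to infer dry matter (default 0.858,
#'   typical of fresh onion).
#' @param m_e equilibrium moisture content (dry basis), default 0.
#' @return An object of class `moisture_series` with components `times`
#'   (min), `mc_db` (kg/kg), `mr` (dimensionless) and `condition`.
#' @export
moisture_series <- function(curve, initial_mc_wb = 0.858, m_e = 0) {
  stopifnot(inherits(curve, "drying_curve"))
  if (curve$value_kind == "mass") {
    dry_mass <- curve$values[1] * (1 - initial_mc_wb)
    mc_db <- mc_dry_basis(pmax(curve$values, dry_mass), dry_mass)
  } else {
    mc_db <- curve$values
  }
  mr <- moisture_ratio(mc_db, mc_db[1], m_e)
  structure(list(times = curve$times, mc_db = mc_db, mr = mr,
                 condition = curve$condition),
            class = "moisture_series")
}

#' Construct a moisture series directly from time and moisture-ratio data
#'
#' Convenience constructor used when the moisture ratio is already known
#' (e.g. simulated trajectories).  `mc_db` is reconstructed as
#' `mr * initial_mc_db` so the series is internally consistent.
#'
#' @param times minutes, strictly increasing from 0.
#' @param mr moisture ratios.
#' @param condition a [condition()].
#' @param initial_mc_db initial dry-basis moisture content, kg/kg.
#' @return A `moisture_series`.
#' @export
mr_series <- function(times, mr, condition, initial_mc_db = wb_to_db(0.858)) {
  stopifnot(inherits(condition, "condition"),
            length(times) == length(mr))
  if (any(diff(times) <= 0) || times[1] != 0)
    stop("times must be strictly increasing from 0", call. = FALSE)
  structure(list(times = as.numeric(times),
                 mc_db = as.numeric(mr) * initial_mc_db,
                 mr = as.numeric(mr), condition = condition),
            class = "moisture_series")
}

#' @export
print.moisture_series <- function(x, ...) {
  cat(sprintf("<moisture_series %s: %d points, MR %.3f -> %.3f>\n",
              x$condition$id, length(x$times), x$mr[1],
              x$mr[length(x$mr)]))
  invisible(x)
}

#' Per-interval drying rate
#'
#' Finite-difference moisture loss per minute between consecutive
#' samples, reported under the positive-loss convention: the rate is
#' positive while the sample dries.
#'
#' @param series a `moisture_series` (or any list with `times` and
#'   `mc_db`).
#' @return data.frame with the interval midpoint time (`time_mid`, min)
#'   and drying rate (`rate`, kg/kg per min); one row per interval.
#' @export
drying_rate <- function(series) {
  t <- series$times; m <- series$mc_db
  if (length(t) < 2L)
    stop("drying rate needs at least two points", call. = FALSE)
  dt <- diff(t)
  data.frame(time_mid = t[-length(t)] + dt / 2,
             rate = -diff(m) / dt)
}
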