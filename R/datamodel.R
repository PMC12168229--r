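#' Experimental drying condition
#'
#' A `condition` bundles the three manipulated drying parameters —
#' infrared power, drying-air velocity and slice thickness — together with
#' an optional effective sample temperature.  Thickness is stored as the
#' full slice thickness in millimetres; the half-thickness in metres used
#' by the Fickian slab solution is always derived via [half_thickness()],
#' never stored, so the factor-of-two cannot silently go wrong.
#'
#' @param id character label identifying the condition.
#' @param infrared_power infrared radiation intensity in W/m^2 (> 0).
#' @param airflow drying-air velocity in m/s (> 0).
#' @param thickness full slice thickness in mm (> 0).
#' @param temperature optional effective sample temperature in K (> 0).
#'   Required only by the Arrhenius stage; the drying experiments
#'   themselves are indexed by power, not temperature.
#' @return An object of class `condition`.
#' @examples
#' cnd <- condition("c1", infrared_power = 1500, airflow = 0.3, thickness = 4)
#' half_thickness(cnd)  # 0.002 m
#' @export
condition <- function(id, infrared_power, airflow, thickness,
                      temperature = NA_real_) {
  stopifnot(length(id) == 1L)
  id <- as.character(id)
  chk_pos(infrared_power, "infrared_power")
  chk_pos(airflow, "airflow")
  chk_pos(thickness, "thickness")
  if (!is.na(temperature)) chk_pos(temperature, "temperature")
  structure(
    list(id = id, infrared_power = as.numeric(infrared_power),
         airflow = as.numeric(airflow), thickness = as.numeric(thickness),
         temperature = as.numeric(temperature)),
    class = "condition")
}

#' @rdname condition
#' @param x a `condition`.
#' @return `half_thickness()`: half the slice thickness in metres.
#' @export
half_thickness <- function(x) {
  stopifnot(inherits(x, "condition"))
  x$thickness / 2000
}

#' @export
print.condition <- function(x, ...) {
  cat(sprintf("<condition %s: %g W/m^2, %g m/s, %g mm%s>\n",
              x$id, x$infrared_power, x$airflow, x$thickness,
              if (is.na(x$temperature)) ""
              else sprintf(", %g K", x$temperature)))
  invisible(x)
}

#' Raw drying curve for one condition
#'
#' A time series of either sample mass (g) or dry-basis moisture content
#' (kg water / kg dry matter) recorded during a drying run.  Times are in
#' minutes, must start at zero and be strictly increasing, and at least
#' four points are required (fewer cannot support any of the fitted
#' models).
#'
#' @param condition a [condition()].
#' @param times sampling times in minutes; strictly increasing, first 0.
#' @param values masses in g (strictly positive) or dry-basis moisture
#'   contents (non-negative), matching `value_kind`.
#' @param value_kind `"mass"` or `"moisture_db"`.
#' @return An object of class `drying_curve`.
#' @export
drying_curve <- function(condition, times, values,
                         value_kind = c("moisture_db", "mass")) {
  stopifnot(inherits(condition, "condition"))
  value_kind <- match.arg(value_kind)
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values))
    stop("times and values must have equal length", call. = FALSE)
  if (length(times) < 4L)
    stop(sprintf("curve '%s': need at least 4 points, got %d",
                 condition$id, length(times)), call. = FALSE)
  if (!all(is.finite(times)) || !all(is.finite(values)))
    stop(sprintf("curve '%s': non-finite entries", condition$id),
         call. = FALSE)
  if (times[1] != 0)
    stop(sprintf("curve '%s': first time must be 0, got %g",
                 condition$id, times[1]), call. = FALSE)
  if (any(diff(times) <= 0))
    stop(sprintf("curve '%s': times must be strictly increasing",
                 condition$id), call. = FALSE)
  if (value_kind == "mass" && any(values <= 0))
    stop(sprintf("curve '%s': masses must be strictly positive",
                 condition$id), call. = FALSE)
  if (value_kind == "moisture_db" && any(values < 0))
    stop(sprintf("curve '%s': moisture contents must be non-negative",
                 condition$id), call. = FALSE)
  structure(list(condition = condition, times = times, values = values,
                 value_kind = value_kind),
            class = "drying_curve")
}

#' @export
print.drying_curve <- function(x, ...) {
  cat(sprintf("<drying_curve %s: %d points over %g min (%s)>\n",
              x$condition$id, length(x$times), max(x$times), x$value_kind))
  invisible(x)
}

#' CIELAB colour record
#'
#' @param L_star lightness, in \[0, 100\].
#' @param a_star green-red axis.
#' @param b_star blue-yellow axis.
#' @return An object of class `color_record`.
#' @export
color_record <- function(L_star, a_star, b_star) {
  stopifnot(is.finite(L_star), is.finite(a_star), is.finite(b_star))
  if (L_star < 0 || L_star > 100)
    stop("L* must lie in [0, 100]", call. = FALSE)
  structure(list(L_star = as.numeric(L_star), a_star = as.numeric(a_star),
                 b_star = as.numeric(b_star)),
            class = "color_record")
}

#' Volume / mass record for shrinkage, rehydration and water activity
#'
#' @param volume_fresh fresh-slice volume, cm^3 (> 0).
#' @param volume_dried dried-slice volume, cm^3 (> 0).
#' @param mass_dried dehydrated mass, g (> 0).
#' @param mass_rehydrated rehydrated mass, g (> 0).
#' @param water_activity optional equilibrium relative humidity fraction
#'   in \[0, 1\].  Water activity is an instrument reading: it is stored
#'   and validated here, never computed.
#' @return An object of class `volume_mass_record`.
#' @export
volume_mass_record <- function(volume_fresh, volume_dried,
                               mass_dried, mass_rehydrated,
                               water_activity = NA_real_) {
  chk_pos(volume_fresh, "volume_fresh")
  chk_pos(volume_dried, "volume_dried")
  chk_pos(mass_dried, "mass_dried")
  chk_pos(mass_rehydrated, "mass_rehydrated")
  if (!is.na(water_activity) &&
      (water_activity < 0 || water_activity > 1))
    stop("water_activity must lie in [0, 1]", call. = FALSE)
  structure(list(volume_fresh = as.numeric(volume_fresh),
                 volume_dried = as.numeric(volume_dried),
                 mass_dried = as.numeric(mass_dried),
                 mass_rehydrated = as.numeric(mass_rehydrated),
                 water_activity = as.numeric(water_activity)),
            class = "volume_mass_record")
}

chk_pos <- function(x, nm) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("%s must be a single positive finite number", nm),
         call. = FALSE)
  invisible(x)
}
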