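#' Reference Midilli-Kucuk parameter sets for infrared-dried onion slices
#'
#' Nine published parameter rows for the Midilli-Kucuk model fitted to
#' white onion slices dried under combined infrared-convective heating,
#' one per infrared-power x airflow cell (4 mm slices).  These are the
#' default generator truth of [simulation_spec()]: simulating from them
#' and refitting exercises the whole pipeline against known parameters.
#' The airflow levels are kept exactly as published.
#'
#' @return data.frame with columns `infrared_w_m2`, `airflow_m_s`,
#'   `k` (min^-1), `a`, `n`, `b` (min^-1).
#' @export
default_midilli_params <- function() {
  data.frame(
    infrared_w_m2 = rep(c(1500, 3500, 5500), each = 3),
    airflow_m_s   = rep(c(1.5, 1.0, 0.5), times = 3),
    k = c(0.008, 0.001, 0.015, 0.010, 0.014, 0.019, 0.015, 0.014, 0.015),
    a = c(0.999, 1.007, 1.012, 0.999, 1.007, 0.783, 1.005, 1.003, 0.998),
    n = c(1.0580, 1.0290, 1.0440, 1.0240, 1.0020, 1.0570,
          0.9910, 1.0960, 1.0126),
    b = c(0.00004, 0.00001, 0.00009, 0.00016, 0.00011, 0.00400,
          0.00019, 0.00005, 0.00003))
}

#' Reference effective diffusivities for infrared-dried onion slices
#'
#' Published slope-method effective moisture diffusivities for white
#' onion slices: a 3 x 3 power-by-airflow grid at 4 mm thickness plus a
#' thickness series (4, 6, 8 mm) at 0.3 m/s.  Default generator truth
#' for the Fickian simulation mode.
#'
#' @return data.frame with columns `infrared_w_m2`, `airflow_m_s`,
#'   `thickness_mm`, `deff` (m^2/s).
#' @export
default_deff_table <- function() {
  data.frame(
    infrared_w_m2 = c(rep(c(1500, 3500, 5500), times = 3), 3500, 5500),
    airflow_m_s   = c(rep(c(0.3, 0.7, 1.0), each = 3), 0.3, 0.3),
    thickness_mm  = c(rep(4, 9), 6, 8),
    deff = c(5.46, 7.54, 9.59, 4.05, 5.84, 8.09, 2.59, 3.31, 6.01,
             7.35, 9.07) * 1e-10)
}

#' Map infrared power to an effective sample temperature
#'
#' The drying experiments are indexed by infrared power; the Arrhenius
#' stage needs a temperature.  This linear map — 310 K at 1500 W/m^2 to
#' 350 K at 5500 W/m^2 — is an explicit modelling fiction used only to
#' exercise the Arrhenius machinery on synthetic data.  It is quarantined
#' here so no analysis code depends on it implicitly; real analyses must
#' supply measured sample temperatures.
#'
#' @param infrared_power W/m^2; vectorised.
#' @return effective temperature in K.
#' @export
temperature_from_power <- function(infrared_power) {
  310 + (infrared_power - 1500) * (350 - 310) / (5500 - 1500)
}

#' Specify a synthetic drying experiment
#'
#' Fixes every generative choice of the synthetic experiment: the
#' condition grid, the forward model (`"midilli"` trajectories from the
#' reference constants, or `"fick"` slab-series trajectories from the
#' reference diffusivities), the measurement-noise level, the sampling
#' grid, and the seed.  Additive Gaussian noise of sd `noise_sd` is
#' applied on the moisture-ratio scale and truncated at 1e-4 so moisture
#' stays positive; 0.005 MR units mimics balance-reading error and lands
#' refit chi-square values near the 1e-5 to 1e-4 magnitudes typical of
#' real thin-layer fits.
#'
#' @param mode forward model: `"midilli"` or `"fick"`.
#' @param params parameter map, one row per condition.  Default
#'   [default_midilli_params()] or [default_deff_table()] per mode.
#' @param noise_sd additive MR noise standard deviation (>= 0).
#' @param dt sampling interval, minutes.
#' @param horizon last sampling time, minutes.
#' @param initial_mass fresh sample load, g.
#' @param initial_mc_wb initial wet-basis moisture fraction.
#' @param fick_n_terms series terms for the Fickian mode.
#' @param seed integer seed; together with the spec it fully determines
#'   the generated data.
#' @return An object of class `simulation_spec`; conditions are labelled
#'   `I<power>_V<airflow>[_Th<mm>]`.
#' @export
simulation_spec <- function(mode = c("midilli", "fick"), params = NULL,
                            noise_sd = 0.005, dt = 5, horizon = 500,
                            initial_mass = 500, initial_mc_wb = 0.858,
                            fick_n_terms = 200, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(noise_sd >= 0, dt > 0, horizon > dt)
  if (is.null(params))
    params <- if (mode == "midilli") default_midilli_params()
              else default_deff_table()
  if (is.null(params$thickness_mm)) params$thickness_mm <- 4
  params$condition_id <- sprintf(
    "I%d_V%s%s", params$infrared_w_m2,
    sub("\\.?0+$", "", format(params$airflow_m_s)),
    ifelse(params$thickness_mm == 4, "",
           paste0("_Th", params$thickness_mm)))
  structure(list(mode = mode, params = params, noise_sd = noise_sd,
                 dt = dt, horizon = horizon,
                 initial_mass = initial_mass,
                 initial_mc_wb = initial_mc_wb,
                 fick_n_terms = fick_n_terms, seed = seed),
            class = "simulation_spec")
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat(sprintf(
    "<simulation_spec: %s mode, %d conditions, noise sd %g, dt %g min, horizon %g min, seed %d>\n",
    x$mode, nrow(x$params), x$noise_sd, x$dt, x$horizon, x$seed))
  invisible(x)
}

spec_condition <- function(spec, condition_id) {
  i <- match(condition_id, spec$params$condition_id)
  if (is.na(i))
    stop(sprintf("condition '%s' not in the simulation grid", condition_id),
         call. = FALSE)
  row <- spec$params[i, ]
  condition(row$condition_id, row$infrared_w_m2, row$airflow_m_s,
            row$thickness_mm,
            temperature = temperature_from_power(row$infrared_w_m2))
}

spec_true_mr <- function(spec, condition_id, times) {
  i <- match(condition_id, spec$params$condition_id)
  row <- spec$params[i, ]
  if (spec$mode == "midilli") {
    evaluate_model("midilli",
                   c(k = row$k, a = row$a, n = row$n, b = row$b), times)
  } else {
    fick_mr(row$deff, row$thickness_mm / 2000, times * 60,
            n_terms = spec$fick_n_terms)
  }
}

#' Simulate one drying curve
#'
#' Generates the moisture-ratio trajectory of one condition from the
#' spec's forward model, adds truncated Gaussian noise, and returns it
#' either as a `moisture_series` on the MR scale (`as = "mr"`) or as a
#' mass-series [drying_curve()] in grams (`as = "mass"`), using the
#' spec's initial mass and wet-basis moisture.
#'
#' @param spec a [simulation_spec()].
#' @param condition_id one of `spec$params$condition_id`.
#' @param as output representation, `"mr"` or `"mass"`.
#' @param seed overriding seed; default the spec's own.
#' @return a `moisture_series` or a `drying_curve`.
#' @export
simulate_curve <- function(spec, condition_id, as = c("mr", "mass"),
                           seed = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  as <- match.arg(as)
  if (is.null(seed)) seed <- spec$seed
  cnd <- spec_condition(spec, condition_id)
  times <- seq(0, spec$horizon, by = spec$dt)
  mr <- spec_true_mr(spec, condition_id, times)
  if (spec$noise_sd > 0) {
    # per-condition stream: reproducible regardless of simulation order
    set.seed((seed + 7919L *
                match(condition_id, spec$params$condition_id)) %% 2147483629L)
    mr <- pmax(mr + stats::rnorm(length(mr), 0, spec$noise_sd), 1e-4)
  }
  mc_db_i <- wb_to_db(spec$initial_mc_wb)
  if (as == "mr") {
    mr_series(times, mr, cnd, initial_mc_db = mc_db_i)
  } else {
    dry_mass <- spec$initial_mass * (1 - spec$initial_mc_wb)
    drying_curve(cnd, times, dry_mass * (1 + mr * mc_db_i),
                 value_kind = "mass")
  }
}

#' Simulate a full drying experiment bundle
#'
#' Generates one curve per grid condition plus the condition table and
#' synthetic quality tables (CIELAB colours, volumes and masses, water
#' activity).  The quality tables follow simple documented generative
#' choices: colour drift, shrinkage, rehydration and water activity vary
#' linearly with infrared power and airflow inside the ranges typical of
#' infrared-dried onion (shrinkage ratio 0.16-0.25, rehydration ratio
#' 3.5-5.1, water activity 0.37-0.45 against a fresh reference of 0.962).
#'
#' @param spec a [simulation_spec()].
#' @param as representation of the curves, as in [simulate_curve()].
#' @return list with `curves` (named list), `conditions` (data.frame),
#'   `fresh_color` ([color_record()]), `colors` (named list of dried
#'   [color_record()]s), `volume_mass` (named list of
#'   [volume_mass_record()]s), and `quality` (data.frame assembled with
#'   [quality_record()]).
#' @export
simulate_experiment <- function(spec, as = "mass") {
  stopifnot(inherits(spec, "simulation_spec"))
  ids <- spec$params$condition_id
  curves <- lapply(ids, function(id) simulate_curve(spec, id, as = as))
  names(curves) <- ids
  pr <- spec$params
  conditions <- data.frame(
    condition_id = ids,
    infrared_w_m2 = pr$infrared_w_m2,
    airflow_m_s = pr$airflow_m_s,
    thickness_mm = pr$thickness_mm,
    temperature_k = temperature_from_power(pr$infrared_w_m2))

  # quality generative choices (linear in the scaled process variables)
  pw <- (pr$infrared_w_m2 - 1500) / 4000          # 0..1
  af <- (pr$airflow_m_s - min(pr$airflow_m_s)) /
    max(diff(range(pr$airflow_m_s)), 1e-9)        # 0..1
  th <- (pr$thickness_mm - 4) / 4                 # 0..1
  set.seed((spec$seed + 104729L) %% 2147483629L)
  eps <- function(sd) stats::rnorm(length(ids), 0, sd)

  fresh <- color_record(80, 2, 12)
  de_target <- 7 + 9 * pw + 6 * th + 2 * af + eps(0.3)
  colors <- lapply(seq_along(ids), function(i) {
    d <- de_target[i]
    # drift mostly darkening with some yellowing: |(dL, da, db)| = d
    color_record(fresh$L_star - d * 0.8, fresh$a_star + d * 0.35,
                 fresh$b_star + d * sqrt(max(1 - 0.8^2 - 0.35^2, 0)))
  })
  names(colors) <- ids

  # shrinkage falls with power (more at low airflow), rehydration rises
  # with power and thickness; both clamped to the target design ranges
  sr <- pmin(pmax(0.25 - pw * (0.09 - 0.05 * af) + eps(0.003),
                  0.16), 0.25)
  rr <- pmin(pmax(3.5 + 1.6 * pw * (1 - 0.3 * af) + 0.3 * th + eps(0.03),
                  3.5), 5.1)
  aw <- pmin(pmax(0.45 - 0.08 * pw + 0.02 * af + eps(0.005), 0.2), 0.59)
  v_fresh <- 10
  vm <- lapply(seq_along(ids), function(i)
    volume_mass_record(v_fresh, v_fresh * (1 - sr[i]),
                       mass_dried = 5, mass_rehydrated = 5 * rr[i],
                       water_activity = aw[i]))
  names(vm) <- ids

  quality <- do.call(rbind, lapply(seq_along(ids), function(i)
    quality_record(ids[i], colors[[i]], fresh, vm[[i]])))

  list(curves = curves, conditions = conditions, fresh_color = fresh,
       colors = colors, volume_mass = vm, quality = quality)
}

#' Time to dry to a target moisture
#'
#' Solves MR(t) = `target_mr` for a fitted or registered thin-layer
#' model by bisection on `[0, t_max]`.  Returns NA (with a message) when
#' the model never reaches the target within `t_max` — which happens for
#' parameter sets whose linear tail term keeps late-time MR above the
#' target.
#'
#' @param model model name or a `thinlayer_fit`.
#' @param params named parameter vector (ignored when `model` is a fit).
#' @param target_mr target moisture ratio, e.g. the value equivalent to
#'   6% wet-basis moisture.
#' @param t_max search horizon, minutes.
#' @return drying time in minutes, or NA if the target is not reached.
#' @export
drying_time_to <- function(model, params = NULL, target_mr,
                           t_max = 2000) {
  if (inherits(model, "thinlayer_fit")) {
    params <- model$params; model <- model$model
  }
  f <- function(t) evaluate_model(model, params, t) - target_mr
  grid <- seq(0, t_max, length.out = 4001)
  v <- f(grid)
  idx <- which(v <= 0)[1]
  if (is.na(idx) || idx == 1) return(NA_real_)
  stats::uniroot(f, c(grid[idx - 1], grid[idx]), tol = 1e-8)$root
}
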