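#' Run the full drying analysis pipeline
#'
#' One call from raw curves to a report: per-condition thin-layer model
#' screen, slope-method diffusivity, Arrhenius activation energy across
#' conditions sharing airflow and thickness (requires per-condition
#' temperatures — it fails loudly without them), and the quality table
#' if quality inputs are supplied.  Deterministic given inputs and seed.
#'
#' @param curves named list of [drying_curve()] objects.
#' @param config settings list from [read_config()].
#' @param quality optional quality data.frame (e.g. from
#'   [simulate_experiment()]).
#' @param seed integer seed for the fit multistarts.
#' @param out optional output CSV path; when given, the report is
#'   written with [write_report()].
#' @return list with `screens` (per-condition `thinlayer_screen`),
#'   `best` (data.frame of best model per condition), `deff`
#'   (per-condition `deff_fit`), `arrhenius` (per airflow-thickness
#'   group `arrhenius_fit`), `quality`, and `report` (the long-format
#'   data.frame).
#' @export
run_pipeline <- function(curves, config = read_config(), quality = NULL,
                         seed = 1, out = NULL) {
  if (!length(curves)) stop("no curves supplied", call. = FALSE)
  series <- lapply(curves, moisture_series)
  screens <- lapply(series, function(s)
    fit_thinlayer_all(s, models = config$models,
                      multistart = config$multistart, seed = seed))
  best <- do.call(rbind, lapply(names(screens), function(id) {
    b <- screens[[id]]$fits[[screens[[id]]$ranking[1]]]
    data.frame(condition_id = id, model = b$model, chi2 = b$gof$chi2,
               rmse = b$gof$rmse, r2 = b$gof$r2)
  }))
  deff <- lapply(series, function(s)
    estimate_deff(s, window = config$deff_window))

  conds <- lapply(curves, `[[`, "condition")
  grp_key <- vapply(conds, function(cn)
    sprintf("V%g_Th%g", cn$airflow, cn$thickness), character(1))
  arrhenius <- list()
  for (g in unique(grp_key)) {
    ids <- names(conds)[grp_key == g]
    temps <- vapply(conds[ids], `[[`, numeric(1), "temperature")
    dv <- vapply(deff[ids], `[[`, numeric(1), "deff")
    ok <- is.finite(temps) & is.finite(dv) & dv > 0
    if (any(!ok))
      message(sprintf("group %s: dropping %d condition(s) without a usable diffusivity",
                      g, sum(!ok)))
    if (sum(ok) >= 2 && length(unique(temps[ok])) >= 2) {
      arrhenius[[g]] <- fit_arrhenius(dv[ok], temps[ok])
    }
  }
  if (!length(arrhenius) &&
      any(!is.finite(vapply(conds, `[[`, numeric(1), "temperature"))))
    message("Arrhenius stage skipped: conditions carry no temperatures")

  results <- c(screens, deff,
               stats::setNames(arrhenius, names(arrhenius)),
               if (!is.null(quality)) list(quality = quality))
  report <- do.call(rbind, lapply(seq_along(results), function(i)
    report_rows(results[[i]], fallback_id = names(results)[i])))
  if (!is.null(out)) write_report(results, out)
  list(screens = screens, best = best, deff = deff,
       arrhenius = arrhenius, quality = quality, report = report)
}
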