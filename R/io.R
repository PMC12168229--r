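#' Read a condition table
#'
#' Comma-separated, dot-decimal, UTF-8, mandatory header
#' `condition_id,infrared_w_m2,airflow_m_s,thickness_mm` with an
#' optional `temperature_k` column.
#'
#' @param path CSV file path.
#' @return named list of [condition()] objects.
#' @export
read_conditions <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  need <- c("condition_id", "infrared_w_m2", "airflow_m_s", "thickness_mm")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (anyDuplicated(df$condition_id))
    stop(sprintf("%s: duplicated condition_id", path), call. = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i)
    condition(df$condition_id[i], df$infrared_w_m2[i], df$airflow_m_s[i],
              df$thickness_mm[i],
              temperature = if ("temperature_k" %in% names(df))
                df$temperature_k[i] else NA_real_))
  names(out) <- df$condition_id
  out
}

#' Read drying curves
#'
#' Curves CSV dialect: header `condition_id,time_min,value,value_kind`,
#' comma-separated, dot decimal, UTF-8.  `value_kind` is `mass` (g) or
#' `moisture_db` (kg/kg) and must be constant within a condition.  Rows
#' are sorted by time per condition; duplicate times, unknown condition
#' ids and non-finite values fail with a message naming the file and the
#' offending condition.
#'
#' @param path curves CSV path.
#' @param condition_table conditions CSV path, or a named list of
#'   [condition()] objects.
#' @return named list of [drying_curve()] objects, one per condition id
#'   present in the curves file.
#' @export
read_curves <- function(path, condition_table) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  conds <- if (is.character(condition_table)) read_conditions(condition_table)
           else condition_table
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  need <- c("condition_id", "time_min", "value", "value_kind")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  unknown <- setdiff(unique(df$condition_id), names(conds))
  if (length(unknown))
    stop(sprintf("%s: condition id(s) not in the condition table: %s",
                 path, paste(unknown, collapse = ", ")), call. = FALSE)
  ids <- unique(df$condition_id)
  out <- lapply(ids, function(id) {
    sub <- df[df$condition_id == id, ]
    sub <- sub[order(sub$time_min), ]
    if (anyDuplicated(sub$time_min))
      stop(sprintf("%s: duplicate time for condition '%s'", path, id),
           call. = FALSE)
    kind <- unique(sub$value_kind)
    if (length(kind) != 1L || !kind %in% c("mass", "moisture_db"))
      stop(sprintf("%s: condition '%s' has invalid value_kind", path, id),
           call. = FALSE)
    drying_curve(conds[[id]], sub$time_min, sub$value, value_kind = kind)
  })
  names(out) <- ids
  out
}

#' Write drying curves / condition tables
#'
#' Inverse of [read_curves()] / [read_conditions()]; numbers are written
#' with 15 significant digits so a read-write round trip is the identity
#' well beyond 12 significant digits.
#'
#' @param curves list of [drying_curve()] objects.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_curves <- function(curves, path) {
  if (!length(curves)) stop("no curves to write", call. = FALSE)
  rows <- do.call(rbind, lapply(curves, function(cv)
    data.frame(condition_id = cv$condition$id,
               time_min = num15(cv$times), value = num15(cv$values),
               value_kind = cv$value_kind)))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_curves
#' @param conditions list of [condition()] objects or the conditions
#'   data.frame of [simulate_experiment()].
#' @export
write_conditions <- function(conditions, path) {
  if (is.data.frame(conditions)) {
    df <- conditions
  } else {
    if (!length(conditions)) stop("no conditions to write", call. = FALSE)
    df <- do.call(rbind, lapply(conditions, function(cn)
      data.frame(condition_id = cn$id, infrared_w_m2 = cn$infrared_power,
                 airflow_m_s = cn$airflow, thickness_mm = cn$thickness,
                 temperature_k = cn$temperature)))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

num15 <- function(x) as.numeric(formatC(x, digits = 15, format = "g"))

#' Write an analysis report
#'
#' Flattens a collection of results — `thinlayer_fit`,
#' `thinlayer_screen`, `deff_fit`, `arrhenius_fit` objects or quality
#' data.frames — into one long-format CSV with the fixed column order
#' `condition_id,record,model,field,value`, numbers at 15 significant
#' digits so re-reading reproduces the in-memory values.
#'
#' @param results non-empty (optionally named) list of result objects;
#'   names are used as condition ids where the object itself carries
#'   none.
#' @param path output CSV path.
#' @return the written data.frame, invisibly.
#' @export
write_report <- function(results, path) {
  if (!length(results)) stop("refusing to write an empty report",
                             call. = FALSE)
  nm <- names(results)
  if (is.null(nm)) nm <- rep("", length(results))
  rows <- do.call(rbind, lapply(seq_along(results), function(i)
    report_rows(results[[i]], fallback_id = nm[i])))
  rows$value <- num15(rows$value)
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(rows)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

report_rows <- function(x, fallback_id = "") UseMethod("report_rows")

report_rows.thinlayer_fit <- function(x, fallback_id = "") {
  id <- if (nzchar(fallback_id)) fallback_id else x$series$condition$id
  fields <- c(as.list(x$params),
              if (!is.null(x$gof))
                as.list(as.data.frame(x$gof)))
  data.frame(condition_id = id, record = "thinlayer_fit",
             model = x$model, field = names(fields),
             value = as.numeric(unlist(fields)))
}

report_rows.thinlayer_screen <- function(x, fallback_id = "") {
  do.call(rbind, lapply(x$ranking, function(mn)
    report_rows(x$fits[[mn]], fallback_id = fallback_id)))
}

report_rows.deff_fit <- function(x, fallback_id = "") {
  data.frame(condition_id = fallback_id, record = "deff_fit",
             model = "fick_slope",
             field = c("deff", "slope", "r2", "half_thickness"),
             value = c(x$deff, x$slope, x$r2, x$half_thickness))
}

report_rows.arrhenius_fit <- function(x, fallback_id = "") {
  data.frame(condition_id = fallback_id, record = "arrhenius_fit",
             model = "arrhenius",
             field = c("ea_kj_mol", "d0", "r2"),
             value = c(x$ea, x$d0, x$r2))
}

report_rows.data.frame <- function(x, fallback_id = "") {
  if (is.null(x$condition_id))
    stop("quality data.frames need a condition_id column", call. = FALSE)
  num <- names(x)[vapply(x, is.numeric, logical(1))]
  do.call(rbind, lapply(seq_len(nrow(x)), function(i)
    data.frame(condition_id = x$condition_id[i], record = "quality",
               model = "", field = num,
               value = as.numeric(x[i, num]))))
}

report_rows.default <- function(x, fallback_id = "") {
  stop(sprintf("cannot put an object of class '%s' in a report",
               class(x)[1]), call. = FALSE)
}

#' Read an analysis configuration
#'
#' YAML configuration controlling the batch pipeline: which thin-layer
#' models to fit, multistart count, the slope-method MR window, the
#' browning-index denominator constant, and the simulation settings.
#' Unknown keys are rejected; missing keys take the defaults below.
#'
#' @param path YAML file, or NULL for pure defaults.
#' @return named list of settings.
#' @export
read_config <- function(path = NULL) {
  defaults <- list(
    models = thinlayer_models(),
    multistart = 8,
    deff_window = c(0.02, 0.7),
    bi_denominator_constant = 6.645,
    simulation = list(mode = "midilli", noise_sd = 0.005, dt = 5,
                      horizon = 500, initial_mass = 500,
                      initial_mc_wb = 0.858))
  if (is.null(path)) return(defaults)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  for (k in names(cfg)) {
    if (k == "simulation") {
      defaults$simulation[names(cfg$simulation)] <- cfg$simulation
    } else defaults[[k]] <- cfg[[k]]
  }
  if (length(defaults$deff_window) == 2)
    defaults$deff_window <- as.numeric(defaults$deff_window)
  defaults
}
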