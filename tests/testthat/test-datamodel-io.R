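test_that("condition validates its fields and derives half thickness", {
  cnd <- condition("c1", 1500, 0.3, 4, temperature = 310)
  expect_equal(half_thickness(cnd), 0.002)
  expect_equal(half_thickness(condition("c2", 5500, 1, 8)), 0.004)
  expect_error(condition("c", -1, 0.3, 4), "infrared_power")
  expect_error(condition("c", 1500, 0, 4), "airflow")
  expect_error(condition("c", 1500, 0.3, 0), "thickness")
  expect_error(condition("c", 1500, 0.3, 4, temperature = -5),
               "temperature")
})

test_that("drying_curve enforces its invariants", {
  cnd <- demo_condition()
  expect_error(drying_curve(cnd, c(0, 1, 2), c(1, 1, 1), "mass"),
               "at least 4")
  expect_error(drying_curve(cnd, c(0, 2, 1, 3), 4:1, "mass"),
               "strictly increasing")
  expect_error(drying_curve(cnd, c(1, 2, 3, 4), 4:1, "mass"),
               "first time")
  expect_error(drying_curve(cnd, 0:3, c(1, 2, -1, 1), "mass"),
               "positive")
  expect_error(drying_curve(cnd, 0:3, c(1, 2, NA, 1), "mass"),
               "non-finite")
  ok <- drying_curve(cnd, 0:3, c(4, 3, 2, 1), "moisture_db")
  expect_s3_class(ok, "drying_curve")
})

test_that("curve CSV write/read round trip is the identity", {
  td <- withr::local_tempdir()
  spec <- simulation_spec(seed = 3)
  bundle <- simulate_experiment(spec)
  cf <- file.path(td, "curves.csv"); kf <- file.path(td, "conditions.csv")
  write_curves(bundle$curves, cf)
  write_conditions(bundle$conditions, kf)
  back <- read_curves(cf, kf)
  expect_setequal(names(back), names(bundle$curves))
  for (id in names(back)) {
    expect_equal(back[[id]]$times, bundle$curves[[id]]$times,
                 tolerance = 1e-12)
    expect_equal(back[[id]]$values, bundle$curves[[id]]$values,
                 tolerance = 1e-12)
    expect_identical(back[[id]]$value_kind,
                     bundle$curves[[id]]$value_kind)
    expect_equal(back[[id]]$condition$thickness,
                 bundle$curves[[id]]$condition$thickness)
  }
})

test_that("curve reader fails descriptively on bad input", {
  td <- withr::local_tempdir()
  kf <- file.path(td, "conditions.csv")
  writeLines(c("condition_id,infrared_w_m2,airflow_m_s,thickness_mm",
               "a,1500,0.3,4"), kf)
  cf <- file.path(td, "curves.csv")

  writeLines(c("condition_id,time_min,value,value_kind",
               "a,0,1,moisture_db", "a,10,0.8,moisture_db",
               "a,10,0.7,moisture_db", "a,20,0.6,moisture_db"), cf)
  expect_error(read_curves(cf, kf), "duplicate time.*'a'")

  writeLines(c("condition_id,time_min,value,value_kind",
               "zz,0,1,moisture_db", "zz,10,0.8,moisture_db",
               "zz,20,0.7,moisture_db", "zz,30,0.6,moisture_db"), cf)
  expect_error(read_curves(cf, kf), "zz")

  writeLines(c("condition_id,time_min,value", "a,0,1"), cf)
  expect_error(read_curves(cf, kf), "missing column.*value_kind")

  expect_error(read_curves(file.path(td, "nope.csv"), kf), "no such file")
})

test_that("report writing round-trips numbers and rejects empty input", {
  td <- withr::local_tempdir()
  rf <- file.path(td, "report.csv")
  expect_error(write_report(list(), rf), "empty")

  s <- model_series("newton", c(k = 0.01))
  fit <- fit_thinlayer(s, "newton", multistart = 2)
  rows <- write_report(list(demo = fit), rf)
  back <- read_report(rf)
  expect_identical(names(back),
                   c("condition_id", "record", "model", "field", "value"))
  expect_equal(nrow(back[back$field == "k", ]), 1L)
  expect_equal(back$value, rows$value, tolerance = 1e-12)

  # full pipeline report re-read equals the in-memory values
  bundle <- simulate_experiment(simulation_spec(seed = 5, dt = 25))
  res <- run_pipeline(bundle$curves[1:3], quality = bundle$quality,
                      seed = 5, out = rf)
  back2 <- read_report(rf)
  written <- write_report(c(res$screens, res$deff,
                            list(quality = bundle$quality)),
                          file.path(td, "again.csv"))
  expect_equal(nrow(back2) > 100, TRUE)
  expect_equal(back2$value[back2$record == "quality"],
               written$value[written$record == "quality"],
               tolerance = 1e-12)
})

test_that("config reader merges defaults and rejects unknown keys", {
  cfg <- read_config()
  expect_setequal(cfg$models, thinlayer_models())
  expect_equal(cfg$deff_window, c(0.02, 0.7))

  td <- withr::local_tempdir()
  yf <- file.path(td, "cfg.yaml")
  writeLines(c("multistart: 3", "deff_window: [0.05, 0.6]",
               "simulation:", "  noise_sd: 0.01"), yf)
  cfg2 <- read_config(yf)
  expect_equal(cfg2$multistart, 3)
  expect_equal(cfg2$deff_window, c(0.05, 0.6))
  expect_equal(cfg2$simulation$noise_sd, 0.01)
  expect_equal(cfg2$simulation$dt, 5)  # untouched default

  writeLines("bogus_key: 1", yf)
  expect_error(read_config(yf), "unknown config key")
})
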