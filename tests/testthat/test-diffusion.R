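test_that("slab series normalisation and limits", {
  # truncation error at t = 0 is the analytic tail (8/pi^2) * sum_{j>=J} (2j+1)^-2,
  # which is bounded by (8/pi^2)/(4J) and vanishes as J grows
  for (J in c(200, 2000)) {
    err <- 1 - fick_mr(5e-10, 0.002, 0, n_terms = J)
    tail <- (8 / pi^2) * sum(1 / (2 * (J:(J + 2e6)) + 1)^2)
    expect_gt(err, 0)
    expect_lt(err, (8 / pi^2) / (4 * J))
    expect_equal(err, tail, tolerance = 1e-2)
  }
  expect_equal(fick_mr(5e-10, 0.002, 0, n_terms = 2500), 1,
               tolerance = 1e-4)
  expect_equal(fick_mr(5e-10, 0.002, 0, n_terms = 1), 8 / pi^2,
               tolerance = 1e-12)
  # decay limit
  expect_lt(fick_mr(5.46e-10, 0.002, 1e7, n_terms = 50), 1e-10)
  expect_error(fick_mr(-1e-10, 0.002, 0), "deff > 0")
  expect_error(fick_mr(1e-10, 0.002, -5), ">= 0")
})

test_that("slab series is strictly decreasing in time and diffusivity", {
  tt <- seq(600, 24000, by = 600)
  mr <- fick_mr(5.46e-10, 0.002, tt, n_terms = 50)
  expect_true(all(diff(mr) < 0))
  dd <- seq(1e-10, 1e-9, by = 1e-10)
  at_t <- vapply(dd, function(d) fick_mr(d, 0.002, 6000, 50), numeric(1))
  expect_true(all(diff(at_t) < 0))
})

test_that("slope method inverts the one-term solution exactly", {
  tt <- seq(0, 400, by = 10)
  for (case in list(c(5.46e-10, 0.002), c(9.07e-10, 0.004),
                    c(2.59e-10, 0.002))) {
    mr <- fick_mr(case[1], case[2], tt * 60, n_terms = 1)
    d <- estimate_deff(mr, times = tt, half_thickness = case[2],
                       window = c(0, 1))
    expect_lt(rel_err(d$deff, case[1]), 1e-6)
    expect_equal(d$r2, 1, tolerance = 1e-10)
  }
})

test_that("full-series curves with the default window recover deff to 2%", {
  # quantifies the one-term approximation bias on the late-time window
  tt <- seq(0, 400, by = 10)
  for (deff in c(5.46e-10, 9.59e-10)) {
    mr <- fick_mr(deff, 0.002, tt * 60, n_terms = 200)
    d <- estimate_deff(mr, times = tt, half_thickness = 0.002)
    expect_lt(rel_err(d$deff, deff), 0.02)
  }
})

test_that("deff scales with the square of the half thickness", {
  tt <- seq(0, 400, by = 10)
  mr <- fick_mr(5e-10, 0.002, tt * 60, n_terms = 1)
  d1 <- estimate_deff(mr, times = tt, half_thickness = 0.002)
  d2 <- estimate_deff(mr, times = tt, half_thickness = 0.004)
  expect_equal(d2$deff / d1$deff, 4, tolerance = 1e-10)
  expect_equal(d2$slope, d1$slope, tolerance = 1e-12)
})

test_that("slope method validates its window and inputs", {
  tt <- seq(0, 100, by = 10)
  mr <- exp(-0.001 * tt)   # never drops below 0.9
  expect_error(estimate_deff(mr, times = tt, half_thickness = 0.002,
                             window = c(0.02, 0.7)),
               ">= 3 points")
  expect_error(estimate_deff(mr, times = tt), "half_thickness required")
  # only the declining phase enters the regression
  mr2 <- c(exp(-0.05 * 0:10), exp(-0.5) * (1 + 0.2 * (1:5)))
  tt2 <- 0:15 * 10
  d <- estimate_deff(mr2, times = tt2, half_thickness = 0.002,
                     window = c(0, 1))
  expect_true(max(d$used) <= 11)
  expect_gt(d$deff, 0)
})

test_that("Arrhenius fit is exact on noiseless generated diffusivities", {
  temps <- c(310, 330, 350)
  for (ea in c(18, 25, 28.95)) {
    deffs <- 1e-5 * exp(-ea * 1000 / (8.314 * temps))
    fit <- fit_arrhenius(deffs, temps)
    expect_lt(rel_err(fit$ea, ea), 1e-9)
    expect_lt(rel_err(fit$d0, 1e-5), 1e-6)
    expect_equal(fit$r2, 1, tolerance = 1e-10)
  }
  # equal diffusivities imply zero activation energy
  expect_equal(fit_arrhenius(c(3e-10, 3e-10), c(310, 350))$ea, 0,
               tolerance = 1e-12)
  expect_error(fit_arrhenius(c(1e-10, 2e-10), c(310, 310)),
               "distinct temperatures")
  expect_error(fit_arrhenius(c(-1e-10, 2e-10), c(310, 330)), "> 0")
})

test_that("Arrhenius predict inverts the fitted law", {
  temps <- seq(305, 355, by = 10)
  deffs <- 2e-6 * exp(-22000 / (8.314 * temps))
  fit <- fit_arrhenius(deffs, temps)
  expect_equal(predict(fit, temps), deffs, tolerance = 1e-8)
  expect_equal(unname(coef(fit)["ea"]), 22, tolerance = 1e-9)
})
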