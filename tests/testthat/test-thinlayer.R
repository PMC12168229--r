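test_that("model registry evaluates its closed forms", {
  # published parameter row: at t = 0 the Midilli MR equals its amplitude a
  expect_equal(
    evaluate_model("midilli", c(k = 0.008, a = 0.999, n = 1.058,
                                b = 0.00004), 0), 0.999)
  expect_equal(evaluate_model("newton", c(k = 0.01), 0), 1)
  expect_equal(
    evaluate_model("midilli", c(k = 0.01, a = 1, n = 1, b = 0), 100),
    exp(-1), tolerance = 1e-12)

  expect_error(evaluate_model("nonsense", c(k = 1), 0), "unknown")
  expect_error(evaluate_model("page", c(k = 1), 0), "2 parameters")
  expect_error(evaluate_model("newton", c(q = 1), 0), "parameters are")
  expect_error(evaluate_model("newton", c(k = 1), -1), ">= 0")
})

test_that("amplitude parameterisations sum correctly at t = 0", {
  expect_equal(evaluate_model("two_term",
                              c(a = 0.6, k0 = 0.01, b = 0.3, k1 = 0.002),
                              0), 0.9)
  expect_equal(evaluate_model("verma", c(a = 0.7, k = 0.01, g = 0.03), 0),
               1)
  expect_equal(evaluate_model("logarithmic",
                              c(a = 0.9, k = 0.01, c = 0.05), 0), 0.95)
  expect_equal(evaluate_model(
    "modified_henderson_pabis",
    c(a = 0.5, k = 0.01, b = 0.3, g = 0.02, c = 0.2, h = 0.005), 0), 1)
  expect_equal(evaluate_model("wang_singh", c(a = -0.002, b = 1e-6), 0), 1)
})

test_that("model nesting holds in evaluation and in fitted chi-square", {
  tt <- seq(0, 400, by = 8)
  expect_equal(evaluate_model("page", c(k = 0.013, n = 1), tt),
               evaluate_model("newton", c(k = 0.013), tt))
  expect_equal(evaluate_model("midilli", c(k = 0.013, a = 1, n = 1, b = 0),
                              tt),
               evaluate_model("newton", c(k = 0.013), tt))

  # on any series, a nesting model fits at least as well as its nested one
  s <- noisy_midilli_series(c(k = 0.01, a = 1, n = 1.1, b = 1e-4),
                            seed = 9)
  f_newton <- fit_thinlayer(s, "newton", seed = 1)
  f_page <- fit_thinlayer(s, "page", seed = 1)
  f_midilli <- fit_thinlayer(s, "midilli", seed = 1)
  expect_lte(f_page$gof$sse, f_newton$gof$sse + 1e-10)
  expect_lte(f_midilli$gof$sse, f_newton$gof$sse + 1e-10)
})

test_that("noiseless self-consistency recovers generating parameters", {
  s <- model_series("newton", c(k = 0.02))
  f <- fit_thinlayer(s, "newton", multistart = 2)
  expect_true(f$converged)
  expect_equal(unname(f$params["k"]), 0.02, tolerance = 1e-8)
  expect_equal(f$gof$r2, 1, tolerance = 1e-12)

  # representative published Midilli rows (full grid in the acceptance suite)
  pp <- default_midilli_params()[c(1, 2, 6), ]
  for (i in seq_len(nrow(pp))) {
    truth <- c(k = pp$k[i], a = pp$a[i], n = pp$n[i], b = pp$b[i])
    s <- model_series("midilli", truth)
    f <- fit_thinlayer(s, "midilli", seed = 1)
    expect_true(f$converged)
    expect_lt(max(rel_err(f$params[names(truth)], truth)), 1e-4)
  }
})

test_that("noisy Midilli recovery lands within Monte-Carlo dispersion", {
  truth <- c(k = 0.008, a = 0.999, n = 1.058, b = 0.00004)
  # brute-force replicate study fixes the sampling SD of each estimate
  reps <- t(vapply(1:200, function(r) {
    s <- noisy_midilli_series(truth, seed = 1000 + r)
    fit_thinlayer(s, "midilli", multistart = 2, seed = r)$params
  }, numeric(4)))
  sds <- apply(reps, 2, sd)
  f <- fit_thinlayer(noisy_midilli_series(truth, seed = 42), "midilli",
                     seed = 42)
  expect_true(all(abs(f$params - truth) <= 3 * sds))
})

test_that("Thompson inverse-space fit recovers its generating curve", {
  a <- -95; b <- -12
  u <- seq(0, -3, length.out = 30)       # ln MR grid
  tt <- a * u + b * u^2                  # strictly increasing times
  cnd <- demo_condition()
  s <- mr_series(tt, exp(u), cnd)
  f <- fit_thinlayer(s, "thomson")
  expect_true(f$converged)
  expect_equal(unname(f$params), c(a, b), tolerance = 1e-8)
  expect_equal(predict(f), exp(u), tolerance = 1e-8)
})

test_that("fit_all ranks by chi2 and keeps single-exponential models exact
           on exponential data", {
  tt <- seq(0, 400, by = 10)
  s <- mr_series(tt, exp(-0.012 * tt), demo_condition())
  scr <- fit_thinlayer_all(s, multistart = 3, seed = 1)
  tab <- scr$table
  for (mn in c("newton", "page", "henderson_pabis"))
    expect_lt(tab$chi2[tab$model == mn], 1e-20)
  expect_equal(nrow(tab), 11L)
  expect_true(!is.unsorted(tab$chi2[tab$converged]))
})

test_that("ranking is stable across fitting seeds on a noisy series", {
  s <- noisy_midilli_series(c(k = 0.015, a = 1.005, n = 0.991,
                              b = 0.00019),
                            times = seq(0, 500, length.out = 60),
                            seed = 77)
  winners <- vapply(1:3, function(sd)
    fit_thinlayer_all(s, multistart = 8, seed = sd)$ranking[1],
    character(1))
  expect_equal(length(unique(winners)), 1L)
})

test_that("thinlayer_fit methods are coherent", {
  truth <- c(k = 0.01, a = 1, n = 1.05, b = 1e-4)
  s <- model_series("midilli", truth)
  f <- fit_thinlayer(s, "midilli", seed = 1)
  expect_equal(coef(f), f$params)
  expect_equal(fitted(f) + residuals(f), s$mr, tolerance = 1e-12)
  expect_equal(predict(f, newdata = s$times), fitted(f))
  expect_output(print(f), "midilli")
  expect_output(print(summary(f)), "Fit statistics")
  sims <- simulate(f, nsim = 3, seed = 1, noise_sd = 0.005)
  expect_equal(dim(sims), c(f$n_obs, 3L))
  expect_false(identical(sims$sim_1, sims$sim_2))
  expect_error(fit_thinlayer(mr_series(0:3, exp(-0.1 * (0:3)),
                                       demo_condition()), "midilli"),
               "only 4 points")
})
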