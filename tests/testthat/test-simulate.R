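test_that("noiseless simulation reproduces the forward model exactly", {
  spec <- simulation_spec(noise_sd = 0)
  id <- spec$params$condition_id[1]
  s <- simulate_curve(spec, id, as = "mr")
  truth <- evaluate_model("midilli",
                          c(k = 0.008, a = 0.999, n = 1.058, b = 0.00004),
                          s$times)
  expect_equal(s$mr, truth, tolerance = 1e-14)

  # mass representation stores the same trajectory in grams
  cv <- simulate_curve(spec, id, as = "mass")
  dry <- 500 * (1 - 0.858)
  expect_equal(cv$values, dry * (1 + truth * wb_to_db(0.858)),
               tolerance = 1e-12)
})

test_that("simulation is deterministic in the seed", {
  spec <- simulation_spec(seed = 4)
  id <- spec$params$condition_id[3]
  s1 <- simulate_curve(spec, id)
  s2 <- simulate_curve(spec, id)
  expect_identical(s1$mr, s2$mr)
  s3 <- simulate_curve(spec, id, seed = 5)
  expect_false(identical(s1$mr, s3$mr))
  expect_error(simulate_curve(spec, "not_a_condition"), "not in the")
})

test_that("noise magnitude matches the specification", {
  spec <- simulation_spec(noise_sd = 0.005, dt = 0.05, horizon = 500,
                          seed = 8)
  id <- spec$params$condition_id[1]
  noisy <- simulate_curve(spec, id, as = "mr")
  clean <- evaluate_model("midilli",
                          c(k = 0.008, a = 0.999, n = 1.058, b = 0.00004),
                          noisy$times)
  diffs <- noisy$mr - clean
  # exclude the truncation region to measure the Gaussian core
  core <- clean > 0.05
  expect_gt(sum(core), 5000)
  expect_lt(abs(sd(diffs[core]) / 0.005 - 1), 0.03)
  expect_true(all(noisy$mr > 0))
})

test_that("experiment bundles have one curve per grid cell", {
  b <- simulate_experiment(simulation_spec(seed = 2, dt = 50))
  expect_length(b$curves, 9L)
  expect_setequal(names(b$curves), b$conditions$condition_id)

  bf <- simulate_experiment(simulation_spec(mode = "fick", seed = 2,
                                            dt = 50))
  expect_length(bf$curves, 11L)
  expect_true(any(grepl("Th8", names(bf$curves))))
})

test_that("synthetic quality tables live in their design ranges", {
  b <- simulate_experiment(simulation_spec(seed = 13, dt = 50))
  q <- b$quality
  expect_true(all(q$sr >= 0.16 - 1e-9 & q$sr <= 0.25 + 1e-9))
  expect_true(all(q$rr >= 3.5 - 1e-9 & q$rr <= 5.1 + 1e-9))
  expect_true(all(q$aw < 0.6))
  expect_identical(unique(q$aw_class), "shelf_stable")
  # quality rows are reproducible from the stored records
  id <- q$condition_id[4]
  expect_equal(q$delta_e[4],
               delta_e(b$colors[[id]], b$fresh_color), tolerance = 1e-12)
  expect_equal(q$sr[4],
               shrinkage_ratio(b$volume_mass[[id]]$volume_fresh,
                               b$volume_mass[[id]]$volume_dried),
               tolerance = 1e-12)
})

test_that("Fickian-mode bundles invert to the generating diffusivities", {
  spec <- simulation_spec(mode = "fick", noise_sd = 0, dt = 10,
                          horizon = 400)
  for (i in c(1, 9, 11)) {
    id <- spec$params$condition_id[i]
    s <- simulate_curve(spec, id, as = "mr")
    d <- estimate_deff(s)
    expect_lt(rel_err(d$deff, spec$params$deff[i]), 0.02)
  }
})

test_that("the full pipeline is deterministic from one seed", {
  spec <- simulation_spec(seed = 21, dt = 25)
  b1 <- simulate_experiment(spec)
  b2 <- simulate_experiment(spec)
  r1 <- run_pipeline(b1$curves[1:3], quality = b1$quality, seed = 21)
  r2 <- run_pipeline(b2$curves[1:3], quality = b2$quality, seed = 21)
  expect_equal(r1$report$value, r2$report$value, tolerance = 1e-15)
  expect_identical(r1$best$model, r2$best$model)
})

test_that("drying_time_to solves the forward model and flags unreachable
           targets", {
  # pure exponential: closed form inverse
  expect_equal(drying_time_to("newton", c(k = 0.01), target_mr = 0.5),
               log(2) / 0.01, tolerance = 1e-6)
  # a linear-tail parameter set that never reaches a deep target
  expect_true(is.na(drying_time_to(
    "midilli", c(k = 0.008, a = 0.999, n = 1.058, b = 0.004),
    target_mr = 0.0106, t_max = 500)))
})
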