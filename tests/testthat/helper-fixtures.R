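# shared fixture builders: everything is generated in code, no data files

demo_condition <- function(id = "demo", power = 1500, airflow = 0.3,
                           thickness = 4, temperature = NA_real_) {
  condition(id, power, airflow, thickness, temperature = temperature)
}

# noiseless series from a registered model
model_series <- function(model, params, times = seq(0, 500, length.out = 100),
                         cnd = demo_condition()) {
  mr_series(times, evaluate_model(model, params, times), cnd)
}

# noisy Midilli series used across fitting tests
noisy_midilli_series <- function(truth, noise_sd = 0.005, seed = 42,
                                 times = seq(0, 500, length.out = 50),
                                 cnd = demo_condition()) {
  set.seed(seed)
  mr <- evaluate_model("midilli", truth, times)
  mr_series(times, pmax(mr + rnorm(length(mr), 0, noise_sd), 1e-4), cnd)
}

rel_err <- function(est, truth) {
  abs(est - truth) / pmax(abs(truth), 1e-12)
}
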