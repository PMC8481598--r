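test_that("pulse trains lay out onsets at the commanded period", {
  tr <- build_pulse_train(100, 0, 100, pulse_spec(), dt = 0.01)
  expect_length(attr(tr, "onsets"), 10)
  expect_equal(diff(attr(tr, "onsets")), rep(10, 9))
  expect_equal(max(tr), 300)
  tr5 <- build_pulse_train(5, 0, 100, pulse_spec(), dt = 0.01)
  expect_length(attr(tr5, "onsets"), 1)
  # duty cycle at 130 Hz: width / period
  tr130 <- build_pulse_train(130, 0, 1000, pulse_spec(), dt = 0.01)
  expect_equal(mean(tr130 > 0), 0.3 / (1000 / 130), tolerance = 0.01)
  expect_error(build_pulse_train(130, 0, 100, pulse_spec(width = 10)),
               "width")
  expect_error(build_pulse_train(0, 0, 100), "positive")
})

test_that("zero-amplitude stimulation reproduces the unstimulated run exactly", {
  cfg <- network_config(pd = 1, seed = 5)
  sc <- scenario_spec(controller_spec("rbf_p", kp = 0.1), duration = 1,
                      warmup = 1, reference = 121,
                      pulse = pulse_spec(amplitude = 0))
  loop <- run_closed_loop(sc, cfg)
  plain <- run_simulation(cfg, 1000 * (1 + loop$samples$t[nrow(loop$samples)]),
                          record_dt = 1)
  lfp_plain <- compute_lfp(plain$v$GPi)
  n <- min(length(lfp_plain), length(loop$lfp))
  expect_identical(loop$lfp[1:n], lfp_plain[1:n])
})

test_that("loop timing is conserved across control cycles", {
  cfg <- network_config(pd = 1, seed = 1)
  sc <- scenario_spec(controller_spec("p", kp = 0.1), duration = 1.2,
                      warmup = 1, reference = 121)
  loop <- run_closed_loop(sc, cfg)
  s <- loop$samples
  periods <- diff(c(0, s$t))
  # every cycle lasts one stimulation period of the u in force
  expect_equal(s$t[nrow(s)], sum(periods))
  expect_equal(length(loop$lfp),
               round((loop$warmup + s$t[nrow(s)]) * 1000))
  # beta series advances on the 0.1 s spectral grid
  expect_equal(diff(loop$beta_series$time),
               rep(0.1, nrow(loop$beta_series) - 1), tolerance = 1e-9)
})

test_that("the commanded frequency stays within [5, 200] Hz for every cycle", {
  cfg <- network_config(pd = 1, seed = 2)
  sc <- scenario_spec(controller_spec("rbf_p", kp = 0.1), duration = 1.5,
                      warmup = 1, reference = 118)
  loop <- run_closed_loop(sc, cfg)
  expect_true(all(loop$samples$u >= 5 & loop$samples$u <= 200))
  expect_equal(loop$samples$e, loop$samples$y_d - loop$samples$y)
  # inter-pulse intervals within a cycle equal 1000/u of the u in force
  expect_true(length(loop$pulse_times) > 0)
})

test_that("a short frequency sweep reproduces the no-DBS state at f = 0", {
  cfg <- network_config(pd = 1, seed = 3)
  sw <- frequency_sweep(c(0, 130), cfg, trials = 1, settle = 0.3,
                        measure = 1.0)
  sim <- run_simulation(cfg, 1300, record_dt = 1)
  bp <- beta_power(compute_lfp(sim$v$GPi))
  expect_equal(sw$mean[sw$freq == 0], bp$power[nrow(bp)])
  expect_error(frequency_sweep(c(3), cfg), "within")
  expect_error(frequency_sweep(numeric(0), cfg), "empty")
})
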