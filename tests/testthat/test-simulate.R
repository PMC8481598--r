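test_that("simulation output shapes match the time grid", {
  cfg <- quiet_config()
  sim <- run_simulation(cfg, 20, record_dt = 1)
  expect_equal(length(sim$time), 20)
  expect_equal(dim(sim$v$GPi), c(10, 20))
  expect_named(sim$v, c("eCTX", "iCTX", "dSTR", "idSTR", "STN", "GPe",
                        "GPi", "TH"))
  expect_error(run_simulation(cfg, 0), "duration")
  expect_error(run_simulation(cfg, 100, stimulus = numeric(10)),
               "full time grid")
})

test_that("identical seeds give bit-identical simulations", {
  cfg <- network_config(pd = 1, seed = 7)
  s1 <- run_simulation(cfg, 300, record_dt = 1)
  s2 <- run_simulation(cfg, 300, record_dt = 1)
  expect_identical(s1$v, s2$v)
  expect_identical(s1$spikes, s2$spikes)
  s3 <- run_simulation(network_config(pd = 1, seed = 8), 300, record_dt = 1)
  expect_false(identical(s1$v$GPi, s3$v$GPi))
})

test_that("gating variables stay within [0, 1] during network activity", {
  for (s in 1:3) {
    cfg <- network_config(pd = s %% 2, seed = s)
    state <- cbgtloop:::.state_init(cfg)
    out <- cbgtloop:::.run_segment(state, cfg, n_steps = 20000,
                                   record_stride = 100)
    for (g in out$state$gates) {
      if (!length(g)) next
      expect_true(all(g >= 0 & g <= 1))
    }
  }
})

test_that("zero synaptic conductance decouples the network", {
  cfg <- zero_conductance(quiet_config(pd = 1, seed = 2))
  full <- run_simulation(cfg, 300, record_dt = 1)
  # same populations integrated without any synapse machinery at all
  iso <- cfg
  iso$synapses <- lapply(iso$synapses, function(s) {
    s$wiring <- s$wiring[0, , drop = FALSE]
    s
  })
  alone <- run_simulation(iso, 300, record_dt = 1)
  expect_identical(full$v, alone$v)
  expect_identical(full$spikes, alone$spikes)
})

test_that("halving dt leaves isolated-population traces essentially unchanged", {
  cfg <- zero_conductance(quiet_config(pd = 1, seed = 1, dt = 0.01))
  cfg5 <- cfg
  cfg5$dt <- 0.005
  a <- run_simulation(cfg, 200, record_dt = 1)
  b <- run_simulation(cfg5, 200, record_dt = 1)
  for (p in names(a$v))
    expect_lt(sqrt(mean((a$v[[p]] - b$v[[p]])^2)), 0.5)
})

test_that("halving dt changes coupled-network traces within the stated bound", {
  # coupling quantizes synaptic event delivery to the step, so spike-phase
  # shifts dominate; the stated tolerance is an RMS of 8 mV over 200 ms
  cfg <- quiet_config(pd = 1, seed = 1, dt = 0.01)
  cfg5 <- cfg
  cfg5$dt <- 0.005
  a <- run_simulation(cfg, 200, record_dt = 1)
  b <- run_simulation(cfg5, 200, record_dt = 1)
  for (p in names(a$v))
    expect_lt(sqrt(mean((a$v[[p]] - b$v[[p]])^2)), 8)
})

test_that("each isolated cell type matches an independent ODE solution", {
  skip_if_not_installed("deSolve")
  cfg <- zero_conductance(quiet_config(pd = 0.5, seed = 3))
  sim <- run_simulation(cfg, 50, record_dt = 0.1)
  biases <- list(STN = 0, GPe = 2, GPi = 3, TH = 0.7, dSTR = 0)
  pops <- c("eCTX", "iCTX", "dSTR", "idSTR", "STN", "GPe", "GPi", "TH")
  v0s <- cbgtloop:::.with_seed(cfg$seed, {
    x <- lapply(pops, function(p) stats::runif(cfg$n, -60, -50))
    stats::setNames(x, pops)
  })
  for (nuc in c("STN", "GPe", "TH", "dSTR")) {
    model <- neuron_model(nuc, gm = cfg$gm_str)
    dyn <- Filter(function(g) g$form != "instantaneous", model$gates)
    v0 <- v0s[[nuc]][1]
    y0 <- c(v = v0, vapply(dyn, function(g) steady_state_gate(v0, g),
                           numeric(1)))
    if (model$has_calcium) y0 <- c(y0, CA = 0.1)
    rhs <- function(t, y, parms) {
      st <- list(v = y[[1]],
                 gates = stats::setNames(as.list(y[2:(1 + length(dyn))]),
                                         names(dyn)))
      if (model$has_calcium) st$CA <- y[[length(y)]]
      I <- ionic_currents(st, model)
      dv <- (-sum(I) + biases[[nuc]]) / model$capacitance
      dg <- vapply(names(dyn), function(nm)
        gate_derivative(st$gates[[nm]], st$v, dyn[[nm]]), numeric(1))
      out <- c(dv, dg)
      if (model$has_calcium)
        out <- c(out, 1e-4 * (-I[, "Ca"] - I[, "T"] - 15 * st$CA))
      list(out)
    }
    sol <- deSolve::ode(y0, seq(0, 50, by = 0.1), rhs, NULL,
                        method = "lsoda", rtol = 1e-8, atol = 1e-8)
    err <- sqrt(mean((sol[-1, "v"] - sim$v[[nuc]][1, ])^2))
    expect_lt(err, 0.2)
  }
})

test_that("stimulation current reaches only the GPi", {
  cfg <- zero_conductance(quiet_config(pd = 0, seed = 4))
  sti <- build_pulse_train(100, 0, 200, pulse_spec(), dt = cfg$dt)
  base <- run_simulation(cfg, 200, record_dt = 1)
  stim <- run_simulation(cfg, 200, stimulus = sti, record_dt = 1)
  expect_false(identical(base$v$GPi, stim$v$GPi))
  for (p in setdiff(names(base$v), "GPi"))
    expect_identical(base$v[[p]], stim$v[[p]])
})
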