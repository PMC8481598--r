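# Shared fixtures. Expensive simulations used by several acceptance tests
# are computed once per test run and memoized here.

# deterministic, noise-free, homogeneous network (for oracle comparisons)
quiet_config <- function(pd = 0, seed = 1, dt = 0.01) {
  network_config(pd = pd, seed = seed, dt = dt,
                 noise_sd = list(eCTX = 0, iCTX = 0),
                 bias_spread = list(eCTX = 0, iCTX = 0, STN = 0, GPe = 0,
                                    GPi = 0, TH = 0, dSTR = 0, idSTR = 0))
}

zero_conductance <- function(config) {
  for (nm in names(config$synapses)) config$synapses[[nm]]$g <- 0
  config
}

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  hit <- .run_cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- force(expr)
  .run_cache[[key]] <- val
  val
}

# healthy/parkinsonian characterization runs (5 s, seeds 1:3), shared by the
# pathophysiology-direction tests
characterization_runs <- function() {
  cached("characterization", {
    out <- list()
    for (pd in c(0, 1)) {
      for (s in 1:3) {
        cfg <- network_config(pd = pd, seed = s)
        sim <- run_simulation(cfg, 5000, record_dt = 1)
        out[[paste0("pd", pd, "_s", s)]] <- list(
          rates = vapply(names(sim$v), function(p)
            firing_rate(sim$spikes[[p]], sim$duration)$mean, numeric(1)),
          chi = vapply(names(sim$v), function(p)
            synchrony_chi(sim$v[[p]])$chi, numeric(1)),
          beta = {
            bp <- beta_power(compute_lfp(sim$v$GPi))
            mean(bp$power[bp$time >= 1.5])
          })
      }
    }
    out
  })
}

char_mean <- function(runs, pd, what, nucleus) {
  mean(vapply(1:3, function(s)
    runs[[paste0("pd", pd, "_s", s)]][[what]][[nucleus]], numeric(1)))
}

# controller-comparison closed-loop runs (6 s control, seeds 1:3), shared by
# the RMSE-ordering and settling-time tests
controller_runs <- function() {
  cached("controllers", {
    out <- list()
    for (s in 1:3) {
      cfg <- network_config(pd = 1, seed = s)
      modes <- list(open = controller_spec("open", u_open = 130),
                    p = controller_spec("p", kp = 0.1),
                    pi = controller_spec("pi", kp = 0.5, ki = 0.5),
                    rbf = controller_spec("rbf_p", kp = 0.1))
      for (nm in names(modes)) {
        sc <- scenario_spec(modes[[nm]], duration = 6, warmup = 1)
        out[[paste(nm, s)]] <- run_closed_loop(sc, cfg)
      }
    }
    out
  })
}
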