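# Driving the compiled network core: initial conditions, state handling,
# and the public single-shot simulation entry point. The closed-loop runner
# reuses the internal segment interface so that controller updates can be
# interleaved with integration without restarting the network.

.POP_INDEX <- stats::setNames(seq_along(.POPS) - 1L, .POPS)

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Per-neuron bias currents with seeded heterogeneity (so that identical
# cells do not lock trivially): bias_i = bias + spread * U(-1, 1), with the
# spread defaulting to 10% of the population bias.
.jittered_bias <- function(config) {
  n <- config$n
  lapply(.POPS, function(p) {
    b <- config$bias[[p]]
    if (is.null(b)) b <- 0
    spread <- config$bias_spread[[p]]
    if (is.null(spread)) spread <- 0.1 * abs(b)
    b + spread * stats::runif(n, -1, 1)
  })
}

# Build the parameter list consumed by the C++ core.
.net_params <- function(config) {
  dt <- config$dt
  conn <- lapply(config$synapses, function(s) {
    list(pre = unname(.POP_INDEX[[s$source]]),
         post = unname(.POP_INDEX[[s$target]]),
         g = s$g, E = s$E, tau = s$tau,
         delay_steps = max(1L, as.integer(round(s$delay / dt))),
         wpre = as.integer(s$wiring[, "pre"] - 1L),
         wpost = as.integer(s$wiring[, "post"] - 1L))
  })
  list(n = config$n,
       gm = config$gm_str,
       conn = unname(conn),
       bias = config$.bias_realized,
       noise_sd = unname(unlist(config$noise_sd[.POPS])),
       izh = list(a = c(0.02, 0.1), d = c(8, 2), b = 0.2, reset = -65,
                  peak = 30),
       v_thre = -20, refractory = 1)
}

# Fresh network state: v(0) ~ U(v_range) per neuron, gates at steady state
# for v(0), CA(0) = 0.1, u(0) = 0.2 v(0); synapses quiescent.
.state_init <- function(config) {
  n <- config$n
  .with_seed(config$seed, {
    v0 <- lapply(.POPS, function(p)
      stats::runif(n, config$init$v_range[1], config$init$v_range[2]))
    names(v0) <- .POPS
    gates <- lapply(.POPS, function(p) {
      model <- neuron_model(p, gm = config$gm_str)
      dyn <- Filter(function(g) g$form != "instantaneous", model$gates)
      if (!length(dyn)) return(matrix(0, 0, n))
      m <- do.call(rbind, lapply(dyn, function(g) steady_state_gate(v0[[p]], g)))
      rownames(m) <- names(dyn)
      m
    })
    u0 <- list(0.2 * v0$eCTX, 0.2 * v0$iCTX)
    ca0 <- list(rep(config$init$CA0, n), rep(config$init$CA0, n))
    bias <- .jittered_bias(config)
    syn <- lapply(config$synapses, function(s) {
      list(z = rep(0, n), s = rep(0, n), buf = numeric(0), head = 0L)
    })
    list(v = unname(v0), u = u0, gates = unname(gates), ca = ca0,
         syn = unname(syn),
         last_spike = rep(list(rep(-1e9, n)), length(.POPS)),
         step0 = 0, .bias_realized = bias)
  })
}

# One integration segment. `state` carries `.bias_realized` so heterogeneity
# survives across segments. Returns list(state, t, v, spikes).
.run_segment <- function(state, config, n_steps, i_sti = numeric(0),
                         record_stride = 0L) {
  net <- .net_params(modifyList(config, list(.bias_realized = state$.bias_realized),
                                keep.null = TRUE))
  bias <- state$.bias_realized
  core_state <- state[c("v", "u", "gates", "ca", "syn", "last_spike", "step0")]
  out <- .cbgt_sim_cpp(core_state, net, as.integer(n_steps), config$dt,
                       as.numeric(i_sti), as.integer(record_stride),
                       as.integer(config$seed))
  out$state$.bias_realized <- bias
  out
}

#' Simulate the network
#'
#' Runs the full cortex-basal ganglia-thalamus network for \code{duration}
#' ms with fixed-step RK4 integration at \code{config$dt}, honoring synaptic
#' transmission delays. An optional stimulation current is injected into
#' every GPi neuron (and only there). Given the same configuration (including
#' the seed), repeated runs are bit-identical.
#'
#' Spikes are detected on-line: an upward crossing of -20 mV with a 1 ms
#' refractory lockout for the HH-type nuclei, and the 30 mV peak-reset rule
#' for the Izhikevich cortical cells.
#'
#' @param config a \code{\link{network_config}}.
#' @param duration simulated time, ms (> 0).
#' @param stimulus optional numeric vector of GPi stimulation current
#'   (uA/cm^2) sampled on the integration grid, length >=
#'   \code{round(duration/dt)}; see \code{\link{build_pulse_train}}.
#' @param record_dt sampling interval of the returned voltage traces, ms.
#' @return an object of class \code{"cbgt_sim"}: list with \code{time} (ms),
#'   \code{v} (named list of neuron x time matrices, mV), \code{spikes}
#'   (named list of per-neuron spike-time vectors, ms), \code{duration} and
#'   the \code{config} used.
#' @export
run_simulation <- function(config, duration, stimulus = NULL,
                           record_dt = 1) {
  stopifnot(inherits(config, "cbgt_config"))
  validate_config(config)
  if (!is.numeric(duration) || duration <= 0)
    stop("duration must be positive")
  n_steps <- as.integer(round(duration / config$dt))
  if (n_steps < 1) stop("duration shorter than one integration step")
  if (!is.null(stimulus) && length(stimulus) < n_steps)
    stop("stimulus must be defined on the full time grid (",
         n_steps, " steps)")
  record_stride <- max(1L, as.integer(round(record_dt / config$dt)))
  state <- .state_init(config)
  out <- .run_segment(state, config, n_steps,
                      i_sti = if (is.null(stimulus)) numeric(0) else stimulus,
                      record_stride = record_stride)
  structure(list(
    time = out$t,
    v = stats::setNames(out$v, .POPS),
    spikes = stats::setNames(lapply(out$spikes, identity), .POPS),
    duration = n_steps * config$dt,
    record_dt = record_stride * config$dt,
    config = config
  ), class = "cbgt_sim")
}

#' @export
print.cbgt_sim <- function(x, ...) {
  cat("<cbgt_sim> ", x$duration, " ms, pd = ", x$config$pd,
      ", recorded every ", x$record_dt, " ms\n", sep = "")
  rates <- vapply(.POPS, function(p)
    mean(lengths(x$spikes[[p]])) / (x$duration / 1000), numeric(1))
  cat("  mean rates (Hz):",
      paste(sprintf("%s %.1f", .POPS, rates), collapse = ", "), "\n")
  invisible(x)
}

#' Write simulation voltages as columnar CSV
#'
#' One \code{time} column (ms) plus one column per neuron with
#' nucleus-prefixed headers (\code{GPi_3}, ...). A JSON sidecar echoing the
#' resolved configuration is written next to it.
#'
#' @param sim a \code{"cbgt_sim"} result.
#' @param path CSV output path.
#' @return invisibly the CSV path.
#' @export
write_sim_csv <- function(sim, path) {
  stopifnot(inherits(sim, "cbgt_sim"))
  cols <- do.call(cbind, lapply(.POPS, function(p) t(sim$v[[p]])))
  colnames(cols) <- unlist(lapply(.POPS, function(p)
    paste0(p, "_", seq_len(nrow(sim$v[[p]])))))
  df <- data.frame(time = sim$time, cols, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  cfg <- sim$config
  cfg$synapses <- lapply(cfg$synapses, function(s) {
    s$wiring <- NULL
    s
  })
  jsonlite::write_json(unclass(cfg), paste0(sub("\\.csv$", "", path),
                                            "_config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(path)
}
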