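# Closing the loop: DBS pulse-train construction, the measure -> control ->
# stimulate cycle, the self-calibrated healthy reference, and the
# stimulation-frequency sweep.

#' DBS pulse specification
#'
#' Monophasic rectangular current pulses delivered intracellularly to every
#' GPi neuron: amplitude 300 uA/cm^2, width 0.3 ms.
#'
#' @param amplitude pulse amplitude, uA/cm^2.
#' @param width pulse duration, ms.
#' @return object of class \code{"pulse_spec"}.
#' @export
pulse_spec <- function(amplitude = 300, width = 0.3) {
  if (amplitude < 0) stop("pulse amplitude must be >= 0")
  if (width <= 0) stop("pulse width must be positive")
  structure(list(amplitude = amplitude, width = width),
            class = "pulse_spec")
}

#' Build a constant-frequency DBS pulse train
#'
#' Rectangular monophasic pulses at onsets \code{t_start},
#' \code{t_start + 1000/u}, ... strictly below \code{t_end}, sampled on the
#' integration grid (period 1000/u ms for a commanded frequency of u Hz).
#'
#' @param u pulse repetition frequency, Hz (> 0).
#' @param t_start,t_end segment limits, ms.
#' @param spec a \code{\link{pulse_spec}}.
#' @param dt integration step, ms.
#' @return numeric vector of stimulation current over
#'   \code{[t_start, t_end)}, with attribute \code{"onsets"} (ms).
#' @export
build_pulse_train <- function(u, t_start, t_end, spec = pulse_spec(),
                              dt = 0.01) {
  stopifnot(inherits(spec, "pulse_spec"))
  if (u <= 0) stop("pulse frequency must be positive")
  period <- 1000 / u
  if (spec$width >= period)
    stop("pulse width must be shorter than the pulse period")
  n <- as.integer(round((t_end - t_start) / dt))
  out <- numeric(n)
  k <- floor((t_end - t_start) / period - 1e-9)
  onsets <- t_start + period * (0:max(0, k))
  onsets <- onsets[onsets < t_end - 1e-9]
  wsteps <- max(1L, as.integer(round(spec$width / dt)))
  for (on in onsets) {
    i0 <- as.integer(round((on - t_start) / dt)) + 1L
    i1 <- min(n, i0 + wsteps - 1L)
    if (i0 <= n) out[i0:i1] <- spec$amplitude
  }
  attr(out, "onsets") <- onsets
  out
}

#' Measure the healthy-state beta-power reference
#'
#' Simulates the same network build at pd = 0 and returns the mean
#' beta-band power of the GPi LFP over the stationary part of the run; this
#' self-calibrated value serves as the default control target.
#'
#' @param config a \code{\link{network_config}} (its pd is ignored).
#' @param duration simulated time, s.
#' @param discard initial transient excluded from the average, s (window
#'   ends before \code{discard + window_length} are dropped).
#' @param cfg a \code{\link{spectral_config}}.
#' @return mean healthy beta power, dB.
#' @export
healthy_beta_reference <- function(config, duration = 2.5, discard = 0.5,
                                   cfg = spectral_config()) {
  healthy <- apply_parkinsonism(config, 0)
  sim <- run_simulation(healthy, duration * 1000, record_dt = 1)
  lfp <- compute_lfp(sim$v$GPi)
  bp <- beta_power(lfp, cfg)
  mean(bp$power[bp$time >= discard + cfg$window_length])
}

#' Closed-loop scenario
#'
#' @param controller a \code{\link{controller_spec}}.
#' @param duration controlled time after the warm-up, s.
#' @param warmup unstimulated warm-up, s (>= the spectral window so the
#'   first beta estimate is available at control onset).
#' @param pd parkinsonism schedule: a constant in [0, 1], a function of
#'   time (s, from run start) returning pd, or \code{"random"} for a
#'   seeded piecewise-constant schedule with uniform [0, 1] draws every
#'   \code{pd_dwell} seconds.
#' @param reference target beta power: \code{"self"} (measured healthy-state
#'   power of the same network build), a fixed dB value, a function of time
#'   (s, from control onset), or \code{"square"} (1 Hz square wave
#'   alternating between the healthy level and healthy + 4 dB, the
#'   parkinsonian excess of this plant).
#' @param pulse a \code{\link{pulse_spec}}.
#' @param pd_dwell dwell time of the random pd schedule, s.
#' @param cadence control update cadence used when no stimulation period is
#'   defined (modes "none"/"open" still log at this cadence), s.
#' @param spectral a \code{\link{spectral_config}}.
#' @return object of class \code{"scenario_spec"}.
#' @export
scenario_spec <- function(controller = controller_spec("rbf_p"),
                          duration = 6, warmup = 1, pd = 1,
                          reference = "self", pulse = pulse_spec(),
                          pd_dwell = 1, cadence = 0.1,
                          spectral = spectral_config()) {
  if (warmup < spectral$window_length)
    stop("warmup must cover at least one spectral window")
  if (duration <= 0) stop("duration must be positive")
  structure(list(controller = controller, duration = duration,
                 warmup = warmup, pd = pd, reference = reference,
                 pulse = pulse, pd_dwell = pd_dwell, cadence = cadence,
                 spectral = spectral),
            class = "scenario_spec")
}

.pd_schedule <- function(scenario, config) {
  if (is.function(scenario$pd)) return(scenario$pd)
  if (identical(scenario$pd, "random")) {
    n_dwell <- ceiling((scenario$warmup + scenario$duration) /
                         scenario$pd_dwell) + 1
    draws <- .with_seed(config$seed + 211L, stats::runif(n_dwell))
    dwell <- scenario$pd_dwell
    return(function(t) draws[pmin(length(draws), floor(t / dwell) + 1)])
  }
  pd0 <- scenario$pd
  function(t) rep(pd0, length(t))
}

.reference_schedule <- function(scenario, config) {
  ref <- scenario$reference
  if (is.function(ref)) return(ref)
  if (is.numeric(ref)) return(function(t) rep(ref, length(t)))
  base <- healthy_beta_reference(config, cfg = scenario$spectral)
  if (identical(ref, "self")) return(function(t) rep(base, length(t)))
  if (identical(ref, "square")) {
    # 1 Hz square wave between the healthy level and the parkinsonian
    # excess of this plant (~4 dB), i.e. the reachable dynamic range
    return(function(t) base + 4 * (floor(t / 0.5) %% 2))
  }
  stop("unknown reference specification")
}

#' Run the closed control loop
#'
#' Couples the network plant with a controller. After an unstimulated
#' warm-up, the loop alternates: simulate one stimulation period with the
#' commanded pulse train, append the GPi voltages to the rolling LFP buffer
#' (1 kHz), recompute the beta power of the trailing 1 s window, and take
#' one controller step to obtain the next pulse frequency. The parkinsonism
#' level and the reference are re-read from their schedules at every cycle.
#' The initial commanded frequency is 5 Hz.
#'
#' @param scenario a \code{\link{scenario_spec}}.
#' @param config a \code{\link{network_config}}; its pd is overridden by the
#'   scenario schedule.
#' @return object of class \code{"cbgt_loop"}: \code{samples} (per-cycle
#'   log: t in s since control onset, y, y_d, e, u_p, u_rbf, u, pd),
#'   \code{beta_series} (0.1 s grid over the whole run, times from run
#'   start), \code{lfp} and \code{lfp_time}, \code{pulse_times} (ms),
#'   \code{weights} (cycle x hidden-node RBF weight log, if applicable),
#'   \code{reference}, \code{rmse_last_window}, \code{warmup}, and the
#'   final \code{controller} and \code{config}.
#' @export
run_closed_loop <- function(scenario, config) {
  stopifnot(inherits(scenario, "scenario_spec"),
            inherits(config, "cbgt_config"))
  sp <- scenario$spectral
  dt <- config$dt
  stride <- max(1L, as.integer(round(1000 / sp$sample_rate / dt)))
  pd_at <- .pd_schedule(scenario, config)
  ref_at <- .reference_schedule(scenario, config)
  ctrl <- scenario$controller

  config <- apply_parkinsonism(config, pd_at(0))
  validate_config(config)
  state <- .state_init(config)

  # warm-up (no stimulation)
  warm_steps <- as.integer(round(scenario$warmup * 1000 / dt))
  seg <- .run_segment(state, config, warm_steps, record_stride = stride)
  state <- seg$state
  lfp <- compute_lfp(seg$v[[.POP_INDEX[["GPi"]] + 1L]])
  nwin <- round(sp$window_length * sp$sample_rate)

  u <- if (ctrl$mode == "open") clamp_command(ctrl$u_open) else U_MIN
  t_ctrl <- 0
  samples <- list()
  weights <- list()
  pulse_times <- numeric(0)
  cycle <- 0L
  while (t_ctrl < scenario$duration - 1e-9) {
    cycle <- cycle + 1L
    pd_now <- pd_at(scenario$warmup + t_ctrl)
    if (abs(pd_now - config$pd) > 1e-12)
      config <- apply_parkinsonism(config, pd_now)
    period_ms <- if (ctrl$mode %in% c("none", "open") && ctrl$mode == "none")
      scenario$cadence * 1000 else 1000 / u
    n_steps <- max(1L, as.integer(round(period_ms / dt)))
    t0_ms <- (scenario$warmup + t_ctrl) * 1000
    if (ctrl$mode == "none" || scenario$pulse$amplitude == 0) {
      i_sti <- numeric(0)
    } else {
      i_sti <- build_pulse_train(u, t0_ms, t0_ms + n_steps * dt,
                                 spec = scenario$pulse, dt = dt)
      pulse_times <- c(pulse_times, attr(i_sti, "onsets"))
    }
    seg <- .run_segment(state, config, n_steps, i_sti = i_sti,
                        record_stride = stride)
    state <- seg$state
    lfp <- c(lfp, compute_lfp(seg$v[[.POP_INDEX[["GPi"]] + 1L]]))
    t_ctrl <- t_ctrl + n_steps * dt / 1000

    buf <- utils::tail(lfp, nwin)
    y <- beta_power(buf, sp)$power[1]
    y_d <- ref_at(t_ctrl)
    step <- supervisory_step(y, y_d, n_steps * dt / 1000, ctrl)
    ctrl <- step$ctrl
    samp <- step$sample
    samp$t <- t_ctrl
    samp$pd <- pd_now
    samples[[cycle]] <- samp
    if (!is.null(ctrl$rbf)) weights[[cycle]] <- ctrl$rbf$w
    u <- if (ctrl$mode == "open") clamp_command(ctrl$u_open) else samp$u
  }

  samples <- do.call(rbind, samples)
  samples <- samples[, c("t", "y", "y_d", "e", "u_p", "u_rbf", "u", "pd")]
  beta_series <- beta_power(lfp, sp)
  lfp_time <- seq_along(lfp) / sp$sample_rate

  total <- scenario$warmup + t_ctrl
  win_lo <- max(total - 4, scenario$warmup + sp$window_length)
  keep <- beta_series$time >= win_lo
  ref_vals <- ref_at(beta_series$time[keep] - scenario$warmup)
  rmse_last <- rmse(beta_series$power[keep], ref_vals)

  structure(list(
    samples = samples,
    beta_series = beta_series,
    lfp = lfp, lfp_time = lfp_time,
    pulse_times = pulse_times,
    weights = if (length(weights)) do.call(rbind, weights) else NULL,
    reference = ref_at,
    rmse_last_window = rmse_last,
    warmup = scenario$warmup,
    controller = ctrl,
    scenario = scenario,
    config = config
  ), class = "cbgt_loop")
}

#' @export
print.cbgt_loop <- function(x, ...) {
  cat("<cbgt_loop> ", nrow(x$samples), " control cycles over ",
      round(max(x$samples$t), 2), " s; final u = ",
      round(utils::tail(x$samples$u, 1), 1), " Hz; RMSE(last window) = ",
      round(x$rmse_last_window, 2), " dB\n", sep = "")
  invisible(x)
}

#' Settling time of a controlled run
#'
#' Time from control onset until the sliding-window beta power first enters
#' and thereafter stays within a relative band around the reference.
#'
#' @param loop a \code{"cbgt_loop"}.
#' @param band_frac half-width of the acceptance band as a fraction of the
#'   reference (0.1 = +/-10 percent).
#' @return settling time in s, or \code{NA} if the band is never held.
#' @export
settling_time <- function(loop, band_frac = 0.1) {
  bs <- loop$beta_series
  keep <- bs$time >= loop$warmup + 1e-9
  t <- bs$time[keep] - loop$warmup
  y <- bs$power[keep]
  yd <- loop$reference(t)
  ok <- abs(y - yd) <= band_frac * abs(yd)
  if (!any(ok)) return(NA_real_)
  stays <- rev(cumprod(rev(ok))) > 0
  if (!any(stays)) return(NA_real_)
  t[which(stays)[1]]
}

#' Stimulation-frequency sweep
#'
#' Simulates the parkinsonian network under constant-frequency DBS for each
#' requested frequency (0 = no stimulation) and reports the steady-state
#' beta power, aggregated over seeded trials. Frequency 0 uses the identical
#' seed and therefore reproduces the unstimulated parkinsonian run exactly.
#'
#' @param freqs frequencies, Hz (0 or within [5, 200]).
#' @param config a \code{\link{network_config}} (typically pd = 1).
#' @param trials number of seeded trials per frequency.
#' @param settle stimulated time before the measurement window, s.
#' @param measure measurement span, s (windows ending within it are
#'   averaged).
#' @param pulse a \code{\link{pulse_spec}}.
#' @param cfg a \code{\link{spectral_config}}.
#' @return data frame of class \code{"freq_sweep"}: freq, mean, se, and the
#'   per-trial powers in \code{attr(, "trials")}.
#' @export
frequency_sweep <- function(freqs, config, trials = 5, settle = 1,
                            measure = 1.2, pulse = pulse_spec(),
                            cfg = spectral_config()) {
  if (!length(freqs)) stop("empty frequency grid")
  bad <- freqs[freqs != 0 & (freqs < U_MIN | freqs > U_MAX)]
  if (length(bad)) stop("frequencies must be 0 or within [5, 200] Hz")
  dur_ms <- (settle + measure) * 1000
  vals <- matrix(NA_real_, length(freqs), trials)
  for (k in seq_len(trials)) {
    cfg_k <- config
    cfg_k$seed <- config$seed + k - 1L
    for (j in seq_along(freqs)) {
      f <- freqs[j]
      sti <- if (f == 0) NULL else
        build_pulse_train(f, 0, dur_ms, spec = pulse, dt = config$dt)
      sim <- run_simulation(cfg_k, dur_ms, stimulus = sti, record_dt = 1)
      lfp <- compute_lfp(sim$v$GPi)
      bp <- beta_power(lfp, cfg)
      use <- bp$time >= settle + cfg$window_length - 1e-9
      if (!any(use)) use <- seq_len(nrow(bp)) == nrow(bp)
      vals[j, k] <- mean(bp$power[use])
    }
  }
  out <- data.frame(freq = freqs,
                    mean = rowMeans(vals),
                    se = apply(vals, 1, stats::sd) / sqrt(trials))
  attr(out, "trials") <- vals
  class(out) <- c("freq_sweep", "data.frame")
  out
}
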