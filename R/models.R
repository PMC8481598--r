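# Single-neuron model definitions for the six cell types in the network:
# Hodgkin-Huxley type STN, GP (shared by GPe/GPi), TH and STR (shared by
# dSTR/idSTR) neurons, and Izhikevich-type cortical neurons (eCTX/iCTX).
# Membrane capacitance is 1 uF/cm^2 for all HH-type cells; currents are in
# uA/cm^2, conductances in mS/cm^2, voltages in mV, time in ms.

#' Ion-channel specification
#'
#' One ionic current of the form
#' \eqn{I = g_{max} \prod_X X^{p_X} (v - E)}, optionally multiplied by the
#' calcium saturation factor \eqn{CA/(CA+10)} (the GP after-hyperpolarization
#' current) or using the derived potassium activation \eqn{0.75(1-h)} of the
#' thalamic model.
#'
#' @param name channel label.
#' @param g maximal conductance in mS/cm^2 (must be >= 0).
#' @param E reversal potential in mV.
#' @param gates named integer vector: gate name -> exponent.
#' @param ca_dependent multiply by CA/(CA+10).
#' @param k_from_h the gate value is computed as 0.75*(1 - h) (TH potassium).
#' @return an object of class \code{"channel_spec"}.
#' @export
channel_spec <- function(name, g, E, gates = c(), ca_dependent = FALSE,
                         k_from_h = FALSE) {
  if (g < 0) stop("channel conductance must be >= 0")
  if (length(gates) && any(gates < 0)) stop("gate exponents must be >= 0")
  structure(list(name = name, g = g, E = E, gates = gates,
                 ca_dependent = ca_dependent, k_from_h = k_from_h),
            class = "channel_spec")
}

.stn_gates <- function() {
  list(
    m = gating_spec("sigmoid_tau", 1, 40, 8,
                    function(v) 0.2 + 3 / (1 + exp((v + 53) / 0.7))),
    h = gating_spec("sigmoid_tau", 1, 45.5, -6.4,
                    function(v) 24.5 / (exp((v + 50) / 15) + exp((v + 50) / 16))),
    n = gating_spec("sigmoid_tau", 1, 41, 14,
                    function(v) 11 / (exp(-(v + 40) / 14) + exp(-(v + 40) / 50))),
    p = gating_spec("sigmoid_tau", 1, 56, 6.7,
                    function(v) 5 + 0.33 / (exp((v + 27) / 10) + exp(-(v + 102) / 15))),
    q = gating_spec("sigmoid_tau", 1, 85, -5.8,
                    function(v) 400 / (exp((v + 50) / 15) + exp(-(v + 50) / 16))),
    r = gating_spec("sigmoid_tau", 1, -0.17, 0.08, 2),
    a = gating_spec("sigmoid_tau", 1, 45, 14.7,
                    function(v) 1 + 1 / (1 + exp((v + 40) / 0.5))),
    b = gating_spec("sigmoid_tau", 1, 90, -7.5,
                    function(v) 200 / (exp((v + 60) / 30) + exp(-(v + 40) / 10))),
    c = gating_spec("sigmoid_tau", 1, 30.6, 5,
                    function(v) 45 + 10 / (exp((v + 27) / 20) + exp(-(v + 50) / 15))),
    d1 = gating_spec("sigmoid_tau", 1, 60, -7.5,
                     function(v) 400 + 500 / (exp((v + 40) / 15) + exp(-(v + 20) / 20))),
    d2 = gating_spec("sigmoid_tau", 1, -0.1, -0.02, 130)
  )
}

.gp_gates <- function() {
  tau_hn <- function(v) 0.05 + 0.27 / (1 + exp((v + 40) / 12))
  list(
    m = gating_spec("instantaneous", half = 37, slope = 10),
    h = gating_spec("sigmoid_tau", 0.05, 58, -12, tau_hn),
    n = gating_spec("sigmoid_tau", 0.1, 50, 14, tau_hn),
    r = gating_spec("sigmoid_tau", 1, 70, -2, 15),
    a = gating_spec("instantaneous", half = 57, slope = 2),
    s = gating_spec("instantaneous", half = 35, slope = 2)
  )
}

.th_gates <- function() {
  list(
    m = gating_spec("instantaneous", half = 37, slope = 7),
    h = gating_spec("sigmoid_tau", 1, 41, -4,
                    function(v) 1 / (0.128 * exp(-(v + 46) / 18) +
                                       4 / (1 + exp(-(v + 23) / 5)))),
    p = gating_spec("instantaneous", half = 60, slope = 6.2),
    r = gating_spec("sigmoid_tau", 1, 84, -4,
                    function(v) 0.15 * (28 + exp(-(v + 25) / 10.5)))
  )
}

.str_gates <- function() {
  list(
    m = gating_spec("alpha_beta",
                    alpha = function(v) 0.32 * .expm1_rate(v + 54, 4),
                    beta  = function(v) 0.28 * .expm1_rate(-(v + 27), 5)),
    h = gating_spec("alpha_beta",
                    alpha = function(v) 0.128 * exp(-(v + 50) / 18),
                    beta  = function(v) 4 / (1 + exp(-(v + 27) / 5))),
    n = gating_spec("alpha_beta",
                    alpha = function(v) 0.032 * .expm1_rate(v + 52, 5),
                    beta  = function(v) 0.5 * exp(-(v + 57) / 40)),
    p = gating_spec("alpha_beta",
                    alpha = function(v) 3.209e-4 * .expm1_rate(v + 30, 9),
                    beta  = function(v) 3.209e-4 * .expm1_rate(-(v + 30), 9))
  )
}

#' Neuron model specification
#'
#' Returns the full single-neuron model for one nucleus: gating kinetics,
#' ionic channels and (for cortical neurons) Izhikevich parameters. GPe and
#' GPi share the GP equations (distinguished only by their bias currents,
#' which live in the network configuration); dSTR and idSTR share the STR
#' equations.
#'
#' @param nucleus one of \code{"STN"}, \code{"GPe"}, \code{"GPi"},
#'   \code{"TH"}, \code{"dSTR"}, \code{"idSTR"}, \code{"eCTX"},
#'   \code{"iCTX"}.
#' @param gm M-type potassium conductance of the striatal model (mS/cm^2);
#'   depends on the parkinsonism variable via
#'   \code{\link{apply_parkinsonism}}.
#' @return object of class \code{"neuron_model"} with fields
#'   \code{nucleus}, \code{capacitance}, \code{gates}, \code{channels},
#'   \code{has_calcium} and, for cortical neurons, \code{izhikevich}.
#' @export
neuron_model <- function(nucleus = c("STN", "GPe", "GPi", "TH", "dSTR",
                                     "idSTR", "eCTX", "iCTX"),
                         gm = 2.6) {
  nucleus <- match.arg(nucleus)
  base <- switch(nucleus,
    STN = list(
      gates = .stn_gates(),
      channels = list(
        channel_spec("Na", 49, 60, c(m = 3, h = 1)),
        channel_spec("K", 57, -90, c(n = 4)),
        channel_spec("l", 0.35, -60),
        channel_spec("T", 5, 165, c(p = 2, q = 1)),
        channel_spec("CaK", 1, -90, c(r = 2)),
        channel_spec("a", 5, -90, c(a = 2, b = 1)),
        channel_spec("L", 15, 165, c(c = 2, d1 = 1, d2 = 1))
      ),
      has_calcium = FALSE),
    GPe = ,
    GPi = list(
      gates = .gp_gates(),
      channels = list(
        channel_spec("Na", 120, 55, c(m = 3, h = 1)),
        channel_spec("K", 30, -80, c(n = 4)),
        channel_spec("l", 0.1, -65),
        channel_spec("T", 0.5, 0, c(a = 3, r = 1)),
        channel_spec("Ca", 0.15, 120, c(s = 2)),
        channel_spec("AHP", 10, -80, ca_dependent = TRUE)
      ),
      has_calcium = TRUE),
    TH = list(
      gates = .th_gates(),
      channels = list(
        channel_spec("Na", 3, 50, c(m = 3, h = 1)),
        channel_spec("K", 5, -75, k_from_h = TRUE),
        channel_spec("l", 0.05, -70),
        channel_spec("T", 5, 0, c(p = 2, r = 1))
      ),
      has_calcium = FALSE),
    dSTR = ,
    idSTR = list(
      gates = .str_gates(),
      channels = list(
        channel_spec("Na", 100, 50, c(m = 3, h = 1)),
        channel_spec("K", 80, -100, c(n = 4)),
        channel_spec("l", 0.1, -67),
        channel_spec("m", gm, -100, c(p = 1))
      ),
      has_calcium = FALSE),
    eCTX = list(gates = list(), channels = list(), has_calcium = FALSE,
                izhikevich = list(a = 0.02, b = 0.2, reset = -65, d = 8,
                                  peak = 30)),
    iCTX = list(gates = list(), channels = list(), has_calcium = FALSE,
                izhikevich = list(a = 0.1, b = 0.2, reset = -65, d = 2,
                                  peak = 30))
  )
  structure(c(list(nucleus = nucleus, capacitance = 1), base),
            class = "neuron_model")
}

#' Ionic currents of a population state
#'
#' Evaluates every channel of a neuron model at the given per-neuron state.
#' Each current is \eqn{g_{max} \prod X^{p} (v - E)}; instantaneous gates are
#' evaluated at the present voltage; the GP AHP current is additionally
#' scaled by \eqn{CA/(CA+10)}.
#'
#' @param state list with numeric vector \code{v} (mV), named list
#'   \code{gates} of per-neuron gate values, and optionally \code{CA}.
#' @param model a \code{\link{neuron_model}}.
#' @return numeric matrix, neurons x channels, in uA/cm^2.
#' @export
ionic_currents <- function(state, model) {
  stopifnot(inherits(model, "neuron_model"))
  v <- state$v
  out <- matrix(0, length(v), length(model$channels))
  colnames(out) <- vapply(model$channels, `[[`, "", "name")
  for (k in seq_along(model$channels)) {
    ch <- model$channels[[k]]
    drive <- ch$g * (v - ch$E)
    if (ch$k_from_h) {
      h <- state$gates[["h"]]
      if (is.null(h)) stop("missing gate 'h' for derived potassium gate")
      drive <- drive * (0.75 * (1 - h))^4
    }
    if (length(ch$gates)) {
      for (gname in names(ch$gates)) {
        spec <- model$gates[[gname]]
        if (is.null(spec)) stop("unknown gate in channel spec: ", gname)
        val <- if (spec$form == "instantaneous") {
          steady_state_gate(v, spec)
        } else {
          g <- state$gates[[gname]]
          if (is.null(g)) stop("missing gate '", gname, "' in state")
          g
        }
        drive <- drive * val^ch$gates[[gname]]
      }
    }
    if (ch$ca_dependent) {
      ca <- state$CA
      if (is.null(ca)) stop("missing calcium state for CA-dependent channel")
      drive <- drive * ca / (ca + 10)
    }
    out[, k] <- drive
  }
  out
}

#' One integration step of an Izhikevich cortical neuron
#'
#' Integrates \eqn{dv/dt = 0.04 v^2 + 5v + 140 - u - I_{in}} and
#' \eqn{du/dt = a(0.2 v - u)} over \code{dt} ms (RK4), then applies the
#' spike-reset rule: if v exceeds the 30 mV peak, v is set to -65 mV and u is
#' incremented by d.
#'
#' @param v membrane potential, mV.
#' @param u recovery variable.
#' @param input total input current entering with negative sign (synaptic
#'   currents; positive values hyperpolarize, matching the sign convention of
#'   the HH cells' synaptic currents). Bias/noise drive should be passed with
#'   negative sign.
#' @param dt step, ms.
#' @param params list with \code{a} and \code{d} (and optionally \code{b},
#'   \code{reset}, \code{peak}).
#' @return list \code{v}, \code{u}, \code{spiked}.
#' @export
izhikevich_step <- function(v, u, input, dt, params) {
  if (dt <= 0) stop("dt must be positive")
  a <- params$a
  b <- if (is.null(params$b)) 0.2 else params$b
  reset <- if (is.null(params$reset)) -65 else params$reset
  peak <- if (is.null(params$peak)) 30 else params$peak
  f <- function(v, u) c(0.04 * v^2 + 5 * v + 140 - u - input,
                        a * (b * v - u))
  k1 <- f(v, u)
  k2 <- f(v + dt / 2 * k1[1], u + dt / 2 * k1[2])
  k3 <- f(v + dt / 2 * k2[1], u + dt / 2 * k2[2])
  k4 <- f(v + dt * k3[1], u + dt * k3[2])
  vn <- v + dt / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1])
  un <- u + dt / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2])
  spiked <- vn > peak
  if (spiked) {
    vn <- reset
    un <- un + params$d
  }
  list(v = vn, u = un, spiked = spiked)
}

#' Alpha-synapse specification
#'
#' @param g maximal conductance, mS/cm^2.
#' @param E reversal potential, mV.
#' @param delay transmission delay, ms.
#' @param tau kernel time constant, ms (default 5).
#' @return object of class \code{"synapse_spec"}.
#' @export
synapse_spec <- function(g = 1, E = 0, delay = 0, tau = 5) {
  if (g < 0) stop("synaptic conductance must be >= 0")
  if (delay < 0) stop("synaptic delay must be >= 0")
  if (tau <= 0) stop("synaptic time constant must be positive")
  structure(list(g = g, E = E, delay = delay, tau = tau),
            class = "synapse_spec")
}

#' Alpha-synapse drive
#'
#' Sums the delayed alpha kernel
#' \eqn{S(t) = \sum_s \frac{t - t_s - t_d}{\tau} e^{-(t - t_s - t_d)/\tau}}
#' over presynaptic spike times, with zero contribution before a spike's
#' delayed arrival. The synaptic current is then
#' \eqn{g (v_{post} - E_{syn}) S(t)}.
#'
#' @param pre_spikes numeric vector of presynaptic spike times, ms.
#' @param t evaluation time(s), ms.
#' @param spec a \code{\link{synapse_spec}}.
#' @return dimensionless drive S(t), same length as \code{t}.
#' @export
synapse_drive <- function(pre_spikes, t, spec) {
  stopifnot(inherits(spec, "synapse_spec"))
  vapply(t, function(tt) {
    dt <- tt - pre_spikes - spec$delay
    dt <- dt[dt > 0]
    if (!length(dt)) return(0)
    sum(dt / spec$tau * exp(-dt / spec$tau))
  }, numeric(1))
}
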