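#' Gating-variable specification
#'
#' Describes the kinetics of one Hodgkin-Huxley gating variable. Three forms
#' are supported: first-order relaxation to a sigmoid steady state
#' (\code{"sigmoid_tau"}), classical alpha/beta rate kinetics
#' (\code{"alpha_beta"}), and instantaneous gates (\code{"instantaneous"})
#' that are slaved to the sigmoid steady state at the current voltage.
#'
#' For the sigmoid forms the steady state is
#' \deqn{X_\infty(v) = 1 / (1 + \exp(-(v + w_X)/\sigma_X))}
#' with half voltage \eqn{w_X} (mV) and slope \eqn{\sigma_X} (mV), and the
#' dynamics are \eqn{dX/dt = \lambda_X (X_\infty - X)/\tau_X(v)}. For the
#' alpha/beta form the dynamics are
#' \eqn{dX/dt = \alpha_X(v)(1 - X) - \beta_X(v) X}.
#'
#' @param form one of \code{"sigmoid_tau"}, \code{"alpha_beta"},
#'   \code{"instantaneous"}.
#' @param lambda dimensionless rate scale \eqn{\lambda_X} (sigmoid form).
#' @param half half voltage \eqn{w_X} in mV (sigmoid forms).
#' @param slope slope \eqn{\sigma_X} in mV (sigmoid forms); must be nonzero.
#' @param tau voltage-dependent time constant in ms: a function of v, or a
#'   single number for a constant time constant (sigmoid_tau form).
#' @param alpha,beta rate functions of v in 1/ms (alpha_beta form).
#' @return an object of class \code{"gating_spec"}.
#' @export
gating_spec <- function(form = c("sigmoid_tau", "alpha_beta", "instantaneous"),
                        lambda = 1, half = NULL, slope = NULL,
                        tau = NULL, alpha = NULL, beta = NULL) {
  form <- match.arg(form)
  if (form %in% c("sigmoid_tau", "instantaneous")) {
    if (is.null(half) || is.null(slope))
      stop("sigmoid gating requires `half` and `slope`")
    if (slope == 0) stop("gating slope must be nonzero")
  }
  if (form == "sigmoid_tau") {
    if (is.null(tau)) stop("sigmoid_tau gating requires `tau`")
    if (is.numeric(tau)) {
      tau_const <- tau
      tau <- function(v) rep_len(tau_const, length(v))
    }
    if (!is.null(alpha) || !is.null(beta))
      stop("sigmoid_tau gating must not carry alpha/beta rates")
  }
  if (form == "alpha_beta") {
    if (is.null(alpha) || is.null(beta))
      stop("alpha_beta gating requires `alpha` and `beta`")
    if (!is.null(tau)) stop("alpha_beta gating must not carry `tau`")
  }
  structure(list(form = form, lambda = lambda, half = half, slope = slope,
                 tau = tau, alpha = alpha, beta = beta),
            class = "gating_spec")
}

#' Steady-state value of a sigmoid gate
#'
#' Evaluates \eqn{X_\infty(v) = 1/(1 + \exp(-(v + w_X)/\sigma_X))}. For
#' alpha/beta gates the steady state \eqn{\alpha/(\alpha+\beta)} is returned.
#'
#' @param v membrane potential in mV (vectorized).
#' @param spec a \code{\link{gating_spec}}.
#' @return gate steady state in (0, 1).
#' @export
steady_state_gate <- function(v, spec) {
  stopifnot(inherits(spec, "gating_spec"))
  if (spec$form == "alpha_beta") {
    a <- spec$alpha(v); b <- spec$beta(v)
    return(a / (a + b))
  }
  if (is.null(spec$slope) || spec$slope == 0) stop("invalid gating spec: zero slope")
  stats::plogis((v + spec$half) / spec$slope)
}

#' Time derivative of a gating variable
#'
#' Returns \eqn{\lambda_X (X_\infty - X)/\tau_X(v)} for sigmoid gates and
#' \eqn{\alpha_X(v)(1-X) - \beta_X(v)X} for alpha/beta gates, in 1/ms.
#'
#' @param x current gate value in \code{[0, 1]}.
#' @param v membrane potential in mV.
#' @param spec a \code{\link{gating_spec}}.
#' @return derivative in 1/ms.
#' @export
gate_derivative <- function(x, v, spec) {
  stopifnot(inherits(spec, "gating_spec"))
  switch(spec$form,
    sigmoid_tau = {
      tau <- spec$tau(v)
      if (any(tau <= 0)) stop("gating time constant must be positive")
      spec$lambda * (steady_state_gate(v, spec) - x) / tau
    },
    alpha_beta = spec$alpha(v) * (1 - x) - spec$beta(v) * x,
    instantaneous = stop("instantaneous gates have no dynamics")
  )
}

# Numerically safe x/(1 - exp(-x/k)) used by the alpha/beta rates, with the
# removable singularity at x = 0 filled by its limit k.
.expm1_rate <- function(x, k) {
  out <- ifelse(abs(x) < 1e-7, k + x / 2, x / (1 - exp(-x / k)))
  out
}
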