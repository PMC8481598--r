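# Feedback controllers for DBS frequency modulation: proportional and
# proportional-integral laws on the beta-power error, and the supervisory
# scheme in which an on-line trained radial basis function (RBF) network
# acts as an adaptive feedforward controller alongside the fixed-gain P/PI
# controller. The commanded pulse frequency is clamped to [5, 200] Hz.

U_MIN <- 5
U_MAX <- 200

#' P/PI controller gains
#'
#' @param kp proportional gain, Hz per dB of beta-power error.
#' @param ki integral gain, Hz per dB s.
#' @param anti_windup bound on the accumulated integral state; defaults to
#'   the command range divided by ki so the integral term alone can span the
#'   full output range but no further (unbounded integration with a clamped
#'   output stalls recovery).
#' @return object of class \code{"pi_gains"} with zero integral state.
#' @export
pi_gains <- function(kp = 0.1, ki = 0, anti_windup = NULL) {
  if (kp < 0 || ki < 0) stop("gains must be >= 0")
  if (is.null(anti_windup))
    anti_windup <- if (ki > 0) U_MAX / ki else Inf
  structure(list(kp = kp, ki = ki, integral_state = 0,
                 anti_windup = anti_windup),
            class = "pi_gains")
}

#' Proportional control step
#'
#' @param e beta-power error y_d - y, dB.
#' @param gains a \code{\link{pi_gains}}.
#' @return commanded increment, Hz (unclamped).
#' @export
p_step <- function(e, gains) {
  stopifnot(inherits(gains, "pi_gains"))
  gains$kp * e
}

#' Proportional-integral control step
#'
#' Accumulates \code{e * dt} into the integral state (bounded by the
#' anti-windup limit) and returns \eqn{k_p e + k_i \int e}.
#'
#' @param e error, dB.
#' @param dt time since the previous update, s.
#' @param gains a \code{\link{pi_gains}}.
#' @return list with \code{u} (Hz, unclamped) and the updated \code{gains}.
#' @export
pi_step <- function(e, dt, gains) {
  stopifnot(inherits(gains, "pi_gains"))
  if (dt <= 0) stop("dt must be positive")
  s <- gains$integral_state + e * dt
  s <- min(max(s, -gains$anti_windup), gains$anti_windup)
  gains$integral_state <- s
  list(u = gains$kp * e + gains$ki * s, gains = gains)
}

#' RBF network state
#'
#' A 1-input, m-hidden-node, 1-output Gaussian RBF network trained on line
#' by gradient descent with momentum. Weights start uniform on [0, 1]
#' (seeded); centers are spaced over the normalized input range and widths
#' are 5. The default hidden-layer size is 11; \code{five_node = TRUE}
#' selects the compact 5-node variant with centers (-2, -1, 0, 1, 2).
#'
#' @param m hidden-layer size.
#' @param centers numeric vector of Gaussian centers (length m).
#' @param widths Gaussian widths (scalar or length m, > 0).
#' @param eta learning rate in (0, 1).
#' @param alpha momentum factor in (0, 1).
#' @param width_floor lower bound kept on widths during adaptation.
#' @param seed integer seed for the weight initialization.
#' @param five_node logical; use the 5-node preset.
#' @return object of class \code{"rbf_state"}.
#' @export
rbf_state <- function(m = 11, centers = seq(-2, 2, length.out = m),
                      widths = 5, eta = 0.30, alpha = 0.05,
                      width_floor = 0.1, seed = 1, five_node = FALSE) {
  if (five_node) {
    m <- 5
    centers <- c(-2, -1, 0, 1, 2)
    widths <- 5
  }
  if (length(centers) != m) stop("centers must have length m")
  widths <- rep_len(widths, m)
  if (any(widths <= 0)) stop("widths must be positive")
  if (eta <= 0 || eta >= 1 || alpha < 0 || alpha >= 1)
    stop("need eta in (0,1) and alpha in [0,1)")
  w <- .with_seed(seed, stats::runif(m))
  st <- list(m = m, w = w, c = centers, b = widths, eta = eta,
             alpha = alpha, width_floor = width_floor,
             prev1 = list(w = w, c = centers, b = widths),
             prev2 = list(w = w, c = centers, b = widths))
  structure(st, class = "rbf_state")
}

#' RBF forward pass
#'
#' Hidden activations \eqn{h_j = \exp(-\|x - c_j\|^2 / (2 b_j^2))} and
#' network output \eqn{u_{rbf} = \sum_j h_j w_j}.
#'
#' @param x network input (scalar).
#' @param state an \code{\link{rbf_state}}.
#' @return list with \code{u_rbf} (Hz) and the activation vector \code{h}.
#' @export
rbf_forward <- function(x, state) {
  stopifnot(inherits(state, "rbf_state"))
  h <- exp(-(x - state$c)^2 / (2 * state$b^2))
  list(u_rbf = sum(h * state$w), h = h)
}

#' On-line RBF parameter update
#'
#' Gradient descent with momentum on the supervisory objective
#' \eqn{E = \frac{1}{2}(u_{rbf} - u)^2} (equivalently \eqn{\frac{1}{2}u_p^2}
#' when the command is unclamped), which drives the network output toward
#' the total command and thereby the feedback term toward zero:
#' \deqn{\Delta w_j = -\eta (u_{rbf} - u) h_j}
#' \deqn{\Delta b_j = -\eta (u_{rbf} - u) w_j h_j \|x - c_j\|^2 / b_j^3}
#' \deqn{\Delta c_j = -\eta (u_{rbf} - u) w_j h_j (x - c_j) / b_j^2}
#' Each parameter also receives the momentum term
#' \eqn{\alpha(\theta(t-1) - \theta(t-2))}; widths are floored at
#' \code{width_floor}.
#'
#' @param u total (clamped) command actually delivered, Hz.
#' @param u_rbf RBF output used for that command, Hz.
#' @param h activation vector from \code{\link{rbf_forward}}.
#' @param x the network input used.
#' @param state an \code{\link{rbf_state}}.
#' @return the updated \code{rbf_state}.
#' @export
rbf_update <- function(u, u_rbf, h, x, state) {
  stopifnot(inherits(state, "rbf_state"))
  err <- u_rbf - u
  dw <- -state$eta * err * h
  db <- -state$eta * err * state$w * h * (x - state$c)^2 / state$b^3
  dc <- -state$eta * err * state$w * h * (x - state$c) / state$b^2
  if (!all(is.finite(c(dw, db, dc))))
    stop("RBF learning diverged (non-finite gradient)")
  new_w <- state$w + dw + state$alpha * (state$prev1$w - state$prev2$w)
  new_b <- state$b + db + state$alpha * (state$prev1$b - state$prev2$b)
  new_c <- state$c + dc + state$alpha * (state$prev1$c - state$prev2$c)
  new_b <- pmax(new_b, state$width_floor)
  state$prev2 <- state$prev1
  state$prev1 <- list(w = state$w, c = state$c, b = state$b)
  state$w <- new_w
  state$b <- new_b
  state$c <- new_c
  state
}

#' Clamp a commanded frequency to the stimulation range
#'
#' Commands are kept in [5, 200] Hz; values below the floor are raised to
#' 5 Hz (stimulation is never fully off under closed-loop control).
#'
#' @param u commanded frequency, Hz.
#' @return clamped frequency.
#' @export
clamp_command <- function(u) {
  pmin(pmax(u, U_MIN), U_MAX)
}

#' Controller configuration
#'
#' @param mode \code{"p"}, \code{"pi"}, \code{"rbf_p"}, \code{"rbf_pi"}
#'   (supervisory), \code{"open"} (fixed-frequency open loop) or
#'   \code{"none"} (no stimulation).
#' @param kp,ki P/PI gains.
#' @param u_open open-loop frequency, Hz.
#' @param rbf an \code{\link{rbf_state}} for the supervisory modes.
#' @param rbf_input \code{"reference"} (default; the RBF acts as a
#'   feedforward inverse model driven by the reference beta power) or
#'   \code{"error"}.
#' @param beta_range dB range used to normalize the RBF input to [-2, 2].
#' @return object of class \code{"controller_spec"}.
#' @export
controller_spec <- function(mode = c("rbf_p", "p", "pi", "rbf_pi", "open",
                                     "none"),
                            kp = 0.1, ki = 0.5, u_open = 130, rbf = NULL,
                            rbf_input = c("reference", "error"),
                            beta_range = c(90, 150)) {
  mode <- match.arg(mode)
  rbf_input <- match.arg(rbf_input)
  gains <- pi_gains(kp = kp, ki = if (mode %in% c("pi", "rbf_pi")) ki else 0)
  if (mode %in% c("rbf_p", "rbf_pi") && is.null(rbf)) rbf <- rbf_state()
  structure(list(mode = mode, gains = gains, u_open = u_open, rbf = rbf,
                 rbf_input = rbf_input, beta_range = beta_range),
            class = "controller_spec")
}

.rbf_input_value <- function(ctrl, y, y_d) {
  raw <- if (ctrl$rbf_input == "reference") y_d else y_d - y
  lo <- ctrl$beta_range[1]
  hi <- ctrl$beta_range[2]
  4 * (raw - lo) / (hi - lo) - 2
}

#' One supervisory control step
#'
#' Computes the error \eqn{e = y_d - y}, the P (or PI) output, the RBF
#' feedforward output, clamps the total command to [5, 200] Hz, and then
#' adapts the RBF against the clamped command actually delivered to the
#' plant. Pure P/PI and open-loop modes reduce to the corresponding
#' sub-steps.
#'
#' Because the plant's static gain is negative in its useful range
#' (raising the pulse frequency above ~50 Hz lowers beta power), the P/PI
#' law is applied to the beta excess \eqn{y - y_d = -e} with positive
#' gains: excess beta drives the commanded frequency up. The logged error
#' keeps the \eqn{e = y_d - y} convention.
#'
#' @param y measured beta power, dB.
#' @param y_d reference beta power, dB.
#' @param dt time since the previous update, s.
#' @param ctrl a \code{\link{controller_spec}} (carries all mutable state).
#' @return list with \code{sample} (one-row data frame: t unset, y, y_d, e,
#'   u_p, u_rbf, u) and the updated \code{ctrl}.
#' @export
supervisory_step <- function(y, y_d, dt, ctrl) {
  stopifnot(inherits(ctrl, "controller_spec"))
  e <- y_d - y
  u_p <- 0
  u_rbf <- 0
  h <- NULL
  x <- NULL
  if (ctrl$mode == "none") {
    u <- 0
  } else if (ctrl$mode == "open") {
    u <- clamp_command(ctrl$u_open)
  } else {
    if (ctrl$mode %in% c("pi", "rbf_pi")) {
      st <- pi_step(-e, dt, ctrl$gains)
      u_p <- st$u
      ctrl$gains <- st$gains
    } else {
      u_p <- p_step(-e, ctrl$gains)
    }
    if (ctrl$mode %in% c("rbf_p", "rbf_pi")) {
      x <- .rbf_input_value(ctrl, y, y_d)
      fw <- rbf_forward(x, ctrl$rbf)
      u_rbf <- fw$u_rbf
      h <- fw$h
    }
    u <- clamp_command(u_p + u_rbf)
    if (!is.null(h))
      ctrl$rbf <- rbf_update(u, u_rbf, h, x, ctrl$rbf)
  }
  sample <- data.frame(y = y, y_d = y_d, e = e, u_p = u_p, u_rbf = u_rbf,
                       u = u)
  list(sample = sample, ctrl = ctrl)
}
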