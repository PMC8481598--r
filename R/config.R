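# Network-level configuration: populations, synaptic topology, parkinsonism
# mapping, serialization. The nucleus-level wiring diagram (direct, indirect
# and hyper-direct pathways, the STN-GPe loop, reciprocal eCTX-iCTX coupling
# and the thalamocortical return projection) is fixed; per-connection
# conductances, delays, fan-in, bias currents and noise levels are editorial
# defaults of this package and every one of them can be overridden.

.POPS <- c("eCTX", "iCTX", "dSTR", "idSTR", "STN", "GPe", "GPi", "TH")

# Ring wiring: post neuron i receives from `fan` presynaptic neurons starting
# at offset `off` (indices mod n). Returns a 2-column matrix (pre, post),
# 1-based.
.ring_wiring <- function(n_pre, n_post, fan, off = 0) {
  post <- rep(seq_len(n_post), each = fan)
  pre <- as.vector(vapply(seq_len(n_post), function(i) {
    as.integer(((i - 1 + off + seq_len(fan) - 1) %% n_pre) + 1)
  }, integer(fan)))
  cbind(pre = pre, post = post)
}

.default_synapses <- function(n = 10, esyn_literal = FALSE) {
  E_EXC <- if (esyn_literal) -85 else 0
  E_INH <- -85
  mk <- function(source, target, g, E, delay, fan, off = 0) {
    list(source = source, target = target, g = g, E = E, delay = delay,
         tau = 5, fan = fan, off = off,
         wiring = .ring_wiring(n, n, fan, off))
  }
  list(
    eCTX_iCTX  = mk("eCTX", "iCTX", 0.10, E_EXC, 1.0, 3),
    iCTX_eCTX  = mk("iCTX", "eCTX", 0.30, E_INH, 1.0, 3),
    TH_eCTX    = mk("TH", "eCTX", 0.10, E_EXC, 2.0, 3),
    eCTX_dSTR  = mk("eCTX", "dSTR", 0.07, E_EXC, 5.0, 2),
    eCTX_idSTR = mk("eCTX", "idSTR", 0.07, E_EXC, 5.0, 2),
    eCTX_STN   = mk("eCTX", "STN", 0.15, E_EXC, 5.9, 3),
    dSTR_GPi   = mk("dSTR", "GPi", 0.40, E_INH, 4.0, 3),
    idSTR_GPe  = mk("idSTR", "GPe", 0.30, E_INH, 4.0, 3),
    STN_GPe    = mk("STN", "GPe", 0.20, E_EXC, 2.0, 3),
    GPe_STN    = mk("GPe", "STN", 0.15, E_INH, 4.0, 3),
    GPe_GPe    = mk("GPe", "GPe", 0.0125, E_INH, 1.0, 6, off = 1),
    STN_GPi    = mk("STN", "GPi", 0.15, E_EXC, 1.5, 6),
    GPe_GPi    = mk("GPe", "GPi", 0.20, E_INH, 3.0, 6),
    GPi_TH     = mk("GPi", "TH", 0.112, E_INH, 5.0, 3)
  )
}

#' Build a network configuration
#'
#' Assembles the full cortex-basal ganglia-thalamus network: eight
#' populations (eCTX, iCTX, dSTR, idSTR, STN, GPe, GPi, TH) of \code{n}
#' single-compartment neurons each, connected through delayed alpha synapses
#' along the direct, indirect and hyper-direct pathways, the STN-GPe loop,
#' reciprocal eCTX-iCTX coupling and the GPi-TH-eCTX return path.
#'
#' The parkinsonism variable \code{pd} in \code{[0, 1]} interpolates three
#' parameters between the healthy (\code{pd = 0}) and fully parkinsonian
#' (\code{pd = 1}) states: the striatal M-type potassium conductance
#' \eqn{g_m = 2.6 - 0.9 pd}, the cortico-striatal coupling
#' \eqn{g_{CTX,STR} = 0.07 - 0.044 pd} and the intra-GPe coupling
#' \eqn{g_{GPe,GPe} = 0.0125 + 0.0375 pd}.
#'
#' @param pd parkinsonism variable in \code{[0, 1]}.
#' @param seed integer seed controlling initial conditions and noise.
#' @param dt integration step, ms.
#' @param n neurons per population.
#' @param esyn_literal logical; if \code{TRUE} every synaptic reversal
#'   potential is forced to -85 mV (the uniform-reversal variant), instead of
#'   the default 0 mV for excitatory and -85 mV for inhibitory projections.
#' @param bias named list overriding per-population bias currents
#'   (uA/cm^2); defaults cover \code{eCTX}, \code{GPe}, \code{GPi},
#'   \code{TH}.
#' @param bias_spread named list of per-population half-widths (uA/cm^2) of
#'   the seeded uniform heterogeneity added to the bias current; defaults to
#'   10 percent of the population bias.
#' @param noise_sd named list overriding per-population noise intensities
#'   (uA/cm^2 sqrt(ms)); default drives cortex only.
#' @param synapses optional replacement/override list of synapse entries (as
#'   produced internally; see \code{\link{network_synapses}}).
#' @return object of class \code{"cbgt_config"}.
#' @export
network_config <- function(pd = 0, seed = 1, dt = 0.01, n = 10,
                           esyn_literal = FALSE, bias = list(),
                           bias_spread = list(), noise_sd = list(),
                           synapses = NULL) {
  if (dt <= 0) stop("dt must be positive")
  if (n < 1) stop("population size must be >= 1")
  b <- list(eCTX = 5, iCTX = 0, dSTR = 0, idSTR = 0, STN = 0,
            GPe = 2, GPi = 3, TH = 0.7)
  b[names(bias)] <- bias
  ns <- list(eCTX = 1.5, iCTX = 1, dSTR = 0, idSTR = 0, STN = 0,
             GPe = 0, GPi = 0, TH = 0)
  ns[names(noise_sd)] <- noise_sd
  # heterogeneous tonic drive keeps the healthy STN population dephased
  bs <- list(STN = 0.3)
  bs[names(bias_spread)] <- bias_spread
  cfg <- structure(list(
    populations = .POPS,
    n = as.integer(n),
    pd = NA_real_,
    dt = dt,
    seed = as.integer(seed),
    esyn_literal = esyn_literal,
    bias = b,
    bias_spread = bs,
    noise_sd = ns,
    synapses = if (is.null(synapses)) .default_synapses(n, esyn_literal) else synapses,
    # v(0) is drawn above the basin of the fast depolarized limit cycle of
    # the STN model (entered from hyperpolarized starts with equilibrated
    # slow gates), so every cell begins in its tonic mode
    init = list(v_range = c(-60, -50), CA0 = 0.1)
  ), class = "cbgt_config")
  apply_parkinsonism(cfg, pd)
}

#' Synapse table of a configuration
#'
#' @param config a \code{\link{network_config}}.
#' @return data frame with one row per projection (source, target, g, E,
#'   delay, tau, fan).
#' @export
network_synapses <- function(config) {
  do.call(rbind, lapply(config$synapses, function(s)
    data.frame(source = s$source, target = s$target, g = s$g, E = s$E,
               delay = s$delay, tau = s$tau, fan = s$fan)))
}

#' Set the parkinsonism level of a configuration
#'
#' Applies the parkinsonism variable to the three affected parameters
#' (striatal \eqn{g_m}, cortico-striatal \eqn{g_{CTX,STR}}, intra-GPe
#' \eqn{g_{GPe,GPe}}); all other parameters are untouched. The mapping is
#' absolute in \code{pd} (repeated application does not compound).
#'
#' @param config a \code{\link{network_config}}.
#' @param pd parkinsonism variable in \code{[0, 1]}.
#' @return the updated configuration.
#' @export
apply_parkinsonism <- function(config, pd) {
  stopifnot(inherits(config, "cbgt_config"))
  if (!is.numeric(pd) || length(pd) != 1 || is.na(pd) || pd < 0 || pd > 1)
    stop("pd must be a single number in [0, 1]")
  config$pd <- pd
  config$gm_str <- 2.6 - 0.9 * pd
  g_ctx_str <- 0.07 - 0.044 * pd
  config$synapses$eCTX_dSTR$g <- g_ctx_str
  config$synapses$eCTX_idSTR$g <- g_ctx_str
  config$synapses$GPe_GPe$g <- 0.0125 + 0.0375 * pd
  config
}

#' Validate a network configuration
#'
#' Checks value ranges and that the required pathway topology is present
#' (direct, indirect, hyper-direct, STN-GPe loop, eCTX-iCTX reciprocity,
#' GPi-TH-eCTX return path).
#'
#' @param config a \code{\link{network_config}}.
#' @return invisibly \code{TRUE}; otherwise an error naming the offending
#'   field.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "cbgt_config"))
  if (config$dt <= 0) stop("config$dt: must be positive")
  if (config$pd < 0 || config$pd > 1) stop("config$pd: must lie in [0, 1]")
  required <- c("eCTX_dSTR", "dSTR_GPi", "GPi_TH", "TH_eCTX",
                "eCTX_idSTR", "idSTR_GPe", "GPe_GPi",
                "eCTX_STN", "STN_GPi", "STN_GPe", "GPe_STN",
                "eCTX_iCTX", "iCTX_eCTX")
  missing <- setdiff(required, names(config$synapses))
  if (length(missing))
    stop("config$synapses: missing required pathway projection(s): ",
         paste(missing, collapse = ", "))
  for (nm in names(config$synapses)) {
    s <- config$synapses[[nm]]
    if (s$g < 0) stop("config$synapses$", nm, "$g: must be >= 0")
    if (s$delay < 0) stop("config$synapses$", nm, "$delay: must be >= 0")
    if (s$tau <= 0) stop("config$synapses$", nm, "$tau: must be > 0")
    if (any(s$wiring < 1) || any(s$wiring > config$n))
      stop("config$synapses$", nm, "$wiring: indices out of range")
  }
  invisible(TRUE)
}

#' Write / read a configuration as YAML
#'
#' The YAML file mirrors the configuration field for field; wiring matrices
#' are stored as pre/post index lists.
#'
#' @param config a \code{\link{network_config}}.
#' @param path file path.
#' @return \code{read_network_config} returns a \code{"cbgt_config"}.
#' @export
write_network_config <- function(config, path) {
  stopifnot(inherits(config, "cbgt_config"))
  ser <- unclass(config)
  ser$synapses <- lapply(ser$synapses, function(s) {
    s$wiring <- list(pre = as.integer(s$wiring[, "pre"]),
                     post = as.integer(s$wiring[, "post"]))
    s
  })
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname write_network_config
#' @export
read_network_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$synapses <- lapply(raw$synapses, function(s) {
    s$wiring <- cbind(pre = as.integer(s$wiring$pre),
                      post = as.integer(s$wiring$post))
    s
  })
  raw$n <- as.integer(raw$n)
  raw$seed <- as.integer(raw$seed)
  raw$init$v_range <- as.numeric(raw$init$v_range)
  cfg <- structure(raw, class = "cbgt_config")
  validate_config(cfg)
  cfg
}

#' @export
print.cbgt_config <- function(x, ...) {
  cat("<cbgt_config> ", length(x$populations), " populations x ", x$n,
      " neurons, pd = ", x$pd, ", dt = ", x$dt, " ms, seed = ", x$seed,
      "\n", sep = "")
  cat("  projections: ", paste(names(x$synapses), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}
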