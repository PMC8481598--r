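# Feedback and evaluation signals: LFP, sliding-window multitaper beta-band
# power, band-pass filtering, spike detection, firing rates, population
# synchrony and the RMSE performance index.

.taper_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first \code{k} DPSS tapers of length \code{n} at
#' time-bandwidth product \code{nw}, via the symmetric tridiagonal
#' formulation (the tapers are eigenvectors of the tridiagonal matrix with
#' diagonal \eqn{((n-1-2t)/2)^2 \cos(2\pi W)} and off-diagonal
#' \eqn{t(n-t)/2}). Tapers are normalized to unit energy; results are cached
#' per (n, nw, k).
#'
#' @param n taper length, samples.
#' @param nw time-bandwidth product.
#' @param k number of tapers (k <= 2 nw - 1).
#' @return n x k matrix, one taper per column.
#' @export
dpss_tapers <- function(n, nw = 3, k = 5) {
  if (k > 2 * nw - 1)
    stop("number of tapers must satisfy k <= 2*nw - 1")
  key <- paste(n, nw, k, sep = "_")
  hit <- .taper_cache[[key]]
  if (!is.null(hit)) return(hit)
  w <- nw / n
  tt <- 0:(n - 1)
  diag_main <- ((n - 1 - 2 * tt) / 2)^2 * cos(2 * pi * w)
  diag_off <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  A <- matrix(0, n, n)
  A[cbind(tt + 1, tt + 1)] <- diag_main
  A[cbind(1:(n - 1), 2:n)] <- diag_off
  A[cbind(2:n, 1:(n - 1))] <- diag_off
  eg <- eigen(A, symmetric = TRUE)
  tap <- eg$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    tap[, j] <- tap[, j] / sqrt(sum(tap[, j]^2))
    if (sum(tap[, j]) < 0) tap[, j] <- -tap[, j]
  }
  .taper_cache[[key]] <- tap
  tap
}

#' Spectral-estimation configuration
#'
#' Sliding-window multitaper settings for the beta-power biomarker: 1 s
#' moving windows advanced in 0.1 s steps, five DPSS tapers at
#' time-bandwidth product 3, total (integrated) power over the 13-30 Hz
#' band. Power is reported as
#' \code{10*log10(power) + calibration_db} when \code{power_scale = "dB"};
#' the calibration offset anchors the package's dB convention (linear power
#' is in mV^2 with a 1 kHz analysis rate) to the conventional operating
#' point of roughly 120 dB for the healthy-state GPi beta power of this
#' model family.
#'
#' @param window_length window, s.
#' @param step window step, s.
#' @param time_bandwidth dimensionless time-bandwidth product.
#' @param n_tapers number of DPSS tapers.
#' @param band beta band limits, Hz.
#' @param sample_rate analysis sampling rate, Hz.
#' @param power_scale "dB" or "linear".
#' @param calibration_db additive dB calibration offset.
#' @return object of class \code{"spectral_config"}.
#' @export
spectral_config <- function(window_length = 1, step = 0.1,
                            time_bandwidth = 3, n_tapers = 5,
                            band = c(13, 30), sample_rate = 1000,
                            power_scale = c("dB", "linear"),
                            calibration_db = 110) {
  power_scale <- match.arg(power_scale)
  if (step <= 0 || step > window_length)
    stop("need 0 < step <= window_length")
  if (n_tapers > 2 * time_bandwidth - 1)
    stop("n_tapers must be <= 2*time_bandwidth - 1")
  if (band[1] <= 0 || band[2] > sample_rate / 2)
    stop("band must lie within (0, Nyquist)")
  structure(list(window_length = window_length, step = step,
                 time_bandwidth = time_bandwidth, n_tapers = n_tapers,
                 band = band, sample_rate = sample_rate,
                 power_scale = power_scale, calibration_db = calibration_db),
            class = "spectral_config")
}

#' Local field potential of a population
#'
#' The LFP is the arithmetic mean of the population's membrane potentials at
#' each time point.
#'
#' @param v_traces neuron x time matrix, mV.
#' @return numeric vector, one value per time sample.
#' @export
compute_lfp <- function(v_traces) {
  if (is.null(dim(v_traces))) v_traces <- matrix(v_traces, nrow = 1)
  if (nrow(v_traces) < 1 || ncol(v_traces) < 1)
    stop("LFP requires a nonempty population")
  colMeans(v_traces)
}

# Multitaper one-sided PSD of one (already demeaned) window.
# Returns list(freq, psd) with sum(psd)*df ~ var(x) (Parseval).
.mt_psd <- function(x, fs, tapers) {
  n <- length(x)
  X <- stats::mvfft(x * tapers)
  p2 <- rowMeans(Mod(X)^2) / fs
  nfold <- floor(n / 2)
  freq <- (0:nfold) * fs / n
  psd <- p2[1:(nfold + 1)]
  idx <- 2:(nfold + ifelse(n %% 2 == 0, 0, 1))
  psd[idx] <- psd[idx] + rev(p2)[idx - 1]
  list(freq = freq, psd = psd)
}

#' Sliding-window multitaper beta-band power
#'
#' For each 1 s window (advanced by the configured step), the LFP is
#' demeaned, tapered with the DPSS family, and the one-sided multitaper PSD
#' is integrated over the beta band (sum of PSD bins times bin width). Times
#' are window end points, so each value uses only past data (causal, as
#' required for feedback use).
#'
#' @param lfp LFP samples, mV, at \code{cfg$sample_rate}.
#' @param cfg a \code{\link{spectral_config}}.
#' @return data frame of class \code{"beta_power_series"} with columns
#'   \code{time} (s, window ends) and \code{power} (dB or mV^2 per
#'   \code{cfg$power_scale}).
#' @export
beta_power <- function(lfp, cfg = spectral_config()) {
  stopifnot(inherits(cfg, "spectral_config"))
  fs <- cfg$sample_rate
  nwin <- round(cfg$window_length * fs)
  nstep <- round(cfg$step * fs)
  if (length(lfp) < nwin)
    stop("LFP shorter than the spectral window (need >= ",
         cfg$window_length, " s)")
  tapers <- dpss_tapers(nwin, cfg$time_bandwidth, cfg$n_tapers)
  starts <- seq(1, length(lfp) - nwin + 1, by = nstep)
  df <- fs / nwin
  pow <- vapply(starts, function(s) {
    x <- lfp[s:(s + nwin - 1)]
    x <- x - mean(x)
    sp <- .mt_psd(x, fs, tapers)
    keep <- sp$freq >= cfg$band[1] & sp$freq <= cfg$band[2]
    sum(sp$psd[keep]) * df
  }, numeric(1))
  if (cfg$power_scale == "dB")
    pow <- 10 * log10(pmax(pow, 1e-300)) + cfg$calibration_db
  structure(data.frame(time = (starts - 1 + nwin) / fs, power = pow),
            class = c("beta_power_series", "data.frame"),
            config = cfg)
}

#' Multitaper power spectral density of an LFP
#'
#' Whole-signal multitaper PSD (single window over the full record),
#' convenient for healthy-vs-parkinsonian spectral contrasts.
#'
#' @inheritParams beta_power
#' @return data frame with \code{freq} (Hz) and \code{psd} (mV^2/Hz).
#' @export
lfp_psd <- function(lfp, cfg = spectral_config()) {
  fs <- cfg$sample_rate
  x <- lfp - mean(lfp)
  tapers <- dpss_tapers(length(x), cfg$time_bandwidth, cfg$n_tapers)
  sp <- .mt_psd(x, fs, tapers)
  data.frame(freq = sp$freq, psd = sp$psd)
}

#' Zero-phase beta band-pass filter
#'
#' 4th-order Butterworth band-pass applied forward and backward
#' (zero-phase); used for visualization of beta-band LFP activity.
#'
#' @param lfp LFP samples.
#' @param band band edges, Hz.
#' @param sample_rate sampling rate, Hz.
#' @return filtered series, same length.
#' @export
bandpass_beta <- function(lfp, band = c(13, 30), sample_rate = 1000) {
  nyq <- sample_rate / 2
  if (band[1] <= 0 || band[2] >= nyq || band[1] >= band[2])
    stop("band must lie within (0, Nyquist)")
  bf <- signal::butter(4, band / nyq, type = "pass")
  as.numeric(signal::filtfilt(bf, lfp))
}

#' Detect spikes by threshold crossing
#'
#' A spike is an upward crossing of the threshold; crossings within the
#' refractory lockout of the previous spike are ignored.
#'
#' @param v voltage samples on a uniform grid, mV.
#' @param dt sample interval, ms.
#' @param threshold detection threshold, mV.
#' @param refractory lockout, ms.
#' @return spike times, ms (time of the crossing sample).
#' @export
detect_spikes <- function(v, dt = 1, threshold = -20, refractory = 1) {
  idx <- which(v[-1] >= threshold & v[-length(v)] < threshold) + 1
  if (!length(idx)) return(numeric(0))
  times <- idx * dt
  keep <- logical(length(times))
  last <- -Inf
  for (i in seq_along(times)) {
    if (times[i] - last >= refractory) {
      keep[i] <- TRUE
      last <- times[i]
    }
  }
  times[keep]
}

#' Firing rates from spike times
#'
#' @param spike_times list of per-neuron spike-time vectors (ms), or a
#'   single numeric vector.
#' @param duration observation period, ms.
#' @return list with \code{per_neuron} (Hz) and \code{mean} (Hz).
#' @export
firing_rate <- function(spike_times, duration) {
  if (duration <= 0) stop("duration must be positive")
  if (!is.list(spike_times)) spike_times <- list(spike_times)
  per <- vapply(spike_times, length, integer(1)) / (duration / 1000)
  list(per_neuron = per, mean = mean(per))
}

#' Population spike synchrony
#'
#' The synchrony measure is the ratio of the temporal variance of the
#' population-mean voltage to the mean temporal variance of the individual
#' voltages,
#' \deqn{\chi = \sigma_V^2 / \frac{1}{n}\sum_i \sigma_{v_i}^2,}
#' normalized between 0 (asynchronous) and 1 (perfectly synchronous).
#'
#' @param v_traces neuron x time matrix, mV (n >= 2 neurons).
#' @return list of class \code{"synchrony_report"} with \code{chi},
#'   \code{population_variance} and \code{mean_individual_variance}.
#' @export
synchrony_chi <- function(v_traces) {
  if (nrow(v_traces) < 2) stop("synchrony needs at least two neurons")
  V <- colMeans(v_traces)
  var_t <- function(x) mean(x^2) - mean(x)^2
  sV <- var_t(V)
  si <- mean(apply(v_traces, 1, var_t))
  if (si == 0) stop("synchrony undefined for constant traces")
  structure(list(chi = sV / si, population_variance = sV,
                 mean_individual_variance = si),
            class = "synchrony_report")
}

#' Read / write columnar time-series CSVs
#'
#' \code{read_lfp_csv} reads a two-column (time in s, voltage in mV) CSV,
#' checks the sampling grid, and returns the LFP with a
#' \code{"sample_rate"} attribute, ready for \code{\link{beta_power}}.
#' \code{write_beta_csv} writes a \code{\link{beta_power}} series as
#' (time, power) CSV.
#'
#' @param path CSV file path.
#' @return \code{read_lfp_csv}: numeric LFP vector with attribute
#'   \code{sample_rate} (Hz).
#' @export
read_lfp_csv <- function(path) {
  df <- utils::read.csv(path)
  if (ncol(df) < 2) stop("expected columns: time, voltage")
  dt <- diff(df[[1]])
  if (any(abs(dt - dt[1]) > 1e-6 * dt[1]))
    stop("time column must be uniformly sampled")
  structure(as.numeric(df[[2]]), sample_rate = 1 / dt[1])
}

#' @rdname read_lfp_csv
#' @param bp a \code{"beta_power_series"} data frame.
#' @export
write_beta_csv <- function(bp, path) {
  utils::write.csv(data.frame(time = bp$time, power = bp$power), path,
                   row.names = FALSE)
  invisible(path)
}

#' Root-mean-square error
#'
#' \eqn{RMSE = \sqrt{\frac{1}{N}\sum_i (y_i - y_{d,i})^2}}; the reference may
#' be a scalar or a series of matching length.
#'
#' @param y controlled output series.
#' @param y_d reference (scalar or same length as y).
#' @return scalar RMSE.
#' @export
rmse <- function(y, y_d) {
  if (length(y) < 1) stop("empty series")
  if (length(y_d) == 1) y_d <- rep(y_d, length(y))
  if (length(y) != length(y_d)) stop("length mismatch between y and y_d")
  sqrt(mean((y - y_d)^2))
}
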