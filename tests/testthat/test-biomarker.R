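tone <- function(freq, fs = 1000, dur = 3, amp = 1, phase = 0) {
  amp * sin(2 * pi * freq * seq(0, dur - 1 / fs, by = 1 / fs) + phase)
}

test_that("the LFP is the arithmetic population mean", {
  m <- matrix(rep(c(-60, -58, -62), each = 5), nrow = 3, byrow = TRUE)
  expect_equal(compute_lfp(m), rep(-60, 5))
  one <- matrix(stats::rnorm(50), 1)
  expect_equal(compute_lfp(one), as.numeric(one))
  # antiphase sinusoids about -65 cancel
  t <- seq(0, 1, by = 1e-3)
  m2 <- rbind(-65 + sin(2 * pi * 10 * t), -65 - sin(2 * pi * 10 * t))
  expect_equal(compute_lfp(m2), rep(-65, length(t)))
  expect_error(compute_lfp(matrix(numeric(0), 0, 0)), "nonempty")
  # matches an independent per-sample mean on simulated traces
  sim <- run_simulation(quiet_config(), 50, record_dt = 1)
  expect_equal(compute_lfp(sim$v$GPi),
               apply(sim$v$GPi, 2, function(x) sum(x) / length(x)))
})

test_that("DPSS tapers are orthonormal and band-concentrated", {
  tp <- dpss_tapers(500, 3, 5)
  expect_equal(crossprod(tp), diag(5), tolerance = 1e-8)
  # leading taper concentrates its energy inside |f| <= NW/N
  spec <- abs(stats::fft(c(tp[, 1], numeric(3500))))^2
  w <- 3 / 500
  inband <- sum(spec[seq_len(ceiling(w * 4000))])
  expect_gt(inband / (sum(spec) / 2), 0.999)
})

test_that("a beta-band tone concentrates its power in the band", {
  cfg <- spectral_config(power_scale = "linear")
  x <- tone(20)
  bp <- beta_power(x, cfg)
  # total power of a unit sinusoid is 1/2
  expect_equal(mean(bp$power), 0.5, tolerance = 0.01)
  # independent periodogram oracle: fraction of power in 13-30 Hz
  pg <- abs(stats::fft(x - mean(x)))^2
  f <- (seq_along(pg) - 1) * 1000 / length(pg)
  frac <- sum(pg[f >= 13 & f <= 30]) / (sum(pg) / 2)
  expect_gt(frac, 0.95)
})

test_that("an out-of-band tone scores at least 20 dB lower", {
  cfg <- spectral_config()
  in_band <- mean(beta_power(tone(20), cfg)$power)
  out_band <- mean(beta_power(tone(5), cfg)$power)
  expect_gt(in_band - out_band, 20)
})

test_that("doubling the amplitude raises beta power by 6.02 dB", {
  cfg <- spectral_config()
  p1 <- mean(beta_power(tone(20), cfg)$power)
  p2 <- mean(beta_power(tone(20, amp = 2), cfg)$power)
  expect_equal(p2 - p1, 20 * log10(2), tolerance = 1e-6)
})

test_that("beta power ignores a constant offset", {
  cfg <- spectral_config()
  x <- tone(18) + 0.3 * stats::rnorm(3000)
  expect_equal(beta_power(x, cfg)$power, beta_power(x - 65, cfg)$power,
               tolerance = 1e-10)
})

test_that("window times advance by the configured step", {
  bp <- beta_power(tone(20, dur = 2.05), spectral_config())
  expect_equal(diff(bp$time), rep(0.1, nrow(bp) - 1), tolerance = 1e-9)
  expect_equal(bp$time[1], 1)
  expect_error(beta_power(tone(20, dur = 0.5), spectral_config()),
               "window")
})

test_that("multitaper total power satisfies Parseval within 10 percent", {
  set.seed(11)
  x <- stats::rnorm(4000)
  ps <- lfp_psd(x, spectral_config())
  total <- sum(ps$psd) * diff(ps$freq[1:2])
  expect_equal(total, stats::var(x), tolerance = 0.1)
})

test_that("the zero-phase band-pass keeps beta and rejects the rest", {
  t20 <- bandpass_beta(tone(20, dur = 5))
  mid <- 1000:4000
  expect_equal(max(abs(t20[mid])), 1, tolerance = 0.05)
  t60 <- bandpass_beta(tone(60, dur = 5))
  expect_lt(20 * log10(max(abs(t60[mid]))), -40)
  dc <- bandpass_beta(rep(3.7, 2000))
  expect_lt(mean(abs(dc[500:1500])), 1e-3)
  expect_error(bandpass_beta(tone(20), band = c(100, 600)), "Nyquist")
})

test_that("spike detection matches a brute-force crossing scan", {
  v <- rep(-65, 100)
  expect_length(detect_spikes(v, dt = 1), 0)
  tri <- rep(-65, 300)
  tri[c(50, 150, 250)] <- 10  # three isolated crossings
  expect_equal(detect_spikes(tri, dt = 1), c(50, 150, 250))
  # noisy conductance-like trace vs oracle with the same lockout rule
  set.seed(5)
  noisy <- -50 + 35 * sin(2 * pi * 0.02 * (1:2000)) + stats::rnorm(2000, 0, 4)
  got <- detect_spikes(noisy, dt = 0.5, threshold = -20, refractory = 1)
  oracle <- local({
    out <- c(); last <- -Inf
    for (i in 2:length(noisy)) {
      tt <- i * 0.5
      if (noisy[i] >= -20 && noisy[i - 1] < -20 && tt - last >= 1) {
        out <- c(out, tt); last <- tt
      }
    }
    out
  })
  expect_equal(got, oracle)
})

test_that("firing rates convert counts to Hz", {
  expect_equal(firing_rate(seq(100, 1000, by = 100), 1000)$mean, 10)
  expect_equal(firing_rate(numeric(0), 500)$mean, 0)
  fr <- firing_rate(list(1:5 * 100, numeric(0)), 1000)
  expect_equal(fr$per_neuron, c(5, 0))
  expect_equal(fr$mean, 2.5)
  expect_error(firing_rate(numeric(0), 0), "duration")
})

test_that("synchrony is 1 for identical traces and affine-invariant", {
  t <- seq(0, 1, by = 1e-3)
  base <- -60 + 5 * sin(2 * pi * 14 * t)
  m <- rbind(base, base, base)
  expect_equal(synchrony_chi(m)$chi, 1)
  set.seed(2)
  mixed <- rbind(base, -60 + 5 * sin(2 * pi * 14 * t + 1.3),
                 base + stats::rnorm(length(t)))
  r1 <- synchrony_chi(mixed)$chi
  r2 <- synchrony_chi(3.7 * mixed - 12)$chi
  expect_equal(r1, r2, tolerance = 1e-12)
  expect_error(synchrony_chi(matrix(-65, 3, 100)), "constant")
  expect_error(synchrony_chi(matrix(1, 1, 100)), "two neurons")
})

test_that("independent oscillators dilute synchrony as n grows", {
  t <- seq(0, 2, by = 1e-3)
  set.seed(9)
  mk <- function(n) t(sapply(seq_len(n), function(i)
    sin(2 * pi * 15 * t + stats::runif(1, 0, 2 * pi))))
  chi_small <- mean(replicate(20, synchrony_chi(mk(4))$chi))
  chi_large <- mean(replicate(20, synchrony_chi(mk(40))$chi))
  expect_lt(chi_large, 0.2)
  expect_lt(chi_large, chi_small)
})

test_that("LFP and beta series round-trip through columnar CSV", {
  x <- tone(20, dur = 1.5)
  lf <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(time = seq_along(x) / 1000, voltage = x), lf,
                   row.names = FALSE)
  back <- read_lfp_csv(lf)
  expect_equal(as.numeric(back), x)
  expect_equal(attr(back, "sample_rate"), 1000, tolerance = 1e-6)
  bp <- beta_power(back, spectral_config())
  bf <- tempfile(fileext = ".csv")
  write_beta_csv(bp, bf)
  again <- utils::read.csv(bf)
  expect_equal(again$power, bp$power)
})

test_that("the RMSE index matches hand arithmetic", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(5, 5, 5), 2), 3)
  expect_equal(rmse(c(1, 2, 3), 2), sqrt(2 / 3))
  expect_error(rmse(1:3, 1:2), "mismatch")
})
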