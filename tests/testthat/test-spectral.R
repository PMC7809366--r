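# Windowing, per-cell FT, cohort averaging, peak detection, inverse
# reconstruction, cohort-size scan.

test_that("detrending and windowing annihilate linear traces and zero the ends", {
  t <- seq(0, 1000, by = 5)
  lin <- list(time = t, mass = 200 + 0.3 * t)
  w <- detrend_and_window(lin)
  expect_lt(max(abs(w$windowed)), 1e-9)

  tr <- generate_trace(T = 1200, seed = 2)
  w2 <- detrend_and_window(tr)
  expect_equal(w2$windowed[1], 0)
  expect_equal(w2$windowed[length(w2$windowed)], 0)

  # pure sinusoid: output equals sinusoid residual x window, pointwise
  y <- sin(2 * pi * 0.004 * t + 0.7)
  s <- list(time = t, mass = y)
  ws <- detrend_and_window(s)
  fitres <- unname(residuals(lm(y ~ t)))
  expect_equal(ws$windowed, fitres * sin(pi * t / 1000), tolerance = 1e-12)

  expect_error(detrend_and_window(list(time = 1:10, mass = 1:10)), "short")
})

test_that("per-cell FT lands a tone on its own grid and scales by window gain", {
  t <- seq(0, 2000, by = 5)
  a <- 37
  y <- a * cos(2 * pi * 0.004 * t + 1.1)
  sp <- cell_ft(detrend_and_window(list(time = t, mass = y)), M = 25)
  expect_equal(sp$df * sp$T * sp$M, 1)
  expect_true(all(diff(sp$freq) > 0))
  expect_lte(max(sp$freq), 1 / 10)

  # zero series: all-zero amplitudes
  sp0 <- cell_ft(detrend_and_window(list(time = t, mass = 0 * t)), M = 25)
  expect_equal(max(sp0$amplitude), 0)

  f_hat <- sp$freq[which.max(sp$amplitude)]
  expect_lt(abs(f_hat - 0.004), sp$df / 2 + 1e-12)

  # peak amplitude equals a x (window gain)/2, with the gain computed by
  # direct numerical quadrature of the sine window (independent oracle)
  w <- sin(pi * (t - t[1]) / sp$T)
  res <- residuals(lm(y ~ t))
  oracle <- abs(sum(res * w * exp(-2i * pi * f_hat * t))) / length(t)
  expect_equal(max(sp$amplitude), oracle, tolerance = 1e-9)
  gain <- mean(w)
  expect_equal(max(sp$amplitude), a * gain / 2, tolerance = 0.02)
})

test_that("cell-level Parseval constant holds on random inputs", {
  set.seed(4)
  ratios <- replicate(5, {
    t <- seq(0, 1500, by = 5)
    y <- rnorm(length(t))
    w <- detrend_and_window(list(time = t, mass = y))
    sp <- cell_ft(w, M = 25)
    L <- (length(t) - 1) * 25
    # zero-padded FFT Parseval: sum |X_k|^2 over the full grid = L * energy
    sum(Mod(fft(c(w$windowed, numeric(L - length(t))))) ^ 2) /
      (L * sum(w$windowed^2))
  })
  expect_equal(ratios, rep(1, 5), tolerance = 1e-9)
})

test_that("cohort averaging bins every frequency once with correct widths", {
  t1 <- seq(0, 1000, by = 5); t2 <- seq(0, 1600, by = 5)
  mk <- function(t, seed) {
    set.seed(seed)
    cell_ft(detrend_and_window(list(time = t, mass = rnorm(length(t)))), 25)
  }
  s1 <- mk(t1, 1); s2 <- mk(t2, 2)
  cs <- average_spectra(list(s1, s2), n_f = 1)
  expect_equal(cs$df, 1 / (1600 * 25))
  expect_equal(sum(cs$count), length(s1$freq) + length(s2$freq))
  # exhaustive counting oracle: each frequency in exactly one bin
  oracle <- tabulate(c(floor(s1$freq / cs$df), floor(s2$freq / cs$df)) + 1L,
                     length(cs$freq))
  expect_equal(cs$count, oracle)

  cs2 <- average_spectra(list(s1, s2), n_f = 2)
  expect_equal(cs2$df, 2 * cs$df)

  # identical spectra: mean equals the spectrum, SD 0
  csI <- average_spectra(list(s1, s1, s1), n_f = 1)
  j <- which(csI$count == 3)
  expect_gt(length(j), 100)
  expect_lt(max(csI$sd[j]), 1e-8)
  expect_error(average_spectra(list()), "no spectra")
})

test_that("the fundamental of the default cohort is 0.004/min within one bin", {
  fx <- default_fit()
  pk <- fx$fit$peak
  expect_true(pk$detected)
  expect_lt(abs(pk$f0 - 0.004), fx$fit$spectrum$df)
  expect_gt(pk$significance, 3)
  expect_gt(pk$harmonic_support, 1)
  # background is 1/f-like: positive power-law exponent
  expect_gt(pk$background$beta, 0.1)
})

test_that("noise-only cohorts report no significant peak", {
  rh0 <- rhythm_params(pulse_amplitude = 0)
  coh <- generate_cohort(cohort_config(n_cells = 120, seed = 77), rhythm = rh0)
  fit <- rhythm_fit(coh)
  expect_false(fit$peak$detected)
  expect_true(is.finite(fit$peak$significance))
})

test_that("injected periods across 180-360 min are recovered within one bin", {
  for (period in c(180, 250, 360)) {
    rh <- rhythm_params(period = period)
    coh <- generate_cohort(cohort_config(n_cells = 200, seed = 5 + period),
                           rhythm = rh)
    fit <- rhythm_fit(coh)
    expect_true(fit$peak$detected)
    expect_lt(abs(fit$peak$f0 - 1 / period), fit$spectrum$df,
              label = sprintf("period %d: |f0 - 1/P|", period))
  }
})

test_that("f0 is unbiased over seeded replicates (mean error below one bin)", {
  errs <- sapply(1:12, function(s) {
    coh <- generate_cohort(cohort_config(n_cells = 150, seed = 400 + s))
    fit <- rhythm_fit(coh)
    (fit$peak$f0 - 0.004) / fit$spectrum$df
  })
  expect_lt(abs(mean(errs)), 1)
})

test_that("inverse reconstruction produces the sign pair and pure tones", {
  fx <- default_fit()
  wf1 <- inverse_reconstruct(fx$fit$peak, duration = 1000, n_harmonics = 1)
  # single harmonic: a pure cosine of period 1/f0
  a <- wf1$amplitudes$amplitude_pg[1]
  expect_equal(wf1$solution_pos,
               a * cos(2 * pi * fx$fit$peak$f0 * wf1$time), tolerance = 1e-12)
  wf <- inverse_reconstruct(fx$fit$peak, duration = 2880)
  expect_equal(wf$solution_pos + wf$solution_neg, rep(0, length(wf$time)))
  expect_lte(nrow(wf$amplitudes), 6)
  # harmonics beyond the sampling Nyquist are refused
  pk_fast <- fx$fit$peak
  pk_fast$f0 <- 0.04
  expect_warning(inverse_reconstruct(pk_fast, duration = 500, dt = 5,
                                     n_harmonics = 6), "Nyquist")
})

test_that("Rice mean inversion is exact on round trips", {
  for (s in c(0, 0.5, 2, 10)) {
    m <- massrhythm:::rice_mean(s, 1.3)
    expect_equal(massrhythm:::rice_invert(m, 1.3), s, tolerance = 1e-6)
  }
  # at or below the Rayleigh mean the inferred amplitude is zero
  expect_equal(massrhythm:::rice_invert(1.3 * sqrt(pi / 2) * 0.9, 1.3), 0)
})

test_that("cohort-size scan reproduces the full fit and grows with size", {
  fx <- default_fit()
  traces <- fx$cohort$traces
  one <- cohort_size_scan(traces, sizes = length(traces), n_rep = 1)
  expect_equal(one$mean_significance, fx$fit$peak$significance,
               tolerance = 1e-9)
  expect_error(cohort_size_scan(traces, sizes = 1000), "exceed")
})

test_that("waveform spike metrics read a synthetic spike train correctly", {
  # analytic check of the measurement itself: raised-cosine train
  t <- seq(0, 2880, by = 5)
  rh <- rhythm_params()
  s <- pulse_train(t, rh, offset = 125)
  wf <- structure(list(time = t, solution_pos = s, solution_neg = -s,
                       f0 = 1 / 250, dt = 5), class = "rhythm_waveform")
  sm <- spike_metrics(wf)
  expect_equal(sm$interval_h, 250 / 60, tolerance = 1e-9)
  expect_equal(sm$height_pg, 100, tolerance = 1e-9)
  expect_equal(sm$fwhm_min, 15, tolerance = 2)   # FWHM of one raised cosine
})
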