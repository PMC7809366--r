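# Cohort Fourier statistics for rhythm detection in heterogeneous-length
# dry-mass traces: per-cell sine-windowed spectra on an M-fold oversampled
# frequency grid, bin-averaging over the cohort, power-law (1/f) background
# rejection, fundamental-peak detection, and inverse-FT reconstruction.

#' Detrend a trace and apply the sine window
#'
#' The least-squares linear trend (cell growth) is removed and the residual
#' is multiplied pointwise by the half-period sine window
#' w(t) = sin(pi (t - t0) / T), which vanishes at both ends of the record.
#'
#' @param trace a \code{"drymass_trace"} (or list with \code{time},
#'   \code{mass}).
#' @param min_samples minimum number of samples (default 16); shorter traces
#'   are rejected.
#' @return list with \code{time}, \code{windowed} (residual x window),
#'   \code{residual}, \code{window}, \code{T}, \code{dt}.
#' @export
detrend_and_window <- function(trace, min_samples = 16) {
  t <- trace$time; m <- trace$mass
  if (length(t) < min_samples)
    stop(sprintf("trace too short (%d < %d samples)", length(t), min_samples))
  fit <- stats::lm.fit(cbind(1, t), m)
  resid <- fit$residuals
  T <- t[length(t)] - t[1]
  w <- sin(pi * (t - t[1]) / T)
  list(time = t, windowed = resid * w, residual = resid, window = w,
       T = T, dt = t[2] - t[1])
}

#' Per-cell Fourier spectrum on an oversampled frequency grid
#'
#' Absolute Fourier amplitudes of the windowed series, evaluated at
#' frequencies k * df(j) with df(j) = 1 / (T(j) * M) up to the Nyquist
#' frequency, and normalized by the number of samples so that a unit
#' sinusoid contributes the same peak amplitude regardless of trace length.
#' Implemented by zero-padding to M times the record length.
#'
#' @param windowed result of \code{\link{detrend_and_window}}, or a
#'   \code{"drymass_trace"} (windowed internally).
#' @param M frequency oversampling factor (default 25).
#' @return object of class \code{"cell_spectrum"}: list with \code{freq}
#'   (min^-1), \code{amplitude} (pg), \code{df}, \code{T}, \code{M},
#'   \code{n}.
#' @export
cell_ft <- function(windowed, M = 25) {
  if (M < 1 || M != round(M)) stop("M must be a positive integer")
  if (inherits(windowed, "drymass_trace")) windowed <- detrend_and_window(windowed)
  y <- windowed$windowed
  n <- length(y)
  T <- windowed$T
  df <- 1 / (T * M)
  L <- (n - 1L) * M                 # pad so the FFT grid step is exactly df
  amp_all <- Mod(stats::fft(c(y, numeric(L - n)))) / n
  nyq <- 1 / (2 * windowed$dt)
  K <- floor(nyq / df)
  K <- min(K, L - 1L)
  structure(list(freq = (1:K) * df, amplitude = amp_all[2:(K + 1L)],
                 df = df, T = T, M = M, n = n),
            class = "cell_spectrum")
}

#' @export
print.cell_spectrum <- function(x, ...) {
  cat(sprintf("<cell_spectrum> T=%g min, df=%.3g min^-1, %d frequencies up to %.3g min^-1\n",
              x$T, x$df, length(x$freq), max(x$freq)))
  invisible(x)
}

#' Average per-cell spectra into a cohort spectrum
#'
#' All per-cell amplitudes are accumulated into common frequency bins of
#' width df = n_f / (T_max * M), where T_max is the longest trace duration;
#' every per-cell grid frequency falls in exactly one bin. Per bin, the mean
#' absolute amplitude, its standard deviation and the contribution count are
#' returned. Because every cell's amplitudes are already normalized by its
#' own trace length, and bins divide by their own counts, cells of different
#' lengths and bins of different populations are comparable.
#'
#' @param spectra list of \code{"cell_spectrum"} objects.
#' @param n_f bin-size integer (1 or 2 typically).
#' @return object of class \code{"cohort_spectrum"}: data.frame-backed list
#'   with \code{freq} (bin centers), \code{mean}, \code{sd}, \code{count},
#'   plus \code{df}, \code{T_max}, \code{M}, \code{n_cells}.
#' @export
average_spectra <- function(spectra, n_f = 1) {
  if (length(spectra) == 0) stop("no spectra to average")
  if (!n_f %in% c(1, 2)) {
    if (n_f < 1 || n_f != round(n_f)) stop("n_f must be a positive integer")
  }
  T_max <- max(vapply(spectra, function(s) s$T, numeric(1)))
  M <- spectra[[1]]$M
  df <- n_f / (T_max * M)
  fmax <- max(vapply(spectra, function(s) max(s$freq), numeric(1)))
  nbins <- ceiling(fmax / df) + 1L
  ball <- unlist(lapply(spectra, function(s)
    pmin(floor(s$freq / df) + 1L, nbins)), use.names = FALSE)
  aall <- unlist(lapply(spectra, function(s) s$amplitude), use.names = FALSE)
  s1 <- numeric(nbins); s2 <- numeric(nbins)
  sums <- rowsum(cbind(aall, aall^2), ball)
  idx <- as.integer(rownames(sums))
  s1[idx] <- sums[, 1]; s2[idx] <- sums[, 2]
  cnt <- tabulate(ball, nbins)
  nz <- cnt > 0
  mean_ <- ifelse(nz, s1 / pmax(cnt, 1L), NA_real_)
  var_ <- ifelse(cnt > 1, (s2 - cnt * mean_^2) / (cnt - 1L), NA_real_)
  structure(list(freq = (seq_len(nbins) - 0.5) * df, mean = mean_,
                 sd = sqrt(pmax(var_, 0)), count = cnt, df = df,
                 T_max = T_max,
                 T_med = stats::median(vapply(spectra, function(s) s$T,
                                              numeric(1))),
                 M = M, n_f = n_f, n_cells = length(spectra)),
            class = "cohort_spectrum")
}

#' @export
print.cohort_spectrum <- function(x, ...) {
  cat(sprintf("<cohort_spectrum> %d cells, %d bins of df=%.3g min^-1 (T_max=%g, M=%d, n_f=%d)\n",
              x$n_cells, length(x$freq), x$df, x$T_max, x$M, x$n_f))
  invisible(x)
}

# Iterative background fit, masking candidate peak bins (> 3 SE above the
# fit) and refitting. The mean-amplitude background is modeled as a power
# law plus a white floor adding in quadrature,
#     A(f) = sqrt((c f^-beta)^2 + w^2),
# because incoherent noise components add in power, not amplitude: a 1/f
# component dominates the low frequencies and flat measurement noise the
# high ones. (A single log-log line through such a mixture is convex-biased:
# it sits below the data at both band edges, which fakes significant excess
# there and tilts the peak region.)
fit_background <- function(cohort, band, z_mask = 3, max_iter = 10) {
  inband <- which(cohort$freq >= band[1] & cohort$freq <= band[2] &
                    cohort$count > 0 & cohort$mean > 0)
  if (length(inband) < 10) stop("fewer than 10 populated bins in the band")
  f <- cohort$freq[inband]; y <- cohort$mean[inband]
  lx <- log(f); ly <- log(y)
  se <- cohort$sd[inband] / sqrt(pmax(cohort$count[inband], 1))
  se[!is.finite(se) | se <= 0] <- Inf   # bins with a single contribution
  model <- function(p, f) sqrt((exp(p[1]) * f^(-p[2]))^2 + exp(2 * p[3]))
  # initialization: slope from the lower half-band, floor from the top decile
  lo <- f <= stats::median(f)
  init_line <- stats::lm.fit(cbind(1, lx[lo]), ly[lo])$coefficients
  w0 <- log(stats::quantile(y[f >= 0.9 * max(f)], 0.5, names = FALSE))
  par <- c(init_line[1], -init_line[2], w0)
  masked <- rep(FALSE, length(inband))
  for (it in seq_len(max_iter)) {
    use <- !masked
    obj <- function(p) {
      # box guard: the two flat components are degenerate on white spectra
      # and can push parameters to overflow
      if (any(!is.finite(p)) || abs(p[1]) > 50 || abs(p[3]) > 50 ||
          p[2] < -2 || p[2] > 6) return(1e12)
      v <- log(model(p, f[use]))
      if (any(!is.finite(v))) return(1e12)
      sum((v - ly[use])^2)
    }
    par <- stats::optim(par, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-10))$par
    bg <- model(par, f)
    z <- (y - bg) / pmax(se, 1e-12)
    new_mask <- z > z_mask
    if (identical(new_mask, masked)) break
    masked <- new_mask
  }
  list(log_c = unname(par[1]), beta = unname(par[2]),
       log_w = unname(par[3]), inband = inband, bg = bg, z = z,
       masked = masked, se = se)
}

#' Fitted background level at given frequencies
#'
#' Evaluates the cohort background model (power law plus white floor in
#' quadrature) stored in a peak report.
#'
#' @param peak a \code{"peak_report"}.
#' @param freq frequencies (min^-1).
#' @return background mean-amplitude values.
#' @export
background_at <- function(peak, freq) {
  b <- peak$background
  sqrt((exp(b$log_c) * freq^(-b$beta))^2 + exp(2 * b$log_w))
}

#' Detect the fundamental rhythm peak in a cohort spectrum
#'
#' Fits a power-law background c * f^-beta by iterated log-log least squares
#' (bins more than 3 standard errors above the fit are excluded and the fit
#' repeated), then locates the fundamental as the maximum background excess
#' within the search band. The per-bin significance is
#' (mean - background) / (sd / sqrt(count)); the peak is "detected" when its
#' significance exceeds \code{z_detect} (default 3). Harmonic amplitudes are
#' read near integer multiples of the fundamental (within half a spectral
#' resolution width).
#'
#' @param cohort a \code{"cohort_spectrum"}.
#' @param band numeric length-2 search band in min^-1 (default
#'   c(0.001, 0.02)).
#' @param z_detect detection threshold on the significance.
#' @param n_harmonics harmonics (m = 2, 3, ...) to report.
#' @param min_support minimum number of higher-harmonic lobes (m >= 2) the
#'   comb refinement must find for a detection: a rhythm peak appears along
#'   with its harmonics, a background bump does not.
#' @return object of class \code{"peak_report"}: \code{f0} (min^-1),
#'   \code{period} (min), \code{AF} (pg), \code{significance},
#'   \code{detected}, \code{harmonics} (data.frame m/freq/amplitude/
#'   background), \code{background} (log_c, beta), \code{window_gain},
#'   \code{df}, \code{band}.
#' @export
find_fundamental <- function(cohort, band = c(0.001, 0.02), z_detect = 3,
                             n_harmonics = 6, min_support = 2) {
  bgfit <- fit_background(cohort, band)
  inband <- bgfit$inband
  excess <- cohort$mean[inband] - bgfit$bg
  # Candidate peaks: contiguous clusters of significant bins (a peak spans
  # about one window main lobe, i.e. several cohort bins). The fundamental
  # is the first (lowest-frequency) significant cluster; higher significant
  # clusters are its harmonics.
  # nearest populated bin to a frequency
  at_bin <- function(fm) {
    sel <- which(cohort$count > 0)
    sel[which.min(abs(cohort$freq[sel] - fm))]
  }
  bg_model <- function(fr)
    sqrt((exp(bgfit$log_c) * fr^(-bgfit$beta))^2 + exp(2 * bgfit$log_w))
  T_typ <- cohort$T_med %||% cohort$T_max
  halfw <- 0.75 / T_typ                # half main-lobe width, typical trace
  fb <- cohort$freq[inband]

  # comb refinement: the m-th harmonic lobe sits at m*f0, so its centroid
  # locates f0 with m-fold leverage. Within each harmonic window the excess
  # is first detrended by a line fitted to the window flanks (removing
  # smooth leakage tilt that would drag the centroid), then the centroid of
  # the top half of the lobe is taken; per-harmonic estimates are combined
  # with Fisher-style weights (lobe height x leverage)^2 and the windows
  # re-centered on the improving estimate. Returns the refined f0 and the
  # number of higher-harmonic lobes that supported it.
  refine_comb <- function(f0) {
    est_last <- NULL
    for (pass in 1:4) {
      est <- do.call(rbind, lapply(seq_len(n_harmonics), function(m) {
        win <- which(abs(fb - m * f0) <= 1.3 * halfw)
        if (length(win) < 8) return(NULL)
        d <- fb[win] - m * f0
        flank <- abs(d) >= 0.8 * halfw
        if (sum(flank) < 4) return(NULL)
        lf <- stats::lm.fit(cbind(1, d[flank]),
                            excess[win][flank])$coefficients
        ex <- excess[win] - (lf[1] + lf[2] * d)
        pk_loc <- max(ex)
        if (!is.finite(pk_loc) ||
            pk_loc <= z_detect * stats::median(bgfit$se[win]))
          return(NULL)
        sel <- ex >= pk_loc / 2 & abs(d) < 0.8 * halfw
        if (!any(sel) || sum(ex[sel]) <= 0) return(NULL)
        f0m <- sum(fb[win][sel] * ex[sel]) / sum(ex[sel]) / m
        if (!is.finite(f0m)) return(NULL)
        data.frame(m = m, f0m = f0m, w = (m * pk_loc)^2)
      }))
      if (is.null(est) || nrow(est) == 0) break
      est_last <- est
      f0_new <- sum(est$f0m * est$w) / sum(est$w)
      if (!is.finite(f0_new)) break
      if (abs(f0_new - f0) < cohort$df / 10) { f0 <- f0_new; break }
      f0 <- f0_new
    }
    list(f0 = f0,
         support = if (is.null(est_last)) 0L else sum(est_last$m >= 2))
  }
  # significance of the refined fundamental at its bin
  z_at <- function(f0) {
    j <- at_bin(f0)
    se <- cohort$sd[j] / sqrt(max(cohort$count[j], 1))
    if (!is.finite(se) || se <= 0) se <- Inf  # single-contribution bin
    (cohort$mean[j] - bg_model(cohort$freq[j])) / max(se, 1e-12)
  }

  # Candidate peaks: contiguous clusters of significant bins (a peak spans
  # about one window main lobe, i.e. several cohort bins), in frequency
  # order. The fundamental is the first cluster that survives the comb
  # refinement: its refined bin stays significant and it appears together
  # with at least min_support higher-harmonic lobes -- a rhythm peak comes
  # "along with its harmonics", a background bump does not (and a bump
  # below the true fundamental is skipped rather than ending the search).
  sig <- which(bgfit$z > z_detect)
  detected <- FALSE
  f0 <- NA_real_; z0 <- NA_real_; harmonic_support <- 0L
  if (length(sig)) {
    gap_bins <- max(1L, ceiling((0.75 / cohort$T_max) / cohort$df))
    cluster <- cumsum(c(1L, diff(sig) > gap_bins))
    for (cl in unique(cluster)) {
      members <- sig[cluster == cl]
      ipk <- members[which.max(excess[members])]
      # initial centroid over the top half of the cluster lobe
      top <- members[excess[members] >= excess[ipk] / 2]
      f0_try <- sum(fb[top] * excess[top]) / sum(excess[top])
      ref <- refine_comb(f0_try)
      z_try <- z_at(ref$f0)
      if (is.finite(z_try) && z_try > z_detect &&
          ref$support >= min_support) {
        f0 <- ref$f0; z0 <- z_try; harmonic_support <- ref$support
        detected <- TRUE
        break
      }
    }
  }
  if (!detected) {
    ipk <- if (length(sig)) sig[which.max(bgfit$z[sig])]
           else which.max(bgfit$z)
    f0 <- cohort$freq[inband[ipk]]    # best bin, reported as non-detection
    z0 <- bgfit$z[ipk]
    harmonic_support <- 0L
  }
  AF <- cohort$mean[at_bin(f0)]
  # harmonic amplitudes: count-weighted mean over the flat top of each
  # harmonic lobe (within ~0.2/T of the center the window response is above
  # 0.95); single bins can be sparsely populated by the beating of the
  # per-cell frequency grids against the common bins
  pool_hw <- 0.2 / (cohort$T_med %||% cohort$T_max)
  harmonics <- do.call(rbind, lapply(seq_len(n_harmonics), function(m) {
    fm <- m * f0
    if (fm > max(cohort$freq))
      return(data.frame(m = m, freq = fm, amplitude = NA_real_,
                        background = NA_real_))
    sel <- which(abs(cohort$freq - fm) <= pool_hw & cohort$count > 0)
    if (!length(sel)) sel <- at_bin(fm)
    amp <- sum(cohort$mean[sel] * cohort$count[sel]) / sum(cohort$count[sel])
    data.frame(m = m, freq = fm, amplitude = amp,
               background = bg_model(fm))
  }))
  structure(list(f0 = f0, period = 1 / f0, AF = AF, significance = z0,
                 detected = detected, harmonic_support = harmonic_support,
                 harmonics = harmonics,
                 background = list(log_c = bgfit$log_c, beta = bgfit$beta,
                                   log_w = bgfit$log_w),
                 window_gain = 2 / pi, df = cohort$df, T_max = cohort$T_max,
                 band = band, z_detect = z_detect,
                 n_cells = cohort$n_cells),
            class = "peak_report")
}

#' @export
print.peak_report <- function(x, ...) {
  cat(sprintf("<peak_report> f0 = %.5g min^-1 (period %.1f min = %.2f h)\n",
              x$f0, x$period, x$period / 60))
  cat(sprintf("  AF = %.3g pg, significance = %.1f (%s), background f^-%.2f\n",
              x$AF, x$significance,
              if (x$detected) "detected" else "no significant peak",
              x$background$beta))
  invisible(x)
}

# Mean of a Rice distribution with coherent amplitude s and per-component
# noise sd sigma (exponentially scaled Bessel functions for stability).
rice_mean <- function(s, sigma) {
  if (sigma <= 0) return(s)
  x <- s^2 / (2 * sigma^2)
  sigma * sqrt(pi / 2) *
    ((1 + x) * besselI(x / 2, 0, expon.scaled = TRUE) +
       x * besselI(x / 2, 1, expon.scaled = TRUE))
}

# Invert the Rice mean: coherent amplitude whose expected absolute amplitude
# under noise sigma equals the observed mean. Returns 0 when the observed
# mean does not exceed the noise-only (Rayleigh) mean.
rice_invert <- function(mean_obs, sigma) {
  if (!is.finite(mean_obs) || sigma <= 0) return(max(mean_obs, 0))
  if (mean_obs <= sigma * sqrt(pi / 2)) return(0)
  upper <- mean_obs + 4 * sigma
  stats::uniroot(function(s) rice_mean(s, sigma) - mean_obs,
                 c(0, upper), tol = 1e-10)$root
}

#' Reconstruct the rhythm waveform by inverse Fourier transform
#'
#' Harmonic amplitudes are estimated from the cohort spectrum by inverting
#' the Rician mean: the observed bin mean is the expected absolute amplitude
#' of a coherent harmonic embedded in incoherent background noise whose
#' scale is set by the fitted background (Rayleigh mean). Subtracting the
#' background linearly would bias the signal low, because the amplitude of
#' signal plus noise is not the sum of the two amplitudes; the inversion is
#' unbiased to first order. Estimates are then converted to physical cosine
#' amplitudes by dividing by the sine-window gain (2/pi) and the 1/2 cosine
#' split. Cohort averaging keeps only absolute amplitudes, so all harmonics
#' are cosine-aligned at t = 0 and the sign of the waveform is undetermined:
#' both solutions (mass-gain pulses and mass-loss pulses) are returned.
#'
#' @param peak a \code{"peak_report"} from \code{\link{find_fundamental}}.
#' @param duration length of the reconstructed record, minutes.
#' @param dt time step of the reconstruction, minutes.
#' @param n_harmonics harmonics to use; defaults to all with positive
#'   background-excluded amplitude, capped at 6. Harmonics beyond the
#'   Nyquist frequency of the sampling are dropped with a warning.
#' @return object of class \code{"rhythm_waveform"}: \code{time},
#'   \code{solution_pos}, \code{solution_neg} (pg), \code{amplitudes}
#'   (per-harmonic physical cosine amplitudes), \code{f0}.
#' @export
inverse_reconstruct <- function(peak, duration = 2880, dt = 5,
                                n_harmonics = NULL) {
  h <- peak$harmonics
  a_meas <- vapply(seq_len(nrow(h)), function(i) {
    if (!is.finite(h$amplitude[i])) return(NA_real_)
    rice_invert(h$amplitude[i], h$background[i] / sqrt(pi / 2))
  }, numeric(1))
  a_phys <- a_meas * 2 / peak$window_gain      # undo window gain and cosine split
  keep <- which(is.finite(a_phys) & a_phys > 0)
  cap <- n_harmonics %||% 6
  keep <- keep[h$m[keep] <= cap]
  nyq <- 1 / (2 * dt)
  over <- h$m[keep] * peak$f0 > nyq
  if (any(over)) {
    warning("harmonics beyond the Nyquist frequency dropped")
    keep <- keep[!over]
  }
  time <- seq(0, duration, by = dt)
  s <- rep(0, length(time))
  for (i in keep)
    s <- s + a_phys[i] * cos(2 * pi * h$m[i] * peak$f0 * time)
  structure(list(time = time, solution_pos = s, solution_neg = -s,
                 amplitudes = data.frame(m = h$m[keep],
                                         amplitude_pg = a_phys[keep]),
                 f0 = peak$f0, dt = dt),
            class = "rhythm_waveform")
}

#' @export
print.rhythm_waveform <- function(x, ...) {
  sm <- spike_metrics(x)
  cat(sprintf("<rhythm_waveform> %d harmonics, period %.1f min; spikes: interval %.2f h, FWHM %.0f min, height %.0f pg\n",
              nrow(x$amplitudes), 1 / x$f0, sm$interval_h, sm$fwhm_min,
              sm$height_pg))
  invisible(x)
}

#' Spike metrics of a reconstructed waveform
#'
#' Locates spikes as local maxima above half of the global peak-to-baseline
#' range (baseline = waveform minimum), and reports the mean inter-spike
#' interval, the full width at half maximum of the spike nearest the record
#' midpoint (linear interpolation between samples), and the peak-to-baseline
#' height.
#'
#' @param waveform a \code{"rhythm_waveform"} (the positive solution is
#'   measured; the negative one is its mirror image).
#' @return list with \code{interval_h} (hours), \code{fwhm_min} (minutes),
#'   \code{height_pg} (pg), \code{spike_times} (minutes).
#' @export
spike_metrics <- function(waveform) {
  t <- waveform$time; s <- waveform$solution_pos
  base <- min(s); pk <- max(s)
  height <- pk - base
  half <- base + height / 2
  n <- length(s)
  locmax <- which(s > half & s >= c(-Inf, s[-n]) & s >= c(s[-1], Inf))
  # collapse plateaus / ripple within a quarter period
  if (length(locmax) > 1) {
    keep <- c(TRUE, diff(t[locmax]) > 0.25 / waveform$f0)
    locmax <- locmax[keep]
  }
  spike_times <- t[locmax]
  interval_h <- if (length(spike_times) > 1) mean(diff(spike_times)) / 60
                else NA_real_
  # FWHM of the spike nearest the record midpoint
  mid <- t[n] / 2
  ctr <- locmax[which.min(abs(t[locmax] - mid))]
  cross <- function(dir) {
    i <- ctr
    while (i + dir >= 1 && i + dir <= n && s[i + dir] > half) i <- i + dir
    j <- i + dir
    if (j < 1 || j > n) return(t[i])
    # linear interpolation to the half-maximum crossing
    t[i] + dir * (s[i] - half) / (s[i] - s[j]) * abs(t[j] - t[i])
  }
  fwhm <- abs(cross(1L) - cross(-1L))
  list(interval_h = interval_h, fwhm_min = fwhm, height_pg = height,
       spike_times = spike_times)
}

#' Significance as a function of cohort size
#'
#' Subsamples the supplied traces at each requested size (\code{n_rep}
#' times), recomputes the cohort spectrum and fundamental peak, and reports
#' the mean significance per size. With a coherent rhythm present the
#' significance grows with cohort size (the background fluctuations of the
#' mean spectrum average down as 1/sqrt(n)).
#'
#' @param traces list of \code{"drymass_trace"} objects.
#' @param sizes integer cohort sizes to test.
#' @param n_rep subsample replicates per size.
#' @param seed integer seed.
#' @param M,n_f,band spectral parameters, see \code{\link{cell_ft}},
#'   \code{\link{average_spectra}}, \code{\link{find_fundamental}}.
#' @return data.frame with \code{size}, \code{mean_significance},
#'   \code{sd_significance}, \code{detect_rate}.
#' @export
cohort_size_scan <- function(traces, sizes, n_rep = 5, seed = 1, M = 25,
                             n_f = 1, band = c(0.001, 0.02)) {
  if (any(sizes > length(traces))) stop("sizes exceed the number of traces")
  spectra <- lapply(traces, function(tr) cell_ft(detrend_and_window(tr), M))
  out <- lapply(sizes, function(sz) {
    zs <- vapply(seq_len(n_rep), function(r) {
      set.seed(derive_seed(seed, sz * 1000L + r))
      idx <- if (sz == length(traces) && n_rep == 1) seq_along(traces)
             else sample(length(traces), sz)
      pk <- find_fundamental(average_spectra(spectra[idx], n_f), band)
      c(pk$significance, as.numeric(pk$detected))
    }, numeric(2))
    data.frame(size = sz, mean_significance = mean(zs[1, ]),
               sd_significance = stats::sd(zs[1, ]),
               detect_rate = mean(zs[2, ]))
  })
  do.call(rbind, out)
}
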