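# The central model interface: fit the cohort rhythm model to a set of
# single-cell dry-mass traces and expose it through the usual S3 methods.

#' Fit the cohort ultradian-rhythm model to dry-mass traces
#'
#' Runs the full spectral chain: each trace is linearly detrended and
#' sine-windowed (\code{\link{detrend_and_window}}), transformed on its own
#' oversampled frequency grid (\code{\link{cell_ft}}), the cohort spectrum is
#' bin-averaged (\code{\link{average_spectra}}), and the fundamental peak is
#' detected against the fitted 1/f-plus-floor background
#' (\code{\link{find_fundamental}}).
#'
#' @param traces a \code{"drymass_cohort"}, or a list of
#'   \code{"drymass_trace"} objects.
#' @param M frequency oversampling factor (default 25).
#' @param n_f bin-size integer for cohort averaging (1 or 2).
#' @param band search band for the fundamental, min^-1.
#' @param min_samples traces shorter than this many samples are excluded
#'   (with a recorded reason).
#' @param ... passed on to \code{\link{find_fundamental}}.
#' @return an object of class \code{"rhythm_fit"} with components
#'   \code{peak} (the \code{"peak_report"}), \code{spectrum} (the
#'   \code{"cohort_spectrum"}), \code{spectra} (per-cell spectra),
#'   \code{n_traces}, \code{excluded}, \code{call}.
#' @examples
#' coh <- generate_cohort(cohort_config(n_cells = 40, seed = 1))
#' fit <- rhythm_fit(coh)
#' coef(fit)
#' @export
rhythm_fit <- function(traces, M = 25, n_f = 1, band = c(0.001, 0.02),
                       min_samples = 16, ...) {
  cl <- match.call()
  if (inherits(traces, "drymass_cohort")) traces <- traces$traces
  if (!length(traces)) stop("no traces supplied")
  ok <- vapply(traces, function(tr) length(tr$time) >= min_samples, logical(1))
  excluded <- which(!ok)
  if (!any(ok)) stop("all traces shorter than min_samples")
  spectra <- lapply(traces[ok], function(tr)
    cell_ft(detrend_and_window(tr, min_samples), M))
  spectrum <- average_spectra(spectra, n_f)
  peak <- find_fundamental(spectrum, band, ...)
  structure(list(peak = peak, spectrum = spectrum, spectra = spectra,
                 n_traces = sum(ok), excluded = excluded, band = band,
                 M = M, n_f = n_f, call = cl),
            class = "rhythm_fit")
}

#' @export
print.rhythm_fit <- function(x, ...) {
  cat("Cohort rhythm fit\n")
  cat(sprintf("  %d traces (%d excluded), bins of %.3g min^-1\n",
              x$n_traces, length(x$excluded), x$spectrum$df))
  if (x$peak$detected) {
    cat(sprintf("  fundamental: %.5g min^-1 (period %.2f h), AF = %.3g pg, significance %.1f\n",
                x$peak$f0, x$peak$period / 60, x$peak$AF, x$peak$significance))
  } else {
    cat(sprintf("  no significant peak (best bin significance %.2f)\n",
                x$peak$significance))
  }
  invisible(x)
}

#' @export
summary.rhythm_fit <- function(object, ...) {
  out <- list(coef = coef.rhythm_fit(object),
              harmonics = object$peak$harmonics,
              n_traces = object$n_traces,
              excluded = length(object$excluded),
              detected = object$peak$detected,
              harmonic_support = object$peak$harmonic_support,
              band = object$band)
  class(out) <- "summary.rhythm_fit"
  out
}

#' @export
print.summary.rhythm_fit <- function(x, ...) {
  cat("Cohort rhythm model\n\nCoefficients:\n")
  print(round(x$coef, 5))
  cat(sprintf("\nDetected: %s (harmonic support: %d)\n",
              x$detected, x$harmonic_support))
  cat(sprintf("Traces: %d used, %d excluded; band %.3g-%.3g min^-1\n",
              x$n_traces, x$excluded, x$band[1], x$band[2]))
  cat("\nHarmonics:\n")
  print(x$harmonics, digits = 4)
  invisible(x)
}

#' @export
coef.rhythm_fit <- function(object, ...) {
  p <- object$peak
  c(f0 = p$f0, period_min = p$period, AF = p$AF,
    significance = p$significance,
    bg_log_c = p$background$log_c, bg_beta = p$background$beta,
    bg_floor = exp(p$background$log_w))
}

#' Predicted rhythm waveform of a fitted model
#'
#' Returns the inverse-Fourier reconstruction of the detected rhythm
#' evaluated at the requested times (both sign solutions).
#'
#' @param object a \code{"rhythm_fit"}.
#' @param times minutes (default: 48 h at 5-min steps).
#' @param n_harmonics see \code{\link{inverse_reconstruct}}.
#' @param ... unused.
#' @return data.frame with \code{time}, \code{solution_pos},
#'   \code{solution_neg}.
#' @export
predict.rhythm_fit <- function(object, times = seq(0, 2880, by = 5),
                               n_harmonics = NULL, ...) {
  dt <- if (length(times) > 1) times[2] - times[1] else 5
  wf <- inverse_reconstruct(object$peak, duration = max(times), dt = dt,
                            n_harmonics = n_harmonics)
  idx <- match(round(times, 9), round(wf$time, 9))
  data.frame(time = times, solution_pos = wf$solution_pos[idx],
             solution_neg = wf$solution_neg[idx])
}

#' Simulate cohorts from a fitted rhythm model
#'
#' Generates synthetic dry-mass cohorts whose injected rhythm matches the
#' fitted fundamental (period from 1/f0, pulse amplitude from the
#' reconstructed spike height), useful for parametric-bootstrap checks.
#'
#' @param object a \code{"rhythm_fit"}.
#' @param nsim number of cohorts.
#' @param seed integer seed.
#' @param n_cells cells per simulated cohort.
#' @param ... passed to \code{\link{cohort_config}}.
#' @return a list of \code{"drymass_cohort"} objects (length \code{nsim}).
#' @export
simulate.rhythm_fit <- function(object, nsim = 1, seed = 1, n_cells = NULL,
                                ...) {
  n_cells <- n_cells %||% object$n_traces
  wf <- inverse_reconstruct(object$peak)
  amp <- spike_metrics(wf)$height_pg
  rhythm <- rhythm_params(period = round(object$peak$period),
                          pulse_amplitude = max(amp, 0))
  lapply(seq_len(nsim), function(k)
    generate_cohort(cohort_config(n_cells = n_cells,
                                  seed = derive_seed(seed, k), ...),
                    rhythm = rhythm))
}

#' Plot a fitted cohort spectrum
#'
#' Log-log cohort spectrum with the fitted background, the detected
#' fundamental marked by an asterisk, and harmonic positions ticked.
#'
#' @param x a \code{"rhythm_fit"}.
#' @param ... passed to \code{plot.default}.
#' @export
plot.rhythm_fit <- function(x, ...) {
  cs <- x$spectrum
  sel <- cs$count > 0 & cs$freq >= x$band[1] / 2 & cs$freq <= x$band[2] * 2
  plot(cs$freq[sel], cs$mean[sel], log = "xy", type = "l", col = "grey40",
       xlab = expression(frequency ~ (min^-1)),
       ylab = "mean |amplitude| (pg)", ...)
  fgrid <- exp(seq(log(min(cs$freq[sel])), log(max(cs$freq[sel])),
                   length.out = 200))
  graphics::lines(fgrid, background_at(x$peak, fgrid), col = "steelblue",
                  lwd = 2)
  if (x$peak$detected) {
    graphics::points(x$peak$f0, x$peak$AF, pch = 8, cex = 1.6, col = "red")
    h <- x$peak$harmonics
    graphics::points(h$freq, h$amplitude, pch = 1, col = "red")
  }
  invisible(x)
}

#' Residual spectrum of a fitted rhythm model
#'
#' Background-excess amplitudes (mean minus fitted background) over the
#' search band; under a pure-noise cohort these fluctuate around zero.
#'
#' @param object a \code{"rhythm_fit"}.
#' @param ... unused.
#' @return data.frame with \code{freq}, \code{excess}, \code{se}.
#' @export
residuals.rhythm_fit <- function(object, ...) {
  cs <- object$spectrum
  sel <- which(cs$freq >= object$band[1] & cs$freq <= object$band[2] &
                 cs$count > 0)
  data.frame(freq = cs$freq[sel],
             excess = cs$mean[sel] - background_at(object$peak, cs$freq[sel]),
             se = cs$sd[sel] / sqrt(pmax(cs$count[sel], 1)))
}
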