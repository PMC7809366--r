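#' Rhythm parameters for the synthetic dry-mass generator
#'
#' Describes the injected ultradian pulse train: symmetric pulses of full width
#' \code{pulse_width} minutes repeating every \code{period} minutes, with
#' peak height \code{pulse_amplitude} picograms. The defaults correspond to
#' the rhythm class the analysis chain is designed to detect: ~30 min wide
#' ~100 pg pulses every 250 min (0.004 min^-1).
#'
#' @param period pulse repetition period in minutes.
#' @param pulse_width full pulse width in minutes; must be < \code{period}.
#' @param pulse_amplitude pulse height in pg; 0 yields a rhythm-free trace.
#' @param pulse_shape \code{"raised-cosine"} (default, band-limited) or
#'   \code{"triangular"}.
#' @param pulse_sign +1 for mass-gain pulses, -1 for mass-loss pulses. The
#'   cohort spectrum cannot distinguish the two (see
#'   \code{\link{inverse_reconstruct}}).
#' @return an object of class \code{"rhythm_params"}.
#' @export
rhythm_params <- function(period = 250, pulse_width = 30, pulse_amplitude = 100,
                          pulse_shape = c("raised-cosine", "triangular"),
                          pulse_sign = 1) {
  pulse_shape <- match.arg(pulse_shape)
  stopifnot_scalar(period, "period", positive = TRUE)
  stopifnot_scalar(pulse_width, "pulse_width", positive = TRUE)
  stopifnot_scalar(pulse_amplitude, "pulse_amplitude", nonneg = TRUE)
  if (!pulse_sign %in% c(-1, 1)) stop("pulse_sign must be +1 or -1")
  if (period <= pulse_width) stop("period must exceed pulse_width")
  structure(list(period = period, pulse_width = pulse_width,
                 pulse_amplitude = pulse_amplitude, pulse_shape = pulse_shape,
                 pulse_sign = pulse_sign),
            class = "rhythm_params")
}

#' Growth and noise parameters for the synthetic dry-mass generator
#'
#' The deterministic part of a trace is a linear growth background
#' \code{initial_mass + growth_rate * t}. Stochastic components are a 1/f
#' ("pink") noise term with RMS \code{pink_noise_rms} whose amplitude spectrum
#' falls as \code{f^(-pink_noise_exponent/2)}, and white measurement noise with
#' standard deviation \code{measurement_noise_sd} (default 35 pg, the
#' instrument precision the imaging chain is calibrated to).
#'
#' @param initial_mass starting dry mass in pg.
#' @param growth_rate linear growth rate in pg/min.
#' @param pink_noise_rms RMS of the 1/f noise component in pg.
#' @param pink_noise_exponent power-law exponent of the noise power spectrum;
#'   the amplitude spectrum falls as \code{f^(-exponent/2)}.
#' @param measurement_noise_sd white measurement noise SD in pg.
#' @return an object of class \code{"growth_noise_params"}.
#' @export
growth_noise_params <- function(initial_mass = 300, growth_rate = 0.25,
                                pink_noise_rms = 30, pink_noise_exponent = 1,
                                measurement_noise_sd = 35) {
  stopifnot_scalar(initial_mass, "initial_mass", positive = TRUE)
  stopifnot_scalar(growth_rate, "growth_rate")
  stopifnot_scalar(pink_noise_rms, "pink_noise_rms", nonneg = TRUE)
  stopifnot_scalar(pink_noise_exponent, "pink_noise_exponent", nonneg = TRUE)
  stopifnot_scalar(measurement_noise_sd, "measurement_noise_sd", nonneg = TRUE)
  structure(list(initial_mass = initial_mass, growth_rate = growth_rate,
                 pink_noise_rms = pink_noise_rms,
                 pink_noise_exponent = pink_noise_exponent,
                 measurement_noise_sd = measurement_noise_sd),
            class = "growth_noise_params")
}

#' Cohort configuration for the synthetic generator
#'
#' @param n_cells number of cells (founder tracks) in the cohort.
#' @param sampling_interval sampling step in minutes (default 5, matching the
#'   acquisition cadence the analysis assumes).
#' @param duration total observation span in minutes.
#' @param cycle_median median interphase (cell-cycle) duration in minutes of
#'   the lognormal cycle-length distribution.
#' @param cycle_sdlog log-scale SD of the cycle-length distribution.
#' @param seed master seed; per-cell substreams are derived deterministically.
#' @param field_px side of the square pixel field used when the cohort is
#'   rendered into images.
#' @param motility_sd_px per-frame random-walk step SD, pixels.
#' @return an object of class \code{"cohort_config"}.
#' @export
cohort_config <- function(n_cells, sampling_interval = 5, duration = 4320,
                          cycle_median = 1200, cycle_sdlog = 0.25, seed = 1,
                          field_px = 256, motility_sd_px = 0.7) {
  stopifnot_scalar(n_cells, "n_cells", positive = TRUE)
  if (n_cells != round(n_cells)) stop("n_cells must be an integer")
  stopifnot_scalar(sampling_interval, "sampling_interval", positive = TRUE)
  stopifnot_scalar(duration, "duration", positive = TRUE)
  stopifnot_scalar(cycle_median, "cycle_median", positive = TRUE)
  stopifnot_scalar(cycle_sdlog, "cycle_sdlog", nonneg = TRUE)
  structure(list(n_cells = as.integer(n_cells),
                 sampling_interval = sampling_interval, duration = duration,
                 cycle_median = cycle_median, cycle_sdlog = cycle_sdlog,
                 seed = as.integer(seed), field_px = as.integer(field_px),
                 motility_sd_px = motility_sd_px),
            class = "cohort_config")
}

#' Detection and linking configuration for cell tracking
#'
#' Defaults mirror the standard single-particle tracking setup used for
#' lens-free phase images: blob diameter 15 px, detector threshold 0.7 on the
#' normalized response, 15 px maximum linking and gap-closing distances, up to
#' 5 missed frames bridged by gap closing, and a minimum of 10 spots per
#' retained track.
#'
#' @param blob_diameter_px estimated cell blob diameter, pixels.
#' @param detector_threshold threshold on the detector response normalized to
#'   the image maximum (in `[0,1]`).
#' @param max_link_px maximum frame-to-frame linking distance, pixels.
#' @param gap_close_px maximum gap-closing distance, pixels.
#' @param max_frame_gap maximum number of consecutive missed frames that gap
#'   closing may bridge.
#' @param min_spots minimum number of detections for a track to be kept.
#' @return an object of class \code{"linking_config"}.
#' @export
linking_config <- function(blob_diameter_px = 15, detector_threshold = 0.7,
                           max_link_px = 15, gap_close_px = 15,
                           max_frame_gap = 5, min_spots = 10) {
  vals <- list(blob_diameter_px = blob_diameter_px,
               detector_threshold = detector_threshold,
               max_link_px = max_link_px, gap_close_px = gap_close_px,
               max_frame_gap = max_frame_gap, min_spots = min_spots)
  for (nm in names(vals)) stopifnot_scalar(vals[[nm]], nm, positive = TRUE)
  structure(vals, class = "linking_config")
}
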