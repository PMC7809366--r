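# Synthetic dry-mass trajectory generator: the ground-truthed signal class the
# downstream spectral analysis is designed to detect.

#' 1/f (pink) noise by spectral shaping
#'
#' White Gaussian noise is shaped in the Fourier domain by multiplying the
#' amplitude at frequency f by f^(-exponent/2) (zero DC), then transformed
#' back and rescaled to the requested RMS. With exponent = 1 the power
#' spectrum falls as 1/f.
#'
#' @param n number of samples.
#' @param dt sampling step (minutes); sets the frequency scale only.
#' @param rms target root-mean-square amplitude.
#' @param exponent power-spectrum exponent.
#' @return numeric vector of length \code{n} with zero mean.
#' @export
pink_noise <- function(n, dt = 5, rms = 30, exponent = 1) {
  if (n < 2 || rms == 0) return(numeric(n))
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- abs(fft_freq(n, dt))
  shape <- ifelse(f > 0, f^(-exponent / 2), 0)
  x <- Re(stats::fft(W * shape, inverse = TRUE) / n)
  s <- sqrt(mean(x^2))
  if (s > 0) x <- x * (rms / s)
  x
}

#' Evaluate the pulse train of a rhythm at given times
#'
#' @param t times in minutes.
#' @param rhythm a \code{\link{rhythm_params}} object.
#' @param offset phase offset in minutes: pulse centers sit at
#'   \code{offset + k * period}.
#' @return pulse-train values in pg.
#' @export
pulse_train <- function(t, rhythm, offset = 0) {
  P <- rhythm$period; W <- rhythm$pulse_width; A <- rhythm$pulse_amplitude
  if (A == 0) return(numeric(length(t)))
  u <- (t - offset) %% P
  d <- pmin(u, P - u)                      # distance to nearest pulse center
  v <- numeric(length(t))
  inside <- d < W / 2
  if (rhythm$pulse_shape == "raised-cosine") {
    v[inside] <- A * 0.5 * (1 + cos(2 * pi * d[inside] / W))
  } else {
    v[inside] <- A * (1 - 2 * d[inside] / W)
  }
  rhythm$pulse_sign * v
}

new_drymass_trace <- function(track_id, time, mass, truth = NULL,
                              interphase = NULL, meta = list()) {
  dt <- if (length(time) > 1) time[2] - time[1] else NA_real_
  structure(list(track_id = track_id, time = time, mass = mass, truth = truth,
                 interphase = interphase %||% rep(TRUE, length(time)),
                 dt = dt, T = time[length(time)] - time[1], meta = meta),
            class = "drymass_trace")
}

#' @export
print.drymass_trace <- function(x, ...) {
  cat(sprintf("<drymass_trace> id=%s  n=%d samples  dt=%g min  T=%g min  mass %.0f-%.0f pg\n",
              as.character(x$track_id), length(x$time), x$dt, x$T,
              min(x$mass), max(x$mass)))
  invisible(x)
}

#' Generate one synthetic dry-mass trace
#'
#' A trace is the sum of a linear growth background, a periodic pulse train,
#' a 1/f noise term and white measurement noise, sampled every \code{dt}
#' minutes over \code{T} minutes. The noise-free twin (background + pulses) is
#' returned alongside for use as ground truth.
#'
#' @param rhythm a \code{\link{rhythm_params}} object.
#' @param gn a \code{\link{growth_noise_params}} object.
#' @param T trace duration in minutes; must be at least two rhythm periods
#'   (shorter traces cannot carry a detectable rhythm) and a multiple of
#'   \code{dt}.
#' @param dt sampling interval in minutes.
#' @param seed optional integer seed for reproducibility.
#' @param phase_offset pulse-train phase offset in minutes.
#' @param track_id identifier stored in the trace.
#' @return a \code{"drymass_trace"} with fields \code{time}, \code{mass} and
#'   noise-free \code{truth}.
#' @export
generate_trace <- function(rhythm = rhythm_params(), gn = growth_noise_params(),
                           T = 1200, dt = 5, seed = NULL, phase_offset = 0,
                           track_id = 1L) {
  if (T < 2 * rhythm$period)
    stop("T must be at least twice the rhythm period for the rhythm to be detectable")
  if (abs(T / dt - round(T / dt)) > 1e-9) stop("dt must divide T")
  if (!is.null(seed)) set.seed(seed)
  time <- seq(0, T, by = dt)
  n <- length(time)
  truth <- gn$initial_mass + gn$growth_rate * time +
    pulse_train(time, rhythm, phase_offset)
  noise <- pink_noise(n, dt, gn$pink_noise_rms, gn$pink_noise_exponent) +
    stats::rnorm(n, 0, gn$measurement_noise_sd)
  new_drymass_trace(track_id, time, truth + noise, truth = truth,
                    meta = list(rhythm = rhythm, gn = gn,
                                phase_offset = phase_offset, seed = seed))
}

# Draw one interphase duration (minutes, multiple of dt, >= 2 periods).
draw_cycle_length <- function(config, rhythm) {
  lo <- 2 * rhythm$period
  for (i in 1:100) {
    T <- stats::rlnorm(1, meanlog = log(config$cycle_median),
                       sdlog = config$cycle_sdlog)
    T <- round(T / config$sampling_interval) * config$sampling_interval
    if (T >= lo && T <= config$duration) return(T)
  }
  stop("could not draw an interphase duration in [2*period, duration]")
}

#' Generate a synthetic cohort of dry-mass traces with ground truth
#'
#' Each cell receives its own interphase duration (lognormal cycle-length
#' distribution), a uniform random pulse-train phase offset (asynchronous
#' culture), its own noise realization, a random-walk position history, and
#' division events: at the end of each interphase the mass drops abruptly to
#' a fraction u ~ U(0.45, 0.55) of the pre-division mass and a daughter track
#' is born nearby on the following frame. The returned \code{traces} are the
#' first full interphase of each of the \code{n_cells} cells (one trace per
#' cell, with duration T(j) recorded); full timelines, division times and
#' positions live in \code{ground_truth}.
#'
#' @param config a \code{\link{cohort_config}}.
#' @param rhythm a \code{\link{rhythm_params}}.
#' @param gn a \code{\link{growth_noise_params}}.
#' @return an object of class \code{"drymass_cohort"} with elements
#'   \code{traces} (list of \code{drymass_trace}), \code{ground_truth},
#'   \code{config}, \code{rhythm}, \code{gn}.
#' @export
generate_cohort <- function(config, rhythm = rhythm_params(),
                            gn = growth_noise_params()) {
  dt <- config$sampling_interval
  n_frames <- floor(config$duration / dt) + 1L
  frames <- seq_len(n_frames)
  time_all <- (frames - 1) * dt
  traces <- vector("list", config$n_cells)
  gt <- vector("list", config$n_cells)

  # plating: cells seed the dish spread out (adherent cells exclude each
  # other), so start positions keep a minimum separation where the field
  # allows it (dart throwing, relaxed when the dish gets crowded)
  margin <- 20; lim <- c(margin, config$field_px - margin)
  set.seed(derive_seed(config$seed, 0L))
  min_sep <- min(45, 0.7 * (lim[2] - lim[1]) / ceiling(sqrt(config$n_cells)))
  starts <- matrix(NA_real_, config$n_cells, 2)
  for (j in seq_len(config$n_cells)) {
    for (try in 1:200) {
      p <- stats::runif(2, lim[1], lim[2])
      if (j == 1 || all(sqrt(rowSums((starts[seq_len(j - 1), , drop = FALSE] -
                                        rep(p, each = j - 1))^2)) >= min_sep))
        break
    }
    starts[j, ] <- p
  }

  for (j in seq_len(config$n_cells)) {
    set.seed(derive_seed(config$seed, j))
    offset <- stats::runif(1, 0, rhythm$period)
    # generations of interphase durations until duration is exhausted
    cycles <- c(); t_acc <- 0
    while (t_acc < config$duration) {
      Tg <- draw_cycle_length(config, rhythm)
      cycles <- c(cycles, Tg)
      t_acc <- t_acc + Tg
    }
    div_times <- cumsum(cycles)
    div_times <- div_times[div_times < config$duration]
    u <- stats::runif(length(div_times), 0.45, 0.55)

    # noise-free mass timeline with division drops
    base <- gn$initial_mass + gn$growth_rate * time_all
    truth <- base + pulse_train(time_all, rhythm, offset)
    if (length(div_times)) {
      for (k in seq_along(div_times)) {
        after <- time_all >= div_times[k]
        m_pre <- truth[which(after)[1] - 1L]
        if (is.na(m_pre)) m_pre <- truth[which(after)[1]]
        drop <- m_pre * (1 - u[k])
        truth[after] <- truth[after] - drop
      }
    }
    noise <- pink_noise(n_frames, dt, gn$pink_noise_rms, gn$pink_noise_exponent) +
      stats::rnorm(n_frames, 0, gn$measurement_noise_sd)
    mass <- truth + noise

    # random-walk positions, reflected into the field with a margin
    start <- starts[j, ]
    pos <- cbind(
      reflect_walk(start[1], stats::rnorm(n_frames - 1, 0,
                                          config$motility_sd_px), lim),
      reflect_walk(start[2], stats::rnorm(n_frames - 1, 0,
                                          config$motility_sd_px), lim))

    # daughters: born one frame after each division, <= 15 px away; the two
    # cells then respread away from the cleavage plane (a saturating drift
    # on top of the baseline random walk) as freshly divided cells do
    daughters <- list()
    for (k in seq_along(div_times)) {
      bf <- which(time_all >= div_times[k])[1] + 1L
      if (is.na(bf) || bf > n_frames) next
      # two freshly divided cells sit side by side: centers about two cell
      # radii apart, within the 15 px linking reach
      ang <- stats::runif(1, 0, 2 * pi)
      sep_dir <- c(cos(ang), sin(ang))
      r <- stats::runif(1, 14, 15)
      drift <- pmin(0.5 * (0:(n_frames - bf + 1L)), 8)
      idxm <- (bf - 1L):n_frames
      pos[idxm, ] <- pmin(pmax(pos[idxm, ] -
                                 drift[seq_along(idxm)] %o% sep_dir, lim[1]),
                          lim[2])
      dpos <- matrix(NA_real_, n_frames, 2)
      dstart <- pmin(pmax(pos[bf, ] + r * sep_dir, lim[1]), lim[2])
      dpos[bf:n_frames, 1] <-
        reflect_walk(dstart[1], stats::rnorm(n_frames - bf, 0,
                                             config$motility_sd_px), lim)
      dpos[bf:n_frames, 2] <-
        reflect_walk(dstart[2], stats::rnorm(n_frames - bf, 0,
                                             config$motility_sd_px), lim)
      dd <- pmin(0.5 * (0:(n_frames - bf)), 8)
      dpos[bf:n_frames, ] <- pmin(pmax(dpos[bf:n_frames, ] + dd %o% sep_dir,
                                       lim[1]), lim[2])
      # daughter noise-free mass: complementary fraction of the pre-division
      # mass, then linear growth with the mother's pulse phase
      idx <- bf:n_frames
      pre_mass <- truth[bf - 1L] / u[k] * (1 - u[k])
      dtruth <- pre_mass + gn$growth_rate * (time_all[idx] - time_all[bf]) +
        pulse_train(time_all[idx], rhythm, offset)
      dmass <- dtruth +
        pink_noise(length(idx), dt, gn$pink_noise_rms, gn$pink_noise_exponent) +
        stats::rnorm(length(idx), 0, gn$measurement_noise_sd)
      daughters[[length(daughters) + 1L]] <-
        list(birth_frame = bf, positions = dpos, time = time_all[idx],
             truth = dtruth, mass = dmass)
    }

    # the analyzed trace: first full interphase
    Tj <- if (length(div_times)) div_times[1] else
      max(time_all[time_all <= config$duration])
    sel <- time_all <= Tj
    traces[[j]] <- new_drymass_trace(j, time_all[sel], mass[sel],
                                     truth = truth[sel],
                                     meta = list(phase_offset = offset, gn = gn,
                                                 rhythm = rhythm))
    gt[[j]] <- list(track_id = j, T = Tj, phase_offset = offset,
                    division_times = div_times, u = u, positions = pos,
                    time = time_all, truth = truth, mass = mass,
                    daughters = daughters)
  }
  structure(list(traces = traces, ground_truth = gt, config = config,
                 rhythm = rhythm, gn = gn),
            class = "drymass_cohort")
}

#' @export
print.drymass_cohort <- function(x, ...) {
  Ts <- vapply(x$ground_truth, function(g) g$T, numeric(1))
  cat(sprintf("<drymass_cohort> %d cells, dt=%g min, interphase T(j): %g-%g min (median %g)\n",
              length(x$traces), x$config$sampling_interval,
              min(Ts), max(Ts), stats::median(Ts)))
  invisible(x)
}

#' Negative-control transforms of a dry-mass trace
#'
#' \code{"shuffle"} removes the fitted linear trend, randomly permutes the
#' residuals and adds the trend back: the value multiset is preserved but any
#' temporal structure is destroyed (the random-dataset control).
#' \code{"constant"} replaces the trace by a flat mass plus white measurement
#' noise only (the fixed-cell control).
#'
#' @param trace a \code{"drymass_trace"}.
#' @param mode \code{"shuffle"} or \code{"constant"}.
#' @param seed optional seed.
#' @return a \code{"drymass_trace"}.
#' @export
negative_control <- function(trace, mode = c("shuffle", "constant"), seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  t <- trace$time
  if (mode == "shuffle") {
    fit <- stats::lm.fit(cbind(1, t), trace$mass)
    trend <- trace$mass - fit$residuals
    mass <- trend + sample(fit$residuals)
  } else {
    sd_meas <- trace$meta$gn$measurement_noise_sd %||% 35
    mass <- mean(trace$mass) + stats::rnorm(length(t), 0, sd_meas)
  }
  new_drymass_trace(trace$track_id, t, mass,
                    meta = c(trace$meta, list(control = mode)))
}

#' Apply a negative control to every trace of a cohort
#'
#' @param cohort a \code{"drymass_cohort"} or a list of traces.
#' @param mode passed to \code{\link{negative_control}}.
#' @param seed master seed; per-trace seeds are derived from it.
#' @return a list of control traces.
#' @export
negative_control_cohort <- function(cohort, mode = c("shuffle", "constant"),
                                    seed = 1) {
  mode <- match.arg(mode)
  traces <- if (inherits(cohort, "drymass_cohort")) cohort$traces else cohort
  lapply(seq_along(traces), function(j)
    negative_control(traces[[j]], mode, seed = derive_seed(seed, j)))
}

#' Write dry-mass traces to CSV
#'
#' Columns: track_id, frame, time_min, mass_pg, interphase_flag.
#'
#' @param traces list of \code{"drymass_trace"} objects (or a cohort).
#' @param path output file.
#' @export
write_traces_csv <- function(traces, path) {
  if (inherits(traces, "drymass_cohort")) traces <- traces$traces
  df <- do.call(rbind, lapply(traces, function(tr)
    data.frame(track_id = tr$track_id,
               frame = as.integer(round(tr$time / tr$dt)),
               time_min = tr$time, mass_pg = tr$mass,
               interphase_flag = as.integer(tr$interphase))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read dry-mass traces from CSV
#'
#' @param path CSV written by \code{\link{write_traces_csv}}.
#' @return list of \code{"drymass_trace"} objects.
#' @export
read_traces_csv <- function(path) {
  df <- utils::read.csv(path)
  lapply(split(df, df$track_id), function(d) {
    d <- d[order(d$time_min), ]
    new_drymass_trace(d$track_id[1], d$time_min, d$mass_pg,
                      interphase = as.logical(d$interphase_flag %||%
                                                rep(1, nrow(d))))
  })
}
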