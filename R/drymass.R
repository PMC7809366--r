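# Phase -> OPD -> OVD -> cell dry mass, and per-track trace assembly.

#' Convert a phase image to optical path difference
#'
#' OPD(x,y) = lambda * phase_shift / (2 pi), where phase_shift is the phase
#' referenced to the surrounding medium. The medium reference is estimated as
#' the median phase over background (non-cell) pixels and subtracted first;
#' pass \code{background = "none"} for phases that are already referenced.
#'
#' @param phase real matrix of phases (radians).
#' @param wavelength illumination wavelength, micrometers.
#' @param pixel_pitch micrometers per pixel.
#' @param background \code{"median"} (subtract the median over non-cell
#'   pixels) or \code{"none"}.
#' @param cell_mask optional logical matrix marking cell pixels to exclude
#'   from the background estimate.
#' @return OPD matrix (micrometers) with a \code{pixel_pitch} attribute.
#' @export
phase_to_opd <- function(phase, wavelength = 0.647, pixel_pitch = 1.67,
                         background = c("median", "none"), cell_mask = NULL) {
  background <- match.arg(background)
  stopifnot_scalar(wavelength, "wavelength", positive = TRUE)
  shift <- phase
  if (background == "median") {
    bg <- if (is.null(cell_mask)) phase else phase[!cell_mask]
    shift <- phase - stats::median(bg)
  }
  opd <- wavelength * shift / (2 * pi)
  attr(opd, "pixel_pitch") <- pixel_pitch
  attr(opd, "wavelength") <- wavelength
  opd
}

#' Integrate OPD over a segmentation mask: optical volume difference
#'
#' OVD = sum of OPD over the mask times the pixel area, in cubic
#' micrometers; the projected cell area S is reported alongside.
#'
#' @param opd OPD matrix (micrometers) with a \code{pixel_pitch} attribute,
#'   or any matrix plus an explicit \code{pixel_pitch}.
#' @param mask logical matrix of the same shape.
#' @param pixel_pitch micrometers per pixel (defaults to the attribute).
#' @return list with \code{ovd} (um^3), \code{area} (um^2), \code{npx},
#'   and \code{empty} (TRUE for an empty mask).
#' @export
integrate_ovd <- function(opd, mask, pixel_pitch = NULL) {
  pitch <- pixel_pitch %||% attr(opd, "pixel_pitch") %||% 1.67
  if (!identical(dim(opd), dim(mask))) stop("opd and mask shapes differ")
  npx <- sum(mask)
  list(ovd = sum(opd[mask]) * pitch^2, area = npx * pitch^2, npx = npx,
       empty = npx == 0L)
}

#' Convert optical volume difference to cell dry mass
#'
#' CDM = OVD / alpha with the specific refractive increment alpha
#' (0.18 um^3/pg for typical eukaryotic cell content). Phases obtained
#' through the TV-regularized retrieval under-estimate the optical signal;
#' \code{apply_correction = TRUE} multiplies by \code{correction_factor}
#' (default 1/0.65) to compensate. The correction is meant for the retrieval
#' path only, never for directly rendered ground-truth phases.
#'
#' @param ovd optical volume difference in um^3, or the list returned by
#'   \code{\link{integrate_ovd}}.
#' @param alpha specific refractive increment, um^3/pg.
#' @param apply_correction logical; compensate the retrieval signal loss.
#' @param correction_factor multiplicative correction (default 1/0.65).
#' @return list with \code{ovd}, \code{cdm} (pg), \code{area} (um^2 or NA),
#'   \code{correction_applied}.
#' @export
ovd_to_cdm <- function(ovd, alpha = 0.18, apply_correction = FALSE,
                       correction_factor = 1 / 0.65) {
  area <- NA_real_
  if (is.list(ovd)) { area <- ovd$area %||% NA_real_; ovd <- ovd$ovd }
  stopifnot_scalar(alpha, "alpha", positive = TRUE)
  cdm <- ovd / alpha
  if (apply_correction) cdm <- cdm * correction_factor
  list(ovd = ovd, cdm = cdm, area = area,
       correction_applied = isTRUE(apply_correction))
}

#' Assemble per-track dry-mass traces from a phase stack
#'
#' For every track and frame, segments the cell at the tracked position
#' (joint geodesic growing when several tracked cells share a frame, so
#' touching cells split), integrates OPD over the mask and converts to dry
#' mass. Interphase flags are derived from the division events: samples
#' between two divisions (or after the last division) are interphase.
#'
#' @param tracks a \code{"cell_tracks"} object.
#' @param phase_stack list of phase matrices, one per frame (frame index =
#'   list position - 1 + \code{frame0}).
#' @param divisions result of \code{\link{detect_divisions}}, or NULL to
#'   flag everything interphase.
#' @param phase_threshold segmentation threshold (radians).
#' @param dt minutes per frame.
#' @param wavelength,pixel_pitch optics metadata, micrometers.
#' @param apply_correction passed to \code{\link{ovd_to_cdm}}.
#' @param alpha specific refractive increment, um^3/pg.
#' @param frame0 frame index of the first stack entry.
#' @return list of \code{"drymass_trace"} objects, named by track id.
#' @export
build_traces <- function(tracks, phase_stack, divisions = NULL,
                         phase_threshold = 0.15, dt = 5,
                         wavelength = 0.647, pixel_pitch = 1.67,
                         apply_correction = FALSE, alpha = 0.18,
                         frame0 = 0L) {
  spots <- tracks$spots
  ids <- unique(spots$track_id)
  masses <- stats::setNames(
    lapply(ids, function(id) rep(NA_real_, sum(spots$track_id == id))), ids)
  frames <- sort(unique(spots$frame))
  for (f in frames) {
    img <- phase_stack[[f - frame0 + 1L]]
    sel <- spots[spots$frame == f, , drop = FALSE]
    opd <- phase_to_opd(img, wavelength, pixel_pitch)
    masks <- segment_cells(opd / (wavelength / (2 * pi)), sel,
                           phase_threshold)
    for (k in seq_len(nrow(sel))) {
      id <- sel$track_id[k]
      s <- track_spots(tracks, id)
      pos <- which(s$frame == f)
      samp <- ovd_to_cdm(integrate_ovd(opd, masks[[k]], pixel_pitch),
                         alpha = alpha, apply_correction = apply_correction)
      masses[[as.character(id)]][pos] <- samp$cdm
    }
  }
  out <- lapply(ids, function(id) {
    s <- track_spots(tracks, id)
    m <- masses[[as.character(id)]]
    inter <- rep(TRUE, nrow(s))
    if (!is.null(divisions)) {
      divs <- divisions$events$frame[divisions$events$track_id == id]
      # the division frames themselves are not interphase samples
      inter[s$frame %in% divs] <- FALSE
    }
    new_drymass_trace(id, s$frame * dt, m, interphase = inter,
                      meta = list(frames = s$frame,
                                  phase_threshold = phase_threshold))
  })
  stats::setNames(out, ids)
}

#' Split a trace into interphase segments at division frames
#'
#' @param trace a \code{"drymass_trace"} whose meta carries frames.
#' @param division_frames integer frames of detected divisions on the track.
#' @param dt minutes per frame.
#' @param min_samples minimum samples for a segment to be returned.
#' @return list of \code{"drymass_trace"} segments (times re-zeroed).
#' @export
split_interphases <- function(trace, division_frames, dt = 5,
                              min_samples = 10) {
  frames <- trace$meta$frames %||% (trace$time / dt)
  bounds <- sort(unique(division_frames))
  bounds <- bounds[bounds > min(frames) & bounds < max(frames)]
  cuts <- c(min(frames), bounds, max(frames) + 1L)
  segs <- list()
  for (k in seq_len(length(cuts) - 1)) {
    sel <- frames >= cuts[k] & frames < cuts[k + 1]
    if (sum(sel) < min_samples) next
    tt <- trace$time[sel]
    segs[[length(segs) + 1L]] <-
      new_drymass_trace(paste0(trace$track_id, ".", k), tt - tt[1],
                        trace$mass[sel],
                        meta = c(trace$meta, list(segment = k)))
  }
  segs
}
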