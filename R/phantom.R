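# Optical cell phantoms: render ground-truth dry mass as a phase object.

#' Optical phantom of an adherent cell
#'
#' A radially symmetric optical-path-difference (OPD) profile: either a
#' uniform disc or a cosine dome \code{peak_opd * cos(pi r / (2 radius))}.
#' The integrated OPD over the phantom equals \code{alpha * mass} when built
#' with \code{\link{phantom_from_mass}}.
#'
#' @param center length-2 pixel coordinates (x, y), 0-based pixel centers.
#' @param radius_um cell radius in micrometers.
#' @param peak_opd_um peak OPD in micrometers (>= 0).
#' @param profile \code{"cosine-dome"} (default) or \code{"uniform-disc"}.
#' @return an object of class \code{"cell_phantom"}.
#' @export
cell_phantom <- function(center, radius_um, peak_opd_um,
                         profile = c("cosine-dome", "uniform-disc")) {
  profile <- match.arg(profile)
  stopifnot_scalar(radius_um, "radius_um", positive = TRUE)
  stopifnot_scalar(peak_opd_um, "peak_opd_um", nonneg = TRUE)
  structure(list(center = center, radius_um = radius_um,
                 peak_opd_um = peak_opd_um, profile = profile),
            class = "cell_phantom")
}

#' Analytic integrated OPD of a phantom (um^3)
#'
#' Uniform disc: \code{pi R^2 peak}. Cosine dome:
#' \code{2 pi peak R^2 (2 pi - 4) / pi^2} (closed-form integral of
#' \code{cos(pi r / 2R)} over the disc).
#'
#' @param phantom a \code{\link{cell_phantom}}.
#' @return integrated OPD in cubic micrometers.
#' @export
phantom_ovd <- function(phantom) {
  R <- phantom$radius_um; p <- phantom$peak_opd_um
  switch(phantom$profile,
         "uniform-disc" = pi * R^2 * p,
         "cosine-dome"  = 2 * pi * p * R^2 * (2 * pi - 4) / pi^2)
}

#' Build a phantom whose integrated OPD encodes a target dry mass
#'
#' Inverts \code{\link{phantom_ovd}} so that integrated OPD = alpha * mass,
#' i.e. the phantom renders exactly \code{mass_pg} picograms of dry mass at
#' specific refractive increment \code{alpha}.
#'
#' @param mass_pg target dry mass, pg.
#' @param center pixel coordinates.
#' @param radius_um cell radius, micrometers.
#' @param profile OPD profile.
#' @param alpha specific refractive increment, um^3/pg.
#' @return a \code{\link{cell_phantom}}.
#' @export
phantom_from_mass <- function(mass_pg, center, radius_um = 16,
                              profile = c("cosine-dome", "uniform-disc"),
                              alpha = 0.18) {
  profile <- match.arg(profile)
  target <- alpha * mass_pg
  unit <- phantom_ovd(cell_phantom(center, radius_um, 1, profile))
  cell_phantom(center, radius_um, target / unit, profile)
}

#' Render phantoms into an OPD image
#'
#' Overlapping phantoms add. Coordinates are 0-based pixel centers; pixel
#' (i, j) of the matrix holds x = i - 1 along rows, y = j - 1 along columns.
#'
#' @param phantoms a \code{\link{cell_phantom}} or list of them.
#' @param dim image side(s) in pixels (scalar or length-2).
#' @param pixel_pitch micrometers per pixel.
#' @return an OPD matrix (micrometers) with \code{pixel_pitch} attribute.
#' @export
render_phantom_opd <- function(phantoms, dim = 256, pixel_pitch = 1.67) {
  if (inherits(phantoms, "cell_phantom")) phantoms <- list(phantoms)
  if (length(dim) == 1) dim <- c(dim, dim)
  opd <- matrix(0, dim[1], dim[2])
  for (ph in phantoms) {
    Rpx <- ph$radius_um / pixel_pitch
    cx <- ph$center[1]; cy <- ph$center[2]
    i0 <- max(1L, floor(cx - Rpx)); i1 <- min(dim[1], ceiling(cx + Rpx) + 2L)
    j0 <- max(1L, floor(cy - Rpx)); j1 <- min(dim[2], ceiling(cy + Rpx) + 2L)
    if (i0 > i1 || j0 > j1) next
    xi <- (i0:i1) - 1; yj <- (j0:j1) - 1
    r <- sqrt(outer((xi - cx)^2, (yj - cy)^2, `+`)) * pixel_pitch
    prof <- matrix(0, length(xi), length(yj))
    inside <- r < ph$radius_um
    if (ph$profile == "uniform-disc") {
      prof[inside] <- ph$peak_opd_um
      # antialias the hard edge: fractional pixel coverage by 4x4
      # subsampling so the integrated OPD meets its discretization bound
      edge <- which(abs(r - ph$radius_um) < pixel_pitch, arr.ind = TRUE)
      if (nrow(edge)) {
        sub <- (seq_len(4) - 2.5) / 4
        for (e in seq_len(nrow(edge))) {
          ex <- xi[edge[e, 1]]; ey <- yj[edge[e, 2]]
          rs <- sqrt(outer((ex + sub - cx)^2, (ey + sub - cy)^2, `+`)) *
            pixel_pitch
          prof[edge[e, 1], edge[e, 2]] <-
            ph$peak_opd_um * mean(rs < ph$radius_um)
        }
      }
    } else {
      prof[inside] <- ph$peak_opd_um * cos(pi * r[inside] / (2 * ph$radius_um))
    }
    opd[i0:i1, j0:j1] <- opd[i0:i1, j0:j1] + prof
  }
  attr(opd, "pixel_pitch") <- pixel_pitch
  opd
}

#' Render a hologram (sensor intensity) of a phantom scene
#'
#' Builds the object-plane phase field \code{A0 = exp(i 2 pi OPD / lambda)}
#' under unit plane-wave illumination, propagates it to the sensor plane at
#' distance \code{Z} and returns the recorded intensity \code{|A_Z|^2}.
#' Optional shot noise replaces each pixel by a scaled Poisson draw with
#' \code{photons} expected counts per unit intensity.
#'
#' @param phantoms phantom or list of phantoms (empty list allowed).
#' @param dim image side(s), pixels.
#' @param pixel_pitch micrometers per pixel.
#' @param wavelength illumination wavelength, micrometers.
#' @param Z object-to-sensor distance, micrometers.
#' @param shot_noise logical; add Poisson shot noise.
#' @param photons expected photon count per unit intensity.
#' @return intensity matrix with grid metadata attributes.
#' @export
render_hologram <- function(phantoms, dim = 256, pixel_pitch = 1.67,
                            wavelength = 0.647, Z = 1500,
                            shot_noise = FALSE, photons = 1e4) {
  stopifnot_scalar(Z, "Z", positive = TRUE)
  opd <- render_phantom_opd(phantoms, dim, pixel_pitch)
  A0 <- complex_field(exp(2i * pi * opd / wavelength), pixel_pitch, wavelength)
  I <- sensor_intensity(propagate(A0, Z))
  if (shot_noise) {
    I <- matrix(stats::rpois(length(I), I * photons) / photons,
                nrow(I), ncol(I))
    attr(I, "pixel_pitch") <- pixel_pitch
    attr(I, "wavelength") <- wavelength
  }
  I
}

#' Render a cohort into per-frame images with ground truth
#'
#' Builds, for each requested frame, the phantom scene implied by the
#' cohort's ground truth (founder cells at their random-walk positions plus
#' daughters after birth, each carrying its instantaneous noise-free dry
#' mass), and renders either the ground-truth phase image or the sensor-plane
#' hologram intensity.
#'
#' @param cohort a \code{"drymass_cohort"}.
#' @param frames integer frame indices (0-based) to render.
#' @param mode \code{"phase"} (ground-truth object phase, radians) or
#'   \code{"hologram"} (sensor intensity).
#' @param radius_um phantom cell radius.
#' @param pixel_pitch,wavelength,Z optics, micrometers.
#' @param alpha specific refractive increment, um^3/pg.
#' @return list with \code{images} (list of matrices), \code{truth}
#'   (data.frame: frame, x, y, cell, mass_pg, daughter).
#' @export
render_scene <- function(cohort, frames, mode = c("phase", "hologram"),
                         radius_um = 16, pixel_pitch = 1.67,
                         wavelength = 0.647, Z = 1500, alpha = 0.18) {
  mode <- match.arg(mode)
  dimpx <- cohort$config$field_px
  images <- vector("list", length(frames))
  truth <- NULL
  for (k in seq_along(frames)) {
    f <- frames[k]
    phs <- list()
    for (j in seq_along(cohort$ground_truth)) {
      gt <- cohort$ground_truth[[j]]
      pos <- gt$positions[f + 1L, ]
      mass <- gt$truth[f + 1L]
      phs[[length(phs) + 1L]] <-
        phantom_from_mass(mass, pos, radius_um, alpha = alpha)
      truth <- rbind(truth, data.frame(frame = f, x = pos[1], y = pos[2],
                                       cell = j, mass_pg = mass,
                                       daughter = 0L))
      for (di in seq_along(gt$daughters)) {
        d <- gt$daughters[[di]]
        if (f + 1L < d$birth_frame) next
        dpos <- d$positions[f + 1L, ]
        dmass <- d$truth[f + 1L - d$birth_frame + 1L]
        if (!is.finite(dmass) || any(!is.finite(dpos))) next
        phs[[length(phs) + 1L]] <-
          phantom_from_mass(dmass, dpos, radius_um, alpha = alpha)
        truth <- rbind(truth, data.frame(frame = f, x = dpos[1], y = dpos[2],
                                         cell = j, mass_pg = dmass,
                                         daughter = di))
      }
    }
    if (mode == "phase") {
      opd <- render_phantom_opd(phs, dimpx, pixel_pitch)
      img <- 2 * pi * opd / wavelength
      attr(img, "pixel_pitch") <- pixel_pitch
      images[[k]] <- img
    } else {
      images[[k]] <- render_hologram(phs, dimpx, pixel_pitch, wavelength, Z)
    }
  }
  list(images = images, truth = truth)
}
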