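# Complex optical fields and Fresnel propagation.

#' Complex optical field on a pixel grid
#'
#' @param values complex (or real) matrix of field amplitudes.
#' @param pixel_pitch pixel pitch in micrometers.
#' @param wavelength illumination wavelength in micrometers.
#' @return an object of class \code{"complex_field"}.
#' @export
complex_field <- function(values, pixel_pitch = 1.67, wavelength = 0.647) {
  if (!is.matrix(values)) stop("values must be a matrix")
  stopifnot_scalar(pixel_pitch, "pixel_pitch", positive = TRUE)
  stopifnot_scalar(wavelength, "wavelength", positive = TRUE)
  if (any(!is.finite(Mod(values)))) stop("field values must be finite")
  structure(list(values = matrix(as.complex(values), nrow(values), ncol(values)),
                 pixel_pitch = pixel_pitch, wavelength = wavelength),
            class = "complex_field")
}

#' @export
print.complex_field <- function(x, ...) {
  cat(sprintf("<complex_field> %dx%d px, pitch %g um, lambda %g um, power %.4g\n",
              nrow(x$values), ncol(x$values), x$pixel_pitch, x$wavelength,
              sum(Mod(x$values)^2)))
  invisible(x)
}

# Fresnel transfer function exp(-i pi lambda Z f^2) on the FFT frequency
# grid. Unitary (|H| = 1), and H(-Z) = conj(H(Z)). The constant piston term
# exp(i 2 pi Z / lambda) of the physical kernel is omitted: it carries no
# spatial information and would put an arbitrary global phase offset on
# fields reconstructed from intensity-only data.
fresnel_tf <- function(dims, pixel_pitch, wavelength, Z) {
  fx <- fft_freq(dims[1], pixel_pitch)
  fy <- fft_freq(dims[2], pixel_pitch)
  f2 <- outer(fx^2, fy^2, `+`)
  exp(-1i * pi * wavelength * Z * f2)
}

#' Fresnel propagation of a complex field
#'
#' Propagates the field over a signed distance \code{Z} (micrometers) by
#' multiplication with the analytic Fresnel transfer function in Fourier
#' space (angular-spectrum implementation with periodic boundaries). The
#' kernel is unitary, so total power is conserved, and propagation by
#' \code{-Z} exactly inverts propagation by \code{+Z}.
#'
#' @param field a \code{\link{complex_field}}.
#' @param Z signed propagation distance in micrometers; positive is
#'   object-to-sensor.
#' @return a \code{\link{complex_field}} in the destination plane.
#' @export
propagate <- function(field, Z) {
  stopifnot(inherits(field, "complex_field"))
  if (Z == 0) {
    warning("Z = 0: returning the field unchanged")
    return(field)
  }
  H <- fresnel_tf(dim(field$values), field$pixel_pitch, field$wavelength, Z)
  out <- ifft2(fft2(field$values) * H)
  complex_field(out, field$pixel_pitch, field$wavelength)
}

#' Sensor intensity of a field
#'
#' @param field a \code{\link{complex_field}}.
#' @return a real matrix \code{|A|^2} with the grid metadata in attributes.
#' @export
sensor_intensity <- function(field) {
  I <- Mod(field$values)^2
  attr(I, "pixel_pitch") <- field$pixel_pitch
  attr(I, "wavelength") <- field$wavelength
  I
}

#' Write a stack of real-valued images as a multi-page 32-bit TIFF
#'
#' Samples are stored rescaled to `[0,1]` at 32-bit depth (the TIFF writer
#' only stores that range); the affine scaling (offset, scale) is recorded
#' in a JSON sidecar \code{<path>.scale.json} so that
#' \code{\link{read_image_stack}} restores physical values.
#'
#' @param stack a matrix or list of matrices.
#' @param path output file.
#' @export
write_image_stack <- function(stack, path) {
  if (is.matrix(stack)) stack <- list(stack)
  lo <- min(vapply(stack, min, numeric(1)))
  hi <- max(vapply(stack, max, numeric(1)))
  scale <- if (hi > lo) hi - lo else 1
  scaled <- lapply(stack, function(m) {
    m <- (m - lo) / scale
    matrix(pmin(pmax(m, 0), 1), nrow(m))
  })
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L)
  jsonlite::write_json(list(offset = lo, scale = scale),
                       paste0(path, ".scale.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF written by \code{\link{write_image_stack}}
#'
#' Values are mapped back to physical units through the scaling sidecar when
#' present; a plain TIFF without a sidecar is returned as stored.
#'
#' @param path TIFF file.
#' @return list of numeric matrices in physical units.
#' @export
read_image_stack <- function(path) {
  out <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(out)) out <- list(out)
  off <- 0; sc <- 1
  sidecar <- paste0(path, ".scale.json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::fromJSON(sidecar)
    off <- meta$offset; sc <- meta$scale
  }
  lapply(out, function(m) {
    m <- m * sc + off
    attributes(m) <- list(dim = dim(m))
    m
  })
}
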