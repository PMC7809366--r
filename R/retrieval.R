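# Total-variation regularized phase retrieval for inline holograms.
#
# The sensor records only the intensity I_Z = |A_Z|^2. For any sensor-plane
# phase phi_Z the object-plane field A0(phi_Z) = backpropagate(sqrt(I_Z)
# e^{i phi_Z}) matches the data exactly, so the retrieval problem reduces to
# choosing phi_Z. We pick the phi_Z whose object field minimizes a
# total-variation criterion, by nonlinear conjugate gradients
# (Hestenes-Stiefel) with a second-order line search.

tv_forms <- c("smoothed", "l1")

#' Total-variation criterion of a complex field
#'
#' Two variants of the edge-sparsity criterion, both reducing to
#' \code{N * sqrt(eps)} on a constant field of N pixels:
#' \describe{
#'   \item{\code{"smoothed"}}{\code{sum(sqrt(eps + |dA/dx|^2 + |dA/dy|^2))} —
#'     isotropic TV with the usual smoothing constant. Here \code{eps}
#'     genuinely prevents division by zero in the gradient, and the criterion
#'     is differentiable everywhere. This is the form the retrieval
#'     minimizes.}
#'   \item{\code{"l1"}}{\code{sum(sqrt(eps + |dA/dx| + |dA/dy|))} — square
#'     root of the L1 gradient norm. More aggressively sparsifying, but its
#'     derivative is singular wherever a difference vanishes (eps does not
#'     remove that singularity), which stalls gradient descent on flat
#'     regions; provided for comparison.}
#' }
#' Differences are forward differences with periodic wrap, consistent with
#' the FFT-based propagation.
#'
#' @param field a \code{\link{complex_field}} or a complex matrix.
#' @param eps regularizing constant (default 1e-4).
#' @param form criterion variant.
#' @return scalar criterion value.
#' @export
tv_criterion <- function(field, eps = 1e-4, form = c("smoothed", "l1")) {
  form <- match.arg(form)
  stopifnot_scalar(eps, "eps", positive = TRUE)
  A <- if (inherits(field, "complex_field")) field$values else field
  gx <- shift_rows(A, 1L) - A
  gy <- shift_cols(A, 1L) - A
  if (form == "smoothed") sum(sqrt(eps + Mod(gx)^2 + Mod(gy)^2))
  else sum(sqrt(eps + Mod(gx) + Mod(gy)))
}

# Object field from a sensor-plane phase estimate:
# A0 = backpropagate(sqrt(I) e^{i phi}).
object_field <- function(phi, sqrtI, pixel_pitch, wavelength, Z) {
  u <- complex_field(sqrtI * exp(1i * phi), pixel_pitch, wavelength)
  propagate(u, -Z)
}

#' Gradient of the TV criterion with respect to the sensor-plane phase
#'
#' Analytic gradient obtained by the chain rule through
#' \code{A0 = backpropagate(sqrt(I_Z) exp(i phi_Z))}; the back-propagation is
#' unitary so its adjoint is forward propagation. Verified against central
#' finite differences in the test suite.
#'
#' @param phi sensor-plane phase matrix (radians).
#' @param I_Z sensor intensity matrix.
#' @param Z propagation distance, micrometers.
#' @param eps TV regularizing constant.
#' @param pixel_pitch,wavelength grid metadata, micrometers.
#' @param form criterion variant, see \code{\link{tv_criterion}}.
#' @return real matrix, same shape as \code{phi}.
#' @export
tv_gradient <- function(phi, I_Z, Z, eps = 1e-4, pixel_pitch = 1.67,
                        wavelength = 0.647, form = c("smoothed", "l1")) {
  form <- match.arg(form)
  sqrtI <- sqrt(pmax(I_Z, 0))
  u <- sqrtI * exp(1i * phi)
  A <- object_field(phi, sqrtI, pixel_pitch, wavelength, Z)$values
  gx <- shift_rows(A, 1L) - A
  gy <- shift_cols(A, 1L) - A
  if (form == "smoothed") {
    r <- sqrt(eps + Mod(gx)^2 + Mod(gy)^2)
    Wx <- gx / (2 * r)
    Wy <- gy / (2 * r)
  } else {
    r <- sqrt(eps + Mod(gx) + Mod(gy))
    tiny <- 1e-300
    Wx <- gx / (4 * r * pmax(Mod(gx), tiny))
    Wy <- gy / (4 * r * pmax(Mod(gy), tiny))
  }
  # d(criterion)/d(A0*): adjoint of the forward differences
  G <- (shift_rows(Wx, -1L) - Wx) + (shift_cols(Wy, -1L) - Wy)
  # adjoint of backpropagation = forward propagation (unitary kernel)
  B <- propagate(complex_field(G, pixel_pitch, wavelength), Z)$values
  2 * Re(1i * u * Conj(B))
}

#' Phase retrieval from an inline hologram by TV-regularized NLCG
#'
#' Runs preconditioned nonlinear conjugate gradients (Hestenes-Stiefel
#' conjugation with restart on non-descent) on the sensor-plane phase,
#' starting from phi_Z = 0, for a fixed number of iterations (default 15).
#' The advancement step minimizes the second-order development of the
#' criterion along the search direction (directional curvature estimated
#' from a differenced gradient), with backtracking halving as a safeguard,
#' so the criterion never increases across accepted iterations. Data
#' fidelity is exact by construction: the returned object field reproduces
#' the measured intensity when propagated back to the sensor.
#'
#' In the small-residual regime the Hessian of the criterion approaches
#' Laplacian / (2 sqrt(eps)), so the gradient is preconditioned in Fourier
#' space by 1 / (lap(k) + precond_c0), where lap(k) is the eigenvalue of the
#' discrete Laplacian; without it the low-spatial-frequency content of the
#' object (the cell body and its twin image) converges very slowly.
#'
#' @param I_Z sensor intensity matrix (nonnegative, finite).
#' @param Z object-to-sensor distance, micrometers.
#' @param wavelength,pixel_pitch grid metadata, micrometers.
#' @param iterations number of NLCG iterations.
#' @param eps TV regularizing constant.
#' @param precond_c0 additive constant of the Fourier preconditioner
#'   (dimensionless, relative to the Laplacian band `[0, 8]`).
#' @return list with \code{field} (object-plane \code{complex_field}),
#'   \code{phase} (object-plane phase matrix, radians), \code{phase_sensor}
#'   (retrieved sensor-plane phase), and \code{criterion} (TV value per
#'   iteration, starting at the initialization).
#' @export
retrieve_phase <- function(I_Z, Z, wavelength = 0.647, pixel_pitch = 1.67,
                           iterations = 15, eps = 1e-4, precond_c0 = 0.05) {
  if (any(!is.finite(I_Z))) stop("intensity must be finite")
  if (any(I_Z < 0)) stop("intensity must be nonnegative")
  sqrtI <- sqrt(I_Z)
  nr <- nrow(I_Z); nc <- ncol(I_Z)
  phi <- matrix(0, nr, nc)
  lapk <- outer(4 * sin(pi * fft_freq(nr))^2, 4 * sin(pi * fft_freq(nc))^2, `+`)
  prec <- function(g)
    Re(stats::fft(stats::fft(g) / (lapk + precond_c0), inverse = TRUE)) / length(g)
  crit <- function(p)
    tv_criterion(object_field(p, sqrtI, pixel_pitch, wavelength, Z), eps)
  grad <- function(p)
    tv_gradient(p, I_Z, Z, eps, pixel_pitch, wavelength)

  history <- numeric(iterations + 1)
  history[1] <- crit(phi)
  D <- NULL; g_prev <- NULL

  for (k in seq_len(iterations)) {
    g <- grad(phi)
    gt <- prec(g)
    if (is.null(D)) {
      D <- -gt
    } else {
      ydiff <- g - g_prev
      denom <- sum(D * ydiff)
      beta <- if (is.finite(denom) && abs(denom) > 1e-300)
        sum(gt * ydiff) / denom else 0
      beta <- max(beta, 0)              # restart guarantees descent
      D <- -gt + beta * D
    }
    slope <- sum(g * D)
    if (!is.finite(slope) || slope >= 0) { D <- -gt; slope <- sum(g * D) }
    if (slope == 0) { history[k + 1] <- history[k]; g_prev <- g; next }

    # second-order development along D: sigma = -slope / curvature
    h <- 1e-3 / max(abs(D))
    curv <- sum((grad(phi + h * D) - g) * D) / h
    sigma <- if (is.finite(curv) && curv > 0) -slope / curv else h
    e0 <- history[k]
    e_new <- crit(phi + sigma * D)
    halved <- 0
    while (e_new > e0 && halved < 12) {   # backtracking fallback
      sigma <- sigma / 2
      e_new <- crit(phi + sigma * D)
      halved <- halved + 1
    }
    if (e_new > e0) { sigma <- 0; e_new <- e0 }
    phi <- phi + sigma * D
    history[k + 1] <- e_new
    g_prev <- g
  }

  A0 <- object_field(phi, sqrtI, pixel_pitch, wavelength, Z)
  list(field = A0, phase = Arg(A0$values), phase_sensor = phi,
       criterion = history)
}

#' Unwrap reconstructed phase by the negative-region rule
#'
#' Cells inducing a phase shift beyond +pi wrap around to negative values in
#' the principal branch. The unwrapping rule used for these reconstructions
#' sets every contiguous (4-connected) region of pixels below the threshold
#' to +pi and leaves the rest untouched. Since all pixels of such a region
#' receive the same value, the rule is applied pixelwise. The literal rule
#' (\code{threshold = 0}, the default) assumes a noise-free nonnegative
#' background; on reconstructions whose background ripples around zero it
#' would flip half the background to +pi, so pipeline use passes a small
#' negative floor (genuinely wrapped cell pixels sit far below zero).
#'
#' @param phase real matrix of phases in (-pi, pi].
#' @param threshold pixels with phase strictly below this value are
#'   considered wrapped.
#' @return phase matrix with wrapped regions replaced by +pi.
#' @export
unwrap_phase <- function(phase, threshold = 0) {
  phase[phase < threshold] <- pi
  phase
}
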