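# Cell detection and seeded-region segmentation on reconstructed phase images.

#' Detect cell-like blobs in a phase image
#'
#' Scale-normalized Laplacian-of-Gaussian detection at the scale implied by
#' the configured blob diameter (sigma = diameter / (2 sqrt(2))), computed
#' spectrally. Responses are normalized to the image maximum so the detector
#' threshold is a relative quality in `[0, 1]`; local maxima (8-neighborhood)
#' above threshold are kept and refined to sub-pixel accuracy by a quadratic
#' fit along each axis.
#'
#' @param phase real matrix (phase image, radians).
#' @param cfg a \code{\link{linking_config}}.
#' @param frame frame index stored with the detections.
#' @return data.frame with columns \code{frame}, \code{x}, \code{y} (0-based
#'   pixel-center coordinates) and \code{quality}.
#' @export
detect_spots <- function(phase, cfg = linking_config(), frame = 0L) {
  if (any(!is.finite(phase))) stop("phase must be finite")
  empty <- data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                      quality = numeric(0))
  nr <- nrow(phase); nc <- ncol(phase)
  sigma <- cfg$blob_diameter_px / (2 * sqrt(2))
  fx <- fft_freq(nr); fy <- fft_freq(nc)
  f2 <- outer(fx^2, fy^2, `+`)
  # -sigma^2 * Laplacian of Gaussian-smoothed image, in Fourier space
  ker <- sigma^2 * 4 * pi^2 * f2 * exp(-2 * pi^2 * sigma^2 * f2)
  resp <- Re(stats::fft(stats::fft(phase) * ker, inverse = TRUE)) / length(phase)
  mx <- max(resp)
  if (!is.finite(mx) || mx < 1e-8) return(empty)
  q <- resp / mx

  keep <- which(q >= cfg$detector_threshold, arr.ind = TRUE)
  keep <- keep[keep[, 1] > 1 & keep[, 1] < nr & keep[, 2] > 1 & keep[, 2] < nc, ,
               drop = FALSE]
  if (nrow(keep) == 0) return(empty)
  is_max <- vapply(seq_len(nrow(keep)), function(i) {
    r <- keep[i, 1]; c <- keep[i, 2]
    nb <- resp[(r - 1):(r + 1), (c - 1):(c + 1)]
    resp[r, c] >= max(nb)
  }, logical(1))
  keep <- keep[is_max, , drop = FALSE]
  if (nrow(keep) == 0) return(empty)

  subpix <- function(a, b, c) {       # parabola through (-1,a),(0,b),(1,c)
    den <- a - 2 * b + c
    if (den >= 0) 0 else max(-0.5, min(0.5, 0.5 * (a - c) / den))
  }
  out <- lapply(seq_len(nrow(keep)), function(i) {
    r <- keep[i, 1]; c <- keep[i, 2]
    dx <- subpix(resp[r - 1, c], resp[r, c], resp[r + 1, c])
    dy <- subpix(resp[r, c - 1], resp[r, c], resp[r, c + 1])
    data.frame(frame = frame, x = r - 1 + dx, y = c - 1 + dy,
               quality = q[r, c])
  })
  do.call(rbind, out)
}

#' Seeded region growing segmentation of one cell
#'
#' Grows a 4-connected region from the seed over all pixels whose phase is at
#' least \code{phase_threshold}. If the seed pixel itself is below threshold
#' an empty mask is returned with attribute \code{empty = TRUE}.
#'
#' @param phase real matrix.
#' @param seed numeric length-2 (x, y) in 0-based pixel-center coordinates,
#'   or a one-row detection data.frame.
#' @param phase_threshold separation between background and cell.
#' @return logical matrix of the same shape; attribute \code{empty} flags a
#'   below-threshold seed, attribute \code{phase_threshold} records the
#'   parameter.
#' @export
segment_cell <- function(phase, seed, phase_threshold) {
  if (is.data.frame(seed)) seed <- c(seed$x[1], seed$y[1])
  nr <- nrow(phase); nc <- ncol(phase)
  r0 <- round(seed[1]) + 1L; c0 <- round(seed[2]) + 1L
  if (r0 < 1 || r0 > nr || c0 < 1 || c0 > nc) stop("seed outside the image")
  mask <- matrix(FALSE, nr, nc)
  if (phase[r0, c0] < phase_threshold) {
    attr(mask, "empty") <- TRUE
    attr(mask, "phase_threshold") <- phase_threshold
    return(mask)
  }
  above <- phase >= phase_threshold
  queue <- integer(nr * nc); qh <- 1L; qt <- 1L
  queue[1] <- (c0 - 1L) * nr + r0
  mask[queue[1]] <- TRUE
  while (qh <= qt) {
    p <- queue[qh]; qh <- qh + 1L
    r <- ((p - 1L) %% nr) + 1L; cc <- ((p - 1L) %/% nr) + 1L
    if (r > 1L)  { q2 <- p - 1L;  if (above[q2] && !mask[q2]) { mask[q2] <- TRUE; qt <- qt + 1L; queue[qt] <- q2 } }
    if (r < nr)  { q2 <- p + 1L;  if (above[q2] && !mask[q2]) { mask[q2] <- TRUE; qt <- qt + 1L; queue[qt] <- q2 } }
    if (cc > 1L) { q2 <- p - nr;  if (above[q2] && !mask[q2]) { mask[q2] <- TRUE; qt <- qt + 1L; queue[qt] <- q2 } }
    if (cc < nc) { q2 <- p + nr;  if (above[q2] && !mask[q2]) { mask[q2] <- TRUE; qt <- qt + 1L; queue[qt] <- q2 } }
  }
  attr(mask, "empty") <- FALSE
  attr(mask, "phase_threshold") <- phase_threshold
  mask
}

#' Segment several cells jointly with a geodesic split of touching cells
#'
#' Multi-source breadth-first growth: every above-threshold pixel is assigned
#' to the seed that reaches it first through 4-connected above-threshold
#' paths (ties to the lower seed index), so touching cells are split along
#' the equidistance boundary, watershed-fashion, and the returned masks are
#' disjoint.
#'
#' @param phase real matrix.
#' @param seeds data.frame with \code{x}, \code{y} columns (0-based), or a
#'   list of length-2 vectors.
#' @param phase_threshold separation between background and cell.
#' @return list of logical masks, one per seed (empty where the seed is below
#'   threshold).
#' @export
segment_cells <- function(phase, seeds, phase_threshold) {
  if (is.data.frame(seeds))
    seeds <- lapply(seq_len(nrow(seeds)), function(i) c(seeds$x[i], seeds$y[i]))
  nr <- nrow(phase); nc <- ncol(phase)
  above <- phase >= phase_threshold
  label <- matrix(0L, nr, nc)
  queue <- integer(nr * nc); qh <- 1L; qt <- 0L
  for (i in seq_along(seeds)) {
    r0 <- round(seeds[[i]][1]) + 1L; c0 <- round(seeds[[i]][2]) + 1L
    if (r0 < 1 || r0 > nr || c0 < 1 || c0 > nc) stop("seed outside the image")
    p <- (c0 - 1L) * nr + r0
    if (above[p] && label[p] == 0L) { label[p] <- i; qt <- qt + 1L; queue[qt] <- p }
  }
  while (qh <= qt) {
    p <- queue[qh]; qh <- qh + 1L
    lab <- label[p]
    r <- ((p - 1L) %% nr) + 1L; cc <- ((p - 1L) %/% nr) + 1L
    for (q2 in c(if (r > 1L) p - 1L, if (r < nr) p + 1L,
                 if (cc > 1L) p - nr, if (cc < nc) p + nr)) {
      if (above[q2] && label[q2] == 0L) {
        label[q2] <- lab; qt <- qt + 1L; queue[qt] <- q2
      }
    }
  }
  lapply(seq_along(seeds), function(i) {
    m <- label == i
    attr(m, "empty") <- !any(m)
    attr(m, "phase_threshold") <- phase_threshold
    m
  })
}
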