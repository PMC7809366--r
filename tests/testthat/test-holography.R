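# Fresnel propagation, TV criterion and gradient, NLCG retrieval, unwrapping.

test_that("plane waves propagate to plane waves and roundtrips invert", {
  v <- matrix(1 + 0i, 64, 64)
  fld <- complex_field(v)
  out <- propagate(fld, 1500)
  expect_lt(max(Mod(out$values - out$values[1, 1])), 1e-12)
  expect_equal(Mod(out$values[1, 1]), 1, tolerance = 1e-12)

  set.seed(1)
  r <- matrix(complex(real = rnorm(64^2), imaginary = rnorm(64^2)), 64)
  fld <- complex_field(r)
  rt <- propagate(propagate(fld, 1500), -1500)
  expect_lt(max(Mod(rt$values - fld$values)), 1e-6)

  expect_warning(propagate(fld, 0), "unchanged")
})

test_that("propagation conserves power and the kernel conjugates under -Z", {
  set.seed(2)
  r <- matrix(complex(real = rnorm(128^2), imaginary = rnorm(128^2)), 128)
  fld <- complex_field(r)
  expect_lt(abs(sum(Mod(propagate(fld, 900)$values)^2) -
                  sum(Mod(r)^2)) / sum(Mod(r)^2), 0.005)
  Hp <- massrhythm:::fresnel_tf(c(64, 64), 1.67, 0.647, 1500)
  Hm <- massrhythm:::fresnel_tf(c(64, 64), 1.67, 0.647, -1500)
  expect_equal(Hm, Conj(Hp), tolerance = 1e-12)
})

test_that("a Gaussian beam expands by the analytic beam formula", {
  n <- 256; pitch <- 1.67; w0 <- 20; lam <- 0.647; Z <- 1500
  x <- (seq_len(n) - n / 2 - 0.5) * pitch
  g <- complex_field(matrix(as.complex(exp(-outer(x^2, x^2, `+`) / w0^2)), n),
                     pitch, lam)
  I <- Mod(propagate(g, Z)$values)^2
  w_meas <- 2 * sqrt(sum(I * outer(x^2, rep(1, n))) / sum(I))
  zR <- pi * w0^2 / lam
  w_true <- w0 * sqrt(1 + (Z / zR)^2)
  expect_lt(abs(w_meas - w_true) / w_true, 0.02)
})

test_that("TV criterion of a constant field is N * sqrt(eps), both forms", {
  fld <- complex_field(matrix(0.7 + 0.2i, 32, 32))
  for (form in c("smoothed", "l1")) {
    expect_equal(tv_criterion(fld, 1e-4, form), 32 * 32 * sqrt(1e-4))
    # default eps honored
    expect_equal(tv_criterion(fld, form = form), 1024 * 0.01)
  }
})

test_that("TV criterion of a single-pixel step matches brute-force summation", {
  A <- matrix(1 + 0i, 8, 8)
  A[4, 5] <- 2 + 0i
  # oracle: direct pixel-wise summation with periodic forward differences
  brute <- function(A, eps, square) {
    n <- nrow(A); m <- ncol(A); s <- 0
    for (i in 1:n) for (j in 1:m) {
      gx <- Mod(A[i %% n + 1, j] - A[i, j])
      gy <- Mod(A[i, j %% m + 1] - A[i, j])
      s <- s + if (square) sqrt(eps + gx^2 + gy^2) else sqrt(eps + gx + gy)
    }
    s
  }
  expect_equal(tv_criterion(A, 1e-4, "smoothed"), brute(A, 1e-4, TRUE))
  expect_equal(tv_criterion(A, 1e-4, "l1"), brute(A, 1e-4, FALSE))
  expect_gt(tv_criterion(A, 1e-4), tv_criterion(matrix(1 + 0i, 8, 8), 1e-4))
})

test_that("TV gradient matches central finite differences on 16x16 fields", {
  set.seed(3)
  n <- 16
  I_Z <- matrix(runif(n^2, 0.5, 1.5), n)
  phi <- matrix(rnorm(n^2, 0, 0.2), n)
  sq <- sqrt(I_Z)
  for (form in c("smoothed", "l1")) {
    g <- tv_gradient(phi, I_Z, 700, 1e-4, 1.67, 0.647, form)
    critf <- function(p)
      tv_criterion(massrhythm:::object_field(p, sq, 1.67, 0.647, 700),
                   1e-4, form)
    h <- 1e-5
    fd <- matrix(0, n, n)
    for (i in seq_len(n^2)) {
      pp <- phi; pp[i] <- pp[i] + h
      pm <- phi; pm[i] <- pm[i] - h
      fd[i] <- (critf(pp) - critf(pm)) / (2 * h)
    }
    expect_lt(max(abs(g - fd)) / max(abs(fd)), 1e-4)
    # criterion invariant to a global sensor-phase shift:
    # directional derivative along the constant direction vanishes
    expect_lt(abs(sum(g)) / sum(abs(g)), 1e-8)
  }
})

test_that("retrieval of an empty scene returns (numerically) zero phase", {
  I <- render_hologram(list(), 64)
  res <- retrieve_phase(I, 1500)
  expect_lt(sqrt(mean(res$phase^2)), 0.01)
  expect_length(res$criterion, 16)   # init + 15 iterations by default
  expect_error(retrieve_phase(matrix(c(NA, 1, 1, 1), 2), 1500), "finite")
  expect_error(retrieve_phase(matrix(-1, 4, 4), 1500), "nonnegative")
})

test_that("NLCG at 15 iterations halves the phase error of back-propagation", {
  n <- 256; pitch <- 1.67; lam <- 0.647; Z <- 1500
  ph <- cell_phantom(c(128, 128), radius_um = 15, peak_opd_um = 0.05)
  opd <- render_phantom_opd(ph, n, pitch)
  true_phase <- 2 * pi * opd / lam
  I <- render_hologram(ph, n, pitch, lam, Z)
  res <- retrieve_phase(I, Z, lam, pitch)
  bp <- propagate(complex_field(sqrt(I) + 0i, pitch, lam), -Z)
  rmse <- function(p) sqrt(mean((p - true_phase)^2))
  expect_lt(rmse(res$phase), 0.5 * rmse(Arg(bp$values)))
  # criterion non-increasing across iterations
  expect_true(all(diff(res$criterion) <= 1e-9 * res$criterion[1]))
  # data fidelity is exact by construction
  I_back <- Mod(propagate(res$field, Z)$values)^2
  expect_equal(I_back, matrix(as.numeric(I), n, n), tolerance = 1e-10)
})

test_that("criterion decreases monotonically on random retrieval instances", {
  set.seed(8)
  ok <- replicate(6, {
    phs <- lapply(1:2, function(i)
      cell_phantom(runif(2, 20, 44), runif(1, 6, 10), runif(1, 0.02, 0.08)))
    I <- render_hologram(phs, 64)
    res <- retrieve_phase(I, 1500, iterations = 8)
    all(diff(res$criterion) <= 1e-9 * res$criterion[1])
  })
  expect_gte(mean(ok), 0.95)
})

test_that("end-to-end phase retrieval recovers integrated OPD within 5%", {
  # noiseless 256x256 scene; recovered integrated OPD over the cell support
  # (background-referenced, as the dry-mass chain integrates it) vs truth
  n <- 256; pitch <- 1.67; lam <- 0.647; Z <- 1500
  ph <- phantom_from_mass(400, c(128, 128), radius_um = 16)
  opd_true <- render_phantom_opd(ph, n, pitch)
  I <- render_hologram(ph, n, pitch, lam, Z)
  res <- retrieve_phase(I, Z, lam, pitch)
  rec <- phase_to_opd(unwrap_phase(res$phase, threshold = -0.5), lam, pitch)
  s <- integrate_ovd(rec, opd_true > 0, pitch)
  ovd_true <- sum(opd_true) * pitch^2
  expect_lt(abs(s$ovd - ovd_true) / ovd_true, 0.05)
})

test_that("unwrapping sets negative regions to +pi and leaves the rest", {
  p <- matrix(0.3, 10, 10)
  expect_identical(unwrap_phase(p), p)

  p[3:5, 4:6] <- -0.1
  u <- unwrap_phase(p)
  expect_true(all(u[3:5, 4:6] == pi))
  expect_true(all(u[p > 0] == 0.3))

  # checkerboard: every negative pixel flips, count preserved (oracle:
  # brute-force region labelling is pixelwise here since each negative
  # pixel is its own 4-connected region)
  cb <- matrix(c(-0.1, 0.1), 8, 8)
  ucb <- unwrap_phase(cb)
  expect_equal(sum(ucb == pi), sum(cb < 0))
  expect_equal(ucb[cb > 0], cb[cb > 0])
})

test_that("image stacks survive the TIFF round trip", {
  stack <- list(matrix(runif(64, -2, 5), 8), matrix(runif(64, -2, 5), 8))
  path <- tempfile(fileext = ".tif")
  write_image_stack(stack, path)
  back <- read_image_stack(path)
  expect_length(back, 2)
  expect_equal(back[[1]], stack[[1]], tolerance = 1e-6)
  expect_equal(back[[2]], stack[[2]], tolerance = 1e-6)
})
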