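# Spot detection, seeded segmentation, LAP linking with gap closing,
# division detection.

test_that("blank images yield no detections", {
  expect_equal(nrow(detect_spots(matrix(0, 64, 64))), 0)
  expect_equal(nrow(detect_spots(matrix(1, 64, 64))), 0)
  expect_error(detect_spots(matrix(NA_real_, 8, 8)), "finite")
})

test_that("well-separated phantoms are each detected within 2 px", {
  centers <- list(c(60, 60), c(60, 180), c(180, 60), c(180, 180), c(120, 120))
  phs <- lapply(centers, function(cc) phantom_from_mass(400, cc, 16))
  opd <- render_phantom_opd(phs, 240, 1.67)
  phase <- 2 * pi * opd / 0.647
  det <- detect_spots(phase)
  expect_equal(nrow(det), 5)
  for (cc in centers) {
    d <- sqrt((det$x - cc[1])^2 + (det$y - cc[2])^2)
    expect_lt(min(d), 2)
  }
  expect_true(all(det$quality >= 0.7 & det$quality <= 1))
})

test_that("two blobs closer than the blob diameter do not crash", {
  phs <- list(phantom_from_mass(400, c(100, 100), 16),
              phantom_from_mass(400, c(100, 104), 16))
  phase <- 2 * pi * render_phantom_opd(phs, 200, 1.67) / 0.647
  det <- detect_spots(phase)
  expect_lte(nrow(det), 2)
  expect_gte(nrow(det), 1)
})

test_that("seeded growing recovers a disc area and splits touching cells", {
  ph <- cell_phantom(c(100, 100), radius_um = 25, peak_opd_um = 0.1,
                     profile = "uniform-disc")
  phase <- 2 * pi * render_phantom_opd(ph, 200, 1) / 0.647  # pitch 1 um
  # threshold at half the disc phase cuts the antialiased edge mid-way,
  # so the mask area matches the geometric disc
  mask <- segment_cell(phase, c(100, 100), 0.45)
  expect_false(attr(mask, "empty"))
  expect_lt(abs(sum(mask) - pi * 25^2) / (pi * 25^2), 0.02)

  # seed below threshold -> empty mask, distinctly flagged
  empty <- segment_cell(phase, c(100, 100), 10)
  expect_true(attr(empty, "empty"))
  expect_equal(sum(empty), 0)

  # touching discs with one seed each split disjointly along the boundary
  phs <- list(cell_phantom(c(80, 100), 20, 0.1, "uniform-disc"),
              cell_phantom(c(116, 100), 20, 0.1, "uniform-disc"))
  ph2 <- 2 * pi * render_phantom_opd(phs, 200, 1) / 0.647
  masks <- segment_cells(ph2, data.frame(x = c(80, 116), y = c(100, 100)), 0.1)
  expect_false(any(masks[[1]] & masks[[2]]))
  area_union <- sum(masks[[1]] | masks[[2]])
  expect_equal(sum(masks[[1]]) + sum(masks[[2]]), area_union)
  # split is near the midline: each cell keeps its own disc center side
  expect_gt(sum(masks[[1]][1:98, ]), 0.9 * sum(masks[[1]]))
})

test_that("the assignment solver is optimal (vs exhaustive search)", {
  brute <- function(C) {
    n <- nrow(C)
    best <- Inf
    rec <- function(rows, cols, acc) {
      if (!length(rows)) { best <<- min(best, acc); return() }
      for (j in cols) rec(rows[-1], setdiff(cols, j), acc + C[rows[1], j])
    }
    rec(seq_len(n), seq_len(n), 0)
    best
  }
  set.seed(11)
  for (k in 1:10) {
    n <- sample(2:6, 1)
    C <- matrix(runif(n * n), n)
    a <- massrhythm:::solve_assignment(C)
    expect_equal(sort(a), seq_len(n))       # a permutation
    expect_equal(sum(C[cbind(seq_len(n), a)]), brute(C), tolerance = 1e-12)
  }
})

test_that("linking follows stationary and gap-broken tracks", {
  det <- data.frame(frame = 0:19, x = 50, y = 60, quality = 1)
  tr <- link_tracks(det)
  expect_equal(length(unique(tr$spots$track_id)), 1)
  expect_equal(nrow(tr$spots), 20)

  # detections missing on frames 8-10 (3 missed frames <= 5), displacement
  # below the cutoff: one joined track
  det2 <- det[!det$frame %in% 8:10, ]
  tr2 <- link_tracks(det2)
  expect_equal(length(unique(tr2$spots$track_id)), 1)

  # a 7-frame gap exceeds max_frame_gap: the two fragments stay separate
  det3 <- data.frame(frame = c(0:9, 17:29), x = 50, y = 60, quality = 1)
  tr3 <- link_tracks(det3)
  expect_equal(length(unique(tr3$spots$track_id)), 2)
  expect_equal(nrow(tr3$spots), 23)
})

test_that("linking is invariant to detection row order and assigns uniquely", {
  det <- drifting_detections(k = 5, n_frames = 25)
  tr1 <- link_tracks(det)
  set.seed(99)
  tr2 <- link_tracks(det[sample(nrow(det)), ])
  key <- function(tr) {
    s <- tr$spots[order(tr$spots$track_id, tr$spots$frame), c("frame", "x", "y")]
    rownames(s) <- NULL
    s
  }
  expect_equal(key(tr1), key(tr2))
  # no detection in two tracks: every (frame, x, y) appears once
  expect_false(any(duplicated(tr1$spots[c("frame", "x", "y")])))
  # all retained tracks satisfy min_spots
  expect_true(all(table(tr1$spots$track_id) >= 10))
})

test_that("tracking a synthetic cohort reaches purity and completeness 0.95", {
  coh <- generate_cohort(cohort_config(n_cells = 8, seed = 21,
                                       duration = 1000, field_px = 256))
  # ground-truth detections from founder positions (frames 0..79)
  det <- do.call(rbind, lapply(seq_along(coh$ground_truth), function(j) {
    g <- coh$ground_truth[[j]]
    data.frame(frame = 0:79, x = g$positions[1:80, 1],
               y = g$positions[1:80, 2], quality = 1, truth = j)
  }))
  tr <- link_tracks(det[order(det$x), ])
  spots <- tr$spots   # the ground-truth label rides along with each spot
  # purity: fraction of each track's spots from its majority ground-truth cell
  purity <- sapply(split(spots$truth, spots$track_id),
                   function(tt) max(table(tt)) / length(tt))
  # completeness: fraction of each cell's detections in its majority track
  compl <- sapply(split(spots$track_id, spots$truth),
                  function(ids) max(table(ids)) / length(ids))
  expect_gte(mean(purity), 0.95)
  expect_gte(mean(compl), 0.95)
})

test_that("divisions require both the mass drop and a daughter track", {
  # constant-mass track with an unrelated track appearing nearby: no division
  det <- rbind(data.frame(frame = 0:29, x = 50, y = 50, quality = 1),
               data.frame(frame = 10:29, x = 58, y = 50, quality = 1))
  tr <- link_tracks(det)
  ids <- sort(unique(tr$spots$track_id))
  traces <- setNames(list(rep(500, 30), rep(400, 20)), ids)
  dv <- detect_divisions(tr, traces)
  expect_equal(nrow(dv$events), 0)

  # mass drop without any track birth: still no division
  traces2 <- setNames(list(c(rep(500, 15), rep(250, 15)), rep(400, 20)), ids)
  det_iso <- data.frame(frame = 0:29, x = 50, y = 50, quality = 1)
  tr_iso <- link_tracks(det_iso)
  dv_iso <- detect_divisions(tr_iso,
                             setNames(list(c(rep(500, 15), rep(250, 15))), "1"))
  expect_equal(nrow(dv_iso$events), 0)

  # drop + daughter birth within the distance cutoff: one division at the
  # right frame, and interphases tile the track
  det2 <- rbind(data.frame(frame = 0:29, x = 50, y = 50, quality = 1),
                data.frame(frame = 15:29, x = 55, y = 52, quality = 1))
  tr2 <- link_tracks(det2)
  ids2 <- sort(unique(tr2$spots$track_id))
  m <- c(rep(500, 14), 500, 350, 250, rep(255, 13))
  traces3 <- setNames(list(m, rep(240, 15)), ids2)
  dv2 <- detect_divisions(tr2, traces3)
  expect_equal(nrow(dv2$events), 1)
  expect_lte(abs(dv2$events$frame[1] - 14), 1)
  ip <- dv2$interphases[dv2$interphases$track_id == dv2$events$track_id[1], ]
  expect_equal(min(ip$start_frame), 0)
  expect_equal(max(ip$end_frame), 29)
  expect_equal(sum(ip$end_frame - ip$start_frame), 29)
})

test_that("division recovery on a rendered scene reaches 0.9", {
run_division_scene <- function(seed, n_frames = 280) {
  coh <- generate_cohort(cohort_config(n_cells = 6, seed = seed,
                                       duration = 1400, field_px = 400))
  scene <- render_scene(coh, 0:(n_frames - 1), mode = "phase")
  # detection quality is normalized to the brightest cell in the frame; with
  # division halving and growth, cells span ~2.5x in mass, so the scene
  # threshold admits that range (the 0.7 default assumes comparable cells)
  lcfg <- linking_config(detector_threshold = 0.25)
  dets <- do.call(rbind, lapply(seq_len(n_frames), function(k)
    detect_spots(scene$images[[k]], lcfg, frame = k - 1L)))
  tracks <- link_tracks(dets, lcfg)
  mtr <- build_traces(tracks, scene$images, phase_threshold = 0.1, dt = 5)
  dv <- detect_divisions(tracks, lapply(mtr, function(tr) tr$mass), lcfg)
  # ground-truth divisions observable under the 10-spot track filter (a
  # daughter born in the last frames cannot form a retained track)
  true_divs <- unlist(lapply(coh$ground_truth, function(g)
    round(g$division_times[g$division_times / 5 <= n_frames - 15] / 5)))
  # a detected event within 3 frames (15 min) counts: the event is declared
  # when the daughter track is first resolved, 1-3 frames after cleavage
  hit_true <- sapply(true_divs, function(f) any(abs(dv$events$frame - f) <= 3))
  hit_det <- if (nrow(dv$events))
    sapply(dv$events$frame, function(f) any(abs(true_divs - f) <= 3))
  else logical(0)
  list(n_true = length(true_divs), tp = sum(hit_true),
       n_det = length(hit_det), tp_det = sum(hit_det))
}
  r <- run_division_scene(35)
  expect_gte(r$n_true, 3)
  expect_gte(r$tp / r$n_true, 0.9)
  expect_gte(r$tp_det / r$n_det, 0.9)
})

test_that("tracks CSV round trip preserves spots in tracks", {
  det <- drifting_detections(k = 3, n_frames = 15)
  tr <- link_tracks(det)
  path <- tempfile(fileext = ".csv")
  write_tracks_csv(tr, path)
  back <- read_tracks_csv(path)
  expect_equal(back$spots$x, tr$spots$x)
  expect_equal(back$spots$track_id, tr$spots$track_id)
  hdr <- names(read.csv(path))
  expect_equal(hdr, c("TRACK_ID", "POSITION_X", "POSITION_Y", "FRAME",
                      "QUALITY"))
})
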