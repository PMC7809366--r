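# Frame-to-frame track linking with gap closing, in the style of LAP-based
# single-particle trackers.

# Minimum-cost perfect assignment on a square cost matrix by the O(n^3)
# shortest-augmenting-path (Jonker-Volgenant) algorithm with potentials.
# Returns, for each row, the assigned column. Written here because no
# installed package provides a weighted assignment solver; unit-tested
# against exhaustive permutation search.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  if (n == 0) return(integer(0))
  if (n != ncol(cost)) stop("cost matrix must be square")
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1)   # p[j]: row assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L            # column indices offset by 1 (1 = virtual column)
    minv <- rep(INF, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- INF; j1 <- 0L
      for (j in 2:(n + 1)) {
        if (!used[j]) {
          cur <- cost[i0, j - 1] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in 1:(n + 1)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  ans <- integer(n)
  for (j in 2:(n + 1)) if (p[j] > 0) ans[p[j]] <- j - 1L
  ans
}

# Frame-to-frame matching of two point sets with a distance cutoff, via the
# Jaqaman-style augmented matrix: links cost their distance, non-links cost
# the cutoff (birth/death alternative). Returns an integer vector: for each
# point of set a, the matched index in set b or NA.
match_frame_pair <- function(ax, ay, bx, by, cutoff) {
  n <- length(ax); m <- length(bx)
  if (n == 0 || m == 0) return(rep(NA_integer_, n))
  BIG <- 1e9
  d <- sqrt(outer(ax, bx, `-`)^2 + outer(ay, by, `-`)^2)
  C <- matrix(BIG, n + m, n + m)
  link <- d; link[link > cutoff] <- BIG
  C[1:n, 1:m] <- link
  for (i in 1:n) C[i, m + i] <- cutoff          # death of a_i
  for (j in 1:m) C[n + j, j] <- cutoff          # birth of b_j
  C[(n + 1):(n + m), (m + 1):(m + n)] <- t(link) * 0  # lower-right: feasibility
  asg <- solve_assignment(C)
  out <- rep(NA_integer_, n)
  for (i in 1:n) if (asg[i] <= m && d[i, asg[i]] <= cutoff) out[i] <- asg[i]
  out
}

#' Link per-frame detections into cell tracks
#'
#' Two passes, mirroring LAP-style particle trackers: (1) optimal
#' frame-to-frame assignment (minimum total displacement, bipartite matching
#' with a hard \code{max_link_px} cutoff and birth/death alternatives);
#' (2) gap closing, joining the end of one track to the start of a later one
#' when the spatial distance is at most \code{gap_close_px} and at most
#' \code{max_frame_gap} frames were missed, candidate pairs taken in order of
#' increasing distance then increasing frame gap. Tracks with fewer than
#' \code{min_spots} detections are discarded.
#'
#' @param detections data.frame with columns \code{frame}, \code{x},
#'   \code{y} (and optionally \code{quality}); row order is irrelevant.
#' @param cfg a \code{\link{linking_config}}.
#' @return an object of class \code{"cell_tracks"}: list with \code{spots}
#'   (the detections with a \code{track_id} column) and \code{config}.
#' @export
link_tracks <- function(detections, cfg = linking_config()) {
  det <- detections[order(detections$frame, detections$x, detections$y), ,
                    drop = FALSE]
  det$track_id <- NA_integer_
  if (nrow(det) == 0)
    return(structure(list(spots = det, config = cfg), class = "cell_tracks"))
  frames <- sort(unique(det$frame))
  next_id <- 1L
  idx_by_frame <- split(seq_len(nrow(det)), det$frame)

  # pass 1: frame-to-frame linking
  prev_idx <- idx_by_frame[[as.character(frames[1])]]
  det$track_id[prev_idx] <- seq_len(length(prev_idx))
  next_id <- length(prev_idx) + 1L
  if (length(frames) > 1) {
    for (fi in 2:length(frames)) {
      cur_idx <- idx_by_frame[[as.character(frames[fi])]]
      if (frames[fi] - frames[fi - 1] == 1L && length(prev_idx)) {
        mt <- match_frame_pair(det$x[prev_idx], det$y[prev_idx],
                               det$x[cur_idx], det$y[cur_idx],
                               cfg$max_link_px)
        for (i in seq_along(prev_idx)) {
          if (!is.na(mt[i]))
            det$track_id[cur_idx[mt[i]]] <- det$track_id[prev_idx[i]]
        }
      }
      new <- cur_idx[is.na(det$track_id[cur_idx])]
      if (length(new)) {
        det$track_id[new] <- next_id + seq_along(new) - 1L
        next_id <- next_id + length(new)
      }
      prev_idx <- cur_idx
    }
  }

  # pass 2: gap closing (greedy on distance, then frame gap; repeat to allow
  # chains of closures)
  repeat {
    ends <- do.call(rbind, lapply(split(seq_len(nrow(det)), det$track_id),
      function(ii) {
        last <- ii[which.max(det$frame[ii])]
        first <- ii[which.min(det$frame[ii])]
        data.frame(id = det$track_id[last],
                   end_frame = det$frame[last], ex = det$x[last], ey = det$y[last],
                   start_frame = det$frame[first], sx = det$x[first], sy = det$y[first])
      }))
    cand <- NULL
    for (a in seq_len(nrow(ends))) {
      gap <- ends$start_frame - ends$end_frame[a] - 1L
      dd <- sqrt((ends$sx - ends$ex[a])^2 + (ends$sy - ends$ey[a])^2)
      ok <- which(gap >= 0 & gap <= cfg$max_frame_gap & dd <= cfg$gap_close_px &
                    ends$id != ends$id[a])
      if (length(ok))
        cand <- rbind(cand, data.frame(from = ends$id[a], to = ends$id[ok],
                                       d = dd[ok], gap = gap[ok]))
    }
    if (is.null(cand) || nrow(cand) == 0) break
    cand <- cand[order(cand$d, cand$gap), , drop = FALSE]
    used_from <- used_to <- integer(0)
    merged <- FALSE
    for (r in seq_len(nrow(cand))) {
      if (cand$from[r] %in% used_from || cand$to[r] %in% used_to ||
          cand$from[r] %in% used_to || cand$to[r] %in% used_from) next
      det$track_id[det$track_id == cand$to[r]] <- cand$from[r]
      used_from <- c(used_from, cand$from[r])
      used_to <- c(used_to, cand$to[r])
      merged <- TRUE
    }
    if (!merged) break
  }

  # filter by number of spots and renumber
  counts <- table(det$track_id)
  keep <- names(counts)[counts >= cfg$min_spots]
  det <- det[det$track_id %in% as.integer(keep), , drop = FALSE]
  det$track_id <- as.integer(factor(det$track_id))
  det <- det[order(det$track_id, det$frame), , drop = FALSE]
  rownames(det) <- NULL
  structure(list(spots = det, config = cfg), class = "cell_tracks")
}

#' @export
print.cell_tracks <- function(x, ...) {
  nt <- length(unique(x$spots$track_id))
  cat(sprintf("<cell_tracks> %d tracks, %d spots, frames %s-%s\n", nt,
              nrow(x$spots),
              if (nrow(x$spots)) min(x$spots$frame) else "-",
              if (nrow(x$spots)) max(x$spots$frame) else "-"))
  invisible(x)
}

#' Extract one track's spots
#'
#' @param tracks a \code{"cell_tracks"} object.
#' @param id track id.
#' @return data.frame of the track's spots ordered by frame.
#' @export
track_spots <- function(tracks, id) {
  s <- tracks$spots[tracks$spots$track_id == id, , drop = FALSE]
  s[order(s$frame), , drop = FALSE]
}

#' Detect division events on tracked dry-mass traces
#'
#' A division is declared at frame f of a track when (a) the track's mass
#' drops by at least \code{drop_frac} between f and f + 2, and (b) a new
#' track is born within \code{gap_close_px} of the track's position during
#' `[f, f+2]`. After a declared division the next \code{refractory} frames
#' are skipped. Interphase intervals are the segments between consecutive
#' divisions (or track start/end), which tile the track's lifetime.
#'
#' @param tracks a \code{"cell_tracks"} object.
#' @param traces named list of mass vectors (pg), one per track id, aligned
#'   with the track's frames.
#' @param cfg a \code{\link{linking_config}} (for \code{gap_close_px}).
#' @param drop_frac minimum relative mass drop over two frames.
#' @param refractory frames skipped after a declared division.
#' @return list with \code{events} (data.frame: track_id, frame,
#'   daughter_track) and \code{interphases} (data.frame: track_id,
#'   start_frame, end_frame, from_division, complete).
#' @export
detect_divisions <- function(tracks, traces, cfg = linking_config(),
                             drop_frac = 0.3, refractory = 4L) {
  spots <- tracks$spots
  ids <- unique(spots$track_id)
  births <- do.call(rbind, lapply(ids, function(id) {
    s <- track_spots(tracks, id)
    data.frame(track_id = id, frame = s$frame[1], x = s$x[1], y = s$y[1])
  }))
  global_first <- min(spots$frame)
  events <- NULL
  for (id in ids) {
    s <- track_spots(tracks, id)
    m <- traces[[as.character(id)]]
    if (is.null(m) || length(m) != nrow(s)) next
    i <- 1L
    while (i <= length(m) - 2L) {
      f <- s$frame[i]
      drop <- 1 - m[i + 2L] / m[i]
      if (is.finite(drop) && drop >= drop_frac) {
        nb <- births[births$track_id != id & births$frame >= f &
                       births$frame <= f + 2L & births$frame > global_first, ,
                     drop = FALSE]
        if (nrow(nb)) {
          # distance to the track over the event window: right at the split
          # the merged blob centroid sits between the two cells, so the
          # single-frame position can overshoot the cutoff
          win <- which(s$frame >= f & s$frame <= f + 2L)
          dd <- vapply(seq_len(nrow(nb)), function(q)
            min(sqrt((nb$x[q] - s$x[win])^2 + (nb$y[q] - s$y[win])^2)),
            numeric(1))
          hit <- which(dd <= cfg$gap_close_px)
          if (length(hit)) {
            events <- rbind(events,
                            data.frame(track_id = id, frame = f,
                                       daughter_track = nb$track_id[hit[which.min(dd[hit])]]))
            i <- i + refractory
            next
          }
        }
      }
      i <- i + 1L
    }
  }
  if (is.null(events))
    events <- data.frame(track_id = integer(0), frame = integer(0),
                         daughter_track = integer(0))

  interphases <- do.call(rbind, lapply(ids, function(id) {
    s <- track_spots(tracks, id)
    divs <- sort(unique(events$frame[events$track_id == id]))
    first <- s$frame[1]; last <- s$frame[nrow(s)]
    divs <- divs[divs > first & divs < last]
    bounds <- c(first, divs, last)
    data.frame(track_id = id,
               start_frame = bounds[-length(bounds)],
               end_frame = bounds[-1],
               from_division = bounds[-length(bounds)] %in% divs,
               complete = (bounds[-length(bounds)] %in% divs) &
                          (bounds[-1] %in% divs))
  }))
  list(events = events, interphases = interphases)
}

#' Write tracks as a spots-in-tracks statistics CSV
#'
#' Column layout TRACK_ID, POSITION_X, POSITION_Y, FRAME, QUALITY, matching
#' the text table exported by common particle-tracking tools, so externally
#' produced tracks can enter or leave the pipeline.
#'
#' @param tracks a \code{"cell_tracks"} object.
#' @param path output CSV file.
#' @export
write_tracks_csv <- function(tracks, path) {
  s <- tracks$spots
  df <- data.frame(TRACK_ID = s$track_id, POSITION_X = s$x, POSITION_Y = s$y,
                   FRAME = s$frame,
                   QUALITY = if (is.null(s$quality)) 1 else s$quality)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a spots-in-tracks statistics CSV
#'
#' @param path CSV with TRACK_ID, POSITION_X, POSITION_Y, FRAME, QUALITY.
#' @param cfg linking configuration stored with the result.
#' @return a \code{"cell_tracks"} object.
#' @export
read_tracks_csv <- function(path, cfg = linking_config()) {
  df <- utils::read.csv(path)
  spots <- data.frame(frame = as.integer(df$FRAME), x = df$POSITION_X,
                      y = df$POSITION_Y, quality = df$QUALITY,
                      track_id = as.integer(df$TRACK_ID))
  spots <- spots[order(spots$track_id, spots$frame), ]
  rownames(spots) <- NULL
  structure(list(spots = spots, config = cfg), class = "cell_tracks")
}
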