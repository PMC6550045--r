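# Globally optimal frame-to-frame linking (rectangular assignment problem)
# and sequential track building with gap closing.

# O(n^3) Hungarian algorithm (potentials + augmenting paths) on a full cost
# matrix; returns for each row the assigned column (NA if matched to padding).
# Deterministic for a given input.
hungarian <- function(cost) {
  nr <- nrow(cost); nc <- ncol(cost)
  n <- max(nr, nc)
  big <- max(cost[is.finite(cost)], 0) * n + 1
  a <- matrix(big, n, n)
  fin <- cost
  fin[!is.finite(fin)] <- big
  a[seq_len(nr), seq_len(nc)] <- fin
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1); way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(INF, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]; delta <- INF; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- a[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
          if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else minv[j + 1] <- minv[j + 1] - delta
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign_row <- rep(NA_integer_, nr)
  for (j in seq_len(n)) {
    i <- p[j + 1]
    if (i >= 1 && i <= nr && j <= nc && cost[i, j] < big && is.finite(cost[i, j]))
      assign_row[i] <- j
  }
  assign_row
}

#' Link detections between two frames
#'
#' Finds the one-to-one assignment between two detection sets that minimizes
#' total displacement, restricted to pairs closer than `max_disp` (solved as
#' a rectangular linear assignment problem). Detections with no admissible
#' partner stay unmatched.
#'
#' @param dets_a,dets_b Data frames with columns `x`, `y` (pixels), as
#'   returned by [detect_maxima()].
#' @param max_disp Gating distance in pixels (> 0).
#' @return Data frame with columns `i` (row in `dets_a`), `j` (row in
#'   `dets_b`) and `dist`; zero rows if nothing links.
#' @examples
#' a <- data.frame(x = 0, y = 0); b <- data.frame(x = 3, y = 4)
#' link_frames(a, b, max_disp = 10)  # one link of displacement 5
#' @export
link_frames <- function(dets_a, dets_b, max_disp) {
  if (max_disp <= 0) stop("max_disp must be > 0")
  empty <- data.frame(i = integer(), j = integer(), dist = numeric())
  if (nrow(dets_a) == 0 || nrow(dets_b) == 0) return(empty)
  d <- sqrt(outer(dets_a$x, dets_b$x, "-")^2 +
            outer(dets_a$y, dets_b$y, "-")^2)
  cost <- d
  cost[d > max_disp] <- Inf
  if (all(!is.finite(cost))) return(empty)
  asg <- hungarian(cost)
  i <- which(!is.na(asg))
  out <- data.frame(i = i, j = asg[i], dist = d[cbind(i, asg[i])])
  out[out$dist <= max_disp, , drop = FALSE]
}

#' Build tracks from per-frame detections
#'
#' Sequentially links detections frame to frame with [link_frames()]. A track
#' unmatched in a frame stays open for up to `max_gap` further frames; a
#' gap-closing link over `g` skipped frames is admitted within
#' `max_disp * (g + 1)`. Track ids are assigned in order of first appearance.
#'
#' @param detections Data frame with columns `frame`, `x`, `y`.
#' @param max_disp Per-frame gating distance, pixels.
#' @param max_gap Maximum number of consecutive missed frames (>= 0).
#' @return Data frame with columns `track_id`, `frame`, `x`, `y` and `gap`
#'   (TRUE when the position follows closed gap frames).
#' @export
build_tracks <- function(detections, max_disp, max_gap = 2) {
  stopifnot(all(c("frame", "x", "y") %in% names(detections)))
  if (max_gap < 0) stop("max_gap must be >= 0")
  frames <- sort(unique(detections$frame))
  out <- list()
  # open track state: id, last frame, last x, y
  open <- data.frame(id = integer(), frame = integer(),
                     x = numeric(), y = numeric())
  next_id <- 1L
  for (f in frames) {
    det <- detections[detections$frame == f, , drop = FALSE]
    open <- open[f - open$frame <= max_gap + 1L, , drop = FALSE]
    matched_det <- rep(FALSE, nrow(det))
    if (nrow(open) > 0 && nrow(det) > 0) {
      d <- sqrt(outer(open$x, det$x, "-")^2 + outer(open$y, det$y, "-")^2)
      gate <- max_disp * (f - open$frame)   # gap + 1 elapsed frames
      cost <- d
      cost[d > matrix(gate, nrow(open), nrow(det))] <- Inf
      if (any(is.finite(cost))) {
        asg <- hungarian(cost)
        for (i in which(!is.na(asg))) {
          j <- asg[i]
          out[[length(out) + 1]] <- data.frame(
            track_id = open$id[i], frame = f, x = det$x[j], y = det$y[j],
            gap = (f - open$frame[i]) > 1L)
          open$frame[i] <- f; open$x[i] <- det$x[j]; open$y[i] <- det$y[j]
          matched_det[j] <- TRUE
        }
      }
    }
    for (j in which(!matched_det)) {
      out[[length(out) + 1]] <- data.frame(
        track_id = next_id, frame = f, x = det$x[j], y = det$y[j], gap = FALSE)
      open <- rbind(open, data.frame(id = next_id, frame = f,
                                     x = det$x[j], y = det$y[j]))
      next_id <- next_id + 1L
    }
  }
  if (length(out) == 0)
    return(data.frame(track_id = integer(), frame = integer(), x = numeric(),
                      y = numeric(), gap = logical()))
  res <- do.call(rbind, out)
  res <- res[order(res$track_id, res$frame), ]
  rownames(res) <- NULL
  res
}
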