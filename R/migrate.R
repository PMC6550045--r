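# Migration read-outs: ROI counts over time, step velocities, and the
# 8-bin directionality histogram relative to the wound.

#' Count detections inside the wound counting region
#'
#' Counts centroids falling inside the counting region per frame (boundaries
#' inclusive) and averages the counts within each hour of imaging. Hour `h`
#' covers times `[60*(h-1), 60*h)` minutes, with frame 1 at time 0.
#'
#' @param detections Data frame with columns `frame`, `x`, `y` (pixels).
#' @param roi A [wound_roi()].
#' @param frame_interval Minutes between frames.
#' @param frame_dim Optional `c(width_px, height_px)`; when supplied, the ROI
#'   is checked to lie inside the frame.
#' @return List with `per_frame` (`frame`, `time_min`, `count`) and
#'   `per_hour` (`hour`, `mean_count`, `n_frames`).
#' @export
count_in_roi <- function(detections, roi, frame_interval = 1,
                         frame_dim = NULL) {
  stopifnot(inherits(roi, "wound_roi"))
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  if (!is.null(frame_dim)) {
    r <- roi$region
    bb <- if (r$type == "rect") r$xy else
      c(min(r$xy[, 1]), min(r$xy[, 2]), max(r$xy[, 1]), max(r$xy[, 2]))
    if (bb[1] < -0.5 || bb[2] < -0.5 ||
        bb[3] > frame_dim[1] - 0.5 || bb[4] > frame_dim[2] - 0.5)
      stop("counting region lies outside the frame")
  }
  frames <- sort(unique(detections$frame))
  inside <- in_region(roi, detections$x, detections$y)
  count <- vapply(frames, function(f)
    sum(inside[detections$frame == f]), numeric(1))
  per_frame <- data.frame(frame = frames,
                          time_min = (frames - 1) * frame_interval,
                          count = count)
  per_frame$hour <- floor(per_frame$time_min / 60) + 1L
  agg <- stats::aggregate(count ~ hour, data = per_frame, FUN = mean)
  n <- stats::aggregate(count ~ hour, data = per_frame, FUN = length)
  per_hour <- data.frame(hour = agg$hour, mean_count = agg$count,
                         n_frames = n$count)
  list(per_frame = per_frame[, c("frame", "time_min", "count")],
       per_hour = per_hour)
}

#' Step vectors and per-hour velocity of tracked cells
#'
#' Converts consecutive track positions into step vectors: displacement in
#' micrometers, velocity in micrometers per minute (gap-closed steps divide
#' by the full elapsed time), start time, and — when a wound reference is
#' given — the signed angle between the step and the direction from the
#' step's start point toward the nearest wound point, in degrees in
#' (-180, 180] (NA for zero-displacement steps).
#'
#' @param tracks Data frame from [build_tracks()] (`track_id`, `frame`, `x`,
#'   `y`).
#' @param pixel_size Micrometers per pixel (> 0).
#' @param frame_interval Minutes per frame (> 0).
#' @param roi Optional [wound_roi()] supplying the wound geometry.
#' @return List with `steps` (`track_id`, `time_min`, `displacement_um`,
#'   `velocity`, `theta_deg`) and `per_hour` (`hour`, `mean_velocity`,
#'   `n_steps`), hourly means taken over steps starting within the hour.
#' @export
step_velocities <- function(tracks, pixel_size, frame_interval, roi = NULL) {
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  tracks <- tracks[order(tracks$track_id, tracks$frame), ]
  sp <- split(tracks, tracks$track_id)
  steps <- do.call(rbind, lapply(sp, function(tr) {
    n <- nrow(tr)
    if (n < 2) return(NULL)
    dx <- diff(tr$x); dy <- diff(tr$y)
    df <- diff(tr$frame)
    d_um <- sqrt(dx^2 + dy^2) * pixel_size
    theta <- rep(NA_real_, n - 1)
    if (!is.null(roi)) {
      np <- nearest_wound_point(roi, tr$x[-n], tr$y[-n])
      mu <- atan2(np[, 2] - tr$y[-n], np[, 1] - tr$x[-n])
      ang <- atan2(dy, dx)
      theta <- wrap_angle(ang - mu) * 180 / pi
      theta[d_um == 0] <- NA_real_
    }
    data.frame(track_id = tr$track_id[1],
               time_min = (tr$frame[-n] - 1) * frame_interval,
               displacement_um = d_um,
               velocity = d_um / (df * frame_interval),
               theta_deg = theta)
  }))
  if (is.null(steps))
    steps <- data.frame(track_id = integer(), time_min = numeric(),
                        displacement_um = numeric(), velocity = numeric(),
                        theta_deg = numeric())
  rownames(steps) <- NULL
  if (nrow(steps) > 0) {
    hour <- floor(steps$time_min / 60) + 1L
    agg <- stats::aggregate(steps$velocity, list(hour = hour), mean)
    n <- stats::aggregate(steps$velocity, list(hour = hour), length)
    per_hour <- data.frame(hour = agg$hour, mean_velocity = agg$x,
                           n_steps = n$x)
  } else {
    per_hour <- data.frame(hour = integer(), mean_velocity = numeric(),
                           n_steps = integer())
  }
  list(steps = steps, per_hour = per_hour)
}

#' Assign step angles to the eight directionality bins
#'
#' Bin `k` covers angles `(45k - 22.5, 45k + 22.5]` degrees; bin 0 is the
#' direction toward the wound, bin 4 directly away. The bins are
#' left-open/right-closed, so 22.5 degrees falls in bin 0 and -22.5 degrees
#' in bin 7.
#'
#' @param theta_deg Angles in degrees in (-180, 180].
#' @return Integer bin indices 0..7 (NA propagates).
#' @export
direction_bin <- function(theta_deg) {
  k <- ceiling((theta_deg - 22.5) / 45)
  as.integer(k %% 8)
}

#' Eight-bin directionality histogram of step vectors
#'
#' Bins the nonzero steps starting within a time window by their angle to the
#' wound and normalizes to fractions. Zero-displacement steps are excluded
#' from the angular bins and reported as a separate immobile count.
#'
#' @param steps Step data frame from [step_velocities()] (needs `time_min`,
#'   `displacement_um`, `theta_deg`).
#' @param window Length-2 numeric, minutes; steps with
#'   `window[1] <= time_min < window[2]` are used. Default spans all steps.
#' @return List with `fractions` (named numeric, `bin0`..`bin7`), `n_steps`,
#'   `n_immobile`, `window` and `empty` (TRUE when no nonzero step falls in
#'   the window, in which case fractions are NA).
#' @export
directionality <- function(steps, window = c(-Inf, Inf)) {
  if (length(window) != 2 || window[2] <= window[1])
    stop("window must be a non-empty interval c(t0, t1)")
  sel <- steps$time_min >= window[1] & steps$time_min < window[2]
  s <- steps[sel, , drop = FALSE]
  moving <- s$displacement_um > 0 & !is.na(s$theta_deg)
  n_imm <- sum(!moving)
  s <- s[moving, , drop = FALSE]
  fr <- stats::setNames(rep(NA_real_, 8), paste0("bin", 0:7))
  if (nrow(s) == 0)
    return(list(fractions = fr, n_steps = 0L, n_immobile = n_imm,
                window = window, empty = TRUE))
  b <- direction_bin(s$theta_deg)
  tab <- tabulate(b + 1L, nbins = 8)
  fr[] <- tab / sum(tab)
  list(fractions = fr, n_steps = nrow(s), n_immobile = n_imm,
       window = window, empty = FALSE)
}

#' Compare per-hour group means by ANOVA with Fisher's LSD
#'
#' For each hour, runs a one-way ANOVA across groups on per-replicate hourly
#' means, followed by Fisher's LSD post hoc test (unadjusted pairwise t-tests
#' on the pooled within-group variance). Delegates to [anova_lsd()].
#'
#' @param hourly Data frame with columns `group`, `replicate`, `hour`,
#'   `value` (one value per group x replicate x hour).
#' @return List with `omnibus` (`hour`, `F`, `p`, `degenerate`) and
#'   `pairwise` (`hour`, `group1`, `group2`, `diff`, `p`).
#' @export
compare_hourly <- function(hourly) {
  stopifnot(all(c("group", "replicate", "hour", "value") %in% names(hourly)))
  hours <- sort(unique(hourly$hour))
  omni <- list(); pw <- list()
  for (h in hours) {
    d <- hourly[hourly$hour == h, ]
    res <- anova_lsd(split(d$value, d$group))
    omni[[length(omni) + 1]] <- data.frame(hour = h, F = res$F, p = res$p,
                                           degenerate = res$degenerate)
    pr <- res$pairwise
    pr$hour <- h
    pw[[length(pw) + 1]] <- pr[, c("hour", "group1", "group2", "diff", "p")]
  }
  list(omnibus = do.call(rbind, omni), pairwise = do.call(rbind, pw))
}
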