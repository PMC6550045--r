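#' Configuration for a simulated wound-migration scene
#'
#' Describes a single-channel time-lapse acquisition of leukocytes performing
#' a wound-biased random walk, mimicking confocal maximum-projection movies of
#' a wounded tail fin imaged at roughly one frame per minute. Defaults follow
#' the imaging conditions the pipeline is designed for: a few tens of cells
#' per field moving at a few micrometers per minute.
#'
#' Cells step with speed drawn from a normal distribution truncated at zero
#' and direction drawn from a von Mises distribution centred on the direction
#' toward the nearest point of the wound geometry; `kappa = 0` gives an
#' unbiased random walk. Cells are rendered as anisotropic Gaussian blobs
#' whose major axis follows the direction of motion, so the axis ratio
#' controls the true circularity of each cell's iso-intensity outline.
#'
#' @param width_px,height_px Frame size in pixels.
#' @param pixel_size Pixel size in micrometers per pixel (> 0).
#' @param n_frames Number of frames (>= 2).
#' @param frame_interval Time between frames in minutes (> 0).
#' @param n_cells Number of cells (>= 0).
#' @param speed_mean,speed_sd Step speed distribution, micrometers per minute.
#' @param kappa von Mises concentration of step directions toward the wound
#'   (>= 0; 0 = unbiased walk).
#' @param wound A [wound_roi()] giving the counting region and the wound
#'   geometry, in pixel coordinates.
#' @param axis_ratio_range Length-2 vector `c(1, rmax)`; each cell's
#'   elongation (major/minor axis ratio) is drawn uniformly from it.
#' @param blob_sigma Gaussian point-spread scale of a rendered cell, pixels.
#' @param min_separation Minimum pairwise distance between cells in pixels
#'   (0 = no constraint). Enforced at initialization by rejection placement
#'   and during the walk by volume exclusion: a step that would bring two
#'   cells closer than this is re-drawn (up to 20 tries, then the cell rests
#'   for that frame).
#' @param peak_intensity Peak intensity of a rendered (circular) cell above
#'   background, arbitrary units.
#' @param background_level,noise_sd Background intensity and additive Gaussian
#'   noise standard deviation, arbitrary units.
#' @param seed Integer seed making the whole scene reproducible.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(width_px = 256, height_px = 256, pixel_size = 0.65,
                         n_frames = 60, frame_interval = 1, n_cells = 30,
                         speed_mean = 3.5, speed_sd = 1, kappa = 0,
                         wound = wound_roi(
                           region = c(width_px * 0.6, 0, width_px - 1, height_px - 1),
                           wound = c(width_px - 1, 0, width_px - 1, height_px - 1)),
                         axis_ratio_range = c(1, 3), blob_sigma = 2,
                         min_separation = 0,
                         peak_intensity = 50, background_level = 5,
                         noise_sd = 2, seed = 1) {
  if (min_separation < 0) stop("min_separation must be >= 0")
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  if (n_frames < 2) stop("n_frames must be >= 2")
  if (n_cells < 0) stop("n_cells must be >= 0")
  if (speed_mean < 0 || speed_sd < 0) stop("speeds must be >= 0")
  if (kappa < 0) stop("kappa must be >= 0")
  if (!inherits(wound, "wound_roi")) stop("wound must be a wound_roi object")
  if (length(axis_ratio_range) != 2 || axis_ratio_range[1] < 1 ||
      axis_ratio_range[2] < axis_ratio_range[1])
    stop("axis_ratio_range must be c(1, rmax) with rmax >= 1")
  structure(list(
    width_px = as.integer(width_px), height_px = as.integer(height_px),
    pixel_size = pixel_size, n_frames = as.integer(n_frames),
    frame_interval = frame_interval, n_cells = as.integer(n_cells),
    speed_mean = speed_mean, speed_sd = speed_sd, kappa = kappa,
    wound = wound, axis_ratio_range = axis_ratio_range,
    blob_sigma = blob_sigma, min_separation = min_separation,
    peak_intensity = peak_intensity,
    background_level = background_level, noise_sd = noise_sd,
    seed = as.integer(seed)), class = "scene_config")
}

#' True circularity of an ellipse with a given axis ratio
#'
#' Circularity is 4*pi*area/perimeter^2, which for an ellipse depends only on
#' the major/minor axis ratio. The perimeter is computed exactly from the
#' complete elliptic integral of the second kind.
#'
#' @param axis_ratio Major/minor axis ratio, >= 1.
#' @return Circularity in (0, 1]; exactly 1 for `axis_ratio = 1`.
#' @export
ellipse_circularity <- function(axis_ratio) {
  stopifnot(all(axis_ratio >= 1))
  vapply(axis_ratio, function(r) {
    if (r == 1) return(1)
    a <- r; b <- 1
    m <- 1 - (b / a)^2              # eccentricity squared
    P <- 4 * a * pracma::ellipke(m)$e
    4 * pi * (pi * a * b) / P^2
  }, numeric(1))
}

#' Simulate a time-lapse scene of wound-biased random walkers
#'
#' Generates the image stack and the ground-truth tracks for a
#' [scene_config()]. Cell positions are simulated in micrometer coordinates
#' with reflecting boundaries; each frame is rendered as background plus one
#' anisotropic Gaussian blob per cell plus Gaussian noise, clipped at zero.
#'
#' @param config A [scene_config()].
#' @return A list with `stack`, a `height_px x width_px x n_frames` numeric
#'   array, and `truth`, a data frame with one row per live cell per frame:
#'   `cell_id`, `frame`, `x_um`, `y_um`, `axis_ratio`, `circularity_true`
#'   (circularity of the rendered elliptical outline), and `theta_deg`, the
#'   angle of the step that produced this position relative to the
#'   cell-to-wound direction (NA for the first frame).
#' @examples
#' sc <- simulate_scene(scene_config(n_cells = 5, n_frames = 10, seed = 7))
#' dim(sc$stack)
#' head(sc$truth)
#' @export
simulate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  cf <- config
  with_local_seed(cf$seed, {
    W <- cf$width_px; H <- cf$height_px; ps <- cf$pixel_size
    n <- cf$n_cells
    # positions in um; pixel p (0-based, center) sits at p * ps
    xmax <- (W - 1) * ps; ymax <- (H - 1) * ps
    minsep <- cf$min_separation * ps
    if (minsep == 0 || n == 0) {
      x <- stats::runif(n, 0, xmax); y <- stats::runif(n, 0, ymax)
    } else {
      # rejection placement with the pairwise separation constraint
      x <- y <- numeric(n)
      for (i in seq_len(n)) {
        for (try in 1:2000) {
          xi <- stats::runif(1, 0, xmax); yi <- stats::runif(1, 0, ymax)
          if (i == 1 || all((x[seq_len(i - 1)] - xi)^2 +
                            (y[seq_len(i - 1)] - yi)^2 >= minsep^2)) break
          if (try == 2000)
            stop("cannot place ", n, " cells with min_separation ",
                 cf$min_separation, " px in this field")
        }
        x[i] <- xi; y[i] <- yi
      }
    }
    ar <- stats::runif(n, cf$axis_ratio_range[1], cf$axis_ratio_range[2])
    orient <- stats::runif(n, -pi, pi)          # rendering orientation, radians
    circ_true <- ellipse_circularity(ar)
    stack <- array(0, dim = c(H, W, cf$n_frames))
    truth <- vector("list", cf$n_frames)
    for (f in seq_len(cf$n_frames)) {
      theta_rel <- rep(NA_real_, n)
      if (f > 1L && n > 0L) {
        np <- nearest_wound_point(cf$wound, x / ps, y / ps) * ps
        mu_dir <- atan2(np[, 2] - y, np[, 1] - x)
        if (minsep == 0) {
          dir <- mu_dir + rvonmises(n, 0, cf$kappa)
          step <- rtruncnorm0(n, cf$speed_mean, cf$speed_sd) *
            cf$frame_interval
          x <- reflect_into(x + step * cos(dir), xmax)
          y <- reflect_into(y + step * sin(dir), ymax)
          orient <- wrap_angle(dir)
          theta_rel <- wrap_angle(dir - mu_dir) * 180 / pi
        } else {
          # volume exclusion: re-draw steps that would break the separation
          dir <- numeric(n)
          for (i in seq_len(n)) {
            moved <- FALSE
            for (try in 1:20) {
              di <- mu_dir[i] + rvonmises(1, 0, cf$kappa)
              st <- rtruncnorm0(1, cf$speed_mean, cf$speed_sd) *
                cf$frame_interval
              xi <- reflect_into(x[i] + st * cos(di), xmax)
              yi <- reflect_into(y[i] + st * sin(di), ymax)
              if (all((x[-i] - xi)^2 + (y[-i] - yi)^2 >= minsep^2)) {
                x[i] <- xi; y[i] <- yi
                dir[i] <- di
                moved <- TRUE
                break
              }
            }
            if (moved) {
              orient[i] <- wrap_angle(dir[i])
              theta_rel[i] <- wrap_angle(dir[i] - mu_dir[i]) * 180 / pi
            } # else the cell rests this frame; theta stays NA
          }
        }
      }
      if (n > 0L) {
        stack[, , f] <- render_frame(H, W, x / ps, y / ps, orient, ar,
                                     cf$blob_sigma, cf$peak_intensity)
        truth[[f]] <- data.frame(cell_id = seq_len(n), frame = f,
                                 x_um = x, y_um = y, axis_ratio = ar,
                                 circularity_true = circ_true,
                                 theta_deg = theta_rel)
      }
      stack[, , f] <- stack[, , f] + cf$background_level +
        stats::rnorm(H * W, 0, cf$noise_sd)
    }
    stack[stack < 0] <- 0
    truth <- if (n > 0L) do.call(rbind, truth) else
      data.frame(cell_id = integer(), frame = integer(), x_um = numeric(),
                 y_um = numeric(), axis_ratio = numeric(),
                 circularity_true = numeric(), theta_deg = numeric())
    list(stack = stack, truth = truth, config = cf)
  })
}

# Fold coordinates into [0, m] by reflection at both walls.
reflect_into <- function(v, m) {
  v <- v %% (2 * m)
  ifelse(v > m, 2 * m - v, v)
}

# Additive rendering of anisotropic Gaussian blobs on local patches.
# xc, yc in 0-based pixel coordinates; orientation along the major axis.
render_frame <- function(H, W, xc, yc, orient, axis_ratio, sigma, peak) {
  img <- matrix(0, H, W)
  sa <- sigma * sqrt(axis_ratio)
  sb <- sigma / sqrt(axis_ratio)
  rad <- ceiling(4 * max(sa)) + 1L
  for (i in seq_along(xc)) {
    cx <- xc[i]; cy <- yc[i]
    x0 <- max(0L, floor(cx) - rad); x1 <- min(W - 1L, ceiling(cx) + rad)
    y0 <- max(0L, floor(cy) - rad); y1 <- min(H - 1L, ceiling(cy) + rad)
    if (x0 > x1 || y0 > y1) next
    px <- x0:x1; py <- y0:y1
    dx <- outer(rep(1, length(py)), px - cx)
    dy <- outer(py - cy, rep(1, length(px)))
    u <- cos(orient[i]) * dx + sin(orient[i]) * dy
    v <- -sin(orient[i]) * dx + cos(orient[i]) * dy
    img[py + 1L, px + 1L] <- img[py + 1L, px + 1L] +
      peak * exp(-u^2 / (2 * sa[i]^2) - v^2 / (2 * sb[i]^2))
  }
  img
}
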