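#' Cell-shape circularity
#'
#' Circularity C = 4*pi*area/perimeter^2: 1 for a perfect disk, approaching 0
#' for elongated or dendritic shapes. Used as a proxy for pro-inflammatory
#' (rounded, M1-like) versus ramified macrophage morphology.
#'
#' @param area Area (any squared unit), > 0.
#' @param perimeter Perimeter (matching unit), > 0.
#' @return Dimensionless circularity. Not clamped; see [segment_cells()] for
#'   the clamping convention applied to rasterized shapes.
#' @examples
#' circularity(pi, 2 * pi)  # unit circle -> 1
#' circularity(1, 4)        # unit square -> pi/4
#' @export
circularity <- function(area, perimeter) {
  if (any(area <= 0) || any(perimeter <= 0))
    stop("area and perimeter must be > 0")
  4 * pi * area / perimeter^2
}

#' Detect cells as smoothed local intensity maxima
#'
#' Gaussian-smooths the frame, finds strict 8-neighborhood local maxima at or
#' above `abs_threshold`, and suppresses weaker maxima closer than
#' `min_distance` to a stronger one (ties broken by higher intensity, then by
#' lower (y, x) in lexicographic order). Centroids are refined by an
#' intensity-weighted average over a small window around the peak.
#'
#' @param frame Numeric matrix (rows = y, columns = x) of intensities.
#' @param sigma Gaussian smoothing scale in pixels (>= 0; 0 skips smoothing).
#' @param min_distance Minimum distance between detections, pixels (>= 1).
#' @param abs_threshold Minimum smoothed intensity of a detection.
#' @return Data frame with columns `x`, `y` (0-based pixel-center
#'   coordinates) and `intensity` (smoothed peak value); zero rows if nothing
#'   is detected.
#' @export
detect_maxima <- function(frame, sigma = 2, min_distance = 8,
                          abs_threshold = 0) {
  stopifnot(is.matrix(frame), all(is.finite(frame)))
  if (sigma < 0) stop("sigma must be >= 0")
  if (min_distance < 1) stop("min_distance must be >= 1")
  empty <- data.frame(x = numeric(), y = numeric(), intensity = numeric())
  if (length(frame) == 0) return(empty)
  sm <- if (sigma > 0) gaussian_smooth(frame, sigma) else frame
  H <- nrow(sm); W <- ncol(sm)
  if (H < 3 || W < 3) return(empty)
  pad <- matrix(-Inf, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- sm
  ctr <- pad[2:(H + 1), 2:(W + 1)]
  is_max <- ctr >= abs_threshold
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    is_max <- is_max & (ctr > pad[2:(H + 1) + di, 2:(W + 1) + dj])
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty)
  cand <- data.frame(y = idx[, 1] - 1, x = idx[, 2] - 1,
                     intensity = sm[idx])
  cand <- cand[order(-cand$intensity, cand$y, cand$x), ]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    if (any(keep)) {
      d2 <- (cand$x[keep] - cand$x[i])^2 + (cand$y[keep] - cand$y[i])^2
      ok <- all(d2 >= min_distance^2)
    }
    keep[i] <- ok
  }
  cand <- cand[keep, , drop = FALSE]
  # sub-pixel refinement: intensity-weighted centroid around the peak
  r <- max(1L, round(sigma))
  for (i in seq_len(nrow(cand))) {
    ys <- max(0, cand$y[i] - r):min(H - 1, cand$y[i] + r)
    xs <- max(0, cand$x[i] - r):min(W - 1, cand$x[i] + r)
    wts <- sm[ys + 1, xs + 1, drop = FALSE]
    wts <- pmax(wts - min(wts), 0)
    if (sum(wts) > 0) {
      cand$x[i] <- sum(outer(rep(1, length(ys)), xs) * wts) / sum(wts)
      cand$y[i] <- sum(outer(ys, rep(1, length(xs))) * wts) / sum(wts)
    }
  }
  rownames(cand) <- NULL
  cand[, c("x", "y", "intensity")]
}

# Gaussian smoothing via EBImage; the kernel is isotropic so the matrix
# orientation convention does not matter.
gaussian_smooth <- function(frame, sigma) {
  mx <- max(frame)
  if (mx <= 0) mx <- 1
  out <- EBImage::gblur(EBImage::Image(frame / mx), sigma = sigma)
  EBImage::imageData(out) * mx
}

#' Segment cells by thresholding and 8-connected labeling
#'
#' Thresholds the frame (Otsu by default, or an absolute value), labels
#' 8-connected foreground components, drops components smaller than
#' `min_area`, and measures each remaining cell: pixel-count area, Crofton
#' 4-direction perimeter, circularity 4*pi*A/P^2 (clamped to at most 1 for
#' reporting, raw value retained), and centroid.
#'
#' @param frame Numeric intensity matrix (rows = y).
#' @param threshold_method `"otsu"` or `"absolute"`.
#' @param threshold Threshold value when `threshold_method = "absolute"`.
#' @param min_area Minimum component area in pixels (>= 1).
#' @return Data frame with columns `label`, `area`, `perimeter`,
#'   `circularity` (clamped), `circularity_raw`, `x`, `y`; zero rows for an
#'   all-background frame.
#' @export
segment_cells <- function(frame, threshold_method = c("otsu", "absolute"),
                          threshold = NULL, min_area = 9) {
  stopifnot(is.matrix(frame), all(is.finite(frame)))
  threshold_method <- match.arg(threshold_method)
  if (min_area < 1) stop("min_area must be >= 1")
  th <- if (threshold_method == "absolute") {
    if (is.null(threshold)) stop("absolute thresholding needs `threshold`")
    threshold
  } else {
    rng <- range(frame)
    if (rng[1] == rng[2]) return(empty_cells())
    sc <- (frame - rng[1]) / (rng[2] - rng[1])
    rng[1] + EBImage::otsu(EBImage::Image(sc), range = c(0, 1)) *
      (rng[2] - rng[1])
  }
  mask <- frame > th
  if (!any(mask)) return(empty_cells())
  lab <- label_components(mask)
  out <- lapply(seq_len(max(lab)), function(k) {
    px <- which(lab == k, arr.ind = TRUE)
    A <- nrow(px)
    if (A < min_area) return(NULL)
    m <- matrix(FALSE, nrow(mask), ncol(mask)); m[px] <- TRUE
    P <- crofton_perimeter(m)
    cr <- circularity(A, P)
    data.frame(area = A, perimeter = P,
               circularity = min(cr, 1), circularity_raw = cr,
               x = mean(px[, 2] - 1), y = mean(px[, 1] - 1))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty_cells())
  out$label <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("label", "area", "perimeter", "circularity", "circularity_raw",
          "x", "y")]
}

empty_cells <- function() {
  data.frame(label = integer(), area = numeric(), perimeter = numeric(),
             circularity = numeric(), circularity_raw = numeric(),
             x = numeric(), y = numeric())
}

# 8-connected component labeling of a logical mask via the pixel adjacency
# graph (EBImage::bwlabel is 4-connected, which splits diagonal contacts).
label_components <- function(mask) {
  stopifnot(is.logical(mask))
  H <- nrow(mask); W <- ncol(mask)
  fg <- which(mask)
  lab <- matrix(0L, H, W)
  if (length(fg) == 0) return(lab)
  id <- matrix(0L, H, W)
  id[fg] <- seq_along(fg)
  edges <- list()
  ri <- ((fg - 1) %% H) + 1  # row
  ci <- ((fg - 1) %/% H) + 1 # col
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- ri + d[1]; c2 <- ci + d[2]
    ok <- r2 >= 1 & r2 <= H & c2 >= 1 & c2 <= W
    ok[ok] <- mask[cbind(r2[ok], c2[ok])]
    if (any(ok))
      edges[[length(edges) + 1]] <-
        cbind(id[cbind(ri[ok], ci[ok])], id[cbind(r2[ok], c2[ok])])
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  comp <- igraph::components(g)$membership
  lab[fg] <- as.integer(comp)
  lab
}

#' Crofton 4-direction perimeter of a binary mask
#'
#' Estimates the perimeter from boundary-crossing counts along the
#' horizontal, vertical and two diagonal directions (Cauchy-Crofton formula
#' discretized over four directions):
#' P = pi/8 * (Nh + Nv + (Nd1 + Nd2)/sqrt(2)).
#' Unlike a naive boundary-pixel count, this estimator is close to unbiased
#' for smooth shapes (a rasterized disk recovers 2*pi*r within a percent).
#'
#' @param mask Logical matrix, TRUE = foreground.
#' @return Perimeter estimate in pixel units.
#' @export
crofton_perimeter <- function(mask) {
  stopifnot(is.logical(mask))
  m <- matrix(0L, nrow(mask) + 2, ncol(mask) + 2)
  m[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- as.integer(mask)
  H <- nrow(m); W <- ncol(m)
  nh <- sum(abs(m[, -1] - m[, -W]))            # crossings along rows
  nv <- sum(abs(m[-1, ] - m[-H, ]))            # crossings along columns
  nd1 <- sum(abs(m[-1, -1] - m[-H, -W]))       # down-right diagonals
  nd2 <- sum(abs(m[-1, -W] - m[-H, -1]))       # down-left diagonals
  pi / 8 * (nh + nv + (nd1 + nd2) / sqrt(2))
}
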