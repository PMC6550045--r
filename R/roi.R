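#' Wound region of interest
#'
#' Bundles the two geometric references used throughout the imaging arm: the
#' counting region (the dashed-box area of the tail in which recruited cells
#' are counted) and the wound reference geometry (the amputation line, or a
#' point wound), both in pixel coordinates (0-based, pixel-center convention).
#'
#' @param region Counting region. Either a numeric vector
#'   `c(xmin, ymin, xmax, ymax)` for an axis-aligned rectangle, or a two-column
#'   matrix of polygon vertices (x, y), implicitly closed.
#' @param wound Wound reference. Either `c(x1, y1, x2, y2)` for a line
#'   segment or `c(x, y)` for a point.
#' @return An object of class `wound_roi`.
#' @examples
#' roi <- wound_roi(region = c(100, 0, 255, 255), wound = c(250, 0, 250, 255))
#' @export
wound_roi <- function(region, wound) {
  if (is.matrix(region)) {
    if (ncol(region) != 2 || nrow(region) < 3)
      stop("polygon region needs a two-column matrix with >= 3 vertices")
    reg <- list(type = "polygon", xy = region)
    if (abs(polygon_area(region)) <= 0) stop("degenerate polygon region")
  } else {
    if (length(region) != 4) stop("rectangle region must be c(xmin, ymin, xmax, ymax)")
    if (region[3] <= region[1] || region[4] <= region[2])
      stop("degenerate rectangle region")
    reg <- list(type = "rect", xy = region)
  }
  wound <- as.numeric(wound)
  if (length(wound) == 2) wound <- c(wound, wound)
  if (length(wound) != 4) stop("wound must be a point c(x, y) or segment c(x1, y1, x2, y2)")
  structure(list(region = reg, wound = wound), class = "wound_roi")
}

#' @export
print.wound_roi <- function(x, ...) {
  cat("wound_roi:", x$region$type, "counting region;",
      if (all(x$wound[1:2] == x$wound[3:4])) "point wound" else "segment wound", "\n")
  invisible(x)
}

polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(seq_len(nrow(xy))[-1], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

# Nearest point on the wound geometry to (x, y); vectorized over points.
# Returns a two-column matrix.
nearest_wound_point <- function(roi, x, y) {
  w <- roi$wound
  dx <- w[3] - w[1]; dy <- w[4] - w[2]
  len2 <- dx^2 + dy^2
  if (len2 == 0) {
    cbind(rep(w[1], length(x)), rep(w[2], length(x)))
  } else {
    t <- pmin(1, pmax(0, ((x - w[1]) * dx + (y - w[2]) * dy) / len2))
    cbind(w[1] + t * dx, w[2] + t * dy)
  }
}

# Boundary-inclusive point-in-region test; vectorized, returns logical.
in_region <- function(roi, x, y) {
  r <- roi$region
  if (r$type == "rect") {
    x >= r$xy[1] & x <= r$xy[3] & y >= r$xy[2] & y <= r$xy[4]
  } else {
    vapply(seq_along(x), function(i) point_in_polygon(r$xy, x[i], y[i]),
           logical(1))
  }
}

# Ray casting with an explicit on-edge check (edges count as inside).
point_in_polygon <- function(xy, px, py) {
  n <- nrow(xy)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    xi <- xy[i, 1]; yi <- xy[i, 2]; xj <- xy[j, 1]; yj <- xy[j, 2]
    # on-edge: collinear and within the segment's bounding box
    cross <- (xj - xi) * (py - yi) - (yj - yi) * (px - xi)
    if (abs(cross) < 1e-12 &&
        px >= min(xi, xj) - 1e-12 && px <= max(xi, xj) + 1e-12 &&
        py >= min(yi, yj) - 1e-12 && py <= max(yi, yj) + 1e-12) return(TRUE)
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi) inside <- !inside
    j <- i
  }
  inside
}
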