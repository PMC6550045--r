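# Independent brute-force oracles and small fixture builders used across the
# suite. Oracles are written from definitions, not from the implementation.

# All permutations of 1..n (n small).
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  do.call(c, lapply(seq_len(n), function(i)
    lapply(all_perms(n - 1L), function(p) {
      rest <- setdiff(seq_len(n), i)
      c(i, rest[p])
    })))
}

# Minimum-total-distance one-to-one assignment by exhaustive enumeration,
# with gating: pairs farther than max_disp are inadmissible (a gated pair
# stays unmatched, contributing nothing). Returns the minimum total cost of
# matched pairs over all subsets; for equal-size full matchings it reduces
# to the permutation minimum.
brute_force_min_matching <- function(d, max_disp) {
  n <- nrow(d); m <- ncol(d)
  best <- Inf; best_k <- -1L
  # maximize number of matches first (assignment drops only gated pairs),
  # then minimize cost: enumerate injective maps rows -> cols
  rec <- function(i, used, cost, k) {
    if (i > n) {
      if (k > best_k || (k == best_k && cost < best)) {
        best <<- cost; best_k <<- k
      }
      return(invisible())
    }
    rec(i + 1L, used, cost, k)              # row i unmatched
    for (j in seq_len(m)) {
      if (!used[j] && d[i, j] <= max_disp) {
        used[j] <- TRUE
        rec(i + 1L, used, cost + d[i, j], k + 1L)
        used[j] <- FALSE
      }
    }
  }
  rec(1L, rep(FALSE, m), 0, 0L)
  list(cost = best, n_matched = best_k)
}

# Step-up BH from the definition: p_adj(i) = min_{j: p_j >= p_i} (m/rank_j) p_j
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# One-way ANOVA F from raw sums of squares.
anova_f_oracle <- function(groups) {
  all_v <- unlist(groups)
  gm <- mean(all_v)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- length(groups) - 1
  df2 <- length(all_v) - length(groups)
  (ssb / df1) / (ssw / df2)
}

# KS D by evaluating both ECDFs on the pooled grid, from the definition.
ks_d_oracle <- function(x, y) {
  grid <- sort(c(x, y))
  f1 <- vapply(grid, function(t) mean(x <= t), numeric(1))
  f2 <- vapply(grid, function(t) mean(y <= t), numeric(1))
  max(abs(f1 - f2))
}

# Rasterize a disk of radius r (pixels) centered in a square frame.
disk_mask <- function(r, pad = 10) {
  n <- 2 * (r + pad) + 1
  ctr <- r + pad
  g <- expand.grid(x = 0:(n - 1), y = 0:(n - 1))
  matrix((g$x - ctr)^2 + (g$y - ctr)^2 <= r^2, n, n)
}

# Rasterize an axis-aligned ellipse with semi-axes a, b.
ellipse_mask <- function(a, b, pad = 10) {
  nx <- 2 * (ceiling(a) + pad) + 1
  ny <- 2 * (ceiling(b) + pad) + 1
  cx <- ceiling(a) + pad; cy <- ceiling(b) + pad
  g <- expand.grid(y = 0:(ny - 1), x = 0:(nx - 1))
  matrix(((g$x - cx) / a)^2 + ((g$y - cy) / b)^2 <= 1, ny, nx)
}

# Match detections of one frame to ground-truth positions (px) within
# max_dist; returns data.frame(det = row in dets, cell_id).
match_to_truth <- function(dets, truth_px, max_dist = 3) {
  lk <- link_frames(truth_px[, c("x", "y")], dets[, c("x", "y")],
                    max_disp = max_dist)
  data.frame(det = lk$j, cell_id = truth_px$cell_id[lk$i])
}

# Build a step table directly from simulated ground truth (bypassing
# detection/tracking) for directionality tests.
truth_steps <- function(scene) {
  tr <- scene$truth
  tr <- tr[order(tr$cell_id, tr$frame), ]
  do.call(rbind, lapply(split(tr, tr$cell_id), function(d) {
    n <- nrow(d)
    if (n < 2) return(NULL)
    data.frame(
      track_id = d$cell_id[1],
      time_min = (d$frame[-n] - 1) * scene$config$frame_interval,
      displacement_um = sqrt(diff(d$x_um)^2 + diff(d$y_um)^2),
      theta_deg = d$theta_deg[-1])
  }))
}
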