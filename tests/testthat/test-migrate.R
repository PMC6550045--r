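# Migration read-outs: ROI counts, velocities, directionality bins, and the
# per-hour ANOVA/LSD comparison.

roi_rect <- wound_roi(region = c(0, 0, 10, 10), wound = c(10, 0, 10, 10))

test_that("ROI counting is boundary-inclusive and averaged per hour", {
  det <- data.frame(frame = 1,
                    x = c(1, 5, 10, 11, -1),   # 10 on the edge counts
                    y = c(1, 5, 10, 5, 5))
  res <- count_in_roi(det, roi_rect, frame_interval = 1)
  expect_equal(res$per_frame$count, 3)
  # hourly means: frames 1..120 at 1/min -> hours 1 and 2
  det2 <- data.frame(frame = rep(1:120, each = 1), x = 5, y = 5)
  res2 <- count_in_roi(det2, roi_rect, frame_interval = 1)
  expect_equal(res2$per_hour$hour, c(1, 2))
  expect_equal(res2$per_hour$mean_count, c(1, 1))
  expect_equal(res2$per_hour$n_frames, c(60, 60))
})

test_that("an ROI outside the frame is a configuration error", {
  expect_error(count_in_roi(data.frame(frame = 1, x = 1, y = 1), roi_rect,
                            frame_interval = 1, frame_dim = c(8, 8)),
               "outside")
})

test_that("polygon counting regions agree with the rectangle on a square", {
  poly <- wound_roi(region = cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)),
                    wound = c(10, 5))
  x <- runif(200, -2, 12); y <- runif(200, -2, 12)
  det <- data.frame(frame = 1, x = x, y = y)
  expect_equal(count_in_roi(det, poly, 1)$per_frame$count,
               count_in_roi(det, roi_rect, 1)$per_frame$count)
})

test_that("step velocity follows displacement over elapsed time", {
  trk <- data.frame(track_id = 1, frame = 1:2, x = c(0, 3), y = c(0, 4),
                    gap = FALSE)
  sv <- step_velocities(trk, pixel_size = 1, frame_interval = 1)
  expect_equal(sv$steps$velocity, 5)   # 3-4-5 triangle
  # micrometer conversion and gap steps divide by elapsed time
  trk2 <- data.frame(track_id = 1, frame = c(1, 3), x = c(0, 6), y = c(0, 8))
  sv2 <- step_velocities(trk2, pixel_size = 0.5, frame_interval = 2)
  expect_equal(sv2$steps$velocity, 5 / 4)   # 5 um over 4 min
  # stationary cell
  trk3 <- data.frame(track_id = 1, frame = 1:5, x = 2, y = 2)
  expect_true(all(step_velocities(trk3, 1, 1)$steps$velocity == 0))
})

test_that("velocity is invariant to trading pixel size against coordinates", {
  set.seed(3)
  trk <- data.frame(track_id = rep(1:3, each = 8), frame = rep(1:8, 3),
                    x = cumsum(rnorm(24)), y = cumsum(rnorm(24)))
  v1 <- step_velocities(trk, pixel_size = 2, frame_interval = 1)$steps$velocity
  trk_scaled <- transform(trk, x = x * 2, y = y * 2)
  v2 <- step_velocities(trk_scaled, pixel_size = 1,
                        frame_interval = 1)$steps$velocity
  expect_equal(v1, v2, tolerance = 1e-12)
})

test_that("angles fall in the stated eight half-open bins", {
  expect_equal(direction_bin(10), 0L)
  expect_equal(direction_bin(170), 4L)
  expect_equal(direction_bin(-100), 6L)
  expect_equal(direction_bin(22.5), 0L)    # right-closed: still toward wound
  expect_equal(direction_bin(-22.5), 7L)
  expect_equal(direction_bin(67.5), 1L)
  expect_equal(direction_bin(180), 4L)
})

test_that("directionality fractions sum to one and exclude immobile steps", {
  steps <- data.frame(time_min = c(0, 1, 2, 3),
                      displacement_um = c(1, 1, 0, 1),
                      theta_deg = c(10, 170, NA, -100))
  h <- directionality(steps)
  expect_equal(sum(h$fractions), 1)
  expect_equal(h$n_steps, 3)
  expect_equal(h$n_immobile, 1)
  expect_equal(unname(h$fractions[c("bin0", "bin4", "bin6")]),
               rep(1 / 3, 3))
  empty <- directionality(steps[3, ])
  expect_true(empty$empty)
  expect_true(all(is.na(empty$fractions)))
})

test_that("an unbiased walk fills all eight bins uniformly", {
  cfg <- scene_config(n_cells = 100, n_frames = 102, kappa = 0, seed = 17)
  sc <- simulate_scene(cfg)
  st <- truth_steps(sc)
  st <- st[st$displacement_um > 0, ]
  expect_gte(nrow(st), 1e4)
  h <- directionality(st)
  tol <- 3 * sqrt(0.125 * 0.875 / nrow(st))
  expect_true(all(abs(h$fractions - 0.125) <= tol))
})

test_that("wound bias raises the toward-wound fraction", {
  b0 <- directionality(truth_steps(simulate_scene(
    scene_config(n_cells = 40, n_frames = 40, kappa = 0, seed = 23))))
  b2 <- directionality(truth_steps(simulate_scene(
    scene_config(n_cells = 40, n_frames = 40, kappa = 2, seed = 23))))
  expect_gte(b0$n_steps, 1000)
  expect_gt(b2$fractions["bin0"], b0$fractions["bin0"])
})

test_that("the directionality histogram is rotation-equivariant", {
  set.seed(9)
  n <- 60
  trk <- data.frame(track_id = rep(1:6, each = 10), frame = rep(1:10, 6),
                    x = cumsum(rnorm(n, sd = 2)) + 30,
                    y = cumsum(rnorm(n, sd = 2)) + 30)
  roi <- wound_roi(region = c(0, 0, 60, 60), wound = c(50, 10, 55, 40))
  h1 <- directionality(step_velocities(trk, 1, 1, roi = roi)$steps)
  # rotate everything by 73 degrees about the origin
  a <- 73 * pi / 180
  rot <- function(x, y) cbind(cos(a) * x - sin(a) * y,
                              sin(a) * x + cos(a) * y)
  p <- rot(trk$x, trk$y)
  w <- rbind(rot(50, 10), rot(55, 40))
  trk_r <- transform(trk, x = p[, 1], y = p[, 2])
  roi_r <- wound_roi(region = c(-100, -100, 100, 100),
                     wound = c(w[1, ], w[2, ]))
  h2 <- directionality(step_velocities(trk_r, 1, 1, roi = roi_r)$steps)
  expect_equal(h1$fractions, h2$fractions, tolerance = 1e-10)
})

test_that("hourly group comparison handles typical and degenerate inputs", {
  # identical groups: F = 0, p = 1
  hourly <- data.frame(group = rep(c("a", "b"), each = 3),
                       replicate = rep(1:3, 2), hour = 1,
                       value = rep(c(1, 2, 3), 2))
  res <- compare_hourly(hourly)
  expect_equal(res$omnibus$F, 0)
  expect_equal(res$omnibus$p, 1)
  # zero within-group variance with different means: flagged degenerate
  hourly2 <- data.frame(group = rep(c("a", "b"), each = 3),
                        replicate = rep(1:3, 2), hour = 1,
                        value = rep(c(0, 1), each = 3))
  res2 <- compare_hourly(hourly2)
  expect_true(res2$omnibus$degenerate)
  expect_lte(res2$omnibus$p, .Machine$double.eps)
  # random three-group case agrees with the sum-of-squares oracle
  set.seed(5)
  vals <- rnorm(15)
  hourly3 <- data.frame(group = rep(c("a", "b", "c"), each = 5),
                        replicate = rep(1:5, 3), hour = 2, value = vals)
  res3 <- compare_hourly(hourly3)
  expect_equal(res3$omnibus$F,
               anova_f_oracle(split(vals, rep(c("a", "b", "c"), each = 5))),
               tolerance = 1e-10)
  expect_equal(nrow(res3$pairwise), 3)
})
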