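# synthetic frames rendered by the package's own generator serve as ground
# truth for the trace-fitting math

make_frame <- function(X0 = 40, Y0 = 30, theta = 0.25, a = 0.004,
                       len_um = 7, noise = 0, seed = 1, dim = c(60, 80)) {
  sched <- data.frame(X0 = X0, Y0 = Y0, theta_rot = theta, a_curv = a,
                      length_um = len_um)
  gen_probability_movie(sched, frame_dim = dim, noise_sd = noise,
                        seed = seed)$frames[[1]]
}

# mean distance (px) from points on the fitted curve to the true curve
trace_truth_distance <- function(trace, X0, Y0, theta, a, half_len_px) {
  xs <- seq(-half_len_px, half_len_px, length.out = 200)
  ys <- if (trace$a_curv != 0 || TRUE) trace$a_curv * xs^2
  fit_img <- anaphaseB:::unrotate_points(xs, ys, trace$X0, trace$Y0,
                                         trace$theta_rot)
  # true curve as a dense polyline in image coordinates
  xt <- seq(-half_len_px - 2, half_len_px + 2, by = 0.1)
  yt <- a * xt^2
  cx <- X0 + cos(theta) * xt - sin(theta) * yt
  cy <- Y0 + sin(theta) * xt + cos(theta) * yt
  mean(vapply(seq_along(xs), function(i)
    sqrt(min((cx - fit_img$X[i])^2 + (cy - fit_img$Y[i])^2)), 0))
}

test_that("trace fitting recovers a rendered spindle to sub-pixel accuracy", {
  fr <- make_frame()
  tr <- fit_spindle_trace(fr, alpha_free = TRUE)
  d <- trace_truth_distance(tr, 40, 30, 0.25, 0.004, 7 / (2 * 0.11))
  expect_lt(d, 1)
  # the fit never beats its own objective at a worse point and reaches
  # within 1% of the functional at ground truth
  sel <- fr > 0.8
  idx <- which(sel, arr.ind = TRUE)
  P2 <- fr[sel]^2
  F_true <- anaphaseB:::trace_functional(
    c(40, 30, -0.25, 0.004), idx[, "col"] - 1, idx[, "row"] - 1, P2, 5)
  expect_gt(tr$F_value, 0.99 * F_true)
})

test_that("short spindles are fitted straight until 6 um is exceeded", {
  fr5 <- make_frame(len_um = 5, a = 0)
  tr5 <- fit_spindle_trace(fr5)          # no previous trace: alpha pinned
  expect_identical(tr5$a_curv, 0)
  tr5 <- measure_trace_edges_and_length(fr5, tr5)
  expect_lt(abs(tr5$length_um - 5), 2 * 0.11)
  # sequence fitting frees the curvature only after a > 6 um frame
  sched <- data.frame(X0 = 40, Y0 = 30, theta_rot = c(0.2, 0.2, 0.2),
                      a_curv = c(0, 0, 0.004), length_um = c(5, 6.5, 7))
  mv <- gen_probability_movie(sched, noise_sd = 0)
  traces <- fit_spindle_sequence(mv$frames)
  expect_identical(traces[[1]]$a_curv, 0)
  expect_identical(traces[[2]]$a_curv, 0)  # freed from frame 3 onwards
  expect_false(traces[[3]]$a_curv == 0)
})

test_that("an empty frame raises the no-spindle error", {
  expect_error(fit_spindle_trace(matrix(0, 40, 40)), "no spindle")
  # and projecting with nothing above 0.6 flags empty edges
  fr <- make_frame()
  tr <- fit_spindle_trace(fr)
  tr0 <- measure_trace_edges_and_length(matrix(0.1, 60, 80), tr)
  expect_true(tr0$empty_edges)
  expect_equal(tr0$length_um, 0)
})

test_that("arc length matches a dense polyline oracle", {
  # straight 40-px segment at 0.11 um/px spans 4.4 um
  fr <- matrix(0, 60, 80)
  fr[30, 21:60] <- 1
  tr <- fit_spindle_trace(fr)
  tr <- measure_trace_edges_and_length(fr, tr)
  expect_lt(abs(tr$length_um - (39 * 0.11)), 2 * 0.11)
  # curved trace: quadrature vs dense polyline to 0.1%
  frc <- make_frame(a = 0.006, len_um = 7)
  trc <- measure_trace_edges_and_length(frc, fit_spindle_trace(
    frc, alpha_free = TRUE))
  xg <- seq(trc$edge_x[1], trc$edge_x[2], length.out = 20001)
  yg <- trc$a_curv * xg^2
  poly <- sum(sqrt(diff(xg)^2 + diff(yg)^2)) * trc$pixel_size
  expect_equal(trc$length_um, poly, tolerance = 1e-3)
})

test_that("trace fitting is equivariant under translation and 90-degree rotation", {
  fr <- make_frame(X0 = 35, Y0 = 25, theta = 0.15, a = 0.003, dim = c(70, 70))
  tr <- fit_spindle_trace(fr, alpha_free = TRUE)
  # translation by whole pixels
  sh <- matrix(0, 70, 70)
  sh[6:70, 4:70] <- fr[1:65, 1:67]
  trs <- fit_spindle_trace(sh, alpha_free = TRUE)
  d <- trace_truth_distance(trs, 35 + 3, 25 + 5, 0.15, 0.003,
                            7 / (2 * 0.11))
  expect_lt(d, 1)
  expect_equal(trs$F_value, tr$F_value, tolerance = 0.02)
  # 90-degree rotation: t(flip) maps (x, y) -> (y, nc - 1 - x)
  rot <- t(fr[nrow(fr):1, ])
  trr <- fit_spindle_trace(rot, alpha_free = TRUE)
  expect_equal(trr$F_value, tr$F_value, tolerance = 0.02)
})

test_that("intensity measurement is background-invariant and signal-linear", {
  fr <- make_frame(a = 0, len_um = 5, theta = 0.2)
  tr <- measure_trace_edges_and_length(fr, fit_spindle_trace(fr))
  img <- fr * 50
  m <- measure_spindle_intensity(img, tr)
  expect_equal(measure_spindle_intensity(img + 13, tr)$total, m$total,
               tolerance = 1e-9)
  expect_equal(measure_spindle_intensity(img * 3, tr)$total, 3 * m$total,
               tolerance = 1e-9)
  expect_equal(measure_spindle_intensity(matrix(5, 60, 80), tr)$total, 0,
               tolerance = 1e-9)
  # a rendered ridge of known injected intensity is captured within a few %
  expect_equal(m$total, sum(img), tolerance = 0.05)
  # the central window restricts the sampled points
  m2 <- measure_spindle_intensity(img, tr, central_window = 2)
  expect_lt(m2$n_points, m$n_points)
  expect_true(all(abs(m2$per_point$s_um) <= 1 + 0.11))
})

test_that("kymographs align frames and render motion at the true velocity", {
  fr0 <- make_frame(a = 0, len_um = 7, theta = 0)
  tr <- measure_trace_edges_and_length(fr0, fit_spindle_trace(fr0))
  # static spot: a vertical line
  frames <- lapply(1:8, function(i) {
    f <- matrix(0, 60, 80); f[31, 45] <- 1; f
  })
  ky <- build_kymograph(frames, rep(list(tr), 8))
  expect_equal(nrow(ky$image), 8L)
  cols <- apply(ky$image, 1, function(r) which.max(replace(r, is.na(r), -1)))
  expect_equal(length(unique(cols)), 1L)
  # a comet moving along the trace at 1.25 um/min renders a diagonal of
  # that slope (Gaussian comet, centroid readout per row)
  v_px <- 1.25 / 0.11  # px per min
  frames2 <- lapply(0:7, function(i) {
    cx <- 25 + i * v_px / 4  # 0.25-min frames
    outer(0:59, 0:79, function(y, x)
      exp(-((x - cx)^2 + (y - 30)^2) / (2 * 1.5^2)))
  })
  ky2 <- build_kymograph(frames2, rep(list(tr), 8), frame_interval = 0.25)
  pos <- vapply(seq_len(8), function(rr) {
    v <- ky2$image[rr, ]; v[is.na(v)] <- 0
    sum(ky2$arc_um * v) / sum(v)
  }, 0)
  slope <- coef(lm(pos ~ ky2$t))[2]
  expect_equal(unname(slope), 1.25, tolerance = 0.02)
})
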