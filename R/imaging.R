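# Image-analysis math for spindle movies: rotated-parabola trace fitting on
# probability maps, edge/arc-length measurement, intensity profiles along
# the trace, and kymograph construction.
#
# Conventions: matrices are [row, col]; pixel coordinates are 0-based and
# pixel-centred with x = col - 1 (horizontal), y = row - 1 (vertical).
# Arc length along the trace is signed from the trace midpoint.

# rotate image points into the trace frame (angle theta about (X0, Y0))
rotate_points <- function(X, Y, X0, Y0, theta) {
  ct <- cos(theta); st <- sin(theta)
  dx <- X - X0; dy <- Y - Y0
  list(x = ct * dx - st * dy, y = st * dx + ct * dy)
}

# map trace-frame points back to image coordinates
unrotate_points <- function(x, y, X0, Y0, theta) {
  ct <- cos(theta); st <- sin(theta)
  list(X = X0 + ct * x + st * y, Y = Y0 - st * x + ct * y)
}

# bilinear interpolation at 0-based (x, y); border-clamped
bilinear_sample <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x <- pmin(pmax(x, 0), nc - 1)
  y <- pmin(pmax(y, 0), nr - 1)
  x0 <- pmin(floor(x), nc - 2); y0 <- pmin(floor(y), nr - 2)
  fx <- x - x0; fy <- y - y0
  i <- y0 + 1; j <- x0 + 1
  img[cbind(i, j)] * (1 - fx) * (1 - fy) +
    img[cbind(i, j + 1)] * fx * (1 - fy) +
    img[cbind(i + 1, j)] * (1 - fx) * fy +
    img[cbind(i + 1, j + 1)] * fx * fy
}

# objective of the trace fit: weighted sum over thresholded pixels of
# P^2 * exp(-|alpha x^2 - y| / lambda), lambda in pixels
trace_functional <- function(par, X, Y, P2, lambda_px, alpha_fixed = NULL) {
  a <- if (is.null(alpha_fixed)) par[4] else alpha_fixed
  r <- rotate_points(X, Y, par[1], par[2], par[3])
  sum(P2 * exp(-abs(a * r$x^2 - r$y) / lambda_px))
}

#' Fit the spindle trace to a probability frame
#'
#' Finds the rotated parabola `g(x) = alpha * x^2` (rotation angle
#' `theta_rot` about `(X0, Y0)`) that maximises the functional
#' `F = sum_i P_i^2 * exp(-|alpha x_i^2 - y_i| / lambda)` over the pixels
#' with probability above 0.8, with characteristic width `lambda = 0.55`
#' um. The curvature is held at zero until a trace longer than 6 um has
#' been seen in the sequence (short spindles are straight); pass the
#' previous frame's trace to warm-start and to carry that state. The fit
#' can optionally be steered through two detected pole points (a soft
#' quadratic constraint), mirroring how pole-marker channels are used.
#'
#' @param frame numeric matrix with values in `[0, 1]`.
#' @param previous optional `spindle_trace` from the previous frame.
#' @param pixel_size um per pixel (default 0.11).
#' @param mask optional logical matrix restricting the analysed region.
#' @param alpha_free force the curvature to be free (`TRUE`) or fixed at 0
#'   (`FALSE`); default decides from `previous$length_um > 6`.
#' @param pole_points optional 2x2 matrix (rows = poles, columns = x, y in
#'   pixels) the curve should pass through.
#' @param threshold probability threshold for fitted pixels.
#' @return An object of class `spindle_trace`: list with `X0`, `Y0`,
#'   `theta_rot`, `a_curv`, `lambda_um`, `pixel_size`, `F_value`,
#'   `n_pixels`, and (until measured) `NA` edges and length.
#' @export
fit_spindle_trace <- function(frame, previous = NULL, pixel_size = 0.11,
                              mask = NULL, alpha_free = NULL,
                              pole_points = NULL, threshold = 0.8) {
  stopifnot(is.matrix(frame))
  sel <- frame > threshold
  if (!is.null(mask)) sel <- sel & mask
  if (!any(sel)) stop("no spindle: no pixel above probability ", threshold)
  idx <- which(sel, arr.ind = TRUE)
  X <- idx[, "col"] - 1; Y <- idx[, "row"] - 1
  P2 <- frame[sel]^2
  lambda_px <- 0.55 / pixel_size
  if (is.null(alpha_free))
    alpha_free <- !is.null(previous) && isTRUE(previous$length_um > 6)
  # start from the probability-weighted centroid and principal axis
  w <- P2 / sum(P2)
  cx <- sum(w * X); cy <- sum(w * Y)
  cxx <- sum(w * (X - cx)^2); cyy <- sum(w * (Y - cy)^2)
  cxy <- sum(w * (X - cx) * (Y - cy))
  phi <- 0.5 * atan2(2 * cxy, cxx - cyy)  # axis direction in image frame
  starts <- list(c(cx, cy, -phi), c(cx, cy, -phi + pi / 2))
  if (!is.null(previous))
    starts <- c(list(c(previous$X0, previous$Y0, previous$theta_rot)),
                starts)
  pen <- function(par) {
    if (is.null(pole_points)) return(0)
    a <- if (alpha_free && length(par) >= 4) par[4] else 0
    r <- rotate_points(pole_points[, 1], pole_points[, 2],
                       par[1], par[2], par[3])
    100 * sum((a * r$x^2 - r$y)^2)
  }
  best <- NULL
  for (s0 in starts) {
    par0 <- if (alpha_free) c(s0, if (!is.null(previous))
      previous$a_curv else 0) else s0
    neg <- function(par) -trace_functional(
      par, X, Y, P2, lambda_px,
      alpha_fixed = if (alpha_free) NULL else 0) + pen(par)
    fit <- stats::optim(par0, neg, method = "Nelder-Mead",
                        control = list(maxit = 3000, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  par <- best$par
  tr <- list(X0 = par[1], Y0 = par[2], theta_rot = par[3],
             a_curv = if (alpha_free) par[4] else 0,
             lambda_um = 0.55, pixel_size = pixel_size,
             F_value = trace_functional(
               par, X, Y, P2, lambda_px,
               alpha_fixed = if (alpha_free) NULL else 0),
             n_pixels = length(X),
             edge_x = c(NA_real_, NA_real_),
             edge_s = c(NA_real_, NA_real_),
             length_um = NA_real_, empty_edges = NA)
  class(tr) <- "spindle_trace"
  tr
}

#' @export
print.spindle_trace <- function(x, ...) {
  cat(sprintf(
    "spindle_trace: centre (%.1f, %.1f) px, angle %.3f rad, curvature %.4g 1/px%s\n",
    x$X0, x$Y0, x$theta_rot, x$a_curv,
    if (is.na(x$length_um)) "" else sprintf(", length %.2f um", x$length_um)))
  invisible(x)
}

# arc length of g(x) = a x^2 from 0 to x (quadrature of sqrt(1 + g'^2))
parabola_arc_length <- function(x, a) {
  vapply(x, function(xx) {
    if (xx == 0) return(0)
    sign(xx) * stats::integrate(function(u) sqrt(1 + (2 * a * u)^2),
                                0, abs(xx), rel.tol = 1e-10)$value
  }, 0)
}

#' Measure spindle edges and length along a fitted trace
#'
#' Projects every pixel with probability above 0.6 onto the fitted curve;
#' the spindle edges are the two extreme projections along the curve, and
#' the length is the arc length of `g(x)` between them, by quadrature of
#' `sqrt(1 + g'(x)^2)`.
#'
#' @param frame probability matrix.
#' @param trace a `spindle_trace`.
#' @param threshold projection threshold (0.6).
#' @return The trace updated with `edge_x` (trace-frame x of the edges),
#'   `edge_s` (their arc-length coordinates), `length_um` and
#'   `empty_edges`.
#' @export
measure_trace_edges_and_length <- function(frame, trace, threshold = 0.6) {
  sel <- frame > threshold
  if (!any(sel)) {
    trace$edge_x <- c(NA_real_, NA_real_)
    trace$edge_s <- c(NA_real_, NA_real_)
    trace$length_um <- 0
    trace$empty_edges <- TRUE
    return(trace)
  }
  idx <- which(sel, arr.ind = TRUE)
  r <- rotate_points(idx[, "col"] - 1, idx[, "row"] - 1,
                     trace$X0, trace$Y0, trace$theta_rot)
  # nearest point on a dense polyline of the curve
  xg <- seq(min(r$x) - 2, max(r$x) + 2, by = 0.05)
  yg <- trace$a_curv * xg^2
  proj_x <- vapply(seq_along(r$x), function(i) {
    xg[which.min((xg - r$x[i])^2 + (yg - r$y[i])^2)]
  }, 0)
  edge_x <- range(proj_x)
  edge_s <- parabola_arc_length(edge_x, trace$a_curv)
  trace$edge_x <- edge_x
  trace$edge_s <- edge_s
  trace$length_um <- (edge_s[2] - edge_s[1]) * trace$pixel_size
  trace$empty_edges <- FALSE
  trace
}

#' Fit spindle traces through a movie, sequentially
#'
#' Applies [fit_spindle_trace()] and [measure_trace_edges_and_length()]
#' frame by frame, warm-starting each fit from the previous trace and
#' freeing the curvature once a spindle longer than 6 um has been found
#' (strictly causal: earlier frames are not refitted).
#'
#' @param frames list of probability matrices.
#' @param pixel_size um per pixel.
#' @param ... forwarded to [fit_spindle_trace()].
#' @return List of measured `spindle_trace` objects, one per frame.
#' @export
fit_spindle_sequence <- function(frames, pixel_size = 0.11, ...) {
  traces <- vector("list", length(frames))
  prev <- NULL
  for (i in seq_along(frames)) {
    tr <- fit_spindle_trace(frames[[i]], previous = prev,
                            pixel_size = pixel_size, ...)
    tr <- measure_trace_edges_and_length(frames[[i]], tr)
    traces[[i]] <- tr
    prev <- tr
  }
  traces
}

# arc-equidistant sample points (1-px spacing) along the measured trace,
# with unit normals; arc coordinate signed from the trace midpoint
trace_sample_points <- function(trace, spacing = 1) {
  if (isTRUE(trace$empty_edges) || any(is.na(trace$edge_s)))
    stop("trace has no measured edges; run measure_trace_edges_and_length()")
  s_lo <- trace$edge_s[1]; s_hi <- trace$edge_s[2]
  xg <- seq(trace$edge_x[1], trace$edge_x[2], length.out = 4096)
  sg <- parabola_arc_length(xg, trace$a_curv)
  s_pts <- seq(s_lo, s_hi, by = spacing)
  x_pts <- stats::approx(sg, xg, xout = s_pts, rule = 2)$y
  y_pts <- trace$a_curv * x_pts^2
  # unit normal to the curve in the trace frame
  tx <- 1 / sqrt(1 + (2 * trace$a_curv * x_pts)^2)
  ty <- 2 * trace$a_curv * x_pts * tx
  img <- unrotate_points(x_pts, y_pts, trace$X0, trace$Y0, trace$theta_rot)
  nrm <- unrotate_points(-ty, tx, 0, 0, trace$theta_rot)
  list(s = s_pts - (s_lo + s_hi) / 2,  # signed from midpoint
       X = img$X, Y = img$Y, nX = nrm$X, nY = nrm$Y)
}

#' Measure background-subtracted spindle intensity
#'
#' Samples seven parallel curves (normal offsets -3..+3 px, 1-px arc
#' spacing, total width 0.77 um) along the measured trace as the signal
#' region, and two flanking 4-px bands (offsets 4..7 px on either side) as
#' background. At each arc position the median of the band samples is
#' subtracted from each signal sample; the measurement is the sum of the
#' subtracted signal, optionally restricted to a central window (e.g. 2 um
#' for midzone-protein density). Adding a constant to the whole image
#' leaves the result unchanged.
#'
#' @param image intensity matrix (same geometry as the probability frame).
#' @param trace a measured `spindle_trace`.
#' @param central_window optional window length (um) centred on the trace
#'   midpoint.
#' @return List with `total` (a.u.), `per_point` data frame (`s_um`,
#'   `signal`, `background`), `n_points`.
#' @export
measure_spindle_intensity <- function(image, trace, central_window = NULL) {
  pts <- trace_sample_points(trace)
  if (!is.null(central_window)) {
    keep <- abs(pts$s) * trace$pixel_size <= central_window / 2
    pts <- lapply(pts, `[`, keep)
  }
  if (!length(pts$s)) stop("no sample points inside the central window")
  sig_off <- -3:3
  bg_off <- c(-(4:7), 4:7)
  sig <- sapply(sig_off, function(o)
    bilinear_sample(image, pts$X + o * pts$nX, pts$Y + o * pts$nY))
  bg <- sapply(bg_off, function(o)
    bilinear_sample(image, pts$X + o * pts$nX, pts$Y + o * pts$nY))
  if (is.null(dim(sig))) { sig <- matrix(sig, 1); bg <- matrix(bg, 1) }
  bg_med <- apply(bg, 1, stats::median)
  total <- sum(sig - bg_med)
  list(total = total,
       per_point = data.frame(s_um = pts$s * trace$pixel_size,
                              signal = rowSums(sig),
                              background = bg_med * length(sig_off)),
       n_points = length(pts$s))
}

#' Build a kymograph from a movie and per-frame traces
#'
#' For each frame, intensities are sampled at 1-px arc spacing along the
#' trace and, at each arc position, the maximum over pixels within 3 px of
#' the curve (normal offsets -3..+3) is taken, yielding one 1-D profile
#' per frame with its arc origin at the trace midpoint. Profiles are laid
#' into rows of a common grid and the whole stack is shifted so that the
#' centre of mass of the temporal maximum projection sits at the kymograph
#' centre.
#'
#' @param frames list of intensity matrices (one per frame).
#' @param traces list of measured `spindle_trace` objects, same length.
#' @param frame_interval time between frames (min), for calibration.
#' @return An object of class `kymograph`: list with `image` (frames x
#'   columns, `NA` outside the traced region), `arc_um` (column
#'   coordinates, um, 0 at the kymograph centre), `t` (row times, min),
#'   `pixel_size`, `alignment_offset` (px).
#' @export
build_kymograph <- function(frames, traces, frame_interval = 1) {
  stopifnot(length(frames) == length(traces), length(frames) >= 1)
  profs <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    pts <- trace_sample_points(traces[[i]])
    samp <- sapply(-3:3, function(o)
      bilinear_sample(frames[[i]], pts$X + o * pts$nX, pts$Y + o * pts$nY))
    if (is.null(dim(samp))) samp <- matrix(samp, 1)
    profs[[i]] <- list(s = pts$s, v = apply(samp, 1, max))
  }
  half_w <- max(vapply(profs, function(p) max(abs(p$s)), 0))
  pad <- ceiling(half_w) + 4L
  W <- 2L * pad + 1L
  img <- matrix(NA_real_, length(frames), W)
  for (i in seq_along(profs)) {
    cols <- round(profs[[i]]$s) + pad + 1L
    ok <- cols >= 1L & cols <= W
    img[i, cols[ok]] <- profs[[i]]$v[ok]
  }
  tmax <- apply(img, 2, function(col)
    if (all(is.na(col))) 0 else max(col, na.rm = TRUE))
  if (sum(tmax) > 0) {
    com <- sum(seq_len(W) * tmax) / sum(tmax)
    shift <- as.integer(round((W + 1) / 2 - com))
  } else shift <- 0L
  if (shift != 0L) {
    shifted <- matrix(NA_real_, nrow(img), W)
    src <- seq_len(W) - shift
    ok <- src >= 1L & src <= W
    shifted[, which(ok)] <- img[, src[ok]]
    img <- shifted
  }
  px <- traces[[1]]$pixel_size
  out <- list(image = img,
              arc_um = (seq_len(W) - pad - 1L) * px,
              t = (seq_along(frames) - 1L) * frame_interval,
              pixel_size = px,
              alignment_offset = shift)
  class(out) <- "kymograph"
  out
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("kymograph: %d frames x %d arc columns (%.2f um/px)\n",
              nrow(x$image), ncol(x$image), x$pixel_size))
  invisible(x)
}

#' Read a multi-page TIFF stack as a list of matrices
#'
#' Thin wrapper for probability or intensity movies stored as multi-page
#' TIFF. Requires the `tiff` package.
#'
#' @param path file path.
#' @return List of numeric matrices.
#' @export
read_probability_stack <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to read TIFF stacks")
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  lapply(frames, function(f) {
    if (length(dim(f)) == 3L) f <- f[, , 1]
    f
  })
}
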