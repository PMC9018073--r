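# Seeded generators producing inputs with the statistical structure the
# analysis assumes: three-phase elongation series, two-state growth-speed
# event tables, probability-map movies of a curved spindle, and intensity
# series hiding a scaling factor. Each generator returns the data together
# with its generating ground truth and is a deterministic function of
# (parameters, seed).

ground_truth <- function(generator, params, seed, ...) {
  c(list(generator = generator, params = params, seed = seed), list(...))
}

#' Generate a three-phase spindle elongation series
#'
#' Samples [elongation_curve()] on a regular grid and adds i.i.d. Gaussian
#' noise. Defaults mimic a stereotypical mitosis: slow prophase elongation,
#' a metaphase plateau, then anaphase B elongation at the sliding speed
#' `2 * v_s = 0.7` um/min.
#'
#' @param L0,t1,t2,s1,s2,s3 curve parameters, see [elongation_curve()].
#' @param noise_sd Gaussian noise SD (um).
#' @param dt sampling interval (min).
#' @param T_total series duration (min), must exceed `t2`.
#' @param seed integer seed.
#' @return List with `data` (data frame `t`, `length`) and `truth`.
#' @export
gen_elongation_series <- function(L0 = 1, t1 = 4, t2 = 8,
                                  s1 = 0.25, s2 = 0.05, s3 = 0.7,
                                  noise_sd = 0.05, dt = 0.25, T_total = 25,
                                  seed = 1L) {
  stopifnot(0 < t1, t1 < t2, t2 < T_total)
  t <- seq(0, T_total, by = dt)
  g <- elongation_curve(t, L0, t1, t2, s1, s2, s3)
  y <- with_seed(seed, g + stats::rnorm(length(t), 0, noise_sd))
  list(data = data.frame(t = t, length = y),
       truth = ground_truth("elongation_series",
                            list(L0 = L0, t1 = t1, t2 = t2, s1 = s1,
                                 s2 = s2, s3 = s3, noise_sd = noise_sd,
                                 dt = dt, T_total = T_total),
                            seed, curve = g))
}

#' Generate a microtubule growth-event table
#'
#' Emulates annotated kymograph event tables: distances from plus end to
#' closest pole drawn uniformly over `d_range`, growth speeds from the
#' error-function two-state mean curve plus Gaussian noise, growth
#' durations from the multi-step catastrophe distribution, and rescue
#' positions from the Beta rescue field mapped onto the midzone
#' `[-Lm/2, +Lm/2]` in orientation-signed coordinates.
#'
#' @param v_fast,v_slow fast/slow plateau speeds (um/min).
#' @param d0,w transition midpoint and width (um).
#' @param theta_cat,n_cat catastrophe-clock parameters.
#' @param alpha,beta rescue-field Beta shapes.
#' @param Lm midzone length (um).
#' @param n_events number of events.
#' @param noise_sd speed noise SD (um/min).
#' @param d_range distance range sampled (um).
#' @param seed integer seed.
#' @return List with `data` (data frame `distance_to_pole`, `growth_speed`,
#'   `duration`, `rescue_pos`) and `truth`.
#' @export
gen_event_table <- function(v_fast = 1.60, v_slow = 0.67, d0 = 2.5, w = 0.6,
                            theta_cat = 3.17, n_cat = 8.53,
                            alpha = 4, beta = 2, Lm = 1.23,
                            n_events = 500, noise_sd = 0.1,
                            d_range = c(0.5, 5), seed = 1L) {
  stopifnot(v_fast >= v_slow, w > 0, Lm > 0, n_events > 0)
  with_seed(seed, {
    d <- stats::runif(n_events, d_range[1], d_range[2])
    v_mean <- v_fast - (v_fast - v_slow) * (1 + erf((d - d0) / w)) / 2
    v <- v_mean + stats::rnorm(n_events, 0, noise_sd)
    dur <- sample_growth_duration(theta_cat, n_cat, n_events)
    x <- stats::rbeta(n_events, alpha, beta)
    rescue_pos <- (x - 0.5) * Lm
    list(data = data.frame(distance_to_pole = d, growth_speed = v,
                           duration = dur, rescue_pos = rescue_pos),
         truth = ground_truth("event_table",
                              list(v_fast = v_fast, v_slow = v_slow,
                                   d0 = d0, w = w, theta_cat = theta_cat,
                                   n_cat = n_cat, alpha = alpha,
                                   beta = beta, Lm = Lm,
                                   noise_sd = noise_sd, d_range = d_range),
                              seed, mean_speed = v_mean))
  })
}

# render one probability frame for a rotated-parabola trace
render_probability_frame <- function(X0, Y0, theta_rot, a_curv, half_length,
                                     nrow_px, ncol_px, ridge_sd = 1,
                                     spot_sd = 1.2, spot_peak = 1) {
  xs <- matrix(rep(seq_len(ncol_px) - 1, each = nrow_px), nrow_px)
  ys <- matrix(rep(seq_len(nrow_px) - 1, times = ncol_px), nrow_px)
  # dense polyline of the curve in rotated coordinates
  s_max <- half_length
  xr <- seq(-s_max, s_max, by = 0.25)
  yr <- a_curv * xr^2
  cx <- X0 + cos(theta_rot) * xr - sin(theta_rot) * yr
  cy <- Y0 + sin(theta_rot) * xr + cos(theta_rot) * yr
  d2 <- matrix(Inf, nrow_px, ncol_px)
  for (k in seq_along(cx)) {
    dd <- (xs - cx[k])^2 + (ys - cy[k])^2
    sel <- dd < d2
    d2[sel] <- dd[sel]
  }
  fr <- exp(-d2 / (2 * ridge_sd^2))
  for (end in c(1L, length(cx))) {
    dd <- (xs - cx[end])^2 + (ys - cy[end])^2
    fr <- pmax(fr, spot_peak * exp(-dd / (2 * spot_sd^2)))
  }
  fr
}

#' Generate a probability-map movie of a curved spindle
#'
#' Renders, per frame, a probability ridge (values near 1 on the spindle,
#' falling off as a Gaussian of the distance to the curve) along a
#' scheduled rotated parabola with two brighter pole spots at its ends,
#' plus clamped additive Gaussian noise. This is the input the spindle
#' trace fitter and the kymograph builder consume.
#'
#' @param schedule data frame with one row per frame: `X0`, `Y0` (px),
#'   `theta_rot` (rad), `a_curv` (1/px) and `length_um` (um).
#' @param frame_dim `c(rows, cols)` in pixels.
#' @param pixel_size um per pixel.
#' @param ridge_sd,spot_sd Gaussian widths (px) of ridge and pole spots.
#' @param noise_sd additive noise SD (clamped back to `[0, 1]`).
#' @param seed integer seed.
#' @return List with `frames` (list of matrices in `[0, 1]`), `pixel_size`
#'   and `truth`.
#' @export
gen_probability_movie <- function(schedule, frame_dim = c(60, 80),
                                  pixel_size = 0.11, ridge_sd = 1,
                                  spot_sd = 1.2, noise_sd = 0,
                                  seed = 1L) {
  stopifnot(is.data.frame(schedule), nrow(schedule) >= 1,
            all(c("X0", "Y0", "theta_rot", "a_curv", "length_um") %in%
                  names(schedule)))
  with_seed(seed, {
    frames <- vector("list", nrow(schedule))
    for (i in seq_len(nrow(schedule))) {
      half_len_px <- schedule$length_um[i] / (2 * pixel_size)
      fr <- render_probability_frame(
        schedule$X0[i], schedule$Y0[i], schedule$theta_rot[i],
        schedule$a_curv[i], half_len_px,
        frame_dim[1], frame_dim[2], ridge_sd, spot_sd)
      if (noise_sd > 0)
        fr <- pmin(1, pmax(0, fr + stats::rnorm(length(fr), 0, noise_sd)))
      frames[[i]] <- fr
    }
    list(frames = frames, pixel_size = pixel_size,
         truth = ground_truth("probability_movie",
                              list(schedule = schedule,
                                   frame_dim = frame_dim,
                                   pixel_size = pixel_size,
                                   ridge_sd = ridge_sd, spot_sd = spot_sd,
                                   noise_sd = noise_sd),
                              seed))
  })
}

#' Generate an intensity series hiding a scaling factor
#'
#' Emulates total fluorescent-tubulin intensity paired with spindle length:
#' `intensity = polymer / f_true + noise`, so recovering `f_true` with
#' [fit_intensity_scaling()] closes the loop.
#'
#' @param spindle_length spindle lengths (um).
#' @param polymer true polymer mass values (um), same length.
#' @param f_true hidden scaling factor (> 0).
#' @param noise_sd Gaussian noise SD on intensity.
#' @param seed integer seed.
#' @return List with `data` (data frame `spindle_length`, `intensity`) and
#'   `truth`.
#' @export
gen_intensity_series <- function(spindle_length, polymer, f_true = 3,
                                 noise_sd = 0, seed = 1L) {
  stopifnot(f_true > 0, length(spindle_length) == length(polymer))
  y <- with_seed(seed,
    polymer / f_true + stats::rnorm(length(polymer), 0, noise_sd))
  list(data = data.frame(spindle_length = spindle_length, intensity = y),
       truth = ground_truth("intensity_series",
                            list(f_true = f_true, noise_sd = noise_sd),
                            seed))
}
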