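# Model-data comparison statistics and curve fits: binning by spindle
# length, intensity scaling factor, KS distance, catastrophe-CDF fit,
# three-phase elongation fit, error-function growth-speed transition.

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Bin paired values by spindle length
#'
#' Groups `(spindle length, value)` pairs into fixed-width bins (1 um by
#' default) aligned to multiples of the width, and reports the arithmetic
#' mean and count per bin. Empty bins inside the covered range are kept and
#' flagged by a zero count and `NA` mean.
#'
#' @param spindle_length numeric vector (um).
#' @param value numeric vector, same length.
#' @param width bin width (um, > 0).
#' @return Data frame with `bin_lo`, `bin_hi`, `mid`, `mean`, `n`.
#' @export
bin_by_spindle_length <- function(spindle_length, value, width = 1) {
  stopifnot(width > 0, length(spindle_length) == length(value),
            length(value) > 0)
  idx <- floor(spindle_length / width)
  rng <- seq(min(idx), max(idx))
  mean_v <- vapply(rng, function(k) {
    v <- value[idx == k]
    if (length(v)) mean(v) else NA_real_
  }, 0)
  n_v <- vapply(rng, function(k) sum(idx == k), 0L)
  data.frame(bin_lo = rng * width, bin_hi = (rng + 1) * width,
             mid = (rng + 0.5) * width, mean = mean_v, n = n_v)
}

#' Intensity scaling factor between simulation and experiment
#'
#' Finds the factor `f` minimising the sum of squared differences
#' `sum_i (s_i - f * e_i)^2` between per-bin simulated polymer `s` and
#' measured intensity `e`; the minimiser is the closed form
#' `f = sum(s e) / sum(e^2)`. Inputs are either numeric vectors over
#' matching bins or data frames from [bin_by_spindle_length()], which are
#' matched on bin midpoints (empty bins dropped).
#'
#' @param sim_bins,exp_bins numeric vectors or binned data frames.
#' @return List with `f` and `sse` (the minimised score).
#' @export
fit_intensity_scaling <- function(sim_bins, exp_bins) {
  if (is.data.frame(sim_bins) && is.data.frame(exp_bins)) {
    mrg <- merge(sim_bins[!is.na(sim_bins$mean), c("mid", "mean")],
                 exp_bins[!is.na(exp_bins$mean), c("mid", "mean")],
                 by = "mid", suffixes = c("_s", "_e"))
    if (!nrow(mrg)) stop("no common non-empty bins")
    s <- mrg$mean_s; e <- mrg$mean_e
  } else {
    s <- as.numeric(sim_bins); e <- as.numeric(exp_bins)
    stopifnot(length(s) == length(e), length(s) > 0)
  }
  if (all(e == 0)) stop("experimental values are all zero; f is undefined")
  f <- sum(s * e) / sum(e^2)
  list(f = f, sse = sum((s - f * e)^2))
}

#' Two-sample Kolmogorov-Smirnov distance
#'
#' The supremum over all points of the absolute difference between the two
#' empirical cumulative distribution functions, evaluated exactly at every
#' step point of either sample.
#'
#' @param sample_a,sample_b non-empty numeric vectors.
#' @return The KS statistic, in `[0, 1]`.
#' @export
ks_distance <- function(sample_a, sample_b) {
  stopifnot(length(sample_a) > 0, length(sample_b) > 0)
  a <- sort(sample_a); b <- sort(sample_b)
  x <- sort(unique(c(a, b)))
  Fa <- findInterval(x, a) / length(a)
  Fb <- findInterval(x, b) / length(b)
  max(abs(Fa - Fb))
}

#' Fit the catastrophe-time CDF to observed growth durations
#'
#' Least-squares fit of the empirical cumulative distribution of growth
#' durations to `(1 - exp(-theta * t))^n`, optimised over `(log theta,
#' log n)` from several moment-guided starts (for the wild-type data this
#' recovers theta = 3.17 /min, n = 8.53).
#'
#' @param durations growth durations (min), at least 50.
#' @return List with `theta_hat` (1/min), `n_hat`, `sse`, and `fitted`
#'   function of `t`.
#' @export
fit_catastrophe_cdf <- function(durations) {
  stopifnot(length(durations) >= 50)
  if (stats::sd(durations) == 0)
    stop("degenerate durations (all equal); CDF fit is undefined")
  t_s <- sort(durations)
  F_emp <- seq_along(t_s) / length(t_s)
  sse_of <- function(par) {
    th <- exp(par[1]); nn <- exp(par[2])
    sum((growth_duration_cdf(t_s, th, nn) - F_emp)^2)
  }
  m <- mean(durations)
  best <- NULL
  for (n0 in c(1, 4, 16)) {
    th0 <- (digamma(n0 + 1) - digamma(1)) / m  # mean of max of n0 exponentials
    fit <- stats::optim(c(log(th0), log(n0)), sse_of, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  theta_hat <- exp(best$par[1]); n_hat <- exp(best$par[2])
  list(theta_hat = theta_hat, n_hat = n_hat, sse = best$value,
       fitted = function(t) growth_duration_cdf(t, theta_hat, n_hat))
}

#' Three-phase spindle elongation curve
#'
#' Continuous piecewise-linear elongation model: slope `s1` up to `t1`
#' (prophase), `s2` between `t1` and `t2` (metaphase/anaphase A), `s3`
#' after `t2` (anaphase B), starting from length `L0` at `t = 0`. Anaphase
#' onset is `t2`.
#'
#' @param t time (min), vectorised.
#' @param L0 initial length (um).
#' @param t1,t2 breakpoints (min), `0 < t1 < t2`.
#' @param s1,s2,s3 phase slopes (um/min).
#' @return Length values (um).
#' @export
elongation_curve <- function(t, L0, t1, t2, s1, s2, s3) {
  L0 + s1 * pmin(t, t1) +
    s2 * pmin(pmax(t - t1, 0), t2 - t1) +
    s3 * pmax(t - t2, 0)
}

# linear profile fit for fixed breakpoints: returns coefs and SSE
.piecewise_profile <- function(t, y, t1, t2) {
  X <- cbind(1, pmin(t, t1), pmin(pmax(t - t1, 0), t2 - t1),
             pmax(t - t2, 0))
  fit <- stats::lm.fit(X, y)
  list(coef = fit$coefficients, sse = sum(fit$residuals^2))
}

#' Fit the three-phase elongation model to a length-time series
#'
#' Least-squares fit of [elongation_curve()] with continuity built in.
#' For fixed breakpoints the remaining parameters `(L0, s1, s2, s3)` are a
#' linear solve; the breakpoints are refined by derivative-free
#' multi-start optimisation over a grid of initialisations. A fit is
#' flagged unreliable when the optimum collapses the middle phase
#' (`t1 >= t2`, a breakpoint at the boundary, or indistinguishable
#' neighbouring slopes), replacing the manual intervention such fits would
#' otherwise need.
#'
#' @param t,length time (min) and spindle length (um) series (>= 6 points
#'   spanning the three phases).
#' @return List with `L0`, `t1`, `t2`, `s1`, `s2`, `s3`, `sse`,
#'   `anaphase_onset` (= `t2`) and `reliable`.
#' @export
fit_piecewise_elongation <- function(t, length) {
  stopifnot(length(t) >= 6, length(t) == base::length(length))
  o <- order(t); t <- t[o]; y <- length[o]
  t_lo <- min(t); t_hi <- max(t); span <- t_hi - t_lo
  obj <- function(par) {
    t1 <- par[1]; t2 <- par[2]
    if (!(t1 > t_lo && t2 < t_hi && t1 < t2)) return(1e12)
    .piecewise_profile(t, y, t1, t2)$sse
  }
  qs <- t_lo + span * c(0.2, 0.35, 0.5, 0.65, 0.8)
  best <- NULL
  for (a in qs) for (b in qs) if (a < b) {
    fit <- stats::optim(c(a, b), obj, method = "Nelder-Mead",
                        control = list(maxit = 1000, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  t1 <- best$par[1]; t2 <- best$par[2]
  pr <- .piecewise_profile(t, y, t1, t2)
  cf <- pr$coef
  slopes <- cf[2:4]
  scale_s <- max(abs(slopes), 1e-8)
  reliable <- t1 < t2 &&
    t1 > t_lo + 1e-6 && t2 < t_hi - 1e-6 &&
    abs(slopes[2] - slopes[1]) > 0.01 * scale_s &&
    abs(slopes[3] - slopes[2]) > 0.01 * scale_s
  list(L0 = unname(cf[1]), t1 = t1, t2 = t2,
       s1 = unname(cf[2]), s2 = unname(cf[3]), s3 = unname(cf[4]),
       sse = pr$sse, anaphase_onset = t2, reliable = reliable)
}

#' Fit the error-function transition of growth speed with distance to pole
#'
#' Growth speeds cluster in a fast and a slow state depending on the
#' distance `d` from the plus end to the closest pole at rescue; the mean
#' speed follows
#' `v(d) = v_fast - (v_fast - v_slow) * (1 + erf((d - d0) / w)) / 2`,
#' the signature of a two-state transition centred at `d0` with width `w`.
#' Fitted by multi-start least squares; plateaus are normalised so
#' `v_fast >= v_slow` and `w > 0`.
#'
#' @param distance distance from plus end to closest pole (um), >= 20
#'   values spanning the transition.
#' @param speed growth speed (um/min).
#' @return List with `v_fast`, `v_slow` (um/min), `d0`, `w` (um),
#'   `r_squared`, `sse` and `reliable` (`FALSE` when the speeds carry no
#'   distance structure to identify a width from).
#' @export
fit_erf_transition <- function(distance, speed) {
  stopifnot(length(distance) >= 20, length(distance) == length(speed))
  if (stats::sd(speed) == 0) {
    return(list(v_fast = speed[1], v_slow = speed[1], d0 = NA_real_,
                w = NA_real_, r_squared = NA_real_, sse = 0,
                reliable = FALSE))
  }
  model <- function(d, p) {
    p[1] - (p[1] - p[2]) * (1 + erf((d - p[3]) / p[4])) / 2
  }
  obj <- function(p) {
    if (p[4] == 0) return(1e12)
    sum((speed - model(distance, p))^2)
  }
  q <- stats::quantile(distance, c(0.25, 0.5, 0.75))
  vf0 <- mean(speed[distance <= q[1]])
  vs0 <- mean(speed[distance >= q[3]])
  span <- diff(range(distance))
  best <- NULL
  for (d00 in c(q[2], q[1], q[3])) for (w0 in span * c(0.1, 0.3)) {
    fit <- stats::optim(c(vf0, vs0, d00, w0), obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  p <- best$par
  if (p[4] < 0) { p[1:2] <- p[2:1]; p[4] <- -p[4] }  # same curve, normalised
  if (p[1] < p[2]) p[1:2] <- p[2:1]
  sst <- sum((speed - mean(speed))^2)
  list(v_fast = p[1], v_slow = p[2], d0 = p[3], w = p[4],
       r_squared = 1 - best$value / sst, sse = best$value, reliable = TRUE)
}

#' Histogram of rescue positions and the fraction at positive positions
#'
#' Positions are signed relative to the spindle centre, positive in the
#' growth direction of the rescued microtubule, mirroring how kymograph
#' annotations are scored (in wild-type cells 93% of rescues fall at
#' positive positions, at the midzone edge distal to the pole).
#'
#' @param events either a numeric vector of signed rescue positions (um) or
#'   an event data frame with `kind` and `pos_signed` columns, from which
#'   rescue rows are taken.
#' @param bin_width histogram bin width (um).
#' @return List with `breaks`, `counts`, `mids`, `fraction_positive` and
#'   `n`.
#' @export
rescue_position_histogram <- function(events, bin_width = 0.2) {
  pos <- if (is.data.frame(events)) {
    events$pos_signed[events$kind == "rescue"]
  } else as.numeric(events)
  if (!length(pos)) stop("no rescue events")
  lo <- floor(min(pos) / bin_width) * bin_width
  hi <- ceiling(max(pos) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  br <- seq(lo, hi, by = bin_width)
  h <- graphics::hist(pos, breaks = br, plot = FALSE)
  list(breaks = h$breaks, counts = h$counts, mids = h$mids,
       fraction_positive = mean(pos > 0), n = length(pos))
}
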