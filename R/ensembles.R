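# Batch execution, parameter scans and simulated-kymograph rendering.

#' Run an ensemble of independent seeded simulations
#'
#' Executes `n_runs` simulations whose per-run seeds derive from the master
#' seed by a counter scheme ([derive_seed()]), so results are independent of
#' execution order. Aggregates the collapse fraction, the spindle lengths at
#' collapse, the mean microtubule count versus time, and paired
#' (spindle length, polymer mass) samples.
#'
#' @param params a [sim_params()] object.
#' @param n_runs number of runs (>= 1).
#' @param seed master seed.
#' @param record_dt trajectory sampling interval (min), see
#'   [run_simulation()].
#' @param keep_trajectories keep the full per-run trajectories (memory
#'   heavy; off by default).
#' @return An object of class `ensemble_summary`: list with `params`,
#'   `n_runs`, `collapse_fraction`, `collapse_lengths`, `mt_count_series`
#'   (data frame `t`, `mean_n_mts`, `n_alive`), `polymer_vs_length`
#'   (data frame `S`, `polymer`), `outcomes`, `seeds` and optionally
#'   `trajectories`.
#' @export
run_ensemble <- function(params, n_runs, seed, record_dt = 0.1,
                         keep_trajectories = FALSE) {
  stopifnot(n_runs >= 1)
  seeds <- vapply(seq_len(n_runs), function(i) derive_seed(seed, i), 0L)
  grid_t <- seq(0, params$t_max, by = record_dt)
  counts <- matrix(NA_real_, n_runs, length(grid_t))
  collapsed <- logical(n_runs)
  col_len <- rep(NA_real_, n_runs)
  pv <- vector("list", n_runs)
  trajs <- if (keep_trajectories) vector("list", n_runs) else NULL
  for (i in seq_len(n_runs)) {
    tr <- run_simulation(params, seeds[i], record_dt = record_dt)
    collapsed[i] <- tr$outcome$collapsed
    if (collapsed[i]) col_len[i] <- tr$outcome$S_end
    s <- tr$series
    n_tot <- s$n_left + s$n_right
    j <- findInterval(grid_t, s$t + 1e-9)
    j[j < 1L] <- 1L
    live <- grid_t <= tr$outcome$t_end + 1e-9
    counts[i, live] <- n_tot[j[live]]
    pv[[i]] <- data.frame(S = s$S, polymer = s$polymer)
    if (keep_trajectories) trajs[[i]] <- tr
  }
  out <- list(
    params = params,
    n_runs = n_runs,
    collapse_fraction = mean(collapsed),
    collapse_lengths = col_len[collapsed],
    mt_count_series = data.frame(
      t = grid_t,
      mean_n_mts = colMeans(counts, na.rm = TRUE),
      n_alive = colSums(!is.na(counts))),
    polymer_vs_length = do.call(rbind, pv),
    outcomes = data.frame(run = seq_len(n_runs), seed = seeds,
                          collapsed = collapsed, collapse_length = col_len),
    seeds = seeds)
  if (keep_trajectories) out$trajectories <- trajs
  class(out) <- "ensemble_summary"
  out
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf(
    "ensemble_summary: %d runs (%s rescue, R = %g), collapse fraction %.3f\n",
    x$n_runs, x$params$variant, x$params$R, x$collapse_fraction))
  invisible(x)
}

#' Scan a simulation parameter
#'
#' Runs an ensemble at each value of the scanned parameter (`R`, the rescue
#' budget, or `v_p`, the growth speed) and reports the collapse-probability
#' curve. Values are either drawn uniformly from the standard scan range
#' (`R` in 1-120 um/min, `v_p` in 0.35-1.5 um/min) or taken from a supplied
#' `grid` for reproducible comparisons.
#'
#' @param name `"R"` or `"v_p"`.
#' @param n_points number of scanned values (ignored when `grid` given).
#' @param n_runs_per_point ensemble size at each value.
#' @param seed master seed; value `k` uses child seed `derive_seed(seed,
#'   1000 * k)`.
#' @param params base [sim_params()]; the scanned field is overwritten.
#' @param grid optional explicit vector of parameter values.
#' @return An object of class `scan_result`: list with `name`, `values`,
#'   `collapse_fraction` and per-value `summaries`.
#' @export
scan_parameter <- function(name = c("R", "v_p"), n_points, n_runs_per_point,
                           seed, params = sim_params(), grid = NULL) {
  name <- match.arg(name)
  ranges <- list(R = c(1, 120), v_p = c(0.35, 1.5))
  if (is.null(grid)) {
    grid <- with_seed(derive_seed(seed, 0L), {
      sort(stats::runif(n_points, ranges[[name]][1], ranges[[name]][2]))
    })
  }
  summaries <- vector("list", length(grid))
  for (k in seq_along(grid)) {
    pk <- params
    pk[[name]] <- grid[k]
    summaries[[k]] <- run_ensemble(pk, n_runs_per_point,
                                   derive_seed(seed, 1000L * k))
  }
  out <- list(name = name, values = grid,
              collapse_fraction = vapply(summaries, `[[`, 0,
                                         "collapse_fraction"),
              summaries = summaries)
  class(out) <- "scan_result"
  out
}

#' @export
print.scan_result <- function(x, ...) {
  cat("scan_result over", x$name, "\n")
  print(data.frame(value = x$values,
                   collapse_fraction = x$collapse_fraction))
  invisible(x)
}

#' Render a simulated kymograph
#'
#' Rasterises a trajectory into a space-time image with time on the
#' vertical axis and space on the horizontal axis, origin at the spindle
#' centre. Spindle pole traces are drawn at `+- S(t)/2` and each plus end
#' at its lab-frame position, labelled by orientation. Nearest-pixel
#' rasterisation with unit intensity per trace; region beyond the poles
#' stays zero.
#'
#' @param trajectory a `spindle_trajectory`.
#' @param space_resolution pixel size (um).
#' @param time_resolution row spacing (min); defaults to the trajectory's
#'   sampling interval.
#' @return An object of class `sim_kymograph`: list with `image` (integer
#'   matrix, rows = sampled times), `labels` (0 empty, 1 pole, 2 left-pole
#'   plus end, 3 right-pole plus end), `x` (column centres, um) and `t`
#'   (row times, min).
#' @export
render_sim_kymograph <- function(trajectory, space_resolution = 0.1,
                                 time_resolution = NULL) {
  s <- trajectory$series
  if (!nrow(s)) stop("empty trajectory")
  tt <- s$t
  if (!is.null(time_resolution)) {
    keep <- !duplicated(round(tt / time_resolution))
    s <- s[keep, , drop = FALSE]
    tt <- s$t
  }
  keep_rows <- match(s$t, trajectory$series$t)
  tips <- trajectory$tips[keep_rows, , drop = FALSE]
  S_final <- max(s$S)
  half <- S_final / 2
  ncol_img <- as.integer(ceiling(S_final / space_resolution))
  x_centres <- (seq_len(ncol_img) - 0.5) * space_resolution - half
  img <- matrix(0L, nrow(s), ncol_img)
  to_col <- function(x) pmin(pmax(1L,
    as.integer(round((x + half) / space_resolution + 0.5))), ncol_img)
  for (rr in seq_len(nrow(s))) {
    img[rr, to_col(-s$S[rr] / 2)] <- 1L
    img[rr, to_col(+s$S[rr] / 2)] <- 1L
    tp <- tips[rr, ]
    ok <- which(!is.na(tp))
    for (j in ok) {
      lab <- if (trajectory$tip_pole[j] == 1L) 2L else 3L
      cc <- to_col(tp[j])
      if (img[rr, cc] == 0L) img[rr, cc] <- lab
    }
  }
  out <- list(image = img,
              labels = c(`0` = "empty", `1` = "pole",
                         `2` = "left-pole plus end",
                         `3` = "right-pole plus end"),
              x = x_centres, t = s$t,
              space_resolution = space_resolution)
  class(out) <- "sim_kymograph"
  out
}

#' @export
print.sim_kymograph <- function(x, ...) {
  cat(sprintf("sim_kymograph: %d time rows x %d space columns (%.2f um/px)\n",
              nrow(x$image), ncol(x$image), x$space_resolution))
  invisible(x)
}
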