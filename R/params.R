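#' Simulation parameters for the anaphase B spindle model
#'
#' Builds the single source of model constants used by every simulation
#' function. Defaults are the wild-type values fitted from live-cell imaging
#' of *S. pombe* anaphase B spindles: constant growth, shrinkage and sliding
#' speeds, a multi-step catastrophe clock (`theta_cat`, `n_cat`), a fixed
#' integrated rescue budget `R` distributed over the midzone overlap
#' according to a Beta(`alpha`, `beta`) density, and a midzone length drawn
#' once per run from a truncated normal fit.
#'
#' @param v_p microtubule growth speed (um/min).
#' @param v_d microtubule shrinkage speed (um/min).
#' @param v_s per-pole sliding speed (um/min); the pole separation grows at
#'   `2 * v_s`.
#' @param R integrated rescue rate (um/min). The rescue-rate field integrates
#'   to `2 * R` over all microtubules in the midzone variant, and to `R / 2`
#'   over all microtubule lengths in the uniform variant.
#' @param n_cat,theta_cat shape (dimensionless, may be non-integer) and rate
#'   (1/min) of the catastrophe-time distribution with CDF
#'   `(1 - exp(-theta_cat * t))^n_cat`.
#' @param mu_mz,sigma_mz mean and SD (um) of the normal fit to midzone
#'   length; sampled once per run, truncated to positive values.
#' @param alpha,beta shape parameters of the Beta density that localises
#'   rescue activity along the midzone (`alpha = beta = 1` is uniform;
#'   larger `alpha` skews activity towards the midzone edge).
#' @param h timestep (min).
#' @param variant `"midzone"` (rescue only inside the midzone, on the
#'   antiparallel overlap) or `"uniform"` (rescue anywhere on the spindle, as
#'   in cells lacking the Ase1 crosslinker).
#' @param t_max simulated duration cap (min).
#' @param n_mts0 initial microtubule count (the 3x3 chequerboard holds 9).
#' @param L_mt0 initial microtubule length (um); must not exceed `S0`.
#' @param S0 initial spindle length (um).
#'
#' @return An object of class `sim_params`: a validated named list.
#' @seealso [sim_params_ase1()] for the uniform-rescue preset,
#'   [run_simulation()], [run_ensemble()].
#' @examples
#' p <- sim_params()
#' p$R
#' @export
sim_params <- function(v_p = 1.6, v_d = 3.6, v_s = 0.35, R = 55,
                       n_cat = 8.53, theta_cat = 3.17,
                       mu_mz = 1.23, sigma_mz = 0.25,
                       alpha = 4, beta = 2, h = 0.01,
                       variant = c("midzone", "uniform"),
                       t_max = 20, n_mts0 = 9, L_mt0 = 3, S0 = 4) {
  variant <- match.arg(variant)
  p <- list(v_p = v_p, v_d = v_d, v_s = v_s, R = R,
            n_cat = n_cat, theta_cat = theta_cat,
            mu_mz = mu_mz, sigma_mz = sigma_mz,
            alpha = alpha, beta = beta, h = h, variant = variant,
            t_max = t_max, n_mts0 = n_mts0, L_mt0 = L_mt0, S0 = S0)
  validate_sim_params(p)
  class(p) <- "sim_params"
  p
}

#' Preset for spindles without midzone organisation (ase1-null)
#'
#' Switches the rescue field to the uniform variant, in which the rescue
#' budget spreads along the whole microtubule length, together with the
#' catastrophe-clock parameters fitted for that background and its fixed
#' rescue budget `R = 34` um/min.
#'
#' @param ... overrides forwarded to [sim_params()].
#' @return A `sim_params` object.
#' @export
sim_params_ase1 <- function(...) {
  dots <- list(...)
  base <- list(variant = "uniform", R = 34, n_cat = 6.8, theta_cat = 2.5)
  do.call(sim_params, utils::modifyList(base, dots))
}

validate_sim_params <- function(p) {
  pos <- c("v_p", "v_d", "v_s", "h", "mu_mz", "sigma_mz", "theta_cat",
           "n_cat", "alpha", "beta", "t_max", "L_mt0", "S0")
  for (k in pos) {
    v <- p[[k]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("sim_params: '", k, "' must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(p$R) || length(p$R) != 1L || !is.finite(p$R) || p$R < 0)
    stop("sim_params: 'R' must be a single non-negative number", call. = FALSE)
  if (p$L_mt0 > p$S0)
    stop("sim_params: initial microtubule length 'L_mt0' cannot exceed 'S0'",
         call. = FALSE)
  if (p$n_mts0 != 9)
    stop("sim_params: the 3x3 chequerboard initial condition requires n_mts0 = 9",
         call. = FALSE)
  if (!p$variant %in% c("midzone", "uniform"))
    stop("sim_params: variant must be 'midzone' or 'uniform'", call. = FALSE)
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Anaphase B spindle simulation parameters (", x$variant, " rescue)\n",
      sep = "")
  cat(sprintf("  speeds (um/min): growth %.3g, shrinkage %.3g, sliding %.3g\n",
              x$v_p, x$v_d, x$v_s))
  cat(sprintf("  rescue budget R = %.3g um/min, Beta(%g, %g) localisation\n",
              x$R, x$alpha, x$beta))
  cat(sprintf("  catastrophe clock: theta = %.3g /min, n = %.3g\n",
              x$theta_cat, x$n_cat))
  cat(sprintf("  midzone length ~ N(%.3g, %.3g^2) um (truncated > 0)\n",
              x$mu_mz, x$sigma_mz))
  cat(sprintf("  timestep %g min, cap %g min, start: %d MTs of %g um, S0 = %g um\n",
              x$h, x$t_max, as.integer(x$n_mts0), x$L_mt0, x$S0))
  invisible(x)
}
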