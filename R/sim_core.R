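# ---------------------------------------------------------------------------
# Kinetic Monte-Carlo core of the anaphase B spindle model.
#
# The spindle is one-dimensional: poles sit at +-S/2 around a fixed centre,
# sliding apart at 2*v_s, and each interpolar microtubule is a length plus a
# growing/shrinking state. Transverse geometry is a chequerboard lattice
# whose 4-connected antiparallel contacts define the overlap on which the
# rescue budget is shared. Internal state is a plain list of parallel
# vectors so a 20-min run (2000 steps) stays cheap.
# ---------------------------------------------------------------------------

#' Sample microtubule growth durations
#'
#' Draws times-to-catastrophe from the multi-step catastrophe model with CDF
#' `(1 - exp(-theta * t))^n`: the waiting time for `n` independent
#' rate-`theta` sub-steps to all have fired. Sampling is by the closed-form
#' inverse CDF `t = -log(1 - u^(1/n)) / theta`, so it is exact and fully
#' determined by the RNG stream; uniform draws of exactly 0 or 1 are
#' resampled to avoid infinities.
#'
#' @param theta_cat sub-step rate (1/min).
#' @param n_cat sub-step count (dimensionless, > 0, may be non-integer).
#' @param n number of durations to draw.
#' @return Numeric vector of durations (min).
#' @seealso [growth_duration_cdf()], [fit_catastrophe_cdf()]
#' @examples
#' set.seed(1)
#' mean(sample_growth_duration(3.17, 8.53, 1e4)) * 60 # ~52.6 s
#' @export
sample_growth_duration <- function(theta_cat, n_cat, n = 1L) {
  stopifnot(theta_cat > 0, n_cat > 0, n >= 1)
  u <- stats::runif(n)
  bad <- u <= 0 | u >= 1
  while (any(bad)) {
    u[bad] <- stats::runif(sum(bad))
    bad <- u <= 0 | u >= 1
  }
  -log(1 - u^(1 / n_cat)) / theta_cat
}

#' Catastrophe-time cumulative distribution
#'
#' CDF `(1 - exp(-theta * t))^n` of the multi-step catastrophe clock.
#'
#' @param t time (min), vectorised.
#' @param theta_cat sub-step rate (1/min).
#' @param n_cat sub-step count.
#' @return CDF values in `[0, 1]`.
#' @export
growth_duration_cdf <- function(t, theta_cat, n_cat) {
  ifelse(t <= 0, 0, (1 - exp(-theta_cat * t))^n_cat)
}

#' Mean and SD of the catastrophe-time distribution
#'
#' Computed by quadrature of the survival function; used as the independent
#' check on the inverse-CDF sampler.
#'
#' @inheritParams growth_duration_cdf
#' @return Named vector `c(mean, sd)` in minutes.
#' @export
growth_duration_moments <- function(theta_cat, n_cat) {
  surv <- function(t) 1 - growth_duration_cdf(t, theta_cat, n_cat)
  m1 <- stats::integrate(surv, 0, Inf, rel.tol = 1e-10)$value
  m2 <- stats::integrate(function(t) 2 * t * surv(t), 0, Inf,
                         rel.tol = 1e-10)$value
  c(mean = m1, sd = sqrt(m2 - m1^2))
}

# --- lattice helpers -------------------------------------------------------

# Per-site antiparallel 4-neighbour counts and the total pair count for a
# lattice matrix coded 0 = empty, 1 = left pole, 2 = right pole.
lattice_census <- function(lat) {
  nr <- nrow(lat); nc <- ncol(lat)
  occ <- lat != 0L
  cnt <- matrix(0L, nr, nc)
  # horizontal contacts
  if (nc > 1L) {
    a <- lat[, -nc, drop = FALSE]; b <- lat[, -1L, drop = FALSE]
    anti <- (a != 0L) & (b != 0L) & (a != b)
    cnt[, -nc] <- cnt[, -nc, drop = FALSE] + anti
    cnt[, -1L] <- cnt[, -1L, drop = FALSE] + anti
    nh <- sum(anti)
  } else nh <- 0L
  # vertical contacts
  if (nr > 1L) {
    a <- lat[-nr, , drop = FALSE]; b <- lat[-1L, , drop = FALSE]
    anti <- (a != 0L) & (b != 0L) & (a != b)
    cnt[-nr, ] <- cnt[-nr, , drop = FALSE] + anti
    cnt[-1L, ] <- cnt[-1L, , drop = FALSE] + anti
    nv <- sum(anti)
  } else nv <- 0L
  cnt[!occ] <- 0L
  list(counts = cnt, n_pairs = as.integer(nh + nv))
}

# Antiparallel neighbour count a microtubule of pole `pole` would have at
# (row, col) given the current lattice.
site_antiparallel_count <- function(lat, row, col, pole) {
  other <- if (pole == 1L) 2L else 1L
  n <- 0L
  nr <- nrow(lat); nc <- ncol(lat)
  if (row > 1L && lat[row - 1L, col] == other) n <- n + 1L
  if (row < nr && lat[row + 1L, col] == other) n <- n + 1L
  if (col > 1L && lat[row, col - 1L] == other) n <- n + 1L
  if (col < nc && lat[row, col + 1L] == other) n <- n + 1L
  n
}

refresh_census <- function(state) {
  cen <- lattice_census(state$lat)
  m <- state$mt
  k <- length(m$id)
  nbr <- integer(k)
  if (k) nbr <- cen$counts[cbind(m$row, m$col)]
  state$nbr <- as.integer(nbr)
  state$n_pairs <- cen$n_pairs
  state
}

#' Antiparallel neighbour census of a spindle state
#'
#' Counts, for every microtubule, the 4-connected lattice neighbours held by
#' a microtubule of the opposite pole, and the total number of such
#' unordered antiparallel pairs. The sum of per-microtubule counts is always
#' twice the pair count.
#'
#' @param state a `spindle_state` (from [init_spindle()]).
#' @return List with `counts` (integer vector aligned with `state$mt$id`)
#'   and `n_pairs`.
#' @export
neighbour_census <- function(state) {
  state <- refresh_census(state)
  list(counts = stats::setNames(state$nbr, state$mt$id),
       n_pairs = state$n_pairs)
}

# --- initial condition -----------------------------------------------------

#' Initialise the spindle state
#'
#' Builds the 4-um spindle with nine 3-um growing microtubules on a 3x3
#' chequerboard: corners and centre belong to one pole (five microtubules),
#' edge centres to the other (four), so all 12 adjacent lattice contacts are
#' antiparallel. The midzone length is drawn once from the truncated normal
#' fit and stays constant for the run; each microtubule receives a fresh
#' time-to-catastrophe. Consumes the current RNG stream (seed with
#' `set.seed()` or use [run_simulation()]).
#'
#' @param params a [sim_params()] object.
#' @return An object of class `spindle_state`.
#' @export
init_spindle <- function(params) {
  validate_sim_params(params)
  # midzone length: truncated-normal, resampled while unphysically small
  Lm <- stats::rnorm(1, params$mu_mz, params$sigma_mz)
  while (Lm <= 0.2)
    Lm <- stats::rnorm(1, params$mu_mz, params$sigma_mz)
  lat <- matrix(0L, 3L, 3L)
  for (r in 1:3) for (co in 1:3)
    lat[r, co] <- if ((r + co) %% 2L == 0L) 1L else 2L
  idx <- which(t(lat) > 0L)  # row-major id assignment
  k <- 9L
  rows <- rep(1:3, each = 3L); cols <- rep(1:3, times = 3L)
  pole <- integer(k)
  for (i in seq_len(k)) pole[i] <- lat[rows[i], cols[i]]
  st <- list(
    t = 0,
    S = params$S0,
    Lm = Lm,
    lat = lat,
    mt = list(id = 1:9,
              pole = pole,
              row = rows,
              col = cols,
              len = rep(params$L_mt0, k),
              grow = rep(TRUE, k),
              tau = sample_growth_duration(params$theta_cat, params$n_cat, k)),
    collapsed = FALSE
  )
  st <- refresh_census(st)
  class(st) <- "spindle_state"
  st
}

#' @export
print.spindle_state <- function(x, ...) {
  cat(sprintf(
    "spindle_state: t = %.2f min, S = %.2f um, Lm = %.2f um, %d MTs (%d|%d), %d antiparallel pairs%s\n",
    x$t, x$S, x$Lm, length(x$mt$id), sum(x$mt$pole == 1L),
    sum(x$mt$pole == 2L), x$n_pairs,
    if (isTRUE(x$collapsed)) " [collapsed]" else ""))
  invisible(x)
}

# signed plus-end position (positive in the growth direction); identical
# expression for both orientations since poles are symmetric about 0
tip_pos_signed <- function(len, S) len - S / 2

# lab-frame plus-end position
tip_pos_lab <- function(len, S, pole) {
  ifelse(pole == 1L, len - S / 2, S / 2 - len)
}

#' Reduced midzone coordinate of a microtubule plus end
#'
#' Maps the plus-end position onto `[0, 1]` along the midzone, with 0 at the
#' midzone edge closest to the microtubule's own pole and 1 at the far edge.
#' Returns `NA` when the plus end lies outside the midzone.
#'
#' @param state a `spindle_state`.
#' @param mt_id microtubule id.
#' @return A number in `[0, 1]`, or `NA`.
#' @export
midzone_coordinate <- function(state, mt_id) {
  i <- match(mt_id, state$mt$id)
  if (is.na(i)) stop("unknown mt_id: ", mt_id)
  pos <- tip_pos_signed(state$mt$len[i], state$S)
  x <- (pos + state$Lm / 2) / state$Lm
  eps <- 1e-9  # tips placed exactly on an edge stay inside
  if (x < -eps || x > 1 + eps) NA_real_ else min(max(x, 0), 1)
}

# Beta density with the endpoint limit convention: at x in {0, 1} the
# density is taken as its limit (0 for shapes > 1, finite for shape = 1).
beta_density <- function(x, alpha, beta) {
  d <- stats::dbeta(x, alpha, beta)
  if (!is.finite(d)) d <- 0
  d
}

#' Rescue rate of a microtubule
#'
#' In the midzone variant the rate of a shrinking microtubule with `n`
#' antiparallel neighbours whose plus end sits at reduced midzone coordinate
#' `x` is `r = n * R * P(x, alpha, beta) / (Lm * N)`, where `N` is the
#' current antiparallel pair count: the fixed budget `R` is shared over the
#' overlap, so the midzone-integrated total over all microtubules is exactly
#' `2 R` whatever the Beta shape or the lattice. Outside the midzone, with
#' no antiparallel neighbour, or with no overlap at all, the rate is zero.
#' In the uniform variant the rate is `R / (2 * Lt)` anywhere on the
#' spindle, with `Lt` the summed microtubule length.
#'
#' @param state a `spindle_state`.
#' @param mt_id microtubule id.
#' @param params a [sim_params()] object.
#' @return List with `n_neighbours`, `n_pairs`, `x`, `p_density` and `rate`
#'   (1/min).
#' @export
rescue_rate <- function(state, mt_id, params) {
  i <- match(mt_id, state$mt$id)
  if (is.na(i)) stop("unknown mt_id: ", mt_id)
  if (params$variant == "uniform") {
    Lt <- sum(state$mt$len)
    rate <- if (Lt > 0) params$R / (2 * Lt) else 0
    return(list(n_neighbours = state$nbr[i], n_pairs = state$n_pairs,
                x = NA_real_, p_density = NA_real_, rate = rate))
  }
  n <- state$nbr[i]
  N <- state$n_pairs
  x <- midzone_coordinate(state, mt_id)
  if (is.na(x) || n == 0L || N == 0L)
    return(list(n_neighbours = n, n_pairs = N, x = x,
                p_density = if (is.na(x)) NA_real_
                            else beta_density(x, params$alpha, params$beta),
                rate = 0))
  p <- beta_density(x, params$alpha, params$beta)
  list(n_neighbours = n, n_pairs = N, x = x, p_density = p,
       rate = n * params$R * p / (state$Lm * N))
}

# fast scalar path used inside the stepping loop (midzone variant)
rescue_rate_fast <- function(len, S, Lm, nbr, n_pairs, R, alpha, beta) {
  if (nbr == 0L || n_pairs == 0L) return(0)
  x <- (len - S / 2 + Lm / 2) / Lm
  if (x < 0 || x > 1) return(0)
  p <- stats::dbeta(x, alpha, beta)
  if (!is.finite(p)) return(0)
  nbr * R * p / (Lm * n_pairs)
}

# --- lattice reorganization ------------------------------------------------

# drop microtubule at internal index i, freeing its lattice site
remove_mt <- function(state, i) {
  m <- state$mt
  state$lat[m$row[i], m$col[i]] <- 0L
  keep <- seq_along(m$id)[-i]
  state$mt <- lapply(m, function(v) v[keep])
  refresh_census(state)
}

#' Reorganise the lattice after a microtubule loss
#'
#' Greedily relocates single microtubules (orientation unchanged) to empty
#' lattice sites, applying at each round the move that most increases the
#' number of antiparallel connections; only strictly improving moves are
#' accepted, and the procedure repeats until no move improves. Ties are
#' broken by lowest microtubule id, then by row-major order of the target
#' site, so the result is deterministic.
#'
#' @param state a `spindle_state`.
#' @return List with the updated `state` and a data frame `moves`
#'   (`mt_id`, `from_row`, `from_col`, `to_row`, `to_col`, `gain`).
#' @export
reorganize_lattice <- function(state) {
  moves <- list()
  repeat {
    lat <- state$lat
    empties <- which(lat == 0L)
    if (!length(empties)) break
    erow <- row(lat)[empties]; ecol <- col(lat)[empties]
    # row-major ordering of candidate target sites
    ord <- order(erow, ecol)
    erow <- erow[ord]; ecol <- ecol[ord]
    m <- state$mt
    best <- NULL
    for (j in order(m$id)) {
      for (e in seq_along(erow)) {
        gain <- site_antiparallel_count(lat, erow[e], ecol[e], m$pole[j]) -
          state$nbr[j]
        if (gain > 0L && (is.null(best) || gain > best$gain))
          best <- list(j = j, row = erow[e], col = ecol[e], gain = gain)
      }
    }
    if (is.null(best)) break
    j <- best$j
    moves[[length(moves) + 1L]] <- data.frame(
      mt_id = m$id[j], from_row = m$row[j], from_col = m$col[j],
      to_row = best$row, to_col = best$col, gain = best$gain)
    state$lat[m$row[j], m$col[j]] <- 0L
    state$lat[best$row, best$col] <- m$pole[j]
    state$mt$row[j] <- best$row
    state$mt$col[j] <- best$col
    state <- refresh_census(state)
  }
  moves <- if (length(moves)) do.call(rbind, moves) else
    data.frame(mt_id = integer(), from_row = integer(), from_col = integer(),
               to_row = integer(), to_col = integer(), gain = integer())
  list(state = state, moves = moves)
}

# --- stepping --------------------------------------------------------------

#' Advance the spindle state by one timestep
#'
#' One kinetic Monte-Carlo step of length `h`: (1) poles slide outward by
#' `v_s * h` each; (2) growing microtubules elongate by `v_p * h` and their
#' catastrophe clocks tick down; a microtubule whose clock expires, or whose
#' plus end reaches the opposite pole (length clipped to the pole
#' separation), switches to shrinkage; (3) shrinking microtubules shorten by
#' `v_d * h`; one reaching zero length is removed (loss) and the lattice
#' reorganises; survivors are rescued with probability `1 - exp(-r h)`,
#' where `r` comes from [rescue_rate()], receiving a fresh catastrophe clock
#' on rescue; (4) the neighbour census is refreshed. State switches take
#' effect from the next step. Consumes the current RNG stream.
#'
#' @param state a `spindle_state` (not collapsed).
#' @param params a [sim_params()] object.
#' @return List with the updated `state` and `events`, a list of event
#'   records (`kind`, `t`, `mt_id`, `pos_signed`, `S`).
#' @export
advance_timestep <- function(state, params) {
  if (isTRUE(state$collapsed))
    stop("cannot advance a collapsed spindle")
  h <- params$h
  t_new <- state$t + h
  S <- params$S0 + 2 * params$v_s * t_new  # exact kinematics, no drift
  state$t <- t_new
  state$S <- S
  ev <- list()
  m <- state$mt
  was_grow <- m$grow  # phase membership frozen at entry
  gi <- which(was_grow)
  if (length(gi)) {
    m$len[gi] <- m$len[gi] + params$v_p * h
    m$tau[gi] <- m$tau[gi] - h
    over <- m$len[gi] >= S
    if (any(over)) m$len[gi[over]] <- S
    ci <- gi[m$tau[gi] <= 0 | over]
    if (length(ci)) {
      m$grow[ci] <- FALSE
      for (i in ci)
        ev[[length(ev) + 1L]] <- list(
          kind = "catastrophe", t = t_new, mt_id = m$id[i],
          pos_signed = tip_pos_signed(m$len[i], S), S = S)
    }
  }
  si_id <- m$id[!was_grow]
  if (length(si_id)) {
    si <- match(si_id, m$id)
    m$len[si] <- m$len[si] - params$v_d * h
    state$mt <- m
    lost_id <- si_id[m$len[si] <= 0]
    for (id in lost_id) {
      i <- match(id, state$mt$id)
      ev[[length(ev) + 1L]] <- list(
        kind = "loss", t = t_new, mt_id = id,
        pos_signed = -S / 2, S = S)
      state <- remove_mt(state, i)
      rr <- reorganize_lattice(state)
      state <- rr$state
      if (nrow(rr$moves))
        for (k in seq_len(nrow(rr$moves)))
          ev[[length(ev) + 1L]] <- list(
            kind = "reorganization", t = t_new, mt_id = rr$moves$mt_id[k],
            pos_signed = NA_real_, S = S)
    }
    surv_id <- setdiff(si_id, lost_id)
    if (length(surv_id)) {
      mzv <- params$variant == "midzone"
      Lt <- if (!mzv) sum(state$mt$len) else 0
      u <- stats::runif(length(surv_id))
      for (k in seq_along(surv_id)) {
        i <- match(surv_id[k], state$mt$id)
        r <- if (mzv)
          rescue_rate_fast(state$mt$len[i], S, state$Lm, state$nbr[i],
                           state$n_pairs, params$R, params$alpha, params$beta)
        else if (Lt > 0) params$R / (2 * Lt) else 0
        if (r > 0 && u[k] < 1 - exp(-r * h)) {
          state$mt$grow[i] <- TRUE
          state$mt$tau[i] <-
            sample_growth_duration(params$theta_cat, params$n_cat, 1L)
          ev[[length(ev) + 1L]] <- list(
            kind = "rescue", t = t_new, mt_id = surv_id[k],
            pos_signed = tip_pos_signed(state$mt$len[i], S), S = S)
        }
      }
    }
  } else {
    state$mt <- m
  }
  if (check_collapse(state)) {
    state$collapsed <- TRUE
    ev[[length(ev) + 1L]] <- list(
      kind = "collapse", t = t_new, mt_id = NA_integer_,
      pos_signed = NA_real_, S = S)
  }
  list(state = state, events = ev)
}

#' Test whether the spindle has collapsed
#'
#' The spindle collapses when the longest microtubules from the two poles no
#' longer overlap: either pole holds no microtubule, or the sum of the two
#' maximal lengths does not exceed the pole separation (crosslinking needs
#' strictly positive overlap, so a zero overlap counts as collapsed).
#'
#' @param state a `spindle_state`.
#' @return `TRUE` if collapsed.
#' @export
check_collapse <- function(state) {
  m <- state$mt
  left <- m$len[m$pole == 1L]
  right <- m$len[m$pole == 2L]
  if (!length(left) || !length(right)) return(TRUE)
  max(left) + max(right) <= state$S
}

#' Run one seeded spindle simulation
#'
#' Initialises the spindle and advances it in steps of `h` until collapse or
#' until `t_max`. The result is bit-reproducible from `(params, seed)`; the
#' caller's RNG state is left untouched.
#'
#' @param params a [sim_params()] object.
#' @param seed integer seed for this run.
#' @param record_dt interval (min) at which the trajectory series is
#'   sampled; rounded to a whole number of timesteps.
#' @return An object of class `spindle_trajectory`: list with `series`
#'   (data frame `t`, `S`, `polymer`, `n_left`, `n_right`), `tips` (matrix
#'   of lab-frame plus-end positions, one column per microtubule id, `NA`
#'   once lost), `tip_pole` (orientation per id), `events` (data frame),
#'   `outcome` (`collapsed`, `t_end`, `S_end`), `Lm`, `params`, `seed`.
#' @export
run_simulation <- function(params, seed, record_dt = 0.05) {
  validate_sim_params(params)
  every <- max(1L, as.integer(round(record_dt / params$h)))
  n_steps <- as.integer(ceiling(params$t_max / params$h))
  with_seed(seed, {
    state <- init_spindle(params)
    n_id <- length(state$mt$id)
    cap <- n_steps %/% every + 2L
    t_v <- numeric(cap); S_v <- numeric(cap); poly_v <- numeric(cap)
    nl_v <- integer(cap); nr_v <- integer(cap)
    tips <- matrix(NA_real_, cap, n_id)
    tip_pole <- state$mt$pole[order(state$mt$id)]
    rec <- 0L
    record <- function(st) {
      rec <<- rec + 1L
      t_v[rec] <<- st$t; S_v[rec] <<- st$S
      poly_v[rec] <<- sum(st$mt$len)
      nl_v[rec] <<- sum(st$mt$pole == 1L)
      nr_v[rec] <<- sum(st$mt$pole == 2L)
      tips[rec, st$mt$id] <<- tip_pos_lab(st$mt$len, st$S, st$mt$pole)
    }
    record(state)
    events <- vector("list", 4096L); nev <- 0L
    for (step in seq_len(n_steps)) {
      out <- advance_timestep(state, params)
      state <- out$state
      if (length(out$events)) {
        for (e in out$events) {
          nev <- nev + 1L
          if (nev > length(events)) events <- c(events, vector("list", 4096L))
          events[[nev]] <- e
        }
      }
      if (step %% every == 0L || isTRUE(state$collapsed) || step == n_steps)
        record(state)
      if (isTRUE(state$collapsed)) break
    }
    events <- events[seq_len(nev)]
    ev_df <- if (nev) data.frame(
      kind = vapply(events, `[[`, "", "kind"),
      t = vapply(events, `[[`, 0, "t"),
      mt_id = vapply(events, function(e) as.integer(e$mt_id), 0L),
      pos_signed = vapply(events, `[[`, 0, "pos_signed"),
      S = vapply(events, `[[`, 0, "S"))
    else data.frame(kind = character(), t = numeric(), mt_id = integer(),
                    pos_signed = numeric(), S = numeric())
    traj <- list(
      series = data.frame(t = t_v[1:rec], S = S_v[1:rec],
                          polymer = poly_v[1:rec],
                          n_left = nl_v[1:rec], n_right = nr_v[1:rec]),
      tips = tips[1:rec, , drop = FALSE],
      tip_pole = tip_pole,
      events = ev_df,
      outcome = list(collapsed = isTRUE(state$collapsed),
                     t_end = state$t, S_end = state$S),
      Lm = state$Lm,
      final_state = state,
      params = params,
      seed = seed)
    class(traj) <- "spindle_trajectory"
    traj
  })
}

#' @export
print.spindle_trajectory <- function(x, ...) {
  o <- x$outcome
  cat(sprintf(
    "spindle_trajectory (seed %s): %s at t = %.2f min (S = %.2f um), %d events, %d MTs remain\n",
    format(x$seed), if (o$collapsed) "collapsed" else "survived",
    o$t_end, o$S_end, nrow(x$events), length(x$final_state$mt$id)))
  invisible(x)
}

#' Analytic probability of losing one pole's entire microtubule set
#'
#' If every microtubule is lost independently with probability `p_loss` over
#' anaphase (about 1/2, since spindles start with nine microtubules and end
#' with about five), the chance that a pole holding `n_left` or `n_right`
#' microtubules loses all of them estimates how often a spindle without an
#' even-loss mechanism would collapse. All `2^(n_left + n_right)` outcomes
#' are enumerated and the two per-pole probabilities are summed, matching
#' the additive estimate `p^n_left + p^n_right` (~9.4% for 4 and 5
#' microtubules at `p = 1/2`, i.e. roughly one spindle in ten).
#'
#' @param n_left,n_right microtubules per pole.
#' @param p_loss per-microtubule loss probability.
#' @return Probability (0-1 scale).
#' @examples
#' pole_loss_probability() # 0.09375
#' @export
pole_loss_probability <- function(n_left = 4L, n_right = 5L, p_loss = 0.5) {
  n <- n_left + n_right
  stopifnot(n <= 24, p_loss >= 0, p_loss <= 1)
  total <- 0
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(n)]
    w <- prod(ifelse(bits == 1L, p_loss, 1 - p_loss))
    left_all <- all(bits[seq_len(n_left)] == 1L)
    right_all <- all(bits[n_left + seq_len(n_right)] == 1L)
    total <- total + w * (left_all + right_all)
  }
  total
}
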