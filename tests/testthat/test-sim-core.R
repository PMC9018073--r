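p_wt <- sim_params()

test_that("growth-duration sampler inverts the stated CDF draw for draw", {
  set.seed(101)
  d <- sample_growth_duration(3.17, 8.53, 1000)
  set.seed(101)
  u <- runif(1000)
  expect_equal(d, -log(1 - u^(1 / 8.53)) / 3.17)
  # exponential special case: median = log(2)/theta
  expect_equal(-log(1 - 0.5^(1 / 1)) / 1, log(2))
  # sample agrees with the CDF (one-sample KS against the model)
  set.seed(7)
  big <- sample_growth_duration(3.17, 8.53, 1e5)
  ks <- max(abs(seq_along(big) / length(big) -
                  growth_duration_cdf(sort(big), 3.17, 8.53)))
  expect_lt(ks, 0.01)
})

test_that("sampler moments match quadrature of the survival function", {
  mo <- growth_duration_moments(3.17, 8.53)
  expect_equal(unname(mo["mean"]) * 60, 52.59, tolerance = 1e-3)
  set.seed(11)
  d <- sample_growth_duration(3.17, 8.53, 1e5)
  expect_equal(mean(d), unname(mo["mean"]), tolerance = 0.01)
  expect_equal(sd(d), unname(mo["sd"]), tolerance = 0.02)
})

test_that("initial spindle is the 3x3 chequerboard with 12 antiparallel pairs", {
  st <- anaphaseB:::with_seed(1, init_spindle(p_wt))
  expect_length(st$mt$id, 9L)
  expect_true(all(st$mt$len == 3))
  expect_true(all(st$mt$grow))
  expect_equal(st$S, 4)
  expect_equal(st$n_pairs, 12L)
  expect_setequal(unique(st$mt$pole), c(1L, 2L))
  expect_equal(sort(table(st$mt$pole)), sort(c(`1` = 5L, `2` = 4L)),
               ignore_attr = TRUE)
  cen <- neighbour_census(st)
  # centre has 4 antiparallel neighbours, corners 2, edge-centres 3
  centre <- st$mt$id[st$mt$row == 2 & st$mt$col == 2]
  corner <- st$mt$id[st$mt$row == 1 & st$mt$col == 1]
  expect_equal(unname(cen$counts[as.character(centre)]), 4L)
  expect_equal(unname(cen$counts[as.character(corner)]), 2L)
  expect_equal(sum(cen$counts), 2L * cen$n_pairs)
  # determinism
  st2 <- anaphaseB:::with_seed(1, init_spindle(p_wt))
  expect_identical(st, st2)
})

test_that("midzone length sampling reproduces the normal fit mean", {
  Lms <- anaphaseB:::with_seed(42, {
    vapply(1:10000, function(i) init_spindle(p_wt)$Lm, 0)
  })
  expect_equal(mean(Lms), 1.23, tolerance = 0.01)
  expect_true(all(Lms > 0))
})

test_that("the reduced midzone coordinate runs from own-pole edge to far edge", {
  st <- make_test_state(Lm = 1.23, S = 4)
  left <- st$mt$id[st$mt$pole == 1L][1]
  right <- st$mt$id[st$mt$pole == 2L][1]
  set_tip <- function(st, id, pos) {
    st$mt$len[match(id, st$mt$id)] <- pos + st$S / 2
    st
  }
  # tip at the centre -> x = 1/2 by symmetry
  expect_equal(midzone_coordinate(set_tip(st, left, 0), left), 0.5)
  # left-pole tip at its own midzone edge -> x = 0
  expect_equal(midzone_coordinate(set_tip(st, left, -st$Lm / 2), left), 0)
  # the same lab position is the far edge for a right-pole microtubule
  # (signed coordinates: its tip position is +Lm/2 in its growth direction)
  expect_equal(midzone_coordinate(set_tip(st, right, st$Lm / 2), right), 1)
  # outside the midzone -> NA
  expect_true(is.na(midzone_coordinate(set_tip(st, left, st$Lm), left)))
})

test_that("rescue rate follows the shared-budget field", {
  st <- make_test_state(Lm = 1.23, S = 4)
  centre <- st$mt$id[st$mt$row == 2 & st$mt$col == 2]
  i <- match(centre, st$mt$id)
  st$mt$len[i] <- 0 + st$S / 2  # tip at the centre, x = 0.5
  # flat field (alpha = beta = 1): r = n R / (Lm N)
  p_flat <- sim_params(alpha = 1, beta = 1)
  rc <- rescue_rate(st, centre, p_flat)
  expect_equal(rc$n_neighbours, 4L)
  expect_equal(rc$n_pairs, 12L)
  expect_equal(rc$rate, 4 * 55 / (1.23 * 12), tolerance = 1e-12)
  # Beta(4, 2) at x = 0.75: density 20 x^3 (1 - x)
  st$mt$len[i] <- (0.75 - 0.5) * st$Lm + st$S / 2
  rc2 <- rescue_rate(st, centre, sim_params(alpha = 4, beta = 2))
  expect_equal(rc2$x, 0.75)
  expect_equal(rc2$p_density, 20 * 0.75^3 * 0.25)
  expect_equal(rc2$rate, 4 * 55 * 2.109375 / (1.23 * 12), tolerance = 1e-12)
  # no antiparallel neighbour -> no rescue
  iso <- st
  for (id in setdiff(iso$mt$id, centre)) iso <- anaphaseB:::remove_mt(
    iso, match(id, iso$mt$id))
  expect_equal(rescue_rate(iso, centre, p_flat)$rate, 0)
})

test_that("uniform-variant rate is R / (2 Lt) anywhere", {
  st <- make_test_state(params = sim_params_ase1())
  pa <- sim_params_ase1()
  Lt <- sum(st$mt$len)
  rc <- rescue_rate(st, st$mt$id[1], pa)
  expect_equal(rc$rate, 34 / (2 * Lt))
  # independent of tip position
  st$mt$len[1] <- 0.1
  expect_equal(rescue_rate(st, st$mt$id[1], pa)$rate,
               34 / (2 * sum(st$mt$len)))
})

test_that("neighbour census agrees with exhaustive pair enumeration", {
  set.seed(5)
  for (k in 1:25) {
    nr <- sample(2:4, 1); nc <- sample(2:4, 1)
    lat <- matrix(sample(0:2, nr * nc, replace = TRUE), nr, nc)
    oracle <- brute_force_pairs(lat)
    cen <- anaphaseB:::lattice_census(lat)
    expect_identical(cen$n_pairs, oracle$n_pairs)
    expect_identical(cen$counts, oracle$counts)
  }
})

test_that("losing the centre microtubule lowers each edge-centre count by one", {
  st <- make_test_state()
  centre <- st$mt$id[st$mt$row == 2 & st$mt$col == 2]
  before <- neighbour_census(st)$counts
  st2 <- anaphaseB:::remove_mt(st, match(centre, st$mt$id))
  after <- neighbour_census(st2)$counts
  edges <- as.character(st$mt$id[(st$mt$row == 2) != (st$mt$col == 2)])
  expect_equal(unname(before[edges] - after[edges]), rep(1L, 4L))
})

test_that("lattice reorganization is greedy, deterministic and never loses pairs", {
  st <- make_test_state()
  centre <- st$mt$id[st$mt$row == 2 & st$mt$col == 2]
  st2 <- anaphaseB:::remove_mt(st, match(centre, st$mt$id))
  n_before <- st2$n_pairs
  rr <- reorganize_lattice(st2)
  expect_gte(rr$state$n_pairs, n_before)
  expect_gt(nrow(rr$moves), 0L)
  # the first move brings a same-orientation corner into the centre
  mv <- rr$moves[1, ]
  moved_pole <- st$mt$pole[match(mv$mt_id, st$mt$id)]
  expect_equal(moved_pole, st$mt$pole[match(centre, st$mt$id)])
  expect_true(mv$from_row %in% c(1, 3) && mv$from_col %in% c(1, 3))
  expect_equal(c(mv$to_row, mv$to_col), c(2, 2))
  # lowest-id tie-break: it is the smallest corner id
  corners <- st$mt$id[st$mt$row %in% c(1, 3) & st$mt$col %in% c(1, 3)]
  expect_equal(mv$mt_id, min(corners))
  # verify against enumeration: no single move from the result improves
  res <- rr$state
  for (j in seq_along(res$mt$id)) {
    for (e in which(res$lat == 0L)) {
      er <- row(res$lat)[e]; ec <- col(res$lat)[e]
      gain <- anaphaseB:::site_antiparallel_count(
        res$lat, er, ec, res$mt$pole[j]) - res$nbr[j]
      expect_lte(gain, 0L)
    }
  }
  # a full lattice cannot be improved
  rr0 <- reorganize_lattice(make_test_state())
  expect_equal(nrow(rr0$moves), 0L)
})

test_that("one timestep moves poles exactly and only rescues at positive rate", {
  st <- make_test_state()
  out <- advance_timestep(st, p_wt)
  expect_equal(out$state$S, st$S + 2 * 0.35 * 0.01)
  expect_equal(out$state$t, st$t + 0.01)
  # a shrinking microtubule with zero rescue rate is never rescued
  p0 <- sim_params(R = 0)
  st0 <- make_test_state(params = p0)
  st0$mt$grow[] <- FALSE
  st0$mt$len[] <- 2.5
  set.seed(3)
  for (k in 1:50) {
    o <- advance_timestep(st0, p0)
    expect_false(any(o$state$mt$grow))
  }
})

test_that("per-step rescue frequency matches 1 - exp(-r h)", {
  st <- make_test_state(Lm = 1.23, S = 4)
  centre <- st$mt$id[st$mt$row == 2 & st$mt$col == 2]
  i <- match(centre, st$mt$id)
  st$mt$grow[i] <- FALSE
  p_flat <- sim_params(alpha = 1, beta = 1)
  # tip position after the in-step shrinkage determines the tested rate
  st$mt$len[i] <- 0 + st$S / 2 + p_flat$v_d * p_flat$h
  r <- 4 * 55 / (1.23 * 12)  # flat field: position inside midzone is irrelevant
  p_th <- 1 - exp(-r * p_flat$h)
  set.seed(9)
  hits <- vapply(1:4000, function(k) {
    o <- advance_timestep(st, p_flat)
    o$state$mt$grow[match(centre, o$state$mt$id)]
  }, TRUE)
  se <- sqrt(p_th * (1 - p_th) / 4000)
  expect_lt(abs(mean(hits) - p_th), 4 * se)
})

test_that("collapse triggers on lost overlap or an empty pole", {
  st <- make_test_state(S = 6)
  st$mt$len[st$mt$pole == 1L] <- 3.5
  st$mt$len[st$mt$pole == 2L] <- 3.0
  expect_false(check_collapse(st))
  st$mt$len[st$mt$pole == 1L] <- 2.9
  expect_true(check_collapse(st))
  # empty pole
  st2 <- make_test_state()
  for (id in st2$mt$id[st2$mt$pole == 1L])
    st2 <- anaphaseB:::remove_mt(st2, match(id, st2$mt$id))
  expect_true(check_collapse(st2))
})

test_that("runs are reproducible and a zero rescue budget is lethal", {
  tr1 <- run_simulation(p_wt, seed = 77)
  tr2 <- run_simulation(p_wt, seed = 77)
  expect_identical(tr1$events, tr2$events)
  expect_identical(tr1$series, tr2$series)
  for (s in 1:3) {
    tr <- run_simulation(sim_params(R = 0), seed = s)
    expect_true(tr$outcome$collapsed)
    expect_lt(tr$outcome$t_end, 20)
  }
})

test_that("trajectories respect the hard geometric invariants", {
  tr <- run_simulation(p_wt, seed = 13)
  s <- tr$series
  expect_equal(s$S, 4 + 2 * 0.35 * s$t)        # machine-precision kinematics
  expect_true(all(diff(s$t) > 0))
  expect_true(all(s$polymer >= 0))
  # tips stay between the poles
  for (rr in seq_len(nrow(tr$tips))) {
    tp <- tr$tips[rr, ]
    expect_true(all(abs(tp[!is.na(tp)]) <= s$S[rr] / 2 + 1e-9))
  }
  # rescues happen inside the midzone
  resc <- tr$events[tr$events$kind == "rescue", ]
  expect_gt(nrow(resc), 0L)
  expect_true(all(abs(resc$pos_signed) <= tr$Lm / 2 + 1e-9))
})

test_that("shared rescue budget balances the poles' remaining microtubules", {
  # the budget-sharing mechanism drives the two poles toward the same
  # surviving count (so neither pole empties), even though the pole that
  # starts with five microtubules must shed more of them than the one
  # starting with four
  n_runs <- 200
  left <- numeric(n_runs); right <- numeric(n_runs)
  for (i in seq_len(n_runs)) {
    tr <- run_simulation(p_wt, seed = derive_seed(3100, i))
    st <- tr$final_state
    left[i] <- sum(st$mt$pole == 1L)
    right[i] <- sum(st$mt$pole == 2L)
  }
  expect_lt(abs(mean(left) - mean(right)), 0.5)
  expect_true(all(left > 0) && all(right > 0))
})

test_that("pole-loss enumeration reproduces the analytic estimate", {
  expect_equal(pole_loss_probability(4, 5, 0.5), 1 / 2^4 + 1 / 2^5)
  # general p: additive per-pole probabilities
  expect_equal(pole_loss_probability(3, 2, 0.3), 0.3^3 + 0.3^2)
})
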