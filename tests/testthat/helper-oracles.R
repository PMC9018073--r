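# Independent oracles used across tests; deliberately naive implementations.

# exhaustive antiparallel-pair enumeration on a lattice matrix (0/1/2)
brute_force_pairs <- function(lat) {
  nr <- nrow(lat); nc <- ncol(lat)
  pairs <- 0L
  counts <- matrix(0L, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (lat[r, cc] == 0L) next
    for (d in list(c(0L, 1L), c(1L, 0L), c(0L, -1L), c(-1L, 0L))) {
      r2 <- r + d[1]; c2 <- cc + d[2]
      if (r2 >= 1L && r2 <= nr && c2 >= 1L && c2 <= nc &&
          lat[r2, c2] != 0L && lat[r2, c2] != lat[r, cc])
        counts[r, cc] <- counts[r, cc] + 1L
    }
  }
  pairs <- sum(counts) %/% 2L
  list(counts = counts, n_pairs = pairs)
}

# KS statistic by direct enumeration of both ECDFs at every step point
brute_force_ks <- function(a, b) {
  xs <- sort(unique(c(a, b)))
  d <- 0
  for (x in xs) {
    d <- max(d, abs(mean(a <= x) - mean(b <= x)))
  }
  d
}

# a spindle state with hand-set geometry for rescue-field checks
make_test_state <- function(params = sim_params(), seed = 1, Lm = NULL,
                            S = NULL) {
  st <- anaphaseB:::with_seed(seed, init_spindle(params))
  if (!is.null(Lm)) st$Lm <- Lm
  if (!is.null(S)) st$S <- S
  st
}

# rescue rate of microtubule `id` as a function of signed tip position
rate_at_pos <- function(state, id, pos, params) {
  i <- match(id, state$mt$id)
  state$mt$len[i] <- pos + state$S / 2
  rescue_rate(state, id, params)$rate
}
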