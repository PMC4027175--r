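# Independent oracles, deliberately decoupled from the package internals.

# brute-force pulse metrics: own lsoda call on a 10x finer grid, discrete
# max for A, forward scan plus discrete sum for T and E
brute_pair_metrics <- function(p1, p2, p3, fold = 2, t_step = 1,
                               t_end = 200, dt = 0.001) {
  rhs <- function(t, s, pr) {
    u <- if (t < pr$ts) 1 else pr$fold
    list(c(u - s[1] - pr$p1 * (s[1] * s[2] - s[3]),
           pr$p2 * (u - s[1] * s[2]),
           pr$p3 * (s[1] * s[2] - s[3])))
  }
  one <- function(p2v) {
    times <- seq(0, t_end, by = dt)
    out <- deSolve::lsoda(c(1, 1, 1), times, rhs,
                          list(p1 = p1, p2 = p2v, p3 = p3,
                               ts = t_step, fold = fold),
                          rtol = 1e-10, atol = 1e-12)
    data.frame(t = out[, 1], y = out[, 3])
  }
  y1 <- one(p2); y2 <- one(2 * p2)
  sel <- y1$t >= t_step
  A1 <- max(y1$y[sel]) - 1
  A2 <- max(y2$y[sel]) - 1
  out_band <- which(sel & abs(y1$y - 1) > 0.01)
  T1 <- y1$t[max(out_band) + 1L]
  in_win <- y1$t >= t_step & y1$t <= T1
  E <- sum(abs(y1$y[in_win] - y2$y[in_win])) * dt / (A1 * T1)
  list(A1 = A1, A2 = A2, T1 = T1, R = A2 / A1, E = E)
}

# reference parameter fixtures used across tests
unit_dr <- function(a1 = 1, a2 = 1, b1 = 1, g1 = 1) {
  structure(list(alpha1 = a1, alpha2 = a2, beta1_eff = b1, beta2_eff = 0,
                 gamma1_eff = g1, gamma2_eff = 0), class = "iffl_derived")
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-300)), tol)
}
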