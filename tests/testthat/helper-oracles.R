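# Independent oracles used to freeze expected values.  These re-derive
# results by brute force (bisection, grid search, direct summation) and
# share no code with the implementation paths they check.

# Two-independent-classes ITC forward model with free ligand found by
# plain interval bisection (no uniroot), heats by direct bookkeeping.
oracle_itc_two_site <- function(n1, ka1, dh1, n2, ka2, dh2,
                                cell_volume, cell_conc, syringe_conc,
                                n_injections, injection_volume) {
  f <- injection_volume / cell_volume
  d <- 1 - f
  mt <- cell_conc * d^seq_len(n_injections)
  xt <- syringe_conc * (1 - d^seq_len(n_injections))
  bound_heat <- function(m, x) {
    if (x <= 0) return(0)
    g <- function(xf) {
      xf + n1 * m * ka1 * xf / (1 + ka1 * xf) +
        n2 * m * ka2 * xf / (1 + ka2 * xf) - x
    }
    lo <- 0; hi <- x
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      if (g(mid) > 0) hi <- mid else lo <- mid
    }
    xf <- (lo + hi) / 2
    dh1 * n1 * m * ka1 * xf / (1 + ka1 * xf) +
      dh2 * n2 * m * ka2 * xf / (1 + ka2 * xf)
  }
  q <- cell_volume * vapply(seq_len(n_injections),
                            function(i) bound_heat(mt[i], xt[i]), 0)
  qprev <- c(0, q[-length(q)])
  (q - qprev + f * (q + qprev) / 2) / (syringe_conc * injection_volume)
}

# Brute-force rigid superposition: nested Euler-angle grid search,
# refined three times around the running best.
oracle_superpose_rmsd <- function(mobile, reference) {
  xm <- sweep(mobile, 2, colMeans(mobile))
  xr <- sweep(reference, 2, colMeans(reference))
  rot <- function(a, b, c) {
    rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
    ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
    rx <- matrix(c(1, 0, 0, 0, cos(c), sin(c), 0, -sin(c), cos(c)), 3, 3)
    rz %*% ry %*% rx
  }
  rmsd_at <- function(a, b, c) {
    sqrt(mean(rowSums((xm %*% rot(a, b, c) - xr)^2)))
  }
  centre <- c(0, 0, 0); width <- pi
  best <- c(0, 0, 0); best_val <- rmsd_at(0, 0, 0)
  for (stage in 1:4) {
    grid <- seq(-width, width, length.out = 13)
    for (a in centre[1] + grid) for (b in centre[2] + grid)
      for (c in centre[3] + grid) {
        v <- rmsd_at(a, b, c)
        if (v < best_val) { best_val <- v; best <- c(a, b, c) }
      }
    centre <- best
    width <- width / 5
  }
  best_val
}

# Closed-form bi-exponential fraction remaining at time t (seconds).
biexp_remaining <- function(t, w_fast, tau_fast, tau_slow) {
  w_fast * exp(-t / tau_fast) + (1 - w_fast) * exp(-t / tau_slow)
}

# Depletion-exact fractional saturation of the labelled peptide
# (quadratic binding oracle, written out directly).
oracle_quadratic_saturation <- function(x_total, labeled, kd) {
  s <- labeled + x_total + kd
  ((s - sqrt(s^2 - 4 * labeled * x_total)) / 2) / labeled
}
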