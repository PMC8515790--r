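# shared fixtures and small oracles for the test suite

# trajectory object carrying an arbitrary scalar signal as the
# phosphorylation observable (for period/amplitude detector tests)
make_signal_traj <- function(t, y) {
  structure(list(
    times = t,
    states = NULL,
    observables = data.frame(time = t, phos = y,
                             mean_phase = 0, circ_phase = 0, A_f = 0)
  ), class = "kai_trajectory")
}

# log-uniform jitter of selected preset fields, used for the random
# parameterization suites
jitter_params <- function(base, spread = 0.1) {
  jig <- function(x) x * exp(stats::runif(1, -spread, spread))
  kai_set(base,
          alpha = max(1, jig(base$alpha)), K_d0 = jig(base$K_d0),
          A_T = jig(base$A_T), k3_fwd = jig(base$k3_fwd),
          k2_fwd = jig(base$k2_fwd), omega = jig(base$omega),
          k1 = if (base$k1 > 0) jig(base$k1) else 0,
          eps_seq = if (base$eps_seq > 0) jig(base$eps_seq) else 0)
}

# dynamical growth rate of a small perturbation seeded along the leading
# eigenvector; the independent oracle for the linear stability flag
measured_growth_rate <- function(params, rep, t_end = 700) {
  sp <- build_state_space(params)
  fp <- rep$fixed_point
  M <- linearized_operator(params, fp, space = sp)
  ev <- eigen(M)
  i0 <- which.min(Mod(ev$values))
  lead_pos <- order(-Re(ev$values[-i0]))[1]
  vidx <- seq_along(ev$values)[-i0][lead_pos]
  v <- Re(ev$vectors[, vidx])
  v <- v - mean(v)
  p0 <- fp$p + 1e-3 * v / max(abs(v))
  p0[p0 < 0] <- 0
  p0 <- p0 / sum(p0)
  tr <- integrate_clock(params, p0 = p0, t_end = t_end, n_out = 4 * t_end,
                        space = sp)
  dev <- abs(tr$observables$phos - phosphorylation_level(fp$p, sp))
  seg <- function(a, b) max(dev[tr$times >= a & tr$times < b])
  early <- seg(t_end / 7, t_end * 5 / 14)
  late <- seg(t_end * 11 / 14, t_end)
  mid_gap <- t_end * 9 / 14
  list(rate = log(late / early) / mid_gap, saturated = late > 5e-3)
}

# Goldbeter-Koshland toy: modification fraction of a substrate cycled by two
# saturated antagonistic enzymes, solved by brute-force root finding
gk_fraction <- function(v1, v2, K1, K2) {
  f <- function(x) v1 * (1 - x) / (K1 + 1 - x) - v2 * x / (K2 + x)
  stats::uniroot(f, c(1e-12, 1 - 1e-12), tol = 1e-14)$root
}
gk_curve <- function(v1_grid, K) {
  data.frame(A_T = v1_grid,
             phos = vapply(v1_grid, function(v1) gk_fraction(v1, 1, K, K),
                           numeric(1)))
}
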