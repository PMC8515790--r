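test_that("equilibrium initial condition stays fixed and mass is conserved", {
  eq <- kai_equilibrium_params()
  sp <- build_state_space(eq)
  pu <- rep(1 / sp$n, sp$n)
  tr <- integrate_clock(eq, p0 = pu, t_end = 50, n_out = 120, space = sp)
  expect_lt(max(abs(tr$states - matrix(pu, 120, sp$n, byrow = TRUE))), 1e-7)
  expect_lt(max(abs(rowSums(tr$states) - 1)), 1e-8)
  expect_gt(min(tr$states), -1e-9)
})

test_that("frozen-KaiA dynamics agree with the matrix-exponential solution", {
  skip_if_not_installed("Matrix")
  # A_T so large that A_f is constant to relative 1e-6: linear regime
  p <- kai_preset("affinity", A_T = 1e6, k_Af = 1e-5, k_Ab0 = 2, alpha = 5)
  sp <- build_state_space(p)
  p0 <- rep(1 / sp$n, sp$n)
  W <- rate_matrix(p, p = p0, space = sp)
  tr <- integrate_clock(p, p0 = p0, t_end = 2, n_out = 5, space = sp)
  for (i in c(3, 5)) {
    t <- tr$times[i]
    ref <- as.vector(Matrix::expm(W * t) %*% p0)
    expect_lt(max(abs(tr$states[i, ] - ref)), 1e-6)
  }
})

test_that("period detection recovers a synthetic 24 h sinusoid", {
  t <- seq(0, 400, by = 0.1)
  traj <- make_signal_traj(t, 0.5 + 0.2 * sin(2 * pi * t / 24))
  cyc <- detect_period(traj, transient_fraction = 0.1)
  expect_true(cyc$oscillating)
  expect_lt(abs(cyc$period - 24), 0.1)
  expect_lt(abs(cyc$amplitude - 0.4), 0.01)
  expect_equal(cycle_amplitude(traj, 0.1), cyc$amplitude)
})

test_that("stationary and non-converged signals are classified as specified", {
  t <- seq(0, 400, by = 0.1)
  flat <- make_signal_traj(t, rep(0.5, length(t)) + 1e-6 * sin(t))
  cyc <- detect_period(flat)
  expect_false(cyc$oscillating)
  expect_equal(cyc$amplitude, 0)
  # strongly chirped signal: spacing drifts by far more than 5%
  chirp <- make_signal_traj(t, 0.5 + 0.2 * sin(2 * pi * (t / 30 + t^2 / 4000)))
  expect_error(detect_period(chirp), "not converged")
  short <- make_signal_traj(seq(0, 30, by = 0.1),
                            0.5 + 0.2 * sin(2 * pi * seq(0, 30, by = 0.1) / 24))
  expect_error(detect_period(short, transient_fraction = 0), "not converged")
})

test_that("wavepacket velocity reproduces a uniformly drifting packet", {
  p <- kai_params(N = 20)
  sp <- build_state_space(p)
  omega_drift <- 2 * pi / 24
  t <- seq(0, 240, by = 0.05)
  # von Mises packet whose center advances at constant angular velocity;
  # weights are split between nodes sharing a circle position (P1/P3 double
  # cover of the upper arc, seam at 0 = 2 pi) so the packet is a clean
  # density on the ring
  ph <- sp$nodes$phase
  mult <- vapply(ph, function(x) {
    d <- abs(ph - x)
    sum(pmin(d, 2 * pi - d) < 1e-9)
  }, numeric(1))
  states <- t(vapply(t, function(tt) {
    w <- exp(2 * cos(ph - omega_drift * tt)) / mult
    w / sum(w)
  }, numeric(sp$n)))
  traj <- kairing:::new_trajectory(t, states, sp)
  orb <- wavepacket_velocity(traj, transient_fraction = 0.2)
  expect_lt(max(abs(orb$velocity - omega_drift)) / omega_drift, 0.1)
  eq <- kai_equilibrium_params()
  n_eq <- build_state_space(eq)$n
  flat <- integrate_clock(eq, p0 = rep(1 / n_eq, n_eq), t_end = 60, n_out = 300)
  expect_error(wavepacket_velocity(flat), "stationary")
})

test_that("limit-cycle period is independent of the initial condition", {
  u <- kai_preset("ultrasensitivity")
  sp <- build_state_space(u)
  s1 <- simulate_cycles(u, t_end = 1500)
  p0 <- rep(1 / sp$n, sp$n)
  s2 <- simulate_cycles(u, t_end = 1500, p0 = p0)
  expect_true(s1$cycles$oscillating && s2$cycles$oscillating)
  expect_lt(abs(s1$cycles$period / s2$cycles$period - 1), 0.01)
})

test_that("period is metabolically compensated while amplitude collapses", {
  u <- kai_preset("ultrasensitivity")
  out <- lapply(c(4, 8, 11.5, 12.5), function(kd) {
    simulate_cycles(kai_set(u, K_d0 = kd), t_end = 1200)$cycles
  })
  periods <- vapply(out, `[[`, numeric(1), "period")
  amps <- vapply(out, `[[`, numeric(1), "amplitude")
  expect_true(all(vapply(out, `[[`, logical(1), "oscillating")))
  # period changes by ~10% or less across the ATP proxy range...
  expect_lt(diff(range(periods)) / mean(periods), 0.1)
  # ...while the amplitude varies much more strongly and shrinks
  # towards the oscillation boundary
  expect_gt(max(amps) / min(amps), 2)
  expect_true(all(diff(amps[-1]) < 0))
})

test_that("velocity orbits shrink as K_d0 grows (lower %ATP, smaller loop)", {
  u <- kai_preset("ultrasensitivity")
  area <- vapply(c(4, 12), function(kd) {
    s <- simulate_cycles(kai_set(u, K_d0 = kd), t_end = 1200)
    orb <- wavepacket_velocity(s$trajectory)
    abs(sum(diff(orb$phase) *
              (head(orb$velocity, -1) + tail(orb$velocity, -1)) / 2))
  }, numeric(1))
  expect_gt(area[1], area[2])
})

test_that("trajectory observables export as CSV", {
  tr <- integrate_clock(kai_equilibrium_params(), t_end = 10, n_out = 20)
  path <- tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  tab <- utils::read.csv(path)
  expect_equal(nrow(tab), 20)
  expect_true(all(c("time", "phos", "mean_phase", "A_f") %in% names(tab)))
})
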