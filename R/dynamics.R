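#' Integrate the nonlinear master equation
#'
#' Solves `dP/dt = W(P) P` with a stiff-capable solver (`deSolve::ode`,
#' method `"lsoda"`, relative tolerance 1e-8). Mass conservation is exact at
#' the level of the vector field (columns of `W` sum to zero); the integrator
#' drift in `sum(P)` is monitored, renormalized when it exceeds 1e-9 and
#' treated as a failure beyond 1e-6.
#'
#' @param params A [kai_params()] object.
#' @param p0 Initial probability vector; default: all mass at `P1(0)`, the
#'   fully dephosphorylated KaiA-free state.
#' @param t_end Final time (> 0).
#' @param n_out Number of evenly spaced output samples.
#' @param space Optional prebuilt `kai_space`.
#' @param rtol,atol Integrator tolerances.
#' @return A `kai_trajectory`: list with `times`, `states` (matrix
#'   `n_out x n`, rows renormalized), and `observables`, a data frame with
#'   per-sample `time`, `phos` (phosphorylation level), `mean_phase`
#'   (`sum(phi * p)`), `circ_phase` (unwrapped circular mean phase, used for
#'   velocities) and `A_f`.
#' @seealso [detect_period()], [cycle_amplitude()], [wavepacket_velocity()]
#' @export
integrate_clock <- function(params, p0 = NULL, t_end = 500, n_out = 2000,
                            space = build_state_space(params),
                            rtol = 1e-8, atol = 1e-12) {
  if (t_end <= 0) stop("t_end must be > 0")
  n <- space$n
  if (is.null(p0)) {
    p0 <- numeric(n)
    p0[1] <- 1
  }
  check_prob_state(p0, n)
  times <- seq(0, t_end, length.out = n_out)
  i3 <- space$idx$P3
  i2 <- space$idx$P2
  floor_af <- if (params$k_Af > 0) params$reverse_floor / params$k_Af else 0
  rhs <- function(t, p, parms) {
    af <- max(params$A_T - sum(p[i3]) - params$eps_seq * sum(p[i2]), floor_af, 0)
    list(as.vector(space$W0 %*% p) + af * as.vector(space$B %*% p))
  }
  jac <- function(t, p, parms) {
    linearized_operator(params, list(p = p), space = space, check = FALSE)
  }
  sol <- deSolve::ode(y = p0, times = times, func = rhs, parms = NULL,
                      method = "lsoda", jacfunc = jac, jactype = "fullusr",
                      rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0 || nrow(sol) < n_out) {
    stop("integrator failure before t_end")
  }
  states <- unname(sol[, -1, drop = FALSE])
  mass <- rowSums(states)
  if (any(abs(mass - 1) > 1e-6)) {
    stop("probability mass drifted by more than 1e-6 during integration")
  }
  drift <- abs(mass - 1) > 1e-9
  if (any(drift)) states[drift, ] <- states[drift, ] / mass[drift]
  states[states < 0 & states > -1e-12] <- 0

  new_trajectory(times, states, space)
}

#' @keywords internal
check_prob_state <- function(p, n) {
  if (length(p) != n) stop("probability vector has wrong length")
  if (abs(sum(p) - 1) > 1e-9) stop("probability vector must sum to 1 (tol 1e-9)")
  if (any(p < -1e-12)) stop("probability vector has negative entries")
  invisible(TRUE)
}

#' Assemble a trajectory object from sampled states
#'
#' Internal constructor also used by the tests to build synthetic
#' trajectories. Computes the derived observables, including the unwrapped
#' circular mean phase `Arg(sum p_i exp(i phi_i))`, accumulated over time so
#' it can be differentiated across the 2*pi reset.
#'
#' @param times Increasing sample times.
#' @param states Matrix of probability vectors (rows).
#' @param space The `kai_space` the columns refer to.
#' @return A `kai_trajectory`.
#' @keywords internal
new_trajectory <- function(times, states, space) {
  phos <- as.vector(states %*% space$phos)
  mean_phase <- as.vector(states %*% space$nodes$phase)
  z <- states %*% cbind(cos(space$nodes$phase), sin(space$nodes$phase))
  ang <- atan2(z[, 2], z[, 1])
  dang <- diff(ang)
  dang <- dang - 2 * pi * round(dang / (2 * pi))
  circ <- cumsum(c(ang[1], dang))
  af <- apply(states, 1, function(p) free_kaia(space$params, p, space))
  structure(list(
    times = times, states = states, space = space,
    observables = data.frame(
      time = times, phos = phos, mean_phase = mean_phase,
      circ_phase = circ, A_f = af
    )
  ), class = "kai_trajectory")
}

#' Locate signal peaks with quadratic interpolation
#' @keywords internal
find_peaks <- function(t, y) {
  n <- length(y)
  if (n < 3) return(list(t = numeric(0), y = numeric(0)))
  i <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  i <- i[i > 1 & i < n]
  if (!length(i)) return(list(t = numeric(0), y = numeric(0)))
  # parabola through the three bracketing samples; refines sub-sample timing
  tp <- yp <- numeric(length(i))
  for (k in seq_along(i)) {
    j <- i[k]
    denom <- y[j - 1] - 2 * y[j] + y[j + 1]
    delta <- if (denom < 0) 0.5 * (y[j - 1] - y[j + 1]) / denom else 0
    dt <- t[j + 1] - t[j]
    tp[k] <- t[j] + delta * dt
    yp[k] <- y[j] - 0.25 * (y[j - 1] - y[j + 1]) * delta
  }
  list(t = tp, y = yp)
}

#' Detect the oscillation period of a trajectory
#'
#' Discards the leading `transient_fraction` of the phosphorylation signal,
#' finds its local maxima (with quadratic sub-sample refinement) and reports
#' the mean peak-to-peak spacing. A signal whose peak-to-trough span is below
#' `1e-4` is classified as stationary (`oscillating = FALSE`). A signal whose
#' cycle-to-cycle spacing still varies by more than 5% is treated as not yet
#' converged and raises an error, as does a trajectory with fewer than 3
#' complete cycles after the transient.
#'
#' @param traj A `kai_trajectory`.
#' @param transient_fraction Fraction of the trajectory discarded as
#'   transient (default 0.3).
#' @return A `kai_cycles` list: `period`, `amplitude` (peak-to-trough),
#'   `oscillating`, `n_cycles`, `transient_time`.
#' @export
detect_period <- function(traj, transient_fraction = 0.3) {
  ob <- traj$observables
  keep <- ob$time >= transient_fraction * max(ob$time)
  t <- ob$time[keep]
  y <- ob$phos[keep]
  span <- max(y) - min(y)
  res <- list(period = NA_real_, amplitude = 0, oscillating = FALSE,
              n_cycles = 0L, transient_time = transient_fraction * max(ob$time))
  class(res) <- "kai_cycles"
  if (span < 1e-4) {
    return(res)
  }
  pk <- find_peaks(t, y)
  # ignore micro-peaks from numerical ripple
  sig <- pk$y > min(y) + 0.25 * span
  pk <- list(t = pk$t[sig], y = pk$y[sig])
  if (length(pk$t) < 4) {
    stop("not converged: fewer than 3 complete cycles after the transient")
  }
  gaps <- diff(pk$t)
  period <- mean(gaps)
  if (max(abs(gaps - period)) > 0.05 * period) {
    stop("not converged: cycle-to-cycle period drift exceeds 5%")
  }
  tr <- find_peaks(t, -y)
  res$period <- period
  res$amplitude <- if (length(tr$t)) mean(pk$y) - mean(-tr$y) else span
  res$oscillating <- TRUE
  res$n_cycles <- length(gaps)
  res
}

#' Peak-to-trough amplitude of the limit-cycle phosphorylation signal
#'
#' Returns 0 for stationary trajectories and the mean peak minus mean trough
#' of the post-transient phosphorylation signal otherwise.
#'
#' @inheritParams detect_period
#' @return Scalar amplitude in `[0, 1]`.
#' @export
cycle_amplitude <- function(traj, transient_fraction = 0.3) {
  detect_period(traj, transient_fraction)$amplitude
}

#' Angle--angular-velocity orbit of the phosphorylation wavepacket
#'
#' Central-difference angular velocity `d<phi>/dt` of the unwrapped circular
#' mean phase against the mean phase itself, over the final detected cycle.
#' The closed curve in the `(<phi>, velocity)` plane is the orbit whose
#' enclosed area grows with %ATP (smaller `K_d0`) while the period stays
#' nearly constant -- the geometric picture behind metabolic compensation.
#'
#' @param traj A `kai_trajectory` on a limit cycle.
#' @param transient_fraction Transient fraction passed to [detect_period()].
#' @return Data frame `(phase, velocity)` covering one cycle; `phase` is the
#'   unwrapped mean phase reduced to `[0, 2*pi)`.
#' @export
wavepacket_velocity <- function(traj, transient_fraction = 0.3) {
  cyc <- detect_period(traj, transient_fraction)
  if (!cyc$oscillating) {
    stop("trajectory is stationary: no wavepacket velocity to report")
  }
  ob <- traj$observables
  t_last <- max(ob$time)
  keep <- ob$time >= t_last - cyc$period & ob$time <= t_last
  t <- ob$time[keep]
  ph <- ob$circ_phase[keep]
  if (max(abs(diff(ph))) > 0.2) {
    warning("mean phase advances by more than 0.2 rad between samples; velocity may be under-resolved")
  }
  m <- length(t)
  vel <- c(
    (ph[2] - ph[1]) / (t[2] - t[1]),
    (ph[3:m] - ph[1:(m - 2)]) / (t[3:m] - t[1:(m - 2)]),
    (ph[m] - ph[m - 1]) / (t[m] - t[m - 1])
  )
  data.frame(phase = ph %% (2 * pi), velocity = vel)
}

#' Simulate and summarize a parameter point
#'
#' Convenience wrapper: integrates for `n_periods` predicted linear-stability
#' periods (falling back to `t_end` when the prediction is unavailable) and
#' returns the cycle summary together with the trajectory.
#'
#' @param params A `kai_params` object.
#' @param n_periods Trajectory length in predicted periods (default 40).
#' @param t_end Fallback / override final time.
#' @param n_out Output samples.
#' @param p0 Optional initial state.
#' @param transient_fraction Passed to [detect_period()].
#' @param t_max Cap on the adaptively chosen final time.
#' @return List `(trajectory, cycles)`.
#' @export
simulate_cycles <- function(params, n_periods = 40, t_end = NULL, n_out = NULL,
                            p0 = NULL, transient_fraction = 0.3, t_max = 6000) {
  if (is.null(t_end)) {
    rep <- try(stability_report(params), silent = TRUE)
    t_end <- if (!inherits(rep, "try-error") && is.finite(rep$predicted_period)) {
      grow <- if (rep$oscillating && Re(rep$leading) > 1e-12) {
        # allow slow linear growth near onset to saturate
        12 / Re(rep$leading)
      } else 0
      min(max(n_periods * rep$predicted_period, grow), t_max)
    } else {
      1000
    }
  }
  if (is.null(n_out)) n_out <- max(2000L, as.integer(t_end * 4))
  traj <- integrate_clock(params, p0 = p0, t_end = t_end, n_out = n_out)
  list(trajectory = traj,
       cycles = detect_period(traj, transient_fraction))
}

#' Export trajectory observables as CSV
#'
#' @param traj A `kai_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(traj$observables, path, row.names = FALSE)
  invisible(path)
}
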