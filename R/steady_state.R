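#' Exact time-independent solution in the k1 = 0 limit
#'
#' With the P1 dephosphorylation rung switched off (`k1 = 0`), no KaiA
#' sequestration (`eps_seq = 0`) and switching only at full phosphorylation
#' (`phi0 = pi`), the stationary state of the nonlinear master equation has a
#' closed form. Every interior P1 node is connected only vertically, so
#' `k_Af * A_f * P1(phi) = k_Ab0 * alpha^(phi - pi) * P3(phi)` holds exactly
#' there; the P3 and P2 rungs are constant-current birth--death chains whose
#' profiles are geometric in `1/gamma1` and `1/gamma2` plus a
#' current-proportional offset; and the cycle current `J` together with the
#' P2 anchor follow from a 2x2 linear system at the chain ends. The one
#' remaining scalar -- the free KaiA level, equivalently `b = P3(0)` -- is
#' fixed by the self-consistency `A_f = A_T - sum(P3)`, solved here as a
#' bracketed 1-D root (the closed-form counterpart is a quadratic in `b`).
#'
#' When `phi0 < pi` the same profiles still hold approximately if the states
#' above `phi0` are truncated to zero; in that case the construction is
#' delegated to [fixed_point_approx()] and flagged.
#'
#' @param params A [kai_params()] object with `k1 = 0` and `eps_seq = 0`.
#' @param strict If `TRUE` (default), error unless `k1 = 0` and
#'   `eps_seq = 0`; `phi0 < pi` switches to the flagged truncated mode.
#' @param space Optional prebuilt `kai_space`.
#' @return A `kai_fixed_point`: list with `p` (normalized occupancies),
#'   `residual` (max-norm of `W(p) p`), `max_rate`, `method`
#'   (`"analytic"` or `"analytic-truncated"`), `A_f`, and `b = P3(0)`.
#' @export
fixed_point_exact <- function(params, strict = TRUE, space = build_state_space(params)) {
  if (strict && (params$k1 != 0 || params$eps_seq != 0)) {
    stop("preconditions violated: the exact solution requires k1 = 0 and eps_seq = 0")
  }
  if (params$phi0 < pi - 1e-12) {
    fp <- fixed_point_approx(params, space = space)
    fp$method <- "analytic-truncated"
    return(fp)
  }
  af <- solve_af_consistency(params, function(a) exact_profile(params, a))
  assemble_fixed_point(params, space, af$p_raw, method = "analytic", A_f = af$A_f)
}

# Unnormalized stationary profile at a frozen free-KaiA level (k1 = 0,
# phi0 = pi).  Scale fixed by c_0 = P3(0) = 1.
#' @keywords internal
exact_profile <- function(params, A_f) {
  N <- params$N
  u <- params$k_Af * A_f
  phi <- (0:N) * pi / N
  v <- params$k_Ab0 * params$alpha^(phi - pi)
  lr <- ladder_rates(params)
  f3 <- lr$k3; g1 <- params$gamma1
  f2 <- lr$k2; g2 <- params$gamma2
  om <- params$omega; om1 <- params$omega1
  rf <- if (om1 > 0) params$reverse_floor else 0

  # Constant-current chains, parameterized from the top end to avoid the
  # catastrophic cancellation of the bottom-anchored geometric form:
  #   c_j = gamma1^(N-j) * c_N + Qc_j * J   (f3*c_j - gamma1*f3*c_{j+1} = J)
  #   d_m = gamma2^(N-m) * d_N + Qd_m * J   (f2*d_m - gamma2*f2*d_{m+1} = J)
  Pc <- g1^(N - (0:N))
  Qc <- (1 - Pc) / (f3 * (1 - g1))
  if (g1 == 1) Qc <- (N - (0:N)) / f3
  Pd <- g2^(N - (0:N))
  Qd <- (1 - Pd) / (f2 * (1 - g2))
  if (g2 == 1) Qd <- (N - (0:N)) / f2

  # unknowns x = (J, c_N, d_N), with c_0 = 1 fixing the scale:
  # (E0)  Pc_0 * c_N + Qc_0 * J = 1
  # (E1)  J = om * (a_N - d_0),  a_N = (v_N c_N + om d_0) / (u + om),
  #       d_0 = Pd_0 d_N + Qd_0 J
  # (E2)  J = om1 * d_N - rf * a_0,  a_0 = (v_0 * 1 + om1 d_N) / (u + rf)
  M <- matrix(0, 3, 3); rhs <- numeric(3)
  M[1, ] <- c(Qc[1], Pc[1], 0); rhs[1] <- 1
  s <- om * u / (u + om)   # coefficient of d_0 after substituting a_N
  M[2, ] <- c(1 + s * Qd[1], -om * v[N + 1] / (u + om), s * Pd[1])
  rhs[2] <- 0
  # E2 expanded: J - om1*d_N + q*(v_0 + om1*d_N) = 0
  q <- rf / (u + rf)
  M[3, ] <- c(1, 0, -om1 + q * om1)
  rhs[3] <- -q * v[1]
  x <- solve(M, rhs)
  J <- x[1]; cN <- x[2]; dN <- x[3]

  cj <- Pc * cN + Qc * J
  dm <- Pd * dN + Qd * J
  d0 <- dm[1]
  a <- v * cj / u
  a[1] <- (v[1] * cj[1] + om1 * dN) / (u + rf)
  a[N + 1] <- (v[N + 1] * cj[N + 1] + om * d0) / (u + om)
  c(a, cj, dm)  # node order: P1 block, P3 block, P2 block
}

#' Approximate time-independent solution for k1 >= 0
#'
#' For nonzero `k1` the stationary state is constructed under the ansatz that
#' the KaiA binding/unbinding links are equilibrated,
#' `k_Af * A_f * P1(phi) = k_Ab0 * alpha^(phi - pi) * P3(phi)` for
#' `phi <= phi0`, and that occupancies above `phi0` vanish
#' (`P1 = P3 = 0` there, truncation index `j0 = ceiling(N * phi0 / pi)`).
#' Summing the paired P1/P3 balances eliminates the vertical fluxes exactly
#' and leaves a reduced linear network on `(P3(0..j0), P1(0), P1(j0),
#' P2(N..2N))` whose kernel is the profile; the free-KaiA level (hence
#' `P3(0)`) is again fixed by a bracketed 1-D self-consistency root. At
#' `k1 = 0`, `eps_seq = 0`, `phi0 = pi` the reduction is exact and the result
#' coincides with [fixed_point_exact()].
#'
#' @param params A [kai_params()] object (`k1 >= 0`).
#' @param space Optional prebuilt `kai_space`.
#' @return A `kai_fixed_point` with `method = "approximate"`.
#' @export
fixed_point_approx <- function(params, space = build_state_space(params)) {
  af <- solve_af_consistency(params, function(a) approx_profile(params, a))
  assemble_fixed_point(params, space, af$p_raw, method = "approximate", A_f = af$A_f)
}

# Kernel of the reduced (ansatz) network at a frozen free-KaiA level.
#' @keywords internal
approx_profile <- function(params, A_f) {
  N <- params$N
  j0 <- min(N, ceiling(N * params$phi0 / pi))
  u <- params$k_Af * A_f
  phi <- (0:N) * pi / N
  v <- params$k_Ab0 * params$alpha^(phi - pi)
  w <- v / u
  lr <- ladder_rates(params)
  k1 <- lr$k1; gk1 <- params$gamma * k1
  f3 <- lr$k3; b3 <- params$gamma1 * f3
  f2 <- lr$k2; b2 <- params$gamma2 * f2
  om <- params$omega; om1 <- params$omega1
  rf <- if (om1 > 0) params$reverse_floor else 0
  me <- N - j0  # P2 entry index (m = k - N) of the switch at j0

  # variables: c_0..c_j0 | a_0 | a_j0 | d_0..d_N
  nc <- j0 + 1
  ia0 <- nc + 1
  iaj <- nc + 2
  idm <- function(m) nc + 2 + m + 1
  nv <- nc + 2 + (N + 1)
  A <- matrix(0, nv, nv)
  # columns giving a_i as a function of the variables (interior: w_i * c_i)
  acol <- function(i) {
    z <- numeric(nv)
    if (i == 0) z[ia0] <- 1
    else if (i == j0) z[iaj] <- 1
    else z[i + 1] <- w[i + 1]
    z
  }
  ccol <- function(i) { z <- numeric(nv); z[i + 1] <- 1; z }
  row <- 0L
  addrow <- function(vec) { row <<- row + 1L; A[row, ] <<- vec }

  # paired P1(j)+P3(j) balances, interior j
  if (j0 >= 2) {
    for (j in 1:(j0 - 1)) {
      r <- gk1 * acol(j - 1) + k1 * acol(j + 1) - (k1 + gk1) * acol(j) +
        f3 * ccol(j - 1) + b3 * ccol(j + 1) - (f3 + b3) * ccol(j)
      addrow(r)
    }
  }
  # a_0: dephosphorylation inflow, vertical, reset inflow
  r <- v[1] * ccol(0) - (gk1 + u + rf) * acol(0)
  if (j0 >= 1) r <- r + k1 * acol(1)
  z <- numeric(nv); z[idm(N)] <- om1; r <- r + z
  addrow(r)
  # c_0
  addrow(b3 * ccol(1) + u * acol(0) - (f3 + v[1]) * ccol(0))
  # a_j0: switch to P2 entry
  r <- gk1 * acol(j0 - 1) + v[j0 + 1] * ccol(j0) - (k1 + u + om) * acol(j0)
  z <- numeric(nv); z[idm(me)] <- om; r <- r + z
  addrow(r)
  # c_j0
  addrow(f3 * ccol(j0 - 1) + u * acol(j0) - (b3 + v[j0 + 1]) * ccol(j0))
  # P2 chain
  for (m in 0:N) {
    z <- numeric(nv)
    if (m >= 1) { z[idm(m - 1)] <- z[idm(m - 1)] + f2; z[idm(m)] <- z[idm(m)] - b2 }
    if (m <= N - 1) { z[idm(m + 1)] <- z[idm(m + 1)] + b2; z[idm(m)] <- z[idm(m)] - f2 }
    if (m == me) { z <- z + om * acol(j0); z[idm(me)] <- z[idm(me)] - om }
    if (m == N && om1 > 0) { z[idm(N)] <- z[idm(N)] - om1; z <- z + rf * acol(0) }
    addrow(z)
  }
  stopifnot(row == nv)

  dec <- svd(A)
  y <- dec$v[, nv]
  if (sum(y) < 0) y <- -y

  cj <- c(y[1:nc], rep(0, N - j0))
  a <- w * cj
  a[1] <- y[ia0]
  a[j0 + 1] <- y[iaj]
  if (j0 < N) a[(j0 + 2):(N + 1)] <- 0
  dm <- y[idm(0):idm(N)]
  p <- c(a, cj, dm)
  p[p < 0 & p > -1e-10 * max(p)] <- 0
  p
}

# Solve the free-KaiA self-consistency A_f = max(0, A_T - S3 - eps*S2) for a
# profile builder returning unnormalized occupancies in node order.
#' @keywords internal
solve_af_consistency <- function(params, builder) {
  N <- params$N
  i3 <- (N + 2):(2 * N + 2)
  i2 <- (2 * N + 3):(3 * N + 3)
  h <- function(af) {
    p <- builder(af)
    p <- p / sum(p)
    af - max(0, params$A_T - sum(p[i3]) - params$eps_seq * sum(p[i2]))
  }
  hi <- params$A_T
  lo <- 1e-9 * params$A_T
  flo <- h(lo)
  fhi <- h(hi)
  if (flo > 0 || fhi < 0) {
    stop("free-KaiA self-consistency root not bracketed on (0, A_T]")
  }
  root <- stats::uniroot(h, c(lo, hi), tol = 1e-14 * max(1, params$A_T))$root
  list(A_f = root, p_raw = builder(root))
}

#' @keywords internal
assemble_fixed_point <- function(params, space, p_raw, method, A_f) {
  p <- p_raw / sum(p_raw)
  p[p < 0 & p > -1e-12] <- 0
  W <- rate_matrix(params, p = p, space = space)
  res <- max(abs(W %*% p))
  mr <- max(abs(W[row(W) != col(W)]))
  structure(list(
    p = p, residual = res, max_rate = mr, method = method,
    A_f = free_kaia(params, p, space), b = p[space$idx$P3[1]]
  ), class = "kai_fixed_point")
}

#' General numeric fixed point of the nonlinear master equation
#'
#' Damped Newton iteration on `W(p) p = 0` with the conservation constraint
#' `sum(p) = 1` replacing one (redundant) balance row. The Jacobian is the
#' analytic linearization `W(p) + C(p)`, where `C` is the rank-one free-KaiA
#' feedback term. The default initial guess is the exact or approximate
#' construction when applicable, else uniform. If Newton stalls, falls back
#' to long-time integration and reports a fixed point only when the dynamics
#' actually converge to one (an oscillatory trajectory raises
#' "no stationary convergence").
#'
#' @param params A [kai_params()] object.
#' @param guess Optional initial probability vector.
#' @param space Optional prebuilt `kai_space`.
#' @param tol_factor Residual target as a multiple of the largest rate
#'   (default 1e-10).
#' @return A `kai_fixed_point` with `method = "numeric"`.
#' @export
fixed_point_numeric <- function(params, guess = NULL,
                                space = build_state_space(params),
                                tol_factor = 1e-10) {
  n <- space$n
  if (is.null(guess)) {
    g <- if (params$omega > 0 && params$omega1 > 0) {
      # closed-form / ansatz constructions need the full cycle present
      try(suppressWarnings(
        if (params$k1 == 0 && params$eps_seq == 0 && params$phi0 >= pi - 1e-12) {
          fixed_point_exact(params, space = space)
        } else {
          fixed_point_approx(params, space = space)
        }
      ), silent = TRUE)
    } else {
      NULL
    }
    guess <- if (is.null(g) || inherits(g, "try-error")) rep(1 / n, n) else g$p
  }
  p <- guess / sum(guess)
  Fres <- function(p) as.vector(rate_matrix(params, p = p, space = space) %*% p)
  fv <- Fres(p)
  mr <- function(p) {
    W <- rate_matrix(params, p = p, space = space)
    max(abs(W[row(W) != col(W)]))
  }
  tol <- tol_factor * mr(p)
  ok <- FALSE
  for (it in 1:100) {
    if (max(abs(fv)) < tol) { ok <- TRUE; break }
    M <- linearized_operator(params, list(p = p), space = space, check = FALSE)
    M[n, ] <- 1
    b <- -fv
    b[n] <- 1 - sum(p)
    step <- try(solve(M, b), silent = TRUE)
    if (inherits(step, "try-error")) break
    lam <- 1
    improved <- FALSE
    for (bt in 1:30) {
      p_new <- p + lam * step
      f_new <- Fres(p_new)
      if (max(abs(f_new)) < max(abs(fv)) * (1 - 1e-4 * lam) ||
          max(abs(f_new)) < tol) {
        p <- p_new; fv <- f_new; improved <- TRUE; break
      }
      lam <- lam / 2
    }
    if (!improved) break
  }
  if (!ok && max(abs(fv)) < tol) ok <- TRUE
  if (!ok) {
    # fall back to relaxation by integration
    p0 <- guess / sum(guess)
    p0[p0 < 0] <- 0
    p0 <- p0 / sum(p0)
    traj <- integrate_clock(params, p0 = p0, t_end = 2000, n_out = 500, space = space)
    pT <- traj$states[nrow(traj$states), ]
    if (max(abs(Fres(pT))) > 1e-7 * mr(pT)) {
      stop("no stationary convergence: dynamics appear oscillatory from this guess")
    }
    p <- pT
    # polish by Newton
    return(fixed_point_numeric(params, guess = p, space = space,
                               tol_factor = tol_factor))
  }
  p[p < 0 & p > -1e-9] <- 0
  p <- p / sum(p)
  fp <- assemble_fixed_point(params, space, p, method = "numeric",
                             A_f = free_kaia(params, p, space))
  fp
}

#' Export a fixed point as CSV
#'
#' Writes `(rung, index, phase, occupancy)` rows in the plotting layout used
#' for steady-state profile figures.
#'
#' @param fp A `kai_fixed_point`.
#' @param space The matching `kai_space`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fixed_point <- function(fp, space, path) {
  out <- data.frame(
    rung = space$nodes$rung, index = space$nodes$j,
    phase = space$nodes$phase, occupancy = fp$p
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
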