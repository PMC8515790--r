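#' KaiB-free steady-state dose-response curve
#'
#' Removes KaiB from the model (`omega = omega1 = 0`, so the P2 rung is
#' disconnected and the dynamics are confined to the active P1/P3 ladders)
#' and computes the stationary phosphorylation level as a function of total
#' KaiA. Without the P2 return path the system always relaxes to a steady
#' state; with `k1 > 0` the antagonism between KaiA-assisted phosphorylation
#' (P3 rung) and autodephosphorylation (P1 rung) makes the response
#' ultrasensitive: phosphorylation switches over a narrow band of `A_T`.
#'
#' The steady state is found by damped Newton on the P1/P3 subnetwork with
#' the free-KaiA feedback in the Jacobian, continued along the `A_T` grid
#' (each solution seeds the next); failed points fall back to long-time
#' integration.
#'
#' @param params A [kai_params()] object; `omega`/`omega1` are forced to 0.
#' @param a_grid Strictly increasing positive total-KaiA values.
#' @return A `kai_response`: data frame `(A_T, phos)` with attributes
#'   `context` (K_d0, alpha, k1) and `monotone` flag.
#' @export
kaib_free_response <- function(params, a_grid) {
  if (any(diff(a_grid) <= 0) || any(a_grid < 0)) {
    stop("a_grid must be nonnegative and strictly increasing")
  }
  base <- kai_set(params, omega = 0, omega1 = 0)
  space <- build_state_space(base)
  active <- c(space$idx$P1, space$idx$P3)
  n_act <- length(active)
  # start fully dephosphorylated and KaiA-free
  q <- numeric(n_act)
  q[1] <- 1
  phos <- numeric(length(a_grid))
  for (i in seq_along(a_grid)) {
    pars <- kai_set(base, A_T = a_grid[i])
    q <- steady_active(pars, space, active, q)
    p_full <- numeric(space$n)
    p_full[active] <- q
    phos[i] <- phosphorylation_level(p_full, space)
  }
  structure(
    data.frame(A_T = a_grid, phos = phos),
    context = list(K_d0 = params$K_d0, alpha = params$alpha, k1 = params$k1),
    monotone = !is.unsorted(phos),
    class = c("kai_response", "data.frame")
  )
}

# Newton solve of W p = 0 restricted to the active (P1/P3) nodes, with
# integration fallback.
#' @keywords internal
steady_active <- function(params, space, active, guess) {
  n_act <- length(active)
  embed <- function(q) {
    p <- numeric(space$n)
    p[active] <- q
    p
  }
  Fres <- function(q) {
    p <- embed(q)
    as.vector((rate_matrix(params, p = p, space = space) %*% p))[active]
  }
  q <- guess / sum(guess)
  fv <- Fres(q)
  W0 <- rate_matrix(params, p = embed(q), space = space)
  tol <- 1e-11 * max(abs(W0[row(W0) != col(W0)]))
  ok <- FALSE
  for (it in 1:80) {
    if (max(abs(fv)) < tol) { ok <- TRUE; break }
    M <- linearized_operator(params, list(p = embed(q)), space = space,
                             check = FALSE)[active, active]
    M[n_act, ] <- 1
    b <- -fv
    b[n_act] <- 1 - sum(q)
    step <- try(solve(M, b), silent = TRUE)
    if (inherits(step, "try-error")) break
    lam <- 1
    improved <- FALSE
    for (bt in 1:30) {
      qn <- q + lam * step
      fn <- Fres(qn)
      if (max(abs(fn)) < max(abs(fv)) * (1 - 1e-4 * lam) || max(abs(fn)) < tol) {
        q <- qn; fv <- fn; improved <- TRUE; break
      }
      lam <- lam / 2
    }
    if (!improved) break
  }
  if (!ok && max(abs(fv)) >= tol) {
    p0 <- pmax(embed(q), 0)
    p0[active][1] <- p0[active][1] + max(0, 1 - sum(p0))
    p0 <- p0 / sum(p0)
    traj <- integrate_clock(params, p0 = p0, t_end = 3000, n_out = 400,
                            space = space)
    q <- traj$states[nrow(traj$states), active]
    fv <- Fres(q)
    if (max(abs(fv)) > 1e-6 * max(abs(W0))) {
      stop("KaiB-free subnetwork failed to converge at A_T = ", params$A_T)
    }
  }
  q[q < 0 & q > -1e-11] <- 0
  q / sum(q)
}

#' Effective Hill coefficient of a response curve
#'
#' Default estimator (`method = "ec"`): global sensitivity
#' `n_eff = log(81) / log(EC90 / EC10)`, where EC10 and EC90 are the doses at
#' 10% and 90% of the curve's own dynamic range (baseline to plateau),
#' obtained by monotone interpolation on the log-dose axis. For an ideal Hill
#' curve `x^n / (K^n + x^n)` this recovers `n` exactly. The alternative
#' estimator (`method = "slope"`) reports the maximum local log-log slope
#' `d log(y) / d log(x)`; the two differ in general because the
#' amplification-based definition is global while the slope is local.
#'
#' @param curve A `kai_response` or data frame `(A_T, phos)`.
#' @param method `"ec"` (default) or `"slope"`.
#' @return The dimensionless effective Hill coefficient.
#' @export
hill_coefficient <- function(curve, method = c("ec", "slope")) {
  method <- match.arg(method)
  x <- curve$A_T
  y <- curve$phos
  if (any(x <= 0)) {
    keep <- x > 0
    x <- x[keep]; y <- y[keep]
  }
  n <- length(y)
  if (n < 5) stop("response curve too short")
  rng <- max(y) - min(y)
  if (rng <= 0) stop("flat response curve")
  if (y[n] - y[n - 1] > 0.02 * rng) {
    stop("no plateau: response has not saturated on the dose grid")
  }
  if (method == "slope") {
    ly <- log(y - min(y) + 1e-12 * rng)
    lx <- log(x)
    return(max(diff(ly) / diff(lx)))
  }
  # strictly increasing envelope for inverse interpolation
  yc <- cummax(y)
  keep <- c(TRUE, diff(yc) > 1e-12 * rng)
  yk <- yc[keep]
  lxk <- log(x)[keep]
  target <- min(y) + c(0.1, 0.9) * rng
  if (target[2] > max(yk) || target[1] < min(yk)) {
    stop("dynamic range not covered by the dose grid")
  }
  lec <- stats::approx(yk, lxk, xout = target, ties = "ordered")$y
  log(81) / (lec[2] - lec[1])
}

#' Write a response curve and its Hill summary
#'
#' @param curve A `kai_response`.
#' @param path CSV output path; a JSON summary with the parameter context and
#'   both Hill estimators is written alongside as `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_response <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  summ <- c(attr(curve, "context"),
            list(hill_ec = tryCatch(hill_coefficient(curve), error = function(e) NA),
                 hill_slope = tryCatch(hill_coefficient(curve, "slope"),
                                       error = function(e) NA)))
  jsonlite::write_json(summ, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
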