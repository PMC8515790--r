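#' Linearization of the master equation around a fixed point
#'
#' The Jacobian of `F(p) = W(p) p` is `M = W(p*) + C`, where the feedback
#' term `C = dW/dA_f * (dA_f/dp) * p*` collects the sensitivity of the
#' KaiA-binding edges to the occupancies that deplete free KaiA. `C` is rank
#' one: `dA_f/dp` is `-1` on P3 nodes and `-eps_seq` on P2 nodes (zero when
#' `A_f` is clamped at 0), and `dW/dA_f` acts only on the `P1(j) -> P3(j)`
#' edges with coefficient `k_Af`. Columns of `M` sum to zero, so
#' perturbations conserve total probability.
#'
#' @param params A [kai_params()] object.
#' @param fp A `kai_fixed_point` (or any list with element `p`).
#' @param space Optional prebuilt `kai_space`.
#' @param check Verify that `fp` is actually stationary (residual below
#'   `1e-8 * max_rate`); disable when linearizing off the fixed point.
#' @return Dense matrix `M`.
#' @export
linearized_operator <- function(params, fp, space = build_state_space(params),
                                check = TRUE) {
  p <- fp$p
  W <- rate_matrix(params, p = p, space = space)
  if (check) {
    mr <- max(abs(W[row(W) != col(W)]))
    if (max(abs(W %*% p)) > 1e-8 * mr) {
      stop("fixed-point residual too large for linearization")
    }
  }
  af_raw <- params$A_T - sum(p[space$idx$P3]) - params$eps_seq * sum(p[space$idx$P2])
  floor_af <- if (params$k_Af > 0) params$reverse_floor / params$k_Af else 0
  if (af_raw <= floor_af) return(W)  # clamped or floored: no feedback
  g <- numeric(space$n)
  g[space$idx$P3] <- -1
  g[space$idx$P2] <- -params$eps_seq
  # d(flux)/dA_f applied to the occupancies is the B-part of the generator
  bvec <- as.vector(space$B %*% p)
  W + outer(bvec, g)
}

#' Linear stability of the stationary state
#'
#' Computes a fixed point (exact construction when `k1 = 0`, `eps_seq = 0`
#' and `phi0 = pi`; otherwise the approximate construction, always polished
#' by Newton), linearizes around it and reports the spectrum. The neutral
#' conservation mode (eigenvalue 0, eigenvector of nonzero total mass) is
#' excluded; the leading eigenvalue is the remaining one of largest real
#' part. The stationary state is unstable towards oscillations when the
#' leading real part exceeds 1e-9 with a nonzero imaginary part, and the
#' predicted limit-cycle period near onset is `2*pi / |Im(leading)|`. A real
#' positive leading eigenvalue is reported as a non-oscillatory instability
#' (`oscillating = FALSE`, `instability = "real"`).
#'
#' @param params A [kai_params()] object.
#' @param fp Optional precomputed fixed point (will be Newton-polished).
#' @param space Optional prebuilt `kai_space`.
#' @return A `kai_stability` list: `fixed_point`, `eigenvalues` (sorted by
#'   decreasing real part, conservation mode removed), `leading`,
#'   `oscillating`, `instability` (`"none"`, `"oscillatory"`, `"real"`),
#'   `predicted_period`, `max_rate`.
#' @export
stability_report <- function(params, fp = NULL, space = build_state_space(params)) {
  fp <- if (is.null(fp)) {
    fixed_point_numeric(params, space = space)
  } else {
    fixed_point_numeric(params, guess = fp$p, space = space)
  }
  M <- linearized_operator(params, fp, space = space)
  ev <- eigen(M, only.values = TRUE)$values
  # conservation mode: eigenvalue of smallest modulus; must be numerically 0
  i0 <- which.min(Mod(ev))
  if (Mod(ev[i0]) > 1e-8 * fp$max_rate) {
    warning("conservation eigenvalue deviates from 0 beyond tolerance")
  }
  ev_red <- ev[-i0]
  ev_red <- ev_red[order(-Re(ev_red))]
  lead <- ev_red[1]
  osc <- Re(lead) > 1e-9 && abs(Im(lead)) > 1e-9
  instab <- if (Re(lead) <= 1e-9) "none" else if (osc) "oscillatory" else "real"
  structure(list(
    fixed_point = fp,
    eigenvalues = ev_red,
    leading = lead,
    oscillating = osc,
    instability = instab,
    predicted_period = if (abs(Im(lead)) > 1e-9) 2 * pi / abs(Im(lead)) else NA_real_,
    max_rate = fp$max_rate
  ), class = "kai_stability")
}

#' Critical parameter value for the onset of oscillations
#'
#' Bisection on the sign of the leading real part of the linearized spectrum
#' between `lo` and `hi`. Assigning `K_d0` (or `k_Af`, `k_Ab0`) through
#' [kai_set()] keeps the binding bookkeeping consistent during the scan.
#'
#' @param params Base [kai_params()] object.
#' @param which Parameter name to vary (e.g. `"alpha"`, `"k1"`, `"K_d0"`).
#' @param lo,hi Bracket; the oscillating flag must differ between them.
#' @param tol Relative bracket width at which to stop (default 1e-3).
#' @return The critical value (bracket midpoint at convergence).
#' @export
critical_parameter <- function(params, which, lo, hi, tol = 1e-3) {
  lead_re <- function(x) {
    p <- do.call(kai_set, c(list(params), stats::setNames(list(x), which)))
    Re(stability_report(p)$leading)
  }
  flo <- lead_re(lo)
  fhi <- lead_re(hi)
  if (sign(flo) == sign(fhi)) {
    stop("no sign change: oscillating flag identical at both bracket ends")
  }
  while (hi - lo > tol * max(abs(lo), abs(hi))) {
    mid <- 0.5 * (lo + hi)
    fm <- lead_re(mid)
    if (sign(fm) == sign(flo)) {
      lo <- mid; flo <- fm
    } else {
      hi <- mid; fhi <- fm
    }
  }
  0.5 * (lo + hi)
}

#' Gershgorin disc diagnostics of a matrix
#'
#' Disc centers are the diagonal entries and radii the off-diagonal absolute
#' column sums; all eigenvalues lie in the union of the discs. For a rate
#' matrix the centers are negative with radius equal to `|center|`, so discs
#' touch the origin; state-dependent feedback and growing off-diagonal rates
#' (larger `k1`) push a finite disc area into the positive half-plane, which
#' is the coarse spectral argument for how ultrasensitivity promotes
#' instability.
#'
#' @param M Square matrix.
#' @return A `kai_gershgorin` list: `centers`, `radii`, `max_protrusion`
#'   (`max(center + radius)`), and `eigs_inside` (all eigenvalues verified to
#'   lie in the disc union).
#' @export
gershgorin_discs <- function(M) {
  if (!is.matrix(M) || nrow(M) != ncol(M)) stop("M must be a square matrix")
  centers <- diag(M)
  radii <- colSums(abs(M)) - abs(centers)
  ev <- eigen(M, only.values = TRUE)$values
  tol <- 1e-9 * max(1, max(abs(M)))
  inside <- vapply(ev, function(l) {
    any(Mod(l - centers) <= radii + tol)
  }, logical(1))
  structure(list(
    centers = centers, radii = radii,
    max_protrusion = max(centers + radii),
    eigs_inside = all(inside)
  ), class = "kai_gershgorin")
}
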