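#' Model parameters for the KaiABC phase-ring model
#'
#' Constructs and validates the full parameter set of the three-rung phase-ring
#' model. The ring is discretized into `N` intervals on the half-ring
#' `[0, pi]`: the active rungs P1 (KaiA-free) and P3 (KaiA-bound) live on
#' phases `phi_j = j*pi/N`, `j = 0..N`, and the inactive, KaiA-sequestering
#' rung P2 covers the dephosphorylation arc, with `P2(2N - j)` at phase
#' `2*pi - phi_j`.
#'
#' Rate-law summary (all first order unless noted):
#' * P3 rung: phosphorylation `P3(j) -> P3(j+1)` at `k3_fwd`, reverse
#'   `gamma1 * k3_fwd` (hydrolysis-driven, `gamma1 <= 1`).
#' * P1 rung: dephosphorylation `P1(j) -> P1(j-1)` at `k1` (the
#'   ultrasensitivity knob), reverse `gamma * k1`; `k1 = 0` switches the rung
#'   off entirely.
#' * P2 rung: dephosphorylation `P2(k) -> P2(k+1)` at `k2_fwd`, reverse
#'   `gamma2 * k2_fwd`.
#' * KaiA binding `P1(j) -> P3(j)` at `k_Af * A_f` (second order in the free
#'   KaiA concentration `A_f`); unbinding `P3(j) -> P1(j)` at
#'   `k_Ab0 * alpha^(phi_j - pi)`, so `alpha > 1` implements differential
#'   affinity (weak binding at high phosphorylation).
#' * Conformational switch `P1(j) <-> P2(2N - j)` at `omega`, active for
#'   `phi_j >= phi0`; ring reset `P2(2N) -> P1(0)` at `omega1` (reverse rate
#'   `reverse_floor`, see below).
#'
#' `K_d0 = k_Ab0 / k_Af` is the dissociation constant at full phosphorylation
#' and is the model's proxy for nutrient conditions (larger `K_d0` corresponds
#' to lower %ATP). It is stored redundantly with `k_Ab0` and kept consistent.
#'
#' @param N Number of grid intervals on the half-ring (integer, `>= 2`).
#' @param alpha Differential-affinity base, `>= 1`.
#' @param K_d0 Unbinding/binding ratio `k_Ab0 / k_Af`; ATP proxy.
#' @param k_Af KaiA binding rate coefficient (per concentration per time).
#' @param k_Ab0 Unbinding base rate; default `K_d0 * k_Af`. If both `K_d0` and
#'   `k_Ab0` are given they must agree to relative 1e-12.
#' @param k1 P1-rung dephosphorylation rate; tunes ultrasensitivity.
#' @param k3_fwd P3-rung forward phosphorylation rate.
#' @param k2_fwd P2-rung forward dephosphorylation rate.
#' @param gamma,gamma1,gamma2 Backward/forward ratios in `(0, 1]` of the
#'   hydrolysis-driven P1, P3, P2 rungs.
#' @param omega P1/P2 conformational switch rate (both directions).
#' @param omega1 P2(2pi) -> P1(0) reset rate.
#' @param eps_seq KaiA sequestration stoichiometry of the P2 states (`>= 0`);
#'   free KaiA is depleted by `eps_seq * sum(P2)`.
#' @param A_T Total KaiA concentration (KaiC total is 1).
#' @param phi0 Phase in `(0, pi]` at which P1 -> P2 switching begins.
#' @param reverse_floor Minimal reverse rate given to nominally irreversible
#'   edges (only the reset edge needs it); keeps every flux ratio finite for
#'   entropy-production accounting.
#'
#' @return An object of class `kai_params` (a validated named list).
#' @seealso [kai_preset()], [build_state_space()]
#' @examples
#' p <- kai_params(N = 10, alpha = 5)
#' p$K_d0 * p$k_Af == p$k_Ab0
#' @export
kai_params <- function(N = 20,
                       alpha = 30,
                       K_d0 = 5,
                       k_Af = 250,
                       k_Ab0 = NULL,
                       k1 = 0,
                       k3_fwd = 4,
                       k2_fwd = 2.5,
                       gamma = 0.8,
                       gamma1 = 0.1,
                       gamma2 = 0.1,
                       omega = 16,
                       omega1 = 16,
                       eps_seq = 0,
                       A_T = 0.4,
                       phi0 = pi,
                       reverse_floor = 1e-8) {
  if (is.null(k_Ab0)) {
    k_Ab0 <- K_d0 * k_Af
  } else if (missing(K_d0)) {
    K_d0 <- k_Ab0 / k_Af
  }
  p <- structure(list(
    N = as.integer(N), alpha = alpha, K_d0 = K_d0, k_Af = k_Af, k_Ab0 = k_Ab0,
    k1 = k1, k3_fwd = k3_fwd, k2_fwd = k2_fwd,
    gamma = gamma, gamma1 = gamma1, gamma2 = gamma2,
    omega = omega, omega1 = omega1, eps_seq = eps_seq, A_T = A_T,
    phi0 = phi0, reverse_floor = reverse_floor
  ), class = "kai_params")
  validate_params(p)
}

#' Validate a `kai_params` object
#'
#' Checks positivity/range constraints on every field and the redundant
#' `K_d0 * k_Af == k_Ab0` bookkeeping. Called by [kai_params()]; exported so
#' configurations loaded from files go through the same gate.
#'
#' @param p A `kai_params` object (or plain named list with the same fields).
#' @return `p`, invisibly classed as `kai_params`, if valid; otherwise an error
#'   naming the offending field and its admissible range.
#' @export
validate_params <- function(p) {
  fail <- function(field, msg) {
    stop(sprintf("invalid parameter `%s`: %s", field, msg), call. = FALSE)
  }
  num1 <- function(field) {
    v <- p[[field]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      fail(field, "must be a single finite number")
    }
    v
  }
  if (num1("N") < 2 || p$N != as.integer(p$N)) fail("N", "must be an integer >= 2")
  p$N <- as.integer(p$N)
  if (num1("alpha") < 1) fail("alpha", "must be >= 1")
  for (f in c("k_Af", "k_Ab0", "K_d0", "k1", "k3_fwd", "k2_fwd",
              "omega", "omega1", "eps_seq", "A_T", "reverse_floor")) {
    if (num1(f) < 0) fail(f, "must be >= 0")
  }
  for (f in c("gamma", "gamma1", "gamma2")) {
    v <- num1(f)
    if (v <= 0 || v > 1) fail(f, "must lie in (0, 1]")
  }
  v <- num1("phi0")
  if (v <= 0 || v > pi) fail("phi0", "must lie in (0, pi]")
  ref <- max(abs(p$K_d0 * p$k_Af), abs(p$k_Ab0), 1e-300)
  if (abs(p$K_d0 * p$k_Af - p$k_Ab0) > 1e-12 * ref) {
    fail("K_d0", "inconsistent with k_Ab0: require K_d0 * k_Af == k_Ab0 (rel. 1e-12)")
  }
  class(p) <- "kai_params"
  invisible(p)
}

#' Update parameters while preserving internal consistency
#'
#' Sets named fields of a `kai_params` object and restores the
#' `K_d0 * k_Af == k_Ab0` invariant: assigning `K_d0` (or `k_Af`) recomputes
#' `k_Ab0`; assigning `k_Ab0` recomputes `K_d0`. Used by parameter sweeps and
#' [critical_parameter()].
#'
#' @param p A `kai_params` object.
#' @param ... Named fields to replace, e.g. `alpha = 12`, `K_d0 = 8`.
#' @return The updated, re-validated `kai_params` object.
#' @export
kai_set <- function(p, ...) {
  upd <- list(...)
  if (length(upd) == 0L) return(p)
  nm <- names(upd)
  if (is.null(nm) || any(nm == "")) stop("all arguments to kai_set() must be named")
  unknown <- setdiff(nm, names(unclass(p)))
  if (length(unknown)) {
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "))
  }
  for (f in nm) p[[f]] <- upd[[f]]
  both <- c("K_d0", "k_Ab0") %in% nm
  if ("k_Ab0" %in% nm && !("K_d0" %in% nm)) {
    p$K_d0 <- p$k_Ab0 / p$k_Af
  } else if (!("k_Ab0" %in% nm) && any(c("K_d0", "k_Af") %in% nm)) {
    p$k_Ab0 <- p$K_d0 * p$k_Af
  } else if (all(both) && !("k_Af" %in% nm) && p$K_d0 > 0) {
    p$k_Af <- p$k_Ab0 / p$K_d0
  }
  v <- validate_params(p)
  v
}

#' Built-in parameter presets
#'
#' Three presets define the study conditions used throughout the package.
#' `"default"` is a mid-sized testing configuration. `"affinity"` is the
#' differential-affinity study condition: `k1 = 0`, no sequestration, switch
#' at full phosphorylation, so the exact time-independent solution
#' ([fixed_point_exact()]) applies and the oscillation onset is driven by
#' `alpha`. `"ultrasensitivity"` is the ultrasensitivity study condition:
#' KaiA sequestration by the P2 states is on (`eps_seq > 0`) and the onset is
#' driven by `k1` at fixed `alpha = 10`. The preset numbers are this package's
#' own calibration of the model (see the methods vignette); they emulate a
#' circadian regime with periods of a few tens of time units and onset at
#' moderate parameter values.
#'
#' @param name One of `"default"`, `"affinity"`, `"ultrasensitivity"`.
#' @param ... Field overrides passed to [kai_set()].
#' @return A `kai_params` object.
#' @examples
#' kai_preset("affinity", alpha = 25)
#' @export
kai_preset <- function(name = c("default", "affinity", "ultrasensitivity"), ...) {
  name <- match.arg(name)
  p <- switch(name,
    default = kai_params(),
    affinity = kai_params(
      N = 20, alpha = 30, K_d0 = 5, k_Af = 250, k1 = 0,
      k3_fwd = 4, k2_fwd = 2.5, gamma = 0.8, gamma1 = 0.1, gamma2 = 0.1,
      omega = 16, omega1 = 16, eps_seq = 0, A_T = 0.4, phi0 = pi
    ),
    ultrasensitivity = kai_params(
      N = 20, alpha = 10, K_d0 = 8, k_Af = 150, k1 = 2,
      k3_fwd = 4, k2_fwd = 2.5, gamma = 0.8, gamma1 = 0.25, gamma2 = 0.1,
      omega = 3, omega1 = 30, eps_seq = 6, A_T = 0.8, phi0 = 0.8 * pi
    )
  )
  kai_set(p, ...)
}

#' Detailed-balance (equilibrium) parameterization
#'
#' A parameter set whose network satisfies detailed balance at the uniform
#' distribution: all hydrolysis ratios are 1, `alpha = 1`, the switch is
#' symmetric, the reset edge is removed (`omega1 = 0`), and `A_T` is chosen so
#' that at the uniform state `k_Af * A_f` equals the unbinding rate `k_Ab0`.
#' Used as the zero-entropy-production and stable-spectrum reference case.
#'
#' @param N Grid size.
#' @param rate Common edge rate.
#' @return A `kai_params` object.
#' @export
kai_equilibrium_params <- function(N = 10, rate = 1) {
  # at uniform p, sum(P3) = 1/3 of the mass
  kai_params(
    N = N, alpha = 1, k_Af = 1, K_d0 = rate, k_Ab0 = rate,
    k1 = rate, k3_fwd = rate, k2_fwd = rate,
    gamma = 1, gamma1 = 1, gamma2 = 1,
    omega = rate, omega1 = 0, eps_seq = 0,
    A_T = rate + 1 / 3, phi0 = pi / 2, reverse_floor = 0
  )
}
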