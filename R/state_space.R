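#' Enumerate the nodes and reversible edges of the phase-ring network
#'
#' Builds the discrete state space of the model: `P1(j)` and `P3(j)` for
#' `j = 0..N` at phases `phi_j = j*pi/N`, and `P2(k)` for `k = N..2N` at
#' phases `k*pi/N` on the dephosphorylation arc. Each physical connection is
#' stored once as a reversible edge with a forward and a backward rate; the
#' KaiA-binding edges carry the flag `kaia = TRUE` and their forward rate is
#' `k_Af * A_f`, evaluated per state at matrix-build time.
#'
#' Rung hop rates (`k1`, `k3_fwd`, `k2_fwd`) are specified on the reference
#' grid `N = 20` and are scaled by `N/20` when the space is built, so the
#' phase-drift velocity along the ring -- and with it the cycle period -- is
#' grid-independent, while per-step hydrolysis ratios stay fixed.
#'
#' Edges present:
#' * `p1_ladder` (`k1 > 0` only): `P1(j) -> P1(j-1)` at `k1`, back `gamma*k1`.
#' * `p3_ladder`: `P3(j) -> P3(j+1)` at `k3_fwd`, back `gamma1*k3_fwd`.
#' * `p2_ladder`: `P2(k) -> P2(k+1)` at `k2_fwd`, back `gamma2*k2_fwd`.
#' * `bind`: `P1(j) -> P3(j)` at `k_Af*A_f`, back `k_Ab0*alpha^(phi_j - pi)`.
#' * `switch` (`omega > 0`, `phi_j >= phi0` only): `P1(j) -> P2(2N-j)` at
#'   `omega`, back `omega`.
#' * `reset` (`omega1 > 0` only): `P2(2N) -> P1(0)` at `omega1`, back
#'   `reverse_floor`.
#'
#' Setting `omega = omega1 = 0` removes the P2 connections entirely (the
#' KaiB-free limit used by [kaib_free_response()]).
#'
#' @param params A [kai_params()] object.
#' @return An object of class `kai_space`: a list with
#'   \describe{
#'     \item{nodes}{data frame `(id, rung, j, phase)`; `j` is the grid index
#'       (`0..N` for P1/P3, `N..2N` for P2).}
#'     \item{edges}{data frame `(from, to, fwd, bwd, kaia, type)`; `fwd` of a
#'       `kaia` edge stores the coefficient `k_Af` (multiply by `A_f`).}
#'     \item{idx}{list of node-id vectors `P1`, `P2`, `P3`.}
#'     \item{n}{number of nodes, `3*(N+1)`.}
#'     \item{phos}{per-node phosphorylation weights `f(phi)` (see
#'       [phosphorylation_level()]).}
#'   }
#' @examples
#' sp <- build_state_space(kai_params(N = 4))
#' sp$n
#' table(sp$edges$type)
#' @export
build_state_space <- function(params) {
  params <- validate_params(params)
  N <- params$N
  if (N < 2) stop("N must be >= 2")
  if (params$phi0 > pi) stop("phi0 must be <= pi")

  j_top <- 0:N
  phase_top <- j_top * pi / N
  k_p2 <- N:(2 * N)
  phase_p2 <- k_p2 * pi / N

  nodes <- data.frame(
    id = seq_len(3 * (N + 1)),
    rung = rep(c("P1", "P3", "P2"), each = N + 1),
    j = c(j_top, j_top, k_p2),
    phase = c(phase_top, phase_top, phase_p2),
    stringsAsFactors = FALSE
  )
  id_P1 <- 1:(N + 1)              # P1(j) -> id j + 1
  id_P3 <- (N + 2):(2 * N + 2)    # P3(j) -> id N + 2 + j
  id_P2 <- (2 * N + 3):(3 * N + 3) # P2(k) -> id 2N + 3 + (k - N)
  p2_id <- function(k) 2 * N + 3 + (k - N)

  e <- list()
  add <- function(from, to, fwd, bwd, kaia, type) {
    e[[length(e) + 1L]] <<- data.frame(
      from = from, to = to, fwd = fwd, bwd = bwd, kaia = kaia, type = type,
      stringsAsFactors = FALSE
    )
  }

  lr <- ladder_rates(params)
  if (params$k1 > 0) {
    # dephosphorylation direction: towards lower phase
    add(id_P1[2:(N + 1)], id_P1[1:N],
        lr$k1, params$gamma * lr$k1, FALSE, "p1_ladder")
  }
  add(id_P3[1:N], id_P3[2:(N + 1)],
      lr$k3, params$gamma1 * lr$k3, FALSE, "p3_ladder")
  add(id_P2[1:N], id_P2[2:(N + 1)],
      lr$k2, params$gamma2 * lr$k2, FALSE, "p2_ladder")
  # KaiA binding/unbinding; fwd column stores the coefficient of A_f
  add(id_P1, id_P3,
      params$k_Af, params$k_Ab0 * params$alpha^(phase_top - pi), TRUE, "bind")
  if (params$omega > 0) {
    j_sw <- j_top[phase_top >= params$phi0 - 1e-12]
    if (length(j_sw)) {
      add(id_P1[j_sw + 1], p2_id(2 * N - j_sw),
          params$omega, params$omega, FALSE, "switch")
    }
  }
  if (params$omega1 > 0) {
    add(p2_id(2 * N), id_P1[1], params$omega1, params$reverse_floor, FALSE, "reset")
  }

  edges <- do.call(rbind, e)
  rownames(edges) <- NULL

  phos <- ifelse(nodes$phase <= pi, nodes$phase / pi, 2 - nodes$phase / pi)

  # split the generator as W(A_f) = W0 + A_f * B: W0 collects all constant
  # rates, B the KaiA-binding structure (both with their diagonal parts), so
  # the state dependence is a single scalar multiplier
  n <- nrow(nodes)
  W0 <- matrix(0, n, n)
  B <- matrix(0, n, n)
  for (k in seq_len(nrow(edges))) {
    s <- edges$from[k]; t <- edges$to[k]
    if (edges$kaia[k]) {
      B[t, s] <- B[t, s] + edges$fwd[k]
      B[s, s] <- B[s, s] - edges$fwd[k]
    } else {
      W0[t, s] <- W0[t, s] + edges$fwd[k]
      W0[s, s] <- W0[s, s] - edges$fwd[k]
    }
    W0[s, t] <- W0[s, t] + edges$bwd[k]
    W0[t, t] <- W0[t, t] - edges$bwd[k]
  }

  structure(list(
    nodes = nodes, edges = edges,
    idx = list(P1 = id_P1, P2 = id_P2, P3 = id_P3),
    n = n, phos = phos, params = params, W0 = W0, B = B
  ), class = "kai_space")
}

#' Free KaiA concentration of a probability state
#'
#' `A_f = max(0, A_T - sum(P3) - eps_seq * sum(P2))`: every P3 state holds one
#' KaiA, and every P2 state sequesters `eps_seq` KaiA. The clamp at 0 encodes
#' full depletion. This is the sole source of nonlinearity in the master
#' equation.
#'
#' @param params A `kai_params` object.
#' @param p Probability vector over the nodes of `space`.
#' @param space The `kai_space` for `params` (rebuilt if omitted).
#' @return The free KaiA concentration (scalar, `>= 0`).
#' @export
free_kaia <- function(params, p, space = build_state_space(params)) {
  max(0, params$A_T - sum(p[space$idx$P3]) - params$eps_seq * sum(p[space$idx$P2]))
}

#' State-dependent rate matrix W(P)
#'
#' Assembles the generator of the master equation at a given probability
#' state: `W[i, j]` is the rate from node `j` to node `i` for `i != j`, and
#' the diagonal is set so every column sums to zero. KaiA-binding edges are
#' evaluated at the state's free KaiA level, which is what makes the equation
#' `dP/dt = W(P) P` nonlinear.
#'
#' @param params A `kai_params` object.
#' @param p Probability vector (used only through its free-KaiA level); pass
#'   `A_f` directly to freeze the linear system at a given concentration.
#' @param space Optional prebuilt `kai_space`.
#' @param A_f Optional free-KaiA override (bypasses `p`).
#' @return Dense square rate matrix with zero column sums.
#' @export
rate_matrix <- function(params, p = NULL, space = build_state_space(params),
                        A_f = NULL) {
  if (is.null(A_f)) {
    if (is.null(p)) stop("either `p` or `A_f` must be supplied")
    A_f <- free_kaia(params, p, space)
  }
  if (A_f < 0) stop("negative rate encountered: A_f < 0")
  space$W0 + effective_af(params, A_f) * space$B
}

# Rung hop rates are specified on the reference grid (N_ref = 20) and scale
# with N so the phase-drift velocity -- and therefore the cycle period -- is
# grid-independent (hop rate * step size = constant); diffusion along the
# ring then shrinks as 1/N, the usual drift-dominated discretization.
#' @keywords internal
ladder_rates <- function(params) {
  s <- params$N / 20
  list(k1 = params$k1 * s, k3 = params$k3_fwd * s, k2 = params$k2_fwd * s)
}

# KaiA depletion can clamp A_f to 0, which would make the binding edges
# one-sidedly irreversible; the reverse_floor keeps every existing edge
# bidirectional so fluxes and entropy production stay well defined.
#' @keywords internal
effective_af <- function(params, A_f) {
  if (params$k_Af > 0) max(A_f, params$reverse_floor / params$k_Af) else A_f
}

#' Mean phosphorylation level of a state
#'
#' The per-node phosphorylation function rises linearly from 0 at `phi = 0`
#' to 1 at `phi = pi` and falls symmetrically back to 0 at `phi = 2*pi`:
#' `f(phi) = phi/pi` for `phi <= pi`, `2 - phi/pi` otherwise. The observable
#' is `sum_i f(phi_i) p_i`, the model's analogue of the experimentally
#' tracked fraction of phosphorylated KaiC.
#'
#' @param p Probability vector.
#' @param space A `kai_space`.
#' @return Scalar in `[0, 1]`.
#' @export
phosphorylation_level <- function(p, space) {
  sum(space$phos * p)
}

#' Export the edge list as a TSV file
#'
#' Writes `(source, target, forward_rate, backward_rate)` with node labels
#' `rung(j)`, evaluating KaiA-dependent forward rates at a reference free-KaiA
#' level, for external inspection of the network.
#'
#' @param space A `kai_space`.
#' @param path Output file path.
#' @param A_f Free KaiA level at which to report binding rates (default
#'   `A_T`).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(space, path, A_f = space$params$A_T) {
  lab <- sprintf("%s(%d)", space$nodes$rung, space$nodes$j)
  ed <- space$edges
  out <- data.frame(
    source = lab[ed$from], target = lab[ed$to],
    forward_rate = ifelse(ed$kaia, ed$fwd * A_f, ed$fwd),
    backward_rate = ed$bwd, type = ed$type
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
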