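# Hand-enumerated N = 2 oracle: 9 nodes, 12 edges with phi0 = pi/2.
n2_params <- function() {
  kai_params(N = 2, alpha = 3, K_d0 = 2, k_Af = 1, k1 = 0.7, k3_fwd = 1.1,
             k2_fwd = 0.9, gamma = 0.5, gamma1 = 0.4, gamma2 = 0.3,
             omega = 0.6, omega1 = 0.8, eps_seq = 0.2, A_T = 1,
             phi0 = pi / 2, reverse_floor = 1e-8)
}

test_that("state space matches the hand-enumerated N = 2 network", {
  p <- n2_params()
  sp <- build_state_space(p)
  ls <- 2 / 20   # ladder hop rates live on the N_ref = 20 reference grid
  expect_equal(sp$n, 9)
  expect_equal(sp$nodes$phase, c(0, pi / 2, pi, 0, pi / 2, pi, pi, 3 * pi / 2, 2 * pi))
  expect_equal(sp$nodes$rung, rep(c("P1", "P3", "P2"), each = 3))
  ed <- sp$edges
  expect_equal(nrow(ed), 12)
  key <- paste(ed$from, ed$to, ed$type)
  expected <- c(
    "2 1 p1_ladder", "3 2 p1_ladder",
    "4 5 p3_ladder", "5 6 p3_ladder",
    "7 8 p2_ladder", "8 9 p2_ladder",
    "1 4 bind", "2 5 bind", "3 6 bind",
    "2 8 switch", "3 7 switch",
    "9 1 reset"
  )
  expect_setequal(key, expected)
  # spot-check the rate laws
  get <- function(f, t) ed[ed$from == f & ed$to == t, ]
  expect_equal(get(2, 1)$fwd, 0.7 * ls)
  expect_equal(get(2, 1)$bwd, 0.35 * ls)
  expect_equal(get(4, 5)$fwd, 1.1 * ls)
  expect_equal(get(4, 5)$bwd, 0.4 * 1.1 * ls)
  expect_equal(get(1, 4)$bwd, 2 * 3^(-pi))       # k_Ab0 * alpha^(0 - pi)
  expect_equal(get(3, 6)$bwd, 2 * 3^(pi - pi))   # phase pi
  expect_true(get(1, 4)$kaia)
  expect_equal(get(9, 1)$fwd, 0.8)
  expect_equal(get(9, 1)$bwd, 1e-8)
  expect_equal(get(2, 8)$fwd, 0.6)
  expect_equal(get(2, 8)$bwd, 0.6)
})

test_that("KaiB-free limit removes the P2 connections; alpha = 1 flattens unbinding", {
  p <- kai_set(n2_params(), omega = 0, omega1 = 0)
  sp <- build_state_space(p)
  expect_false(any(sp$edges$type %in% c("switch", "reset")))
  # P2 keeps its internal ladder but no connection to the active rungs
  cross <- xor(sp$edges$from %in% sp$idx$P2, sp$edges$to %in% sp$idx$P2)
  expect_false(any(cross))
  p1 <- kai_set(n2_params(), alpha = 1)
  sp1 <- build_state_space(p1)
  bind <- sp1$edges[sp1$edges$type == "bind", ]
  expect_equal(bind$bwd, rep(p1$k_Ab0, 3))
  # k1 = 0 removes the P1 rung entirely
  sp0 <- build_state_space(kai_set(n2_params(), k1 = 0))
  expect_false(any(sp0$edges$type == "p1_ladder"))
})

test_that("edge graph is strongly connected when the full cycle is present", {
  skip_if_not_installed("igraph")
  set.seed(101)
  for (i in 1:5) {
    p <- jitter_params(kai_preset(c("affinity", "ultrasensitivity")[1 + i %% 2]),
                       spread = 0.4)
    sp <- build_state_space(p)
    g <- igraph::graph_from_edgelist(
      as.matrix(rbind(sp$edges[, c("from", "to")],
                      setNames(sp$edges[, c("to", "from")], c("from", "to")))))
    expect_true(igraph::is_connected(g, mode = "strong"))
  }
})

test_that("free KaiA matches brute-force accounting and is monotone", {
  set.seed(7)
  p <- kai_params(A_T = 1, eps_seq = 0.5)
  sp <- build_state_space(p)
  for (i in 1:5) {
    x <- stats::rexp(sp$n)
    x <- x / sum(x)
    manual <- 0
    for (k in seq_len(sp$n)) {
      manual <- manual + x[k] *
        switch(sp$nodes$rung[k], P3 = 1, P2 = p$eps_seq, P1 = 0)
    }
    expect_equal(free_kaia(p, x, sp), max(0, p$A_T - manual))
  }
  # all mass on P1: nothing bound or sequestered
  pP1 <- numeric(sp$n); pP1[sp$idx$P1] <- 1 / length(sp$idx$P1)
  expect_equal(free_kaia(p, pP1, sp), p$A_T)
  # full binding depletes the pool exactly: sum(P3) = A_T gives A_f = 0
  p0 <- kai_set(p, eps_seq = 0, A_T = 1 / 3)
  mix <- numeric(sp$n)
  mix[sp$idx$P3] <- (1 / 3) / length(sp$idx$P3)
  mix[sp$idx$P1] <- (2 / 3) / length(sp$idx$P1)
  expect_equal(free_kaia(p0, mix, sp), 0)
  # non-increasing in every P2/P3 occupancy
  x <- rep(1 / sp$n, sp$n)
  base_af <- free_kaia(p, x, sp)
  for (k in c(sp$idx$P2, sp$idx$P3)) {
    x2 <- x
    x2[k] <- x2[k] + 0.01
    expect_lte(free_kaia(p, x2, sp), base_af)
  }
})

test_that("rate matrix columns sum to zero and respect the hand oracle", {
  p <- n2_params()
  sp <- build_state_space(p)
  x <- rep(1 / 9, 9)
  W <- rate_matrix(p, p = x, space = sp)
  expect_lt(max(abs(colSums(W))), 1e-10 * max(abs(W)))
  af <- free_kaia(p, x, sp)
  expect_equal(W[4, 1], max(1 * af, 1e-8))     # binding at A_f
  expect_equal(W[1, 4], 2 * 3^(-pi))
  expect_equal(W[1, 2], 0.7 * 0.1)
  expect_equal(W[8, 2], 0.6)
  expect_equal(W[1, 9], 0.8)
  expect_equal(W[9, 1], 1e-8)
})

test_that("phosphorylation observable has the tent profile and its symmetry", {
  p <- kai_params(N = 10)
  sp <- build_state_space(p)
  at <- function(id) { x <- numeric(sp$n); x[id] <- 1; x }
  expect_equal(phosphorylation_level(at(sp$idx$P1[1]), sp), 0)    # phi = 0
  expect_equal(phosphorylation_level(at(sp$idx$P1[11]), sp), 1)   # phi = pi
  expect_equal(phosphorylation_level(at(sp$idx$P2[11]), sp), 0)   # phi = 2 pi
  # mass split between phi and 2 pi - phi equals all mass at phi
  j <- 3
  split <- numeric(sp$n)
  split[sp$idx$P1[j + 1]] <- 0.5
  split[sp$idx$P2[10 - j + 1]] <- 0.5   # P2(2N - j)
  expect_equal(phosphorylation_level(split, sp),
               phosphorylation_level(at(sp$idx$P1[j + 1]), sp))
  # random state: independent elementwise sum
  set.seed(1)
  x <- stats::rexp(sp$n); x <- x / sum(x)
  f <- ifelse(sp$nodes$phase <= pi, sp$nodes$phase / pi, 2 - sp$nodes$phase / pi)
  expect_equal(phosphorylation_level(x, sp), sum(f * x))
})

test_that("edge list export round-trips through TSV", {
  sp <- build_state_space(kai_params(N = 4))
  path <- tempfile(fileext = ".tsv")
  write_edge_list(sp, path)
  tab <- utils::read.delim(path)
  expect_equal(nrow(tab), nrow(sp$edges))
  expect_true(all(c("source", "target", "forward_rate", "backward_rate") %in%
                  names(tab)))
  expect_true(all(tab$forward_rate > 0))
})
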