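# minimal two-state space for the flux arithmetic oracle
two_state_space <- function(kf = 2, kb = 1) {
  params <- kai_params()
  structure(list(
    nodes = data.frame(id = 1:2, rung = c("P1", "P1"), j = 0:1, phase = c(0, pi)),
    edges = data.frame(from = 1, to = 2, fwd = kf, bwd = kb, kaia = FALSE,
                       type = "p1_ladder"),
    idx = list(P1 = 1:2, P2 = integer(0), P3 = integer(0)),
    n = 2, phos = c(0, 1), params = params
  ), class = "kai_space")
}

test_that("edge fluxes reproduce the two-state hand calculation", {
  sp <- two_state_space(2, 1)
  p <- kai_params()
  # stationary for the pair: p = (1/3, 2/3): J+ = J- = 2/3, zero dissipation
  fl <- kairing:::edge_fluxes(p, c(1, 2) / 3, sp)
  expect_equal(fl$J_plus, 2 / 3)
  expect_equal(fl$J_minus, 2 / 3)
  expect_equal(fl$contribution, 0)
  # clamped at (1/2, 1/2): sigma = (1 - 1/2) * log 2
  fl2 <- kairing:::edge_fluxes(p, c(0.5, 0.5), sp)
  expect_equal(fl2$contribution, 0.5 * log(2))
  # one-sided zero flux is rejected
  expect_error(kairing:::edge_fluxes(p, c(0, 1), sp), "one-sided")
})

test_that("equilibrium network produces zero entropy at its fixed point", {
  eq <- kai_equilibrium_params()
  fp <- fixed_point_numeric(eq)
  ent <- entropy_production_stationary(eq, fp)
  expect_lt(abs(ent$sigma_dot), 1e-10)
  expect_true(all(ent$edges$contribution >= -1e-16))
})

test_that("edge-wise total matches an independent per-edge recomputation", {
  p <- kai_preset("affinity", alpha = 20)
  sp <- build_state_space(p)
  fp <- fixed_point_numeric(p, space = sp)
  ent <- entropy_production_stationary(p, fp, space = sp)
  expect_true(all(ent$edges$contribution >= 0))
  # independent summation straight from the edge table
  af <- free_kaia(p, fp$p, sp)
  manual <- 0
  for (k in seq_len(nrow(sp$edges))) {
    e <- sp$edges[k, ]
    kf <- if (e$kaia) max(e$fwd * af, p$reverse_floor) else e$fwd
    jp <- kf * fp$p[e$from]
    jm <- e$bwd * fp$p[e$to]
    manual <- manual + (jp - jm) * log(jp / jm)
  }
  expect_equal(ent$sigma_dot, manual, tolerance = 1e-12)
})

test_that("cycle average reduces to the stationary rate for stable dynamics", {
  p <- kai_preset("affinity", alpha = 10)    # below onset
  sp <- build_state_space(p)
  fp <- fixed_point_numeric(p, space = sp)
  tr <- integrate_clock(p, p0 = fp$p, t_end = 200, n_out = 400, space = sp)
  ent_c <- entropy_production_cycle(p, tr)
  ent_s <- entropy_production_stationary(p, fp, space = sp)
  expect_lt(abs(ent_c$sigma_dot - ent_s$sigma_dot), 1e-8)
})

test_that("dissipation rises and flattens with differential affinity", {
  aff <- kai_preset("affinity")
  alphas <- c(1, 8, 27, 45, 90)
  sd <- vapply(alphas, function(a) {
    entropy_production_at(kai_set(aff, alpha = a))$sigma_dot
  }, numeric(1))
  expect_true(all(diff(sd) > 0))
  inc <- diff(sd) / diff(alphas)
  expect_true(all(diff(inc) < 0))      # concave: plateauing growth
  expect_lt(inc[length(inc)], 0.05 * inc[1])
})
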