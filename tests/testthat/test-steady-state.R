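test_that("exact k1 = 0 solution is a machine-precision fixed point", {
  p <- kai_preset("affinity", alpha = 6)
  sp <- build_state_space(p)
  fe <- fixed_point_exact(p, space = sp)
  expect_equal(fe$method, "analytic")
  expect_lt(fe$residual, 1e-10 * fe$max_rate)
  expect_equal(sum(fe$p), 1, tolerance = 1e-12)
  expect_gte(min(fe$p), 0)
  expect_gt(fe$b, 0)
  expect_lt(fe$b, 1)
  # interior P1 nodes are in exact vertical equilibrium with P3
  u <- p$k_Af * fe$A_f
  v <- p$k_Ab0 * p$alpha^(sp$nodes$phase[sp$idx$P3] - pi)
  inner <- 2:p$N
  expect_lt(max(abs(u * fe$p[sp$idx$P1][inner] /
                    (v[inner] * fe$p[sp$idx$P3][inner]) - 1)), 1e-10)
})

test_that("exact solution enforces its preconditions", {
  expect_error(fixed_point_exact(kai_preset("affinity", k1 = 0.1)),
               "preconditions")
  expect_error(fixed_point_exact(kai_preset("affinity", eps_seq = 1)),
               "preconditions")
  # phi0 < pi: flagged truncated mode instead of an error
  fp <- fixed_point_exact(kai_preset("affinity", phi0 = 0.9 * pi))
  expect_equal(fp$method, "analytic-truncated")
})

test_that("free-KaiA self-consistency root agrees with a dense grid scan", {
  p <- kai_preset("affinity", alpha = 6)
  fe <- fixed_point_exact(p)
  # independent oracle: scan the normalized P3(0) mismatch on a fine grid
  grid <- seq(1e-4, p$A_T, length.out = 20000)
  h <- vapply(grid, function(af) {
    raw <- kairing:::exact_profile(p, af)
    raw <- raw / sum(raw)
    af - (p$A_T - sum(raw[(p$N + 2):(2 * p$N + 2)]))
  }, numeric(1))
  cross <- which(diff(sign(h)) != 0)[1]
  af_scan <- grid[cross]
  expect_lt(abs(af_scan - fe$A_f), 2 * diff(grid)[1])
  b_scan <- {
    raw <- kairing:::exact_profile(p, af_scan)
    raw[p$N + 2] / sum(raw)
  }
  expect_lt(abs(b_scan - fe$b), 1e-5)
})

test_that("ansatz profile reduces to the exact solution as k1 vanishes", {
  p0 <- kai_preset("affinity", alpha = 6)
  fe <- fixed_point_exact(p0)
  fa0 <- fixed_point_approx(p0)
  expect_lt(max(abs(fa0$p - fe$p)), 1e-8)
  errs <- vapply(c(1e-2, 1e-3, 1e-4), function(k) {
    max(abs(fixed_point_approx(kai_set(p0, k1 = k))$p - fe$p))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-4)
})

test_that("ansatz enforces KaiA-link equilibrium by construction", {
  u <- kai_preset("ultrasensitivity", K_d0 = 10)
  sp <- build_state_space(u)
  fa <- fixed_point_approx(u, space = sp)
  j0 <- ceiling(u$N * u$phi0 / pi)
  inner <- setdiff(seq_len(j0 + 1), c(1, j0 + 1))
  uu <- u$k_Af * fa$A_f
  v <- u$k_Ab0 * u$alpha^(sp$nodes$phase[sp$idx$P3] - pi)
  ratio <- uu * fa$p[sp$idx$P1][inner] / (v[inner] * fa$p[sp$idx$P3][inner])
  expect_lt(max(abs(ratio - 1)), 1e-9)
  # truncation: no occupancy above phi0
  expect_equal(fa$p[sp$idx$P1][(j0 + 2):(u$N + 1)], rep(0, u$N - j0))
  expect_equal(fa$p[sp$idx$P3][(j0 + 2):(u$N + 1)], rep(0, u$N - j0))
})

test_that("numeric fixed point hits uniform at equilibrium and polishes guesses", {
  eq <- kai_equilibrium_params()
  fn <- fixed_point_numeric(eq)
  expect_lt(max(abs(fn$p - 1 / length(fn$p))), 1e-10)
  # oscillatory parameters: the unstable fixed point is still found from the
  # analytic expansion point, at tight residual
  p <- kai_preset("affinity", alpha = 35)
  fn2 <- fixed_point_numeric(p)
  expect_lt(fn2$residual, 1e-10 * fn2$max_rate)
  expect_equal(sum(fn2$p), 1, tolerance = 1e-9)
  r <- stability_report(p, fp = fn2)
  expect_true(r$oscillating)
})

test_that("fixed points export as CSV in the profile layout", {
  p <- kai_preset("affinity", alpha = 6)
  sp <- build_state_space(p)
  fp <- fixed_point_exact(p, space = sp)
  path <- tempfile(fileext = ".csv")
  write_fixed_point(fp, sp, path)
  tab <- utils::read.csv(path)
  expect_equal(nrow(tab), sp$n)
  expect_equal(sum(tab$occupancy), 1, tolerance = 1e-8)
})
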