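test_that("equilibrium at modest PFC activity matches the reference cells", {
  # X_p = 0.7, J_d = 1: no D2 effects, heteroreceptor alone, both receptors
  eq00 <- solve_equilibrium(circuit_params(a = 0, b = 0), 0.7)
  expect_equal(eq00$x_s, 0.7, tolerance = 1e-10)
  expect_equal(eq00$y, 0.3, tolerance = 1e-10)

  eq01 <- solve_equilibrium(circuit_params(a = 0, b = 1), 0.7)
  expect_equal(eq01$y, 0.55, tolerance = 0.01)
  expect_equal(eq01$x_s, 0.45, tolerance = 0.01)
  # closed form at b = 1, a = 0: Y^2 = 1 - X_p
  expect_equal(eq01$y^2, 0.3, tolerance = 1e-10)

  eqa <- solve_equilibrium(circuit_params(a = 0.2, b = 1), 0.7)
  expect_equal(eqa$y, 0.50, tolerance = 0.01)
  expect_gte(eqa$x_s, 0.46)  # printed-rounding ambiguity: accept [0.46, 0.47]
  expect_lte(eqa$x_s, 0.47)

  expect_equal(round(enhancement_percent(eq01$y, eq00$y)), 83)
  expect_equal(enhancement_percent(0.5, 0.3), 200 / 3)
  expect_error(enhancement_percent(0.5, 0), "positive")
})

test_that("closed form Y^2 = 1 - X_p holds across PFC activities at b = 1", {
  for (x_p in seq(0.05, 0.95, by = 0.05)) {
    eq <- solve_equilibrium(circuit_params(a = 0, b = 1), x_p)
    expect_equal(eq$y^2, 1 - x_p, tolerance = 1e-10)
  }
})

test_that("equilibrium solver agrees with the cubic-root oracle", {
  set.seed(42)
  for (i in 1:100) {
    x_p <- runif(1, 0.1, 0.9)
    a <- runif(1, 0, 1)
    b <- runif(1, 0, 1)
    j_d <- runif(1, max(x_p + 0.05, 0.8), 1.5)
    eq <- solve_equilibrium(circuit_params(a = a, b = b, j_d = j_d), x_p)
    roots <- oracle_equilibrium_y(x_p, a, b, j_d)
    expect_equal(eq$y, roots[which.min(abs(roots - eq$y))],
                 tolerance = 1e-8)
    # all four fixed-point relations hold at the solution
    p <- eq$y / (1 + eq$y)
    expect_equal(eq$x_s, x_p * (1 - b * p), tolerance = 1e-8)
    expect_equal(eq$x_d, j_d - eq$x_s, tolerance = 1e-8)
    expect_equal(eq$y, eq$x_d * (1 - a * p), tolerance = 1e-8)
  }
})

test_that("solver rejects parameterizations with no positive equilibrium", {
  # PFC drive exceeding the DA-nucleus drive leaves X_d <= 0 at b = 0
  expect_error(solve_equilibrium(circuit_params(a = 0, b = 0), x_p = 1.2),
               "positive equilibrium")
  expect_error(solve_equilibrium(circuit_params(), x_p = -1), "positive")
  expect_error(solve_equilibrium(circuit_params(activation = "tanh"), 0.7),
               "linear")
})

test_that("sweeps are pointwise monotone in the D2 coefficients", {
  b_grid <- c(0, 0.25, 0.5, 0.75, 1)
  sw <- sweep_equilibrium(x_p = seq(0.1, 0.9, by = 0.1), a = 0, b = b_grid)
  expect_true(all(sw$feasible))
  for (xp in unique(sw$x_p)) {
    rows <- sw[sw$x_p == xp, ]
    rows <- rows[order(rows$b), ]
    expect_true(all(diff(rows$y) > 0))      # heteroreceptor raises release
    expect_true(all(diff(rows$x_s) < 0))    # and lowers striatal activity
  }
  # Y decreasing and X_s increasing in PFC activity at each b
  for (bb in b_grid) {
    rows <- sw[sw$b == bb, ]
    rows <- rows[order(rows$x_p), ]
    expect_true(all(diff(rows$y) < 0))
    expect_true(all(diff(rows$x_s) > 0))
  }
  # b = 0 curves are exactly linear: X_s = X_p, Y = J_d - X_p
  b0 <- sw[sw$b == 0, ]
  expect_equal(b0$x_s, b0$x_p, tolerance = 1e-10)
  expect_equal(b0$y, 1 - b0$x_p, tolerance = 1e-10)
  # autoreceptor lowers release at fixed X_p
  swa <- sweep_equilibrium(x_p = 0.7, a = c(0, 0.2), b = 1)
  ys <- swa$y[order(swa$a)]
  expect_lt(ys[2], ys[1])
  expect_equal(ys, c(0.55, 0.50), tolerance = 0.01)
  # infeasible points are flagged, not dropped
  bad <- sweep_equilibrium(x_p = c(0.5, 1.5), a = 0, b = 0)
  expect_equal(nrow(bad), 2L)
  expect_equal(bad$feasible, c(TRUE, FALSE))
  expect_true(is.na(bad$y[2]))
})

test_that("dynamics vanish at fixed points and stay bounded under tanh", {
  params <- circuit_params(a = 0.2, b = 1)
  eq <- solve_equilibrium(params, 0.7)
  d <- dynamics_rhs(c(eq$x_p, eq$x_s, eq$x_d, eq$y), params,
                    pfc_input = eq$x_p)
  expect_true(all(abs(d) < 1e-8))
  # the origin is a fixed point with zero drives
  p0 <- circuit_params(a = 0.2, b = 1, j_d = 1)
  p0$j_d <- 0  # zero tonic drive (bypasses the j_d > 0 construction guard)
  expect_equal(unname(dynamics_rhs(c(0, 0, 0, 0), p0, pfc_input = 0)),
               rep(0, 4))
  # tanh saturation bounds the derivatives for huge states
  pt <- circuit_params(a = 0.2, b = 1, activation = "tanh")
  big <- dynamics_rhs(c(50, -50, 50, 50), pt, pfc_input = 1)
  expect_true(all(is.finite(big)))
  expect_true(all(abs(big) < 200))
})

test_that("time integration converges to the algebraic equilibrium", {
  set.seed(7)
  for (i in 1:5) {
    params <- circuit_params(a = runif(1, 0, 0.5), b = runif(1, 0, 1))
    x_p <- runif(1, 0.3, 0.8)
    eq <- solve_equilibrium(params, x_p)
    tr <- simulate_circuit(params, initial = c(0, 0, 0, 0),
                           pfc_input = x_p, t_end = 80)
    last <- tr[nrow(tr), ]
    expect_equal(last$y, eq$y, tolerance = 1e-6)
    expect_equal(last$x_s, eq$x_s, tolerance = 1e-6)
    d <- dynamics_rhs(unlist(last[c("x_p", "x_s", "x_d", "y")]), params,
                      pfc_input = x_p)
    expect_true(all(abs(d) < 1e-6))
  }
  # zero drives decay to the origin
  p0 <- circuit_params()
  p0$j_d <- 0
  tr0 <- simulate_circuit(p0, initial = c(0.5, 0.5, 0.5, 0.5),
                          pfc_input = 0, t_end = 60)
  expect_true(all(abs(unlist(tr0[nrow(tr0), -1])) < 1e-6))
})
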