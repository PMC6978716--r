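test_that("gating and firing sigmoids hit midpoint, saturation and unit slope point", {
  expect_equal(gating_fraction(-0.01, -0.01, 0.15), 0.5)
  expect_equal(gating_fraction(1e6, 0, 0.3), 1)
  expect_equal(gating_fraction(-1e6, 0, 0.3), 0)
  # one threshold-variance above threshold: 0.5*(1 + tanh 1)
  expect_equal(gating_fraction(0.15, 0, 0.15), 0.88079707797788243)
  expect_error(gating_fraction(0, 0, 0), "positive")

  expect_equal(firing_rate(0, 0, 0.65, 1), 0.5)
  expect_equal(firing_rate(1e6, 0, 0.65, 1), 1)
  expect_equal(firing_rate(0.65, 0, 0.65, 1), 0.88079707797788243)
  expect_equal(firing_rate(0.65, 0, 0.65, 2), 2 * 0.88079707797788243)
  expect_error(firing_rate(0, 0, -1, 1), "positive")
  expect_error(firing_rate(0, 0, 0.65, 0), "positive")
})

test_that("coupling input is the connectivity-weighted convex mean", {
  # single neighbour: region 1 sees region 2's rate exactly
  sc2 <- structural_connectome(matrix(c(0, 1, 1, 0), 2))
  expect_equal(coupling_input(c(0.2, 0.9), sc2), c(0.9, 0.2))

  # 3-region weighted case against a hand-computed dot product
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 2
  w[1, 3] <- w[3, 1] <- 3
  w[2, 3] <- w[3, 2] <- 1
  sc3 <- structural_connectome(w)
  q <- c(0.1, 0.4, 0.8)
  expect_equal(coupling_input(q, sc3),
               c((2 * 0.4 + 3 * 0.8) / 5, (2 * 0.1 + 1 * 0.8) / 3,
                 (3 * 0.1 + 1 * 0.4) / 4))

  # convexity across random cases
  set.seed(42)
  for (i in 1:20) {
    sc <- make_test_connectome(8, seed = i)
    q <- runif(8)
    avg <- coupling_input(q, sc)
    expect_true(all(avg >= min(q) - 1e-12 & avg <= max(q) + 1e-12))
  }
  q <- rep(0.3, 8)
  expect_equal(coupling_input(q, make_test_connectome(8)), q)

  # isolated region: input 0 with a warning
  w0 <- matrix(0, 3, 3)
  w0[1, 2] <- w0[2, 1] <- 1
  sc0 <- structural_connectome(w0)
  expect_warning(out <- coupling_input(c(0.5, 0.5, 0.5), sc0), "isolated")
  expect_equal(out[3], 0)
})

test_that("state derivative matches an independently evaluated scalar oracle", {
  p <- neural_mass_params(C = 0.5, delta_V = 0.65)
  # frozen value: Eqs evaluated symbol-by-symbol at V=Z=W=0, one region
  sc1 <- structural_connectome(matrix(0, 1, 1))
  d0 <- state_derivative(list(V = 0, Z = 0, W = 0), p, sc1)
  expect_equal(d0$dV, 0.76655085154781921, tolerance = 1e-12)
  expect_equal(d0$dZ, 0.012, tolerance = 1e-12)
  expect_equal(d0$dW, 0.35, tolerance = 1e-12)

  # coupled random states against the loop-based oracle
  sc <- make_test_connectome(6, seed = 2)
  set.seed(9)
  st <- list(V = runif(6, -0.3, 0.3), Z = runif(6, -0.3, 0.3),
             W = runif(6, 0.2, 0.5))
  d <- state_derivative(st, p, sc)
  o <- oracle_lb_deriv(st$V, st$Z, st$W, p, sc$weights)
  expect_equal(d$dV, o$dV, tolerance = 1e-12)
  expect_equal(d$dZ, o$dZ, tolerance = 1e-12)
  expect_equal(d$dW, o$dW, tolerance = 1e-12)

  expect_error(state_derivative(list(V = 0, Z = 0, W = 0), p, sc), "region")
})

test_that("at C = 0 regions are decoupled; identical states give identical derivatives", {
  p0 <- neural_mass_params(C = 0, delta_V = 0.6)
  sc <- make_test_connectome(6, seed = 4)
  set.seed(1)
  st <- list(V = runif(6, -0.2, 0.2), Z = runif(6, -0.2, 0.2),
             W = runif(6, 0.3, 0.4))
  d1 <- state_derivative(st, p0, sc)
  st2 <- st
  st2$V[3] <- st2$V[3] + 0.17       # perturb another region
  st2$Z[5] <- st2$Z[5] - 0.21
  d2 <- state_derivative(st2, p0, sc)
  expect_identical(d1$dV[1], d2$dV[1])
  expect_identical(d1$dW[1], d2$dW[1])

  # permutation symmetry: identical per-region states, any coupling
  p5 <- neural_mass_params(C = 0.5, delta_V = 0.6)
  st_eq <- list(V = rep(0.1, 6), Z = rep(-0.05, 6), W = rep(0.35, 6))
  d_eq <- state_derivative(st_eq, p5, sc)
  expect_equal(d_eq$dV, rep(d_eq$dV[1], 6))
  expect_equal(d_eq$dZ, rep(d_eq$dZ[1], 6))
})

test_that("parameter container enforces the coupling and gain domains", {
  expect_error(neural_mass_params(C = -0.1), "C")
  expect_error(neural_mass_params(C = 1.5), "C")
  expect_error(neural_mass_params(delta_V = 0), "delta_V")
  p <- neural_mass_params(delta_V = 0.7)
  expect_identical(p$delta_Z, p$delta_V)
})

test_that("simulation is deterministic and respects the transient contract", {
  sc <- make_test_connectome(4, seed = 5)
  p <- neural_mass_params(C = 0.3, delta_V = 0.65)
  t1 <- simulate_neural_mass(p, sc, duration_s = 3, transient_s = 1, seed = 8)
  t2 <- simulate_neural_mass(p, sc, duration_s = 3, transient_s = 1, seed = 8)
  expect_identical(t1$V, t2$V)
  expect_identical(t1$t0, 1)
  expect_identical(ncol(t1$V), 2001L)
  expect_true(all(is.finite(t1$V)))
  expect_error(simulate_neural_mass(p, sc, duration_s = 1, transient_s = 2),
               "duration_s")
})

test_that("decoupled identical regions produce identical trajectories", {
  sc <- structural_connectome(matrix(c(0, 1, 1, 0), 2))
  p <- neural_mass_params(C = 0, delta_V = 0.65)
  init <- list(V = c(0.05, 0.05), Z = c(-0.02, -0.02), W = c(0.35, 0.35))
  tr <- simulate_neural_mass(p, sc, duration_s = 5, transient_s = 0,
                             init = init)
  expect_equal(tr$V[1, ], tr$V[2, ], tolerance = 1e-10)
})

test_that("single-region dynamics stay bounded over 10 s", {
  sc1 <- structural_connectome(matrix(0, 1, 1))
  p <- neural_mass_params(C = 0, delta_V = 0.65)
  tr <- simulate_neural_mass(p, sc1, duration_s = 10, transient_s = 0,
                             seed = 3)
  expect_true(all(abs(tr$V) < 1.5))
  expect_true(all(is.finite(tr$V)))
})

test_that("relabelling regions permutes the trajectory equivariantly", {
  sc <- make_test_connectome(6, seed = 12)
  perm <- c(4, 1, 6, 2, 5, 3)
  wp <- sc$weights[perm, perm]
  scp <- structural_connectome(wp, sc$region_labels[perm])
  init <- random_initial_state(6, seed = 31)
  initp <- list(V = init$V[perm], Z = init$Z[perm], W = init$W[perm])
  p <- neural_mass_params(C = 0.4, delta_V = 0.65)
  tr <- simulate_neural_mass(p, sc, duration_s = 0.3, transient_s = 0,
                             init = init)
  trp <- simulate_neural_mass(p, scp, duration_s = 0.3, transient_s = 0,
                              init = initp)
  expect_equal(trp$V, tr$V[perm, ], tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("dynamics remain bounded across the swept parameter plane", {
  sc <- make_test_connectome(6, seed = 21)
  for (C in c(0, 0.5, 1)) {
    for (dV in c(0.55, 0.75)) {
      tr <- simulate_neural_mass(neural_mass_params(C = C, delta_V = dV), sc,
                                 duration_s = 5, transient_s = 0, seed = 2)
      expect_true(all(is.finite(tr$V)))
      expect_true(max(abs(tr$V)) < 1.5)
    }
  }
})
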