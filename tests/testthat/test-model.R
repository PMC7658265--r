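test_that("parameter constructor validates and stores defaults", {
  p <- kinetic_params()
  expect_equal(p$phi, 1)
  expect_equal(p$nu, 1.84)
  expect_equal(p$L, 5e6)
  expect_equal(p$n, 4L)
  expect_equal(p$M, 10)
  expect_equal(p$k_s, 0.06)
  expect_error(kinetic_params(nu = -1), "strictly positive")
  expect_error(kinetic_params(n = 2.5), "integer")
  expect_error(kinetic_params(q = -0.1), "non-negative")
  expect_error(update_params(p, bogus = 1), "unknown")
  expect_equal(update_params(p, sigma_inh = 50)$sigma_inh, 50)
})

test_that("vector field satisfies its algebraic identities", {
  topo <- cell_topology("linear", 2)
  p <- kinetic_params()
  # at the origin every nonlinear term vanishes: dx = nu, dy = 0
  expect_equal(cell_rhs(rep(0, 4), p, topo), c(1.84, 1.84, 0, 0))
  # identical cells: coupling sums vanish, N copies of the one-cell value
  s1 <- c(2.5, 17)
  r1 <- cell_rhs(s1, p, cell_topology("linear", 1))
  expect_equal(cell_rhs(c(2.5, 2.5, 17, 17), p, topo), rep(r1, each = 2))
  # phi * (reaction part of dx) + (reaction part of dy) = phi*nu - k_s*y
  for (s in random_states(20, p, cell_topology("cyclic", 3), seed = 2)) {
    topo3 <- cell_topology("cyclic", 3)
    r <- cell_rhs(s, p, topo3)
    x <- s[1:3]; y <- s[4:6]
    coup_x <- -p$q * p$k_ADP * as.vector(topo3$laplacian %*% x)
    coup_y <- -p$k_ADP * as.vector(topo3$laplacian %*% y)
    expect_equal(p$phi * (r[1:3] - coup_x) + (r[4:6] - coup_y),
                 p$phi * p$nu - p$k_s * y, tolerance = 1e-12)
    # mass exchange conserves the total across the array
    expect_equal(sum(coup_x), 0, tolerance = 1e-12)
    expect_equal(sum(coup_y), 0, tolerance = 1e-12)
  }
})

test_that("analytic Jacobian matches finite differences", {
  fx <- generate_fixtures(seed = 5, n_topologies = 3, n_params = 3)
  for (k in seq_along(fx$topologies)) {
    topo <- fx$topologies[[k]]
    p <- fx$params[[k]]
    for (s in random_states(12, kinetic_params(), topo, seed = k)) {
      J <- cell_jacobian(s, p, topo)
      expect_equal(J, fd_jacobian(s, p, topo), tolerance = 1e-6)
    }
  }
})

test_that("uncoupled arrays have block-diagonal Jacobians", {
  p <- kinetic_params(k_ADP = 0)
  topo <- cell_topology("cyclic", 3)
  s <- c(1, 2, 3, 11, 12, 13)
  J <- cell_jacobian(s, p, topo)
  for (i in 1:3) for (j in 1:3) {
    if (i == j) next
    expect_equal(J[i, j], 0)
    expect_equal(J[i, 3 + j], 0)
    expect_equal(J[3 + i, j], 0)
    expect_equal(J[3 + i, 3 + j], 0)
  }
})

test_that("rhs is equivariant under topology automorphisms", {
  fx <- generate_fixtures(seed = 9, n_topologies = 3)
  p <- kinetic_params()
  for (topo in fx$topologies) {
    autos <- automorphisms(topo)
    for (s in random_states(6, p, topo, seed = 3)) {
      r <- cell_rhs(s, p, topo)
      for (pm in autos)
        expect_equal(cell_rhs(permute_state(s, pm), p, topo),
                     permute_state(r, pm), tolerance = 1e-12)
    }
  }
})

test_that("uniform stationary state follows the closed form y* = phi*nu/k_s", {
  p <- kinetic_params()
  ss <- uniform_steady_state(p)
  expect_equal(ss$y, p$phi * p$nu / p$k_s, tolerance = 1e-12)
  expect_equal(ss$y, 30.6667, tolerance = 1e-4)
  expect_lt(ss$residual, 1e-10)
  # y* does not depend on the autocatalysis or inhibition coefficients
  for (si in c(5, 20, 35, 60)) for (sm in c(80, 100, 140)) {
    ss2 <- uniform_steady_state(kinetic_params(sigma_M = sm, sigma_inh = si))
    expect_equal(ss2$y, ss$y)
  }
  # x* differs across sigma_M but the state stays unique (single root)
  expect_gt(abs(uniform_steady_state(kinetic_params(sigma_M = 60))$x - ss$x), 1)
})

test_that("the single cell has exactly one stationary state", {
  p <- kinetic_params()
  topo1 <- cell_topology("linear", 1)
  st <- enumerate_states(p, topo1, n_starts = 120, seed = 8)
  expect_equal(nrow(st), 1L)
  expect_equal(st$symmetry, "uniform")
})

test_that("no uniform state exists when uptake outruns the saturating sink", {
  expect_error(uniform_steady_state(kinetic_params(sigma_M = 10,
                                                   sigma_inh = 20)),
               "no uniform stationary state")
})

test_that("uniform-state spectrum decomposes over Laplacian modes", {
  p <- kinetic_params()
  for (kind in c("linear", "cyclic", "t_shaped")) {
    topo <- cell_topology(kind, 4)
    u <- uniform_state_vector(p, topo)
    full <- sort(Re(eigen(cell_jacobian(u, p, topo))$values))
    jc <- glycell:::cell_kinetics_jac(u[1], u[5], p)
    Jc <- matrix(c(jc$fx_x, jc$fx_y, jc$fy_x, jc$fy_y), 2, 2, byrow = TRUE)
    modes <- unlist(lapply(laplacian_modes(topo), function(mu)
      eigen(Jc - mu * diag(c(p$q * p$k_ADP, p$k_ADP)))$values))
    expect_equal(full, sort(Re(modes)), tolerance = 1e-8)
  }
})
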