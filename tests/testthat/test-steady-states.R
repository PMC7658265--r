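test_that("Newton leaves converged states fixed and respects symmetry", {
  u <- uniform_state_vector(chem_params, cyc3)
  row <- newton_state(u, chem_params, cyc3)
  expect_lt(row$residual, 1e-10)
  expect_equal(row$state[[1]], u, tolerance = 1e-9)
  expect_equal(row$symmetry, "uniform")
  # a permuted converged guess converges to the permuted state
  st <- cyc3_states()
  s <- st$state[[which(st$symmetry == "symmetric_nonuniform")[1]]]
  for (pm in automorphisms(cyc3)) {
    r2 <- newton_state(permute_state(s, pm), chem_params, cyc3)
    expect_equal(r2$state[[1]], permute_state(s, pm), tolerance = 1e-8)
  }
})

test_that("all accepted roots satisfy the residual invariant", {
  set.seed(31)
  ss <- uniform_steady_state(chem_params)
  n_ok <- 0
  for (i in 1:40) {
    g <- c(runif(3, 0, 3 * ss$x), runif(3, 0, 3 * ss$y))
    s <- glycell:::solve_equilibrium(g, chem_params, cyc3)
    if (is.null(s)) next
    n_ok <- n_ok + 1
    expect_lt(max(abs(cell_rhs(s, chem_params, cyc3))), 1e-10)
    expect_true(all(s >= 0))
  }
  expect_gt(n_ok, 5)
})

test_that("enumeration finds the 7-3 state count of the computing point", {
  st <- cyc3_states()
  g <- glance(st)
  expect_equal(g$m, 7L)          # uniform + two rotation triplets
  expect_equal(g$n_stable, 3L)   # one stabilized triplet
  stable_nu <- st[st$stable & st$symmetry != "uniform", ]
  expect_equal(nrow(stable_nu), 3L)
  # the three stable patterns form a single rotation orbit
  expect_equal(length(unique(stable_nu$orbit_id)), 1L)
  expect_setequal(stable_nu$code, c("011", "101", "110"))
})

test_that("state sets are closed under the automorphism group", {
  st <- cyc3_states()
  autos <- automorphisms(cyc3)
  scale <- max(abs(st$state[[1]]))
  for (s in st$state) for (pm in autos) {
    img <- permute_state(s, pm)
    hit <- any(vapply(st$state, function(t) max(abs(t - img)) / scale < 1e-5,
                      logical(1)))
    expect_true(hit)
  }
})

test_that("orbit members share spectra and stability", {
  st <- cyc3_states()
  for (id in unique(st$orbit_id)) {
    sub <- st[st$orbit_id == id, ]
    expect_length(unique(sub$stable), 1L)
    ref <- sort(Re(sub$eigenvalues[[1]]))
    for (ev in sub$eigenvalues)
      expect_equal(sort(Re(ev)), ref, tolerance = 1e-8)
  }
})

test_that("larger multistarts do not lose states", {
  st_small <- enumerate_states(chem_params, cyc3, n_starts = 60, seed = 1)
  st_big <- enumerate_states(chem_params, cyc3, n_starts = 250, seed = 1)
  expect_gte(nrow(st_big), nrow(st_small))
  expect_gte(sum(st_big$stable), sum(st_small$stable))
})

test_that("symmetry classes and orbit sizes follow the stabilizer rule", {
  autos4 <- automorphisms(cell_topology("cyclic", 4))
  # (a,b,a,b) on the 4-cycle: fixed by rotation by two
  s_ab <- c(1, 2, 1, 2, 11, 12, 11, 12)
  cls <- symmetry_class(s_ab, autos4)
  expect_equal(cls$class, "symmetric_nonuniform")
  expect_equal(cls$orbit_size, 8 / cls$stabilizer_order)
  expect_gte(cls$stabilizer_order, 2)
  # four distinct values: trivial stabilizer, full orbit of 8
  s_4 <- c(1, 2, 3, 4, 11, 12, 13, 14)
  cls4 <- symmetry_class(s_4, autos4)
  expect_equal(cls4$class, "asymmetric_nonuniform")
  expect_equal(cls4$stabilizer_order, 1)
  expect_equal(cls4$orbit_size, 8)
  # uniform: stabilized by the whole group
  su <- c(rep(1, 4), rep(11, 4))
  clsu <- symmetry_class(su, autos4)
  expect_equal(clsu$class, "uniform")
  expect_equal(clsu$orbit_size, 1)
})

test_that("reported eigenvalues are true roots of the Jacobian", {
  st <- cyc3_states()
  for (i in c(1L, 2L, nrow(st))) {
    s <- st$state[[i]]
    got <- assess_stability(s, chem_params, cyc3)
    J <- cell_jacobian(s, chem_params, cyc3)
    scale <- max(abs(J))
    for (lam in got$eigenvalues) {
      # singular-value residual: smallest sv of (J - lam I) must vanish
      sv <- min(svd(J - diag(lam + 0i, nrow(J)))$d)
      expect_lt(sv / scale, 1e-8)
    }
    expect_equal(got$stable, max(Re(got$eigenvalues)) < -1e-9)
  }
})

test_that("state tables export with unit-bearing headers", {
  st <- cyc3_states()
  f <- withr::local_tempfile(fileext = ".csv")
  write_states_csv(st, f)
  hdr <- names(utils::read.csv(f, check.names = FALSE))
  expect_true("y_1_dimensionless" %in% hdr)
  expect_true("max_re_eigen_per_s" %in% hdr)
  expect_equal(nrow(utils::read.csv(f)), nrow(st))
})
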