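test_that("the uniform branch keeps ADP pinned at y* across sigma_inh", {
  u <- uniform_state_vector(chem_params, cyc3)
  b <- trace_branch(u, chem_params, cyc3, "sigma_inh", c(15, 60),
                    param_value = 35, direction = 1)
  expect_gt(nrow(b), 5)
  y_star <- chem_params$phi * chem_params$nu / chem_params$k_s
  for (s in b$state) expect_equal(s[4:6], rep(y_star, 3), tolerance = 1e-8)
  # every branch point re-solves from scratch to the same state
  for (i in round(seq(1, nrow(b), length.out = 6))) {
    p_i <- glycell:::set_free(chem_params, "sigma_inh", b$param[i])
    s_re <- glycell:::solve_equilibrium(b$state[[i]], p_i, cyc3)
    expect_equal(s_re, b$state[[i]], tolerance = 1e-8)
  }
})

test_that("Hopf detection matches a dense eigenvalue scan", {
  u <- uniform_state_vector(chem_params, cyc3)
  b <- trace_branch(u, chem_params, cyc3, "sigma_inh", c(12, 30),
                    param_value = 25, direction = -1)
  bf <- detect_bifurcations(b)
  hopf <- bf[bf$kind == "hopf", ]
  expect_equal(nrow(hopf), 1L)
  # dense-scan oracle: bisect max Re of the cell Jacobian eigenvalues
  dense <- uniroot(function(si) {
    p <- glycell:::set_free(chem_params, "sigma_inh", si)
    ss <- uniform_steady_state(p)
    jc <- glycell:::cell_kinetics_jac(ss$x, ss$y, p)
    Jc <- matrix(c(jc$fx_x, jc$fx_y, jc$fy_x, jc$fy_y), 2, 2, byrow = TRUE)
    max(Re(eigen(Jc)$values))
  }, c(15, 22), tol = 1e-10)$root
  expect_equal(hopf$param, dense, tolerance = 1e-6)
  expect_gt(hopf$omega, 0.1)
})

test_that("primary Hopf points do not move with the coupling strength", {
  # the uniform mode of the array Jacobian equals the single-cell
  # Jacobian, so the primary Hopf loci are k_ADP- and q-independent
  locate <- function(k_ADP, q) {
    p <- kinetic_params(k_ADP = k_ADP, q = q)
    u <- uniform_state_vector(p, cyc3)
    b <- trace_branch(u, p, cyc3, "sigma_inh", c(12, 30),
                      param_value = 25, direction = -1)
    bf <- detect_bifurcations(b)
    bf$param[bf$kind == "hopf"][1]
  }
  ref <- locate(0.1, 1)
  expect_equal(locate(0.02, 1), ref, tolerance = 1e-6)
  expect_equal(locate(0.3, 1), ref, tolerance = 1e-6)
  expect_equal(locate(0.1, 1.2), ref, tolerance = 1e-6)
})

test_that("symmetry breaking on the uniform branch matches the mode oracle", {
  u <- uniform_state_vector(chem_params, cyc3)
  b <- trace_branch(u, chem_params, cyc3, "sigma_inh", c(20, 45),
                    param_value = 25, direction = 1)
  bf <- detect_bifurcations(b)
  bps <- bf[bf$kind == "branch_point", ]
  expect_gte(nrow(bps), 1L)
  # oracle: zero of det(J_cell - mu * diag(q k, k)) for the coupling mode
  oracle <- uniroot(function(si) {
    p <- glycell:::set_free(chem_params, "sigma_inh", si)
    ss <- uniform_steady_state(p)
    jc <- glycell:::cell_kinetics_jac(ss$x, ss$y, p)
    mu <- 3  # nonzero Laplacian eigenvalue of the 3-cycle
    (jc$fx_x - mu * p$q * p$k_ADP) * (jc$fy_y - mu * p$k_ADP) -
      jc$fx_y * jc$fy_x
  }, c(30, 40), tol = 1e-10)$root
  expect_equal(bps$param[1], oracle, tolerance = 1e-6)
})

test_that("branch switching yields converged states off the uniform branch", {
  u <- uniform_state_vector(chem_params, cyc3)
  b <- trace_branch(u, chem_params, cyc3, "sigma_inh", c(20, 45),
                    param_value = 25, direction = 1)
  bf <- detect_bifurcations(b)
  bp <- bf[bf$kind == "branch_point", ][1, ]
  seeds <- switch_branch(bp, chem_params, cyc3, "sigma_inh")
  expect_gte(nrow(seeds), 2L)
  for (i in seq_len(nrow(seeds))) {
    s <- seeds$state[[i]]
    p_i <- glycell:::set_free(chem_params, "sigma_inh", seeds$param[i])
    expect_lt(max(abs(cell_rhs(s, p_i, cyc3))), 1e-10)
    expect_gt(max(abs(s[4:6] - mean(s[4:6]))), 1e-4)  # non-uniform
  }
})

test_that("no symmetry breaking from the stable uniform branch at q <= 1, but
           spontaneous Turing onset at q = 100", {
  # q = 1: branch points sit where the uniform state is already unstable
  u <- uniform_state_vector(chem_params, cyc3)
  b <- trace_branch(u, chem_params, cyc3, "sigma_inh", c(12, 60),
                    param_value = 35, direction = 1)
  b2 <- trace_branch(u, chem_params, cyc3, "sigma_inh", c(12, 60),
                     param_value = 35, direction = -1)
  for (bb in list(b, b2)) {
    bf <- detect_bifurcations(bb)
    for (k in which(bf$kind == "branch_point")) {
      p_bp <- glycell:::set_free(chem_params, "sigma_inh", bf$param[k])
      st <- assess_stability(bf$state[[k]], p_bp, cyc3)
      expect_false(st$stable)
    }
  }
  # q = 100, sigma_M = 10: a branch point on the *stable* uniform branch
  p100 <- kinetic_params(sigma_M = 10, q = 100, k_ADP = 0.02)
  lin4 <- cell_topology("linear", 4)
  u4 <- uniform_state_vector(glycell:::set_free(p100, "sigma_inh", 2), lin4)
  b4 <- trace_branch(u4, p100, lin4, "sigma_inh", c(0.5, 8),
                     param_value = 2, direction = 1)
  bf4 <- detect_bifurcations(b4)
  bps <- bf4[bf4$kind == "branch_point", ]
  expect_gte(nrow(bps), 1L)
  stable_side <- vapply(seq_len(nrow(bps)), function(k) {
    any(vapply(c(-1e-2, 1e-2), function(da) {
      p_bp <- glycell:::set_free(p100, "sigma_inh", bps$param[k] + da)
      u_bp <- uniform_state_vector(p_bp, lin4)
      assess_stability(u_bp, p_bp, lin4)$stable
    }, logical(1)))
  }, logical(1))
  expect_true(any(stable_side))
})

test_that("region map labels SUSS nodes as 1-1", {
  rm <- region_map(kinetic_params(), cyc3, c("sigma_inh", "sigma_M"),
                   ranges = list(c(4, 10), c(90, 120)), grid = c(3L, 3L),
                   n_starts = 40L, seed = 2)
  expect_true(all(rm$m == 1L))
  expect_true(all(rm$n == 1L))
  expect_true(all(rm$region == "1-1"))
})

test_that("solution diagram windows are delimited by detected bifurcations", {
  d <- solution_diagram(chem_params, cyc3, "sigma_inh", c(20, 60),
                        max_points = 150)
  expect_gt(nrow(d$windows), 0)
  nonuni <- d$windows[d$windows$symmetry != "uniform", ]
  expect_gt(nrow(nonuni), 0)
  # each stable non-uniform window endpoint lies near a detected
  # bifurcation (or the window border of the scan)
  bfp <- sort(d$bifurcations$param)
  for (i in seq_len(nrow(nonuni))) {
    for (edge in c(nonuni$param_lo[i], nonuni$param_hi[i])) {
      at_border <- min(abs(edge - c(20, 60))) < 1e-6
      near_bif <- length(bfp) && min(abs(bfp - edge)) < 1.5
      expect_true(at_border || near_bif)
    }
  }
})

test_that("branch-collected states agree with pointwise enumeration labels", {
  d <- solution_diagram(chem_params, cyc3, "sigma_inh", c(25, 45),
                        max_points = 150)
  agree <- 0L; total <- 0L
  for (si in seq(27, 43, by = 4)) {
    p <- glycell:::set_free(chem_params, "sigma_inh", si)
    st <- enumerate_states(p, cyc3, n_starts = 120, seed = 7)
    ## states sitting on some branch at this parameter
    onb <- d$branches[abs(d$branches$param - si) < 0.75, ]
    found <- 0L
    for (k in seq_len(nrow(st))) {
      s <- st$state[[k]]
      ok <- any(vapply(onb$state, function(t) max(abs(t - s)) < 0.8,
                       logical(1)))
      found <- found + as.integer(ok)
    }
    total <- total + 1L
    agree <- agree + as.integer(found >= nrow(st) - 0L)
  }
  expect_gte(agree / total, 0.95)
})
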