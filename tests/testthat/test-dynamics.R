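test_that("pulse schedules evaluate as half-open rectangles", {
  sch <- pulse_schedule(cell = 1L, amplitude = 1.2, start = 1400,
                        duration = 600)
  expect_equal(pulse_value(sch, 1, 1500), 1.2)
  expect_equal(pulse_value(sch, 1, 1400), 1.2)   # closed at the start
  expect_equal(pulse_value(sch, 1, 2000), 0)     # open at the end
  expect_equal(pulse_value(sch, 2, 1500), 0)     # other cells unaffected
  expect_equal(pulse_value(pulse_schedule(), 1, 10), 0)
  expect_error(pulse_schedule(1, 1, 0, -5), "durations")
  expect_error(pulse_schedule(c(1, 1), c(1, 1), c(0, 50), c(100, 100)),
               "overlap")
  # same window on two different cells is fine
  expect_silent(pulse_schedule(c(1, 2), c(1, -1), c(0, 0), c(100, 100)))
})

test_that("unperturbed simulation near a stable uniform state stays there", {
  # sigma_inh below the lower Hopf point: SUSS regime
  p <- kinetic_params(sigma_inh = 10)
  topo <- cell_topology("cyclic", 3)
  tr <- simulate_cells(p, topo, t_end = 3000)
  reg <- classify_regime(tr, window = 1500)
  expect_equal(reg$regime, "uniform_ss")
  expect_equal(reg$code, "000")
  u <- uniform_state_vector(p, topo)
  expect_equal(final_state(tr), u, tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("single cell at the computing parameters oscillates at 50.29 s", {
  tr <- simulate_cells(chem_params, cell_topology("linear", 1), t_end = 5000)
  per <- measure_period(tr, 1, "fast")
  expect_equal(per, 50.29, tolerance = 0.005)
  expect_equal(classify_regime(tr, window = 2000)$regime, "uniform_osc")
})

test_that("period measurement recovers a known synthetic period", {
  # forge a trajectory object carrying a pure sinusoid
  tt <- seq(0, 4000, 0.25)
  T0 <- 137.5
  y <- 85 + 10 * sin(2 * pi * tt / T0)
  fake <- tibble::tibble(time = tt, cell = 1L, x = 0, y = y)
  attr(fake, "times") <- tt
  attr(fake, "states") <- cbind(0 * y, y)
  attr(fake, "topology") <- cell_topology("linear", 1)
  attr(fake, "params") <- chem_params
  attr(fake, "schedule") <- pulse_schedule()
  class(fake) <- c("cell_trajectory", class(fake))
  expect_equal(measure_period(fake, 1, "fast", discard = 0, level = 80),
               T0, tolerance = 1e-3)
  expect_error(measure_period(fake, 1, "fast", discard = 3900),
               "peaks found")
})

test_that("slow mode measures an amplitude-modulation envelope", {
  tt <- seq(0, 6000, 0.25)
  Tfast <- 50; Tslow <- 400
  y <- 85 + (5 + 1 * sin(2 * pi * tt / Tslow)) * sin(2 * pi * tt / Tfast)
  fake <- tibble::tibble(time = tt, cell = 1L, x = 0, y = y)
  attr(fake, "times") <- tt
  attr(fake, "states") <- cbind(0 * y, y)
  attr(fake, "topology") <- cell_topology("linear", 1)
  attr(fake, "params") <- chem_params
  attr(fake, "schedule") <- pulse_schedule()
  class(fake) <- c("cell_trajectory", class(fake))
  expect_equal(measure_period(fake, 1, "slow", discard = 0), Tslow,
               tolerance = 0.1)
})

test_that("pattern codes binarize ADP against the uniform level", {
  y_star <- 30.66667
  expect_equal(pattern_code(c(y_star + 1, y_star - 1), y_star), "10")
  # strict inequality: exactly at threshold reads 0
  expect_equal(pattern_code(rep(y_star, 3), y_star), "000")
  expect_error(pattern_code(c(1, 2), threshold = 0))
})

test_that("the long-pulse protocol installs the two-cell Turing pattern", {
  tr <- two_cell_pattern()
  reg <- classify_regime(tr, window = 2000)
  expect_equal(reg$regime, "turing_pattern")
  expect_equal(reg$code, "10")
  fin <- final_state(tr)
  expect_equal(fin[3], 49.74, tolerance = 1e-3)   # ADP in the pulsed cell
  expect_equal(fin[4], 11.59, tolerance = 1e-3)
})

test_that("trajectories are equivariant under topology automorphisms", {
  topo <- cell_topology("cyclic", 3)
  sch <- pulse_schedule(1L, 1.2, 200, 100)
  u <- uniform_state_vector(chem_params, topo)
  s0 <- u; s0[1] <- s0[1] * 1.02
  tr <- simulate_cells(chem_params, topo, initial = s0, schedule = sch,
                       t_end = 600)
  # rotate cells by one: 1 -> 2 -> 3 -> 1
  pm <- c(2L, 3L, 1L)
  sch2 <- pulse_schedule(pm[1], 1.2, 200, 100)
  tr2 <- simulate_cells(chem_params, topo, initial = permute_state(s0, pm),
                        schedule = sch2, t_end = 600)
  st1 <- attr(tr, "states"); st2 <- attr(tr2, "states")
  perm_cols <- c(pm, 3 + pm)
  expect_equal(st2[nrow(st2), perm_cols], st1[nrow(st1), ],
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("tightening integrator tolerances leaves classifications fixed", {
  sch <- pulse_schedule(1L, 1.2, 1400, 600)
  tr1 <- simulate_cells(chem_params, lin2, schedule = sch, t_end = 4500,
                        rtol = 1e-8, atol = 1e-8)
  tr2 <- simulate_cells(chem_params, lin2, schedule = sch, t_end = 4500,
                        rtol = 5e-9, atol = 5e-9)
  expect_equal(classify_regime(tr1)$code, classify_regime(tr2)$code)
  one1 <- simulate_cells(chem_params, cell_topology("linear", 1),
                         t_end = 4000, rtol = 1e-8, atol = 1e-8)
  one2 <- simulate_cells(chem_params, cell_topology("linear", 1),
                         t_end = 4000, rtol = 5e-9, atol = 5e-9)
  expect_equal(measure_period(one1, 1, "fast"), measure_period(one2, 1, "fast"),
               tolerance = 1e-3)
})

test_that("a stable enumerated pattern persists under simulation", {
  st <- cyc3_states()
  s <- st$state[[which(st$stable & st$symmetry == "symmetric_nonuniform")[1]]]
  tr <- simulate_cells(chem_params, cyc3, initial = s, t_end = 10000,
                       sample_dt = 1)
  expect_lt(max(abs(final_state(tr) - s)), 1e-5)
})
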