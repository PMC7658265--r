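test_that("tautology device initializes to (1, 0) and survives stress pulses", {
  td <- make_tautology_device()
  step <- td$step(td, list(), 1)
  expect_equal(step$outputs, c(one = 1L, zero = 0L))
  # the reference stress protocol: positive pulses at 3500/4500/7500 s,
  # negative at 5500/6500 s, each 100 s
  sch <- pulse_schedule(rep(1L, 5),
                        c(1.2, 1.2, -0.5, -0.5, 1.2),
                        c(3500, 4500, 5500, 6500, 7500), rep(100, 5))
  tr <- simulate_cells(chem_params, lin2, initial = td$state,
                       schedule = sch, t_end = 10000, sample_dt = 0.5)
  reg <- classify_regime(tr, window = 2000)
  expect_equal(reg$regime, "turing_pattern")
  expect_equal(reg$code, "10")
})

test_that("the pulse-length / start-time trade-off installs the pattern", {
  for (var in c(0, 500, 1000)) {
    td <- make_tautology_device(t_init = 100 + var, dT_init = 2000 - var)
    expect_equal(td$step(td, list(), 1)$outputs[["one"]], 1L)
  }
})

test_that("clock counter emits ticks at count times the period", {
  ck <- make_clock(count = 20L)
  expect_equal(ck$period, 50.29, tolerance = 0.005)
  expect_equal(ck$tick_interval, 20 * ck$period)
  expect_equal(ck$tick_interval, 1006, tolerance = 0.005)
  ck1 <- make_clock(count = 1L)
  expect_equal(ck1$tick_interval, ck1$period)
  # cross-module consistency with measure_period
  tr <- simulate_cells(chem_params, cell_topology("linear", 1), t_end = 3000)
  expect_equal(ck$tick_interval / 20, measure_period(tr, 1, "fast",
                                                     discard = 1000),
               tolerance = 0.005)
  # a non-oscillatory parameter point is rejected
  expect_error(make_clock(kinetic_params(sigma_inh = 10)), "not oscillating")
})

test_that("memory pairs store, overwrite and read idempotently", {
  m <- make_memory_pair()
  m <- memory_write(m, 1L)
  expect_equal(memory_read(m), 1L)
  s_before <- m$state
  expect_equal(memory_read(m), 1L)     # read does not disturb the state
  expect_identical(m$state, s_before)
  m <- memory_write(m, 0L)
  expect_equal(memory_read(m), 0L)
  m <- memory_write(m, 1L)
  expect_equal(memory_read(m), 1L)
  # the stored pattern persists over a long unperturbed stretch
  tr <- simulate_cells(chem_params, lin2, initial = m$state, t_end = 10000,
                       sample_dt = 1)
  expect_lt(max(abs(final_state(tr) - m$state)), 1e-5)
})

test_that("netlists validate wiring and reject cycles", {
  s1 <- make_source(1L); sk <- make_sink()
  expect_error(netlist(list(a = s1, out = sk),
                       data.frame(from = "a", from_port = "bogus",
                                  to = "out", to_port = "in")),
               "no output port")
  expect_error(netlist(list(a = s1, out = sk),
                       data.frame(from = "ghost", from_port = "out",
                                  to = "out", to_port = "in")),
               "unknown component")
  loopy <- make_nand_block()
  expect_error(netlist(list(n = loopy),
                       data.frame(from = "n", from_port = "out",
                                  to = "n", to_port = "a")),
               "cycle")
})

test_that("a NAND block computes NAND through the chemistry", {
  nb <- make_nand_block()
  net <- netlist(list(a = make_source(), b = make_source(), nand = nb,
                      out = make_sink()),
                 data.frame(from = c("a", "b", "nand"),
                            from_port = c("out", "out", "out"),
                            to = c("nand", "nand", "out"),
                            to_port = c("a", "b", "in")))
  res <- simulate_assemblage(net,
                             input_stream = data.frame(a = c(1, 1, 0, 0),
                                                       b = c(1, 0, 1, 0)),
                             cycles = 4)
  nand_bits <- res$bit[res$component == "nand"]
  expect_equal(nand_bits, c(0L, 1L, 1L, 1L))
  expect_true(is.na(attr(res, "halted")))
})

test_that("a gate array inside a netlist reproduces its standalone cycles", {
  cfg <- gate_config(knockout = c(0, 1, 1))
  ga <- make_gate_array(cfg)
  sources <- list(s1 = make_source(), s2 = make_source(), s3 = make_source())
  net <- netlist(c(sources, list(gate = ga)),
                 data.frame(from = c("s1", "s2", "s3"),
                            from_port = "out",
                            to = "gate", to_port = c("in1", "in2", "in3")))
  stream <- data.frame(s1 = c(0, 1), s2 = c(0, 0), s3 = c(0, 1))
  res <- simulate_assemblage(net, stream, cycles = 2)
  got <- vapply(1:2, function(cy) paste(
    res$bit[res$component == "gate" & res$cycle == cy], collapse = ""), "")
  ## standalone reference
  ga2 <- make_gate_array(cfg)
  r1 <- run_gate_cycle(cfg, c(0, 0, 0), ga2$state, tick = 600)
  r2 <- run_gate_cycle(cfg, c(1, 0, 1), r1$state, tick = 1600)
  expect_equal(got, c(r1$output, r2$output))
})

test_that("the tautology device supplies constant reference signals", {
  td <- make_tautology_device()
  net <- netlist(list(ref = td, sink1 = make_sink()),
                 data.frame(from = "ref", from_port = "one",
                            to = "sink1", to_port = "in"))
  res <- simulate_assemblage(net, cycles = 10)
  ones <- res$bit[res$component == "ref" & res$port == "one"]
  zeros <- res$bit[res$component == "ref" & res$port == "zero"]
  expect_equal(ones, rep(1L, 10))
  expect_equal(zeros, rep(0L, 10))
})

test_that("assemblage runs are deterministic", {
  nb <- make_nand_block()
  net <- netlist(list(a = make_source(1L), b = make_source(0L), nand = nb),
                 data.frame(from = c("a", "b"), from_port = "out",
                            to = "nand", to_port = c("a", "b")))
  r1 <- simulate_assemblage(net, cycles = 2)
  r2 <- simulate_assemblage(net, cycles = 2)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
})
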