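# Shared helpers: finite-difference oracles and small cached fixtures.

fd_jacobian <- function(state, params, topology, h = 1e-6) {
  n <- length(state)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    e <- rep(0, n); e[j] <- h * max(1, abs(state[j]))
    J[, j] <- (cell_rhs(state + e, params, topology) -
                 cell_rhs(state - e, params, topology)) / (2 * e[j])
  }
  J
}

# random admissible states around the uniform state
random_states <- function(n, params, topology, seed = 1) {
  set.seed(seed)
  ss <- uniform_steady_state(params)
  N <- topology$N
  replicate(n, c(runif(N, 0, 3 * ss$x), runif(N, 0, 3 * ss$y)),
            simplify = FALSE)
}

# computing-section parameter point and its arrays, cached across tests
chem_params <- kinetic_params()  # sigma_M = 100, sigma_inh = 35, q = 1, k_ADP = 0.1
cyc3 <- cell_topology("cyclic", 3)
lin2 <- cell_topology("linear", 2)

local_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(local_cache[[key]])) local_cache[[key]] <- force(expr)
  local_cache[[key]]
}

# stable symmetric non-uniform state of the 3-cell cyclic array
cyc3_states <- function() cached("cyc3_states",
  enumerate_states(chem_params, cyc3, n_starts = 150, seed = 42))

# the two-cell Fig-6-style pattern installation
two_cell_pattern <- function() cached("two_cell_pattern", {
  sch <- pulse_schedule(1L, 1.2, 1400, 600)
  tr <- simulate_cells(chem_params, lin2, schedule = sch, t_end = 4500)
  tr
})
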