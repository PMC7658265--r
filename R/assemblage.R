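## Cellular assemblages: ODE-backed components (gate arrays, the
## tautology/contradiction device, a clock cell with counter, two-cell
## memory pairs) wired by idealized binary channels.  Channels are
## delayed digital links; inter-component mass transfer is not
## modelled, only signals.

#' Synchronized oscillating start state
#'
#' State vector of `n_cells` identical cells sitting on the single-cell
#' limit cycle, `offset` seconds after an ADP maximum.  Used as the
#' canonical phase for pulse-installation protocols, which respond to
#' the oscillation phase at pulse onset.
#'
#' @param params a [kinetic_params()] object (oscillatory regime).
#' @param n_cells number of cells.
#' @param offset phase offset past the ADP peak (s).
#' @return Numeric state vector of length `2 * n_cells`.
#' @export
synced_cycle_state <- function(params, n_cells = 2L, offset = 11) {
  topo1 <- cell_topology("linear", 1)
  tr <- simulate_cells(params, topo1, t_end = 3000, sample_dt = 0.5)
  tt <- traj_times(tr)
  st <- traj_states(tr)
  sel <- tt > 2400
  pk <- find_peaks(tt[sel], st[sel, 2], 80)
  if (!nrow(pk)) stop("cell is not oscillating; no reference peak",
                      call. = FALSE)
  t_ic <- pk$time[1L] + offset
  s1 <- st[which.min(abs(tt - t_ic)), ]
  c(rep(s1[1L], n_cells), rep(s1[2L], n_cells))
}

new_component <- function(kind, ports_in, ports_out, state, step, extra = list()) {
  structure(c(list(kind = kind, ports_in = ports_in, ports_out = ports_out,
                   state = state, step = step), extra),
            class = "assemblage_component")
}

#' @export
print.assemblage_component <- function(x, ...) {
  cat(sprintf("<component:%s> in: %s; out: %s\n", x$kind,
              paste(x$ports_in, collapse = ","),
              paste(x$ports_out, collapse = ",")))
  invisible(x)
}

#' Tautology / contradiction device
#'
#' A two-cell array locked into the robust (1, 0) discrete Turing
#' pattern by the long single-cell pulse protocol (duration `dT_init`
#' starting at `t_init`; the defaults are the reference protocol, and
#' any combination on the trade-off line `dT_init = 2000 - var`,
#' `t_init = 100 + var` works as well).  After initialization the
#' device emits constant 1 on port `"one"` (first cell) and constant 0
#' on port `"zero"` (second cell).
#'
#' @param params a [kinetic_params()] object (two-cell coexistence
#'   region).
#' @param amplitude initialization pulse amplitude.
#' @param t_init,dT_init pulse start and duration (s).
#' @param settle extra relaxation time after the pulse (s).
#' @return An `assemblage_component`; errors if the protocol fails to
#'   install the pattern.
#' @export
make_tautology_device <- function(params = kinetic_params(),
                                  amplitude = 1.2, t_init = 1400,
                                  dT_init = 600, settle = 2500) {
  topo <- cell_topology("linear", 2)
  ## canonical start: both cells synchronized on the oscillation cycle,
  ## 11 s past an ADP maximum.  The protocol is phase-sensitive; this
  ## phase admits the whole dT_init/t_init trade-off line (calibration
  ## in inst/scripts/calibrate-gate.R).
  s0 <- synced_cycle_state(params, n_cells = 2L, offset = 11)
  sch <- pulse_schedule(1L, amplitude, t_init, dT_init)
  tr <- simulate_cells(params, topo, initial = s0,
                       schedule = sch, t_end = t_init + dT_init + settle)
  reg <- classify_regime(tr, window = min(2000, settle - 100))
  if (!identical(reg$regime, "turing_pattern") || !identical(reg$code, "10"))
    stop("tautology initialization failed: regime ", reg$regime,
         ", code ", reg$code, call. = FALSE)
  new_component("tautology_device", character(), c("one", "zero"),
                state = final_state(tr),
                step = function(comp, inputs, cycle)
                  list(comp = comp, outputs = c(one = 1L, zero = 0L)),
                extra = list(params = params, topology = topo))
}

#' Clock component: oscillating cell plus counter
#'
#' A single cell left in its oscillatory regime; a counter accumulates
#' oscillation peaks and emits a tick pulse every `count` peaks, then
#' resets.  The emitted tick interval is `count` times the oscillation
#' period.
#'
#' @param params single-cell parameters in the oscillatory region.
#' @param count peaks per tick (20 in the reference design).
#' @return An `assemblage_component` with port `"tick"` and fields
#'   `period` and `tick_interval`; errors if the cell is not
#'   oscillating.
#' @export
make_clock <- function(params = kinetic_params(), count = 20L) {
  topo <- cell_topology("linear", 1)
  tr <- simulate_cells(params, topo, t_end = 3000)
  reg <- classify_regime(tr, window = 1000)
  if (!reg$regime %in% c("uniform_osc", "nonuniform_osc"))
    stop("clock cell is not oscillating (regime ", reg$regime, ")",
         call. = FALSE)
  period <- measure_period(tr, 1L, "fast", discard = 1000, min_cycles = 5L)
  new_component("clock_cell", character(), "tick",
                state = final_state(tr),
                step = function(comp, inputs, cycle)
                  list(comp = comp, outputs = c(tick = 1L)),
                extra = list(params = params, period = period, count = count,
                             tick_interval = count * period))
}

#' Two-cell memory pair
#'
#' Stores one bit as the orientation of the two-cell Turing pattern:
#' writing applies the |1 0| (bit 1) or |0 1| (bit 0) pulse pair and
#' relaxes; reading decodes cell 1's pattern bit without disturbing the
#' state.  The stored pattern persists indefinitely between writes.
#'
#' @param params two-cell parameters in the coexistence region.
#' @param on,off write pulse amplitudes.
#' @param dT write pulse duration (s).
#' @param settle relaxation after a write (s).
#' @return An `assemblage_component` with input port `"write"` and
#'   output port `"read"`.
#' @export
make_memory_pair <- function(params = kinetic_params(), on = 1.2,
                             off = -1.0, dT = 100, settle = 2400) {
  topo <- cell_topology("linear", 2)
  s0 <- uniform_state_vector(params, topo)
  s0[1L] <- s0[1L] * 1.01
  comp <- new_component("memory_pair", "write", "read", state = s0,
                        step = NULL,
                        extra = list(params = params, topology = topo,
                                     on = on, off = off, dT = dT,
                                     settle = settle))
  comp$step <- function(comp, inputs, cycle) {
    if (!is.null(inputs$write) && !is.na(inputs$write))
      comp <- memory_write(comp, inputs$write)
    list(comp = comp, outputs = c(read = memory_read(comp)))
  }
  comp
}

#' @rdname make_memory_pair
#' @param pair a memory-pair component.
#' @param bit 0 or 1.
#' @return `memory_write` returns the updated component; `memory_read`
#'   returns the stored bit (reading does not change the state).
#' @export
memory_write <- function(pair, bit) {
  stopifnot(identical(pair$kind, "memory_pair"), bit %in% 0:1)
  amps <- if (bit == 1L) c(pair$on, pair$off) else c(pair$off, pair$on)
  sch <- pulse_schedule(c(1L, 2L), amps, c(0, 0), c(pair$dT, pair$dT))
  tr <- simulate_cells(pair$params, pair$topology, initial = pair$state,
                       schedule = sch, t_end = pair$dT + pair$settle)
  reg <- classify_regime(tr, window = 1500)
  if (!identical(reg$regime, "turing_pattern"))
    stop("memory write did not settle into a pattern (", reg$regime, ")",
         call. = FALSE)
  pair$state <- final_state(tr)
  pair
}

#' @rdname make_memory_pair
#' @export
memory_read <- function(pair) {
  stopifnot(identical(pair$kind, "memory_pair"))
  y_star <- pair$params$phi * pair$params$nu / pair$params$k_s
  as.integer(pair$state[3L] > y_star)
}

#' Gate-array component
#'
#' Wraps a [gate_config()] as an assemblage component: input ports
#' `in1..inN` (one per cell), output ports `out1..outN` (pattern bits
#' at the cycle's read time).  Each netlist cycle runs one full
#' knockout clock cycle of ODE simulation.
#'
#' @param config a [gate_config()].
#' @param warmup oscillation warm-up time before the first cycle (s).
#' @return An `assemblage_component`.
#' @export
make_gate_array <- function(config, warmup = NULL) {
  N <- config$topology$N
  if (is.null(warmup)) warmup <- config$clock_offset + config$input_delay
  s <- uniform_state_vector(config$params, config$topology)
  s[1L] <- s[1L] * 1.01
  sol <- gate_segment(s, 0, warmup, numeric(N), config)
  new_component("gate_array",
                paste0("in", seq_len(N)), paste0("out", seq_len(N)),
                state = sol[nrow(sol), -1L],
                step = function(comp, inputs, cycle) {
                  word <- vapply(paste0("in", seq_len(N)), function(p) {
                    v <- inputs[[p]]
                    if (is.null(v)) NA_integer_ else as.integer(v)
                  }, integer(1))
                  if (anyNA(word))
                    return(list(comp = comp,
                                outputs = stats::setNames(rep(NA_integer_, N),
                                                          comp$ports_out)))
                  tick <- comp$config$clock_period * (cycle - 1L) +
                    comp$config$clock_offset
                  res <- run_gate_cycle(comp$config, word, comp$state, tick)
                  comp$state <- res$state
                  list(comp = comp,
                       outputs = stats::setNames(res$bits, comp$ports_out))
                },
                extra = list(config = config))
}

#' Constant-source and sink components
#'
#' A source emits a per-cycle bit taken from the assemblage input
#' stream (or a fixed bit); a sink records whatever arrives.
#'
#' @param bit fixed bit, or `NULL` to read from the input stream column
#'   named after the component.
#' @return An `assemblage_component`.
#' @export
make_source <- function(bit = NULL) {
  new_component("source", character(), "out", state = NULL,
                step = function(comp, inputs, cycle) {
                  v <- if (!is.null(comp$bit)) comp$bit else inputs[["stream"]]
                  list(comp = comp, outputs = c(out = as.integer(v)))
                },
                extra = list(bit = bit))
}

#' @rdname make_source
#' @export
make_sink <- function() {
  new_component("sink", "in", character(), state = NULL,
                step = function(comp, inputs, cycle)
                  list(comp = comp, outputs = integer()))
}

#' Assemble components into a netlist
#'
#' @param components named list of `assemblage_component`s.
#' @param links data frame with columns `from`, `from_port`, `to`,
#'   `to_port` and optionally `delay` (s, informational) and `blocked`
#'   (logical knockout switch).
#' @return A validated `netlist` object.  Validation requires the link
#'   graph to be acyclic (signals flow forward within a cycle) and
#'   every referenced component and port to exist.
#' @export
netlist <- function(components, links) {
  stopifnot(is.list(components), length(names(components)) == length(components))
  links <- tibble::as_tibble(links)
  if (!"delay" %in% names(links)) links$delay <- 0
  if (!"blocked" %in% names(links)) links$blocked <- FALSE
  for (i in seq_len(nrow(links))) {
    f <- links$from[i]; t <- links$to[i]
    if (!f %in% names(components)) stop("unknown component '", f, "'", call. = FALSE)
    if (!t %in% names(components)) stop("unknown component '", t, "'", call. = FALSE)
    if (!links$from_port[i] %in% components[[f]]$ports_out)
      stop("component '", f, "' has no output port '", links$from_port[i], "'",
           call. = FALSE)
    if (!links$to_port[i] %in% components[[t]]$ports_in)
      stop("component '", t, "' has no input port '", links$to_port[i], "'",
           call. = FALSE)
  }
  ## topological order (acyclic requirement)
  deps <- lapply(names(components), function(nm)
    unique(links$from[links$to == nm]))
  names(deps) <- names(components)
  order <- character()
  remaining <- names(components)
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(nm)
      all(deps[[nm]] %in% order), logical(1))]
    if (!length(ready))
      stop("netlist has a cycle within one clock interval", call. = FALSE)
    order <- c(order, ready)
    remaining <- setdiff(remaining, ready)
  }
  structure(list(components = components, links = links, order = order),
            class = "netlist")
}

#' Cycle-synchronous co-simulation of an assemblage
#'
#' Each clock cycle, components are evaluated in topological order:
#' sources read the input stream, every gate array runs one full
#' knockout ODE cycle on its input word, and links transmit the
#' resulting bits (blocked links transmit nothing).  An unresolved
#' component output propagates as `NA` and halts the run with a
#' cycle-stamped report attached.
#'
#' @param net a [netlist()].
#' @param input_stream data frame of per-cycle source bits; column
#'   names match source component names (recycled if shorter than
#'   `cycles`).
#' @param cycles number of clock cycles.
#' @return A tibble (`cycle`, `component`, `port`, `bit`) of all port
#'   values; attribute `halted` gives the halt cycle or `NA`.
#' @export
simulate_assemblage <- function(net, input_stream = NULL, cycles = 1L) {
  stopifnot(inherits(net, "netlist"))
  comps <- net$components
  rows <- list()
  halted <- NA_integer_
  for (cyc in seq_len(cycles)) {
    port_values <- list()
    for (nm in net$order) {
      comp <- comps[[nm]]
      inputs <- list()
      if (comp$kind == "source" && is.null(comp$bit)) {
        col <- input_stream[[nm]]
        if (is.null(col)) stop("no input stream for source '", nm, "'",
                               call. = FALSE)
        inputs$stream <- col[((cyc - 1L) %% length(col)) + 1L]
      }
      lk <- net$links[net$links$to == nm & !net$links$blocked, ]
      for (i in seq_len(nrow(lk)))
        inputs[[lk$to_port[i]]] <-
          port_values[[paste0(lk$from[i], ".", lk$from_port[i])]]
      res <- comp$step(comp, inputs, cyc)
      comps[[nm]] <- res$comp
      for (p in names(res$outputs)) {
        port_values[[paste0(nm, ".", p)]] <- res$outputs[[p]]
        rows[[length(rows) + 1L]] <- tibble::tibble(
          cycle = cyc, component = nm, port = p,
          bit = as.integer(res$outputs[[p]]))
      }
      if (length(res$outputs) && anyNA(res$outputs)) halted <- cyc
    }
    if (!is.na(halted)) break
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "halted") <- halted
  attr(out, "components") <- comps
  out
}

#' Two-stage NAND block
#'
#' Computes NAND of two bits with chemistry: an AND stage (three-cell
#' cyclic gate with knockout \{0 1 1\}, third input tied to 0, read at
#' cell 1, whose gate function reduces to `A1 & A2`) followed by an
#' inverter stage (knockout \{1 0 1\} gate with cells 1 and 2 tied to
#' 1, read at cell 2, reducing to `!A3`).  Both stages run a full
#' knockout cycle back to back within one netlist cycle (the block owns
#' an internal clock phase for its second array).
#'
#' @param params array parameters.
#' @return An `assemblage_component` with ports `a`, `b` (in) and
#'   `out`.
#' @export
make_nand_block <- function(params = kinetic_params()) {
  topo <- cell_topology("cyclic", 3)
  cfg_and <- gate_config(params, topo, knockout = c(0, 1, 1))
  cfg_not <- gate_config(params, topo, knockout = c(1, 0, 1))
  g_and <- make_gate_array(cfg_and)
  g_not <- make_gate_array(cfg_not)
  new_component("gate_array", c("a", "b"), "out", state = NULL,
                step = function(comp, inputs, cycle) {
                  a <- inputs$a; b <- inputs$b
                  if (is.null(a) || is.null(b) || is.na(a) || is.na(b))
                    return(list(comp = comp, outputs = c(out = NA_integer_)))
                  r1 <- comp$g_and$step(comp$g_and,
                                        list(in1 = a, in2 = b, in3 = 0L), cycle)
                  comp$g_and <- r1$comp
                  and_bit <- r1$outputs[["out1"]]
                  r2 <- comp$g_not$step(comp$g_not,
                                        list(in1 = 1L, in2 = 1L,
                                             in3 = and_bit), cycle)
                  comp$g_not <- r2$comp
                  list(comp = comp, outputs = c(out = r2$outputs[["out2"]]))
                },
                extra = list(g_and = g_and, g_not = g_not))
}
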