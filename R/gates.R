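#' Configuration of a central-knockout logic gate
#'
#' An array of coupled cells parameterised into the coexistence region
#' operates as a logic gate under the central knockout perturbation
#' system: a global clock ticks at `t_k = clock_period * k +
#' clock_offset`; the input word is applied as ATP pulses
#' `input_delay` seconds before each tick (bit 1 pulses with
#' `input_on`, bit 0 with `input_off`, duration `dT`); after the tick,
#' if any cell's ADP exceeds the receptor level (the array is
#' oscillating), the knockout pulses fire at the first receptor event,
#' writing the gate's base pattern; outputs are decoded
#' `output_delay` seconds after the tick as the ADP pattern code.
#'
#' The pulse amplitudes default to the calibrated values for the cyclic
#' arrays (`+1.2` for bit 1, `-1.0` for bit 0; see the package
#' vignette for the calibration protocol).
#'
#' @param params,topology model configuration (defaults: the
#'   chemical-computing parameter point).
#' @param knockout integer 0/1 vector of length N: the knockout word.
#' @param input_on,input_off input pulse amplitudes for bits 1 / 0.
#' @param knockout_on,knockout_off knockout pulse amplitudes.
#' @param dT pulse duration (s).
#' @param clock_period,clock_offset clock ticks at
#'   `clock_period * k + clock_offset` (s).
#' @param input_delay input pulses start this long before a tick (s,
#'   negative offset).
#' @param output_delay outputs are read this long after a tick (s).
#' @param receptor_level ADP level above which the per-cell receptor
#'   reports oscillations.
#' @return A `gate_config` object.
#' @export
gate_config <- function(params = kinetic_params(),
                        topology = cell_topology("cyclic", 3),
                        knockout,
                        input_on = 1.2, input_off = -1.0,
                        knockout_on = 1.2, knockout_off = -1.0,
                        dT = 100, clock_period = 1000, clock_offset = 600,
                        input_delay = -100, output_delay = 900,
                        receptor_level = 80) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(topology, "cell_topology"))
  knockout <- as.integer(knockout)
  if (length(knockout) != topology$N || !all(knockout %in% 0:1))
    stop("'knockout' must be a 0/1 word of length N", call. = FALSE)
  if (dT <= 0) stop("'dT' must be positive", call. = FALSE)
  if (abs(input_delay) >= clock_period || output_delay >= clock_period)
    stop("delays must fit within one clock interval", call. = FALSE)
  structure(list(params = params, topology = topology, knockout = knockout,
                 input_on = input_on, input_off = input_off,
                 knockout_on = knockout_on, knockout_off = knockout_off,
                 dT = dT, clock_period = clock_period,
                 clock_offset = clock_offset, input_delay = input_delay,
                 output_delay = output_delay,
                 receptor_level = receptor_level),
            class = "gate_config")
}

#' @export
print.gate_config <- function(x, ...) {
  cat(sprintf("<gate_config> %s array of %d cells, knockout {%s}\n",
              x$topology$kind, x$topology$N,
              paste(x$knockout, collapse = " ")))
  cat(sprintf("  pulses: on %+g / off %+g, dT = %g s; receptor > %g\n",
              x$input_on, x$input_off, x$dT, x$receptor_level))
  invisible(x)
}

bits_to_amps <- function(bits, on, off) ifelse(bits == 1L, on, off)

## integrate one segment, returning final state (wide, no tibble cost)
gate_segment <- function(state, t0, t1, pulse, config, sample_dt = 0.5,
                         rtol = 1e-8) {
  deriv <- function(t, s, p) list(cell_rhs(s, config$params, config$topology, p))
  tseq <- unique(c(seq(t0, t1, by = sample_dt), t1))
  sol <- deSolve::ode(y = state, times = tseq, func = deriv, parms = pulse,
                      method = "lsoda", rtol = rtol, atol = rtol,
                      maxsteps = 50000)
  if (attr(sol, "istate")[1L] < 0)
    stop("gate integration failed near t = ", sol[nrow(sol), 1L], call. = FALSE)
  sol
}

#' Run one clock cycle of a gate
#'
#' Starting from `state` at time `tick + input_delay`, applies the
#' input-word pulses, monitors the receptor from the tick onward, fires
#' the knockout pulses at the first receptor event (only if the array
#' is oscillating), and decodes the output at `tick + output_delay`.
#'
#' @param config a [gate_config()].
#' @param input_word integer 0/1 vector of length N.
#' @param state stacked state vector at the start of the cycle.
#' @param tick absolute time of this cycle's clock tick (s).
#' @param rtol integrator tolerance.
#' @return A list with `output` (bit string, or `NA` if unresolved),
#'   `bits` (integer vector), `state` (state at the read time),
#'   `knockout_time` (`NA` if the knockout did not fire), and
#'   `resolved` (logical).
#' @export
run_gate_cycle <- function(config, input_word, state, tick = NULL,
                           rtol = 1e-8) {
  N <- config$topology$N
  input_word <- as.integer(input_word)
  stopifnot(length(input_word) == N, all(input_word %in% 0:1))
  if (is.null(tick)) tick <- config$clock_offset
  t_in <- tick + config$input_delay
  t_read <- tick + config$output_delay
  ## input pulses
  sol <- gate_segment(state, t_in, t_in + config$dT,
                      bits_to_amps(input_word, config$input_on,
                                   config$input_off), config, rtol = rtol)
  s <- sol[nrow(sol), -1L]
  t_cur <- t_in + config$dT
  ## free run with receptor monitoring from the tick
  sol <- gate_segment(s, t_cur, t_read, numeric(N), config, rtol = rtol)
  tt <- sol[, 1L]
  ymax <- apply(sol[, 1L + N + seq_len(N), drop = FALSE], 1L, max)
  hit <- which(tt >= tick & ymax > config$receptor_level)
  ko_time <- NA_real_
  if (length(hit)) {
    ko_time <- tt[hit[1L]]
    s <- sol[hit[1L], -1L]
    ko_end <- min(ko_time + config$dT, t_read)
    sol <- gate_segment(s, ko_time, ko_end,
                        bits_to_amps(config$knockout, config$knockout_on,
                                     config$knockout_off), config, rtol = rtol)
    s <- sol[nrow(sol), -1L]
    if (ko_end < t_read)
      sol <- gate_segment(s, ko_end, t_read, numeric(N), config, rtol = rtol)
  }
  ## resolution check over the last 150 s before the read
  tt <- sol[, 1L]
  tail_sel <- tt >= t_read - 150
  ytail <- sol[tail_sel, 1L + N + seq_len(N), drop = FALSE]
  p2p <- max(apply(ytail, 2L, function(v) diff(range(v))))
  s <- sol[nrow(sol), -1L]
  resolved <- p2p < 1e-2
  y_star <- config$params$phi * config$params$nu / config$params$k_s
  bits <- as.integer(s[N + seq_len(N)] > y_star)
  list(output = if (resolved) paste(bits, collapse = "") else NA_character_,
       bits = if (resolved) bits else rep(NA_integer_, N),
       state = s, knockout_time = ko_time, resolved = resolved)
}

## printed input order of the three-cell tables; binary order otherwise
gate_input_words <- function(N) {
  if (N == 3L)
    rbind(c(0, 1, 1), c(1, 0, 0), c(0, 0, 1), c(0, 1, 0),
          c(1, 0, 1), c(1, 1, 0), c(0, 0, 0), c(1, 1, 1))
  else all_input_words(N)
}

#' Simulate the full truth table of a gate
#'
#' Runs every input word for one clock cycle each, consecutive cycles
#' chained on the clock (each cycle starts from the previous cycle's
#' final state), exactly as in the reference dynamic simulations.  The
#' run starts from uniform oscillations established before the first
#' input.
#'
#' @param config a [gate_config()].
#' @param words optional input-word matrix (rows); defaults to the
#'   printed order for three cells and binary order otherwise.
#' @param infer also infer minimal matching Boolean expressions per
#'   cell (may be slow for N > 3).
#' @param rtol integrator tolerance.
#' @return A `truth_table` object: a tibble with columns `A1..AN`
#'   (inputs), `y1..yN` (output bits), `output` (bit string),
#'   `knockout_time`, `resolved`; attribute `expressions` holds the
#'   inferred per-cell expressions when `infer = TRUE`.
#' @export
truth_table <- function(config, words = NULL, infer = FALSE, rtol = 1e-8) {
  N <- config$topology$N
  if (is.null(words)) words <- gate_input_words(N)
  ## establish uniform oscillations before the first input
  s <- uniform_state_vector(config$params, config$topology)
  s[1L] <- s[1L] * 1.01
  t_first_in <- config$clock_offset + config$input_delay
  sol <- gate_segment(s, 0, t_first_in, numeric(N), config, rtol = rtol)
  s <- sol[nrow(sol), -1L]
  rows <- list()
  for (k in seq_len(nrow(words))) {
    tick <- config$clock_period * (k - 1L) + config$clock_offset
    res <- run_gate_cycle(config, words[k, ], s, tick, rtol = rtol)
    ## advance to the next cycle's input time
    t_next_in <- tick + config$clock_period + config$input_delay
    t_read <- tick + config$output_delay
    if (t_next_in > t_read) {
      sol <- gate_segment(res$state, t_read, t_next_in, numeric(N), config,
                          rtol = rtol)
      s <- sol[nrow(sol), -1L]
    } else s <- res$state
    row <- c(as.list(words[k, ]), as.list(res$bits))
    names(row) <- c(paste0("A", seq_len(N)), paste0("y", seq_len(N)))
    rows[[k]] <- tibble::as_tibble(row)
    rows[[k]]$output <- res$output
    rows[[k]]$knockout_time <- res$knockout_time
    rows[[k]]$resolved <- res$resolved
  }
  tb <- dplyr::bind_rows(rows)
  exprs <- NULL
  if (infer && all(tb$resolved)) {
    ymat <- as.matrix(tb[, paste0("y", seq_len(N))])
    exprs <- vapply(seq_len(N), function(i)
      infer_expression(ymat[, i], words), "")
  }
  structure(tb, class = c("truth_table", class(tb)),
            config = config, expressions = exprs,
            flagged = !all(tb$resolved))
}

#' Check a simulated truth table against Boolean expressions
#'
#' @param table a [truth_table()].
#' @param exprs character vector of N expression strings (per cell).
#' @return A list with `match` (logical), `mismatches` (tibble of
#'   `row`, `cell`, `expected`, `got`) and `per_cell` (logical vector).
#' @export
verify_table <- function(table, exprs) {
  N <- attr(table, "config")$topology$N
  stopifnot(length(exprs) == N)
  words <- as.matrix(table[, paste0("A", seq_len(N))])
  ymat <- as.matrix(table[, paste0("y", seq_len(N))])
  mism <- list()
  per_cell <- logical(N)
  for (i in seq_len(N)) {
    expect <- boolean_truth_vector(exprs[i], N, words)
    ok <- expect == ymat[, i]
    per_cell[i] <- all(ok, na.rm = FALSE) && !anyNA(ok)
    bad <- which(!ok | is.na(ok))
    for (r in bad)
      mism[[length(mism) + 1L]] <- tibble::tibble(
        row = r, cell = i, expected = expect[r], got = ymat[r, i])
  }
  list(match = !length(mism), per_cell = per_cell,
       mismatches = if (length(mism)) dplyr::bind_rows(mism)
       else tibble::tibble(row = integer(), cell = integer(),
                           expected = integer(), got = integer()))
}

#' @export
print.truth_table <- function(x, ...) {
  N <- attr(x, "config")$topology$N
  cat(sprintf("<truth_table> %d-cell gate, knockout {%s}\n", N,
              paste(attr(x, "config")$knockout, collapse = " ")))
  print(tibble::as_tibble(x[, c(paste0("A", seq_len(N)),
                                paste0("y", seq_len(N)))]), n = nrow(x))
  ex <- attr(x, "expressions")
  if (!is.null(ex))
    cat("inferred:", paste(ex, collapse = " ; "), "\n")
  invisible(x)
}

#' Summary statistics of a truth table
#'
#' @param x a `truth_table`.
#' @param ... unused.
#' @return One-row tibble: number of rows, resolved rows, number of
#'   knockout firings, and distinct output patterns.
#' @export
glance.truth_table <- function(x, ...) {
  tibble::tibble(n_rows = nrow(x),
                 n_resolved = sum(x$resolved),
                 n_knockouts = sum(!is.na(x$knockout_time)),
                 n_patterns = length(unique(stats::na.omit(x$output))))
}

#' @export
tidy.truth_table <- function(x, ...) {
  tibble::as_tibble(x)
}
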