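#' Integrate the coupled-cell model under a perturbation schedule
#'
#' Solves the coupled-cell equations with the stiff `lsoda` integrator,
#' restarting the integration at every pulse on/off boundary so that the
#' piecewise-constant perturbation discontinuities are handled exactly.
#' Concentrations are physically non-negative; the integration aborts
#' with a diagnostic if a component drops below `-1e-9` (this can only
#' happen under strong negative pulses).
#'
#' @param params a [kinetic_params()] object.
#' @param topology a [cell_topology()] object.
#' @param initial initial state: numeric vector `c(x, y)` of length 2N,
#'   or `NULL` for the uniform stationary state with a 1 percent ATP
#'   perturbation of cell 1 (the conventional start for oscillatory
#'   runs).
#' @param schedule a [pulse_schedule()] (default: empty).
#' @param t_end final time (s).
#' @param t_start initial time (s, default 0).
#' @param sample_dt output sampling interval (s).
#' @param rtol,atol integrator tolerances.
#' @return A `cell_trajectory` object: a tibble with columns `time`,
#'   `cell`, `x`, `y` (long format), carrying the run configuration and
#'   the wide state matrix as attributes.  `events` attribute lists the
#'   pulse boundaries.
#' @examples
#' topo <- cell_topology("linear", 1)
#' tr <- simulate_cells(kinetic_params(), topo, t_end = 200)
#' head(tr)
#' @export
simulate_cells <- function(params, topology, initial = NULL,
                           schedule = pulse_schedule(), t_end,
                           t_start = 0, sample_dt = 0.25,
                           rtol = 1e-8, atol = 1e-8) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(topology, "cell_topology"))
  schedule <- as_pulse_schedule(schedule)
  N <- topology$N
  if (is.null(initial)) {
    initial <- uniform_state_vector(params, topology)
    initial[1L] <- initial[1L] * 1.01
  }
  if (t_end <= t_start) stop("'t_end' must exceed 't_start'", call. = FALSE)
  if (any(schedule$cell > N))
    stop("schedule targets a cell outside the array", call. = FALSE)

  deriv <- function(t, s, pulse) list(cell_rhs(s, params, topology, pulse))
  breaks <- schedule_breaks(schedule, t_start, t_end)
  times_all <- numeric(0)
  states_all <- NULL
  s <- initial
  for (k in seq_len(length(breaks) - 1L)) {
    a <- breaks[k]; b <- breaks[k + 1L]
    pulse <- schedule_pulse_vector(schedule, N, a, b)
    tseq <- unique(c(seq(a, b, by = sample_dt), b))
    sol <- deSolve::ode(y = s, times = tseq, func = deriv, parms = pulse,
                        method = "lsoda", rtol = rtol, atol = atol,
                        maxsteps = 50000)
    if (attr(sol, "istate")[1L] < 0)
      stop(sprintf("integration failed in segment [%.6g, %.6g]; last good time %.6g",
                   a, b, sol[nrow(sol), 1L]), call. = FALSE)
    smat <- sol[, -1L, drop = FALSE]
    if (min(smat) < -1e-9)
      stop(sprintf("state went negative (min %.3g) near t = %.6g; reduce pulse magnitude",
                   min(smat), sol[which(smat < -1e-9, arr.ind = TRUE)[1, 1], 1L]),
           call. = FALSE)
    keep <- if (k > 1L) -1L else seq_len(nrow(sol))  # drop duplicated boundary row
    times_all <- c(times_all, sol[keep, 1L])
    states_all <- rbind(states_all, smat[keep, , drop = FALSE])
    s <- smat[nrow(smat), ]
  }

  tb <- tibble::tibble(
    time = rep(times_all, times = N),
    cell = rep(seq_len(N), each = length(times_all)),
    x = as.vector(states_all[, seq_len(N)]),
    y = as.vector(states_all[, N + seq_len(N)]))
  structure(tb,
            class = c("cell_trajectory", class(tb)),
            params = params, topology = topology, schedule = schedule,
            times = times_all, states = states_all,
            events = breaks[-c(1L, length(breaks))])
}

## wide state matrix accessors
traj_times <- function(traj) attr(traj, "times")
traj_states <- function(traj) attr(traj, "states")
traj_N <- function(traj) attr(traj, "topology")$N

#' Final state of a trajectory
#'
#' @param traj a `cell_trajectory`.
#' @return Numeric vector `c(x, y)` at the last sample.
#' @export
final_state <- function(traj) {
  st <- traj_states(traj)
  unname(st[nrow(st), ])
}

#' Classify the asymptotic regime of a trajectory
#'
#' Inspects a tail window of the trajectory (after the last pulse) and
#' classifies it as a stable uniform stationary state (`uniform_ss`), a
#' discrete Turing pattern (`turing_pattern`: stationary but spatially
#' non-uniform), uniform oscillations (`uniform_osc`), non-uniform
#' oscillations (`nonuniform_osc`), or `unresolved` when the available
#' tail is shorter than `window`.
#'
#' "Stationary" means every cell's peak-to-peak ADP excursion over the
#' window stays below `eps_stat`; "uniform" means the maximal relative
#' inter-cell deviation stays below `eps_unif`.
#'
#' @param traj a `cell_trajectory`.
#' @param window tail window length (s).
#' @param eps_stat absolute peak-to-peak threshold for stationarity.
#' @param eps_unif relative inter-cell deviation threshold for
#'   uniformity.
#' @return A one-row tibble: `regime`, `stationary`, `uniform`,
#'   `max_p2p`, `max_dev`, `code` (pattern bit string; `NA` unless
#'   stationary).
#' @export
classify_regime <- function(traj, window = 2000, eps_stat = 1e-3,
                            eps_unif = 1e-3) {
  tt <- traj_times(traj)
  st <- traj_states(traj)
  N <- traj_N(traj)
  sch <- attr(traj, "schedule")
  t_tail0 <- max(tt) - window
  last_pulse <- if (nrow(sch)) max(sch$start + sch$duration) else -Inf
  if (t_tail0 < last_pulse || t_tail0 < tt[1L])
    return(tibble::tibble(regime = "unresolved", stationary = NA,
                          uniform = NA, max_p2p = NA_real_,
                          max_dev = NA_real_, code = NA_character_))
  sel <- tt >= t_tail0
  ymat <- st[sel, N + seq_len(N), drop = FALSE]
  xmat <- st[sel, seq_len(N), drop = FALSE]
  p2p <- apply(ymat, 2L, function(v) diff(range(v)))
  stationary <- max(p2p) < eps_stat
  scale <- pmax(rowMeans(ymat), 1e-12)
  dev_y <- max(abs(ymat - rowMeans(ymat)) / scale)
  scale_x <- pmax(rowMeans(xmat), 1e-12)
  dev_x <- max(abs(xmat - rowMeans(xmat)) / scale_x)
  uniform <- max(dev_y, dev_x) < eps_unif
  regime <- if (stationary && uniform) "uniform_ss"
  else if (stationary) "turing_pattern"
  else if (uniform) "uniform_osc"
  else "nonuniform_osc"
  code <- if (stationary) {
    y_star <- uniform_steady_state(attr(traj, "params"))$y
    pattern_code(ymat[nrow(ymat), ], y_star)
  } else NA_character_
  tibble::tibble(regime = regime, stationary = stationary,
                 uniform = uniform, max_p2p = max(p2p),
                 max_dev = max(dev_y, dev_x), code = code)
}

#' Binary pattern code of an ADP profile
#'
#' Each cell is read as logic 1 when its ADP concentration strictly
#' exceeds the threshold (by default the uniform stationary level
#' `y* = phi * nu / k_s`) and logic 0 otherwise.
#'
#' @param y numeric vector of per-cell ADP values.
#' @param threshold concentration threshold (> 0).
#' @return A bit string such as `"011"`.
#' @examples
#' pattern_code(c(31, 29), threshold = 30.6667)
#' @export
pattern_code <- function(y, threshold) {
  stopifnot(threshold > 0)
  paste(as.integer(y > threshold), collapse = "")
}

## Local maxima of a sampled signal with parabolic refinement.
## Returns tibble(time, height).
find_peaks <- function(tt, yy, min_height = -Inf) {
  sg <- sign(diff(yy))
  sg[sg == 0] <- 1          # flat tops count as still rising
  i <- which(diff(sg) == -2) + 1L
  i <- i[yy[i] > min_height]
  if (!length(i)) return(tibble::tibble(time = numeric(), height = numeric()))
  a <- yy[i - 1L]; b <- yy[i]; cc <- yy[i + 1L]
  denom <- a - 2 * b + cc
  d <- ifelse(abs(denom) > 0, (a - cc) / (2 * denom), 0)
  tibble::tibble(time = tt[i] + d * (tt[i + 1L] - tt[i]),
                 height = b - 0.25 * (a - cc) * d)
}

#' Measure the oscillation period of a trajectory
#'
#' `mode = "fast"` returns the mean peak-to-peak interval of the
#' large-amplitude ADP maxima of one cell (peaks above `level`, refined
#' by local quadratic interpolation).  `mode = "slow"` measures the
#' period of the envelope modulation: the sequence of successive peak
#' heights is treated as a slow signal and the mean spacing of its local
#' extrema (doubled half-period) is returned.
#'
#' @param traj a `cell_trajectory`.
#' @param cell cell index (default 1).
#' @param mode `"fast"` or `"slow"`.
#' @param discard initial transient to drop (s).
#' @param level amplitude threshold separating large-amplitude peaks
#'   (the receptor level 80 by default).
#' @param min_cycles minimum number of cycles required.
#' @return Period in seconds.
#' @export
measure_period <- function(traj, cell = 1L, mode = c("fast", "slow"),
                           discard = 2000, level = 80, min_cycles = 5L) {
  mode <- match.arg(mode)
  tt <- traj_times(traj)
  st <- traj_states(traj)
  N <- traj_N(traj)
  sel <- tt >= tt[1L] + discard
  yy <- st[sel, N + cell]
  ts <- tt[sel]
  pk <- find_peaks(ts, yy, min_height = if (mode == "fast") level else -Inf)
  if (mode == "fast") {
    if (nrow(pk) < min_cycles + 1L)
      stop("only ", nrow(pk), " large-amplitude peaks found; need at least ",
           min_cycles + 1L, call. = FALSE)
    return(mean(diff(pk$time)))
  }
  ## slow mode: envelope of successive maxima
  if (nrow(pk) < 3L * min_cycles)
    stop("only ", nrow(pk), " peaks found; envelope period needs at least ",
         3L * min_cycles, call. = FALSE)
  h <- pk$height
  ex <- sort(c(which(diff(sign(diff(h))) == -2) + 1L,
               which(diff(sign(diff(h))) == 2) + 1L))
  if (length(ex) < 3L)
    stop("envelope of oscillation maxima shows no modulation extrema",
         call. = FALSE)
  2 * mean(diff(pk$time[ex]))
}
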