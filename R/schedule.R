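#' Piecewise-constant perturbation schedules
#'
#' A schedule is a tibble of rectangular ATP pulses, one row per pulse:
#' cell index, amplitude (positive = inflow, negative = outflow), start
#' time and duration.  While a pulse is active the perturbation term of
#' that cell equals the amplitude; pulses use half-open intervals
#' `[start, start + duration)`.  Pulses targeting the same cell must not
#' overlap in time.
#'
#' @param cell integer vector of target cells.
#' @param amplitude numeric vector of pulse amplitudes (dimensionless
#'   in/outflow rates; may be negative).
#' @param start numeric vector of pulse onset times (s, >= 0).
#' @param duration numeric vector of pulse lengths (s, > 0).
#' @return A tibble of class `pulse_schedule` with those four columns,
#'   ordered by start time.
#' @examples
#' pulse_schedule(cell = 1, amplitude = 1.2, start = 1400, duration = 600)
#' pulse_schedule()  # empty schedule
#' @export
pulse_schedule <- function(cell = integer(), amplitude = numeric(),
                           start = numeric(), duration = numeric()) {
  tb <- tibble::tibble(cell = as.integer(cell),
                       amplitude = as.numeric(amplitude),
                       start = as.numeric(start),
                       duration = as.numeric(duration))
  if (nrow(tb)) {
    if (any(tb$duration <= 0)) stop("pulse durations must be > 0", call. = FALSE)
    if (any(tb$start < 0)) stop("pulse starts must be >= 0", call. = FALSE)
    tb <- tb[order(tb$start), ]
    for (cl in unique(tb$cell)) {
      sub <- tb[tb$cell == cl, ]
      if (nrow(sub) > 1L &&
          any(sub$start[-1] < (sub$start + sub$duration)[-nrow(sub)] - 1e-9))
        stop("pulses on cell ", cl, " overlap in time", call. = FALSE)
    }
  }
  class(tb) <- c("pulse_schedule", class(tb))
  tb
}

#' @export
#' @rdname pulse_schedule
#' @param x an object to convert (a data frame with columns `cell`,
#'   `amplitude`, `start`, `duration`).
as_pulse_schedule <- function(x) {
  if (inherits(x, "pulse_schedule")) return(x)
  x <- as.data.frame(x)
  pulse_schedule(x$cell, x$amplitude, x$start, x$duration)
}

#' Evaluate a schedule at one time point
#'
#' @param schedule a [pulse_schedule()].
#' @param cell cell index.
#' @param t time (s).
#' @return The active amplitude for `cell` at `t` (0 if no pulse covers
#'   it; intervals are half-open, so `t = start + duration` reads 0).
#' @examples
#' sch <- pulse_schedule(1, 1.2, 1400, 600)
#' pulse_value(sch, 1, 1500)  # 1.2
#' pulse_value(sch, 1, 2000)  # 0
#' @export
pulse_value <- function(schedule, cell, t) {
  stopifnot(t >= 0)
  sub <- schedule[schedule$cell == cell &
                    schedule$start <= t &
                    t < schedule$start + schedule$duration, ]
  if (nrow(sub) == 0L) 0 else sub$amplitude[[1L]]
}

## All pulse on/off boundary times within (t0, t1), plus the endpoints.
schedule_breaks <- function(schedule, t0, t1) {
  br <- sort(unique(c(schedule$start, schedule$start + schedule$duration)))
  br <- br[br > t0 + 1e-12 & br < t1 - 1e-12]
  c(t0, br, t1)
}

## Pulse vector (length N) active on the open interval (a, b).
schedule_pulse_vector <- function(schedule, N, a, b) {
  mid <- (a + b) / 2
  out <- numeric(N)
  if (!nrow(schedule)) return(out)
  act <- schedule[schedule$start <= mid & mid < schedule$start + schedule$duration, ]
  if (nrow(act)) out[act$cell] <- act$amplitude
  out
}
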