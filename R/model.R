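#' @keywords internal
"_PACKAGE"

## Single-cell kinetics ------------------------------------------------
##
## fx = nu + sigma_inh * y^n / (M^n + y^n)
##         - sigma_M * x (1+x)(1+y)^2 / (L + (1+x)^2 (1+y)^2)
## fy = phi * sigma_M * x (1+x)(1+y)^2 / (L + (1+x)^2 (1+y)^2)
##         - k_s * y - phi * sigma_inh * y^n / (M^n + y^n)
##
## Vectorised over x, y.

cell_kinetics <- function(x, y, params) {
  p <- params
  u <- x * (1 + x)
  v <- (1 + y)^2
  D <- p$L + (1 + x)^2 * v
  g <- p$sigma_M * u * v / D
  h <- y^p$n / (p$M^p$n + y^p$n)
  list(fx = p$nu + p$sigma_inh * h - g,
       fy = p$phi * g - p$k_s * y - p$phi * p$sigma_inh * h)
}

## Analytic partial derivatives of the single-cell kinetics.
cell_kinetics_jac <- function(x, y, params) {
  p <- params
  u <- x * (1 + x)
  v <- (1 + y)^2
  D <- p$L + (1 + x)^2 * v
  gx <- p$sigma_M * v * ((1 + 2 * x) * D - u * 2 * (1 + x) * v) / D^2
  gy <- p$sigma_M * u * 2 * (1 + y) * (D - v * (1 + x)^2) / D^2
  hy <- p$n * p$M^p$n * y^(p$n - 1) / (p$M^p$n + y^p$n)^2
  list(fx_x = -gx,
       fx_y = p$sigma_inh * hy - gy,
       fy_x = p$phi * gx,
       fy_y = p$phi * gy - p$k_s - p$phi * p$sigma_inh * hy)
}

#' Right-hand side of the coupled-cell model
#'
#' Time derivative of the stacked state `c(x[1..N], y[1..N])`:
#' each cell runs the two-variable glycolytic kinetics, cells exchange
#' ATP with transport coefficient `q * k_ADP` and ADP with `k_ADP`
#' along the edges of `topology`, and `pulse` adds a per-cell constant
#' ATP in/outflow (the perturbation term).
#'
#' @param state numeric vector of length 2N, `c(x, y)`.
#' @param params a [kinetic_params()] object.
#' @param topology a [cell_topology()] object.
#' @param pulse numeric vector of length N of ATP perturbation rates
#'   (default all zero).
#' @return Numeric vector of length 2N of time derivatives.
#' @examples
#' topo <- cell_topology("linear", 2)
#' p <- kinetic_params()
#' cell_rhs(c(0, 0, 0, 0), p, topo)  # dx = nu, dy = 0 at the origin
#' @export
cell_rhs <- function(state, params, topology, pulse = NULL) {
  N <- topology$N
  if (length(state) != 2L * N)
    stop("'state' must have length 2N = ", 2L * N, call. = FALSE)
  if (is.null(pulse)) pulse <- numeric(N)
  if (length(pulse) != N)
    stop("'pulse' must have length N = ", N, call. = FALSE)
  x <- state[seq_len(N)]
  y <- state[N + seq_len(N)]
  f <- cell_kinetics(x, y, params)
  Lp <- topology$laplacian
  c(f$fx - params$q * params$k_ADP * as.vector(Lp %*% x) + pulse,
    f$fy - params$k_ADP * as.vector(Lp %*% y))
}

#' Analytic Jacobian of the coupled-cell model
#'
#' The 2N x 2N Jacobian of [cell_rhs()] with respect to the state.  The
#' reaction part is block-diagonal with the per-cell 2 x 2 Jacobians;
#' the coupling contributes `-q * k_ADP * Laplacian` on the x block and
#' `-k_ADP * Laplacian` on the y block.
#'
#' @inheritParams cell_rhs
#' @return A 2N x 2N numeric matrix.
#' @export
cell_jacobian <- function(state, params, topology) {
  N <- topology$N
  stopifnot(length(state) == 2L * N)
  x <- state[seq_len(N)]
  y <- state[N + seq_len(N)]
  jc <- cell_kinetics_jac(x, y, params)
  J <- matrix(0, 2L * N, 2L * N)
  ix <- seq_len(N)
  iy <- N + ix
  J[cbind(ix, ix)] <- jc$fx_x
  J[cbind(ix, iy)] <- jc$fx_y
  J[cbind(iy, ix)] <- jc$fy_x
  J[cbind(iy, iy)] <- jc$fy_y
  J[ix, ix] <- J[ix, ix] - params$q * params$k_ADP * topology$laplacian
  J[iy, iy] <- J[iy, iy] - params$k_ADP * topology$laplacian
  J
}

#' Uniform stationary state of the array
#'
#' At a uniform stationary state the coupling sums vanish, so the state
#' solves the single-cell equations.  Adding `phi` times the x equation
#' to the y equation gives the identity `phi * nu - k_s * y = 0`, hence
#' `y* = phi * nu / k_s` exactly (independent of both `sigma_M` and
#' `sigma_inh`); `x*` is then the root of `fx(x, y*) = 0`, which is
#' unique because the autocatalytic sink is monotone in `x`.
#'
#' For small `sigma_M` and large `sigma_inh` the ATP balance can fail to
#' close (`nu + sigma_inh * h(y*) > sigma_M`, the saturating maximum of
#' the sink); no stationary state exists then and an error describing
#' the bracket is raised.
#'
#' @param params a [kinetic_params()] object.
#' @return A list with `x`, `y` (scalars) and `residual`.
#' @examples
#' uniform_steady_state(kinetic_params())$y  # = 1.84 / 0.06 = 30.667
#' @export
uniform_steady_state <- function(params) {
  y_star <- params$phi * params$nu / params$k_s
  f1 <- function(x) cell_kinetics(x, y_star, params)$fx
  hi <- 1
  while (f1(hi) > 0 && hi < 1e12) hi <- hi * 10
  if (f1(hi) > 0)
    stop(sprintf(paste0("no uniform stationary state: fx(x, y* = %.4g) stays ",
                        "positive on (0, %.1g]; ATP uptake exceeds the ",
                        "saturating autocatalytic sink (sigma_M too small)"),
                 y_star, hi), call. = FALSE)
  x_star <- stats::uniroot(f1, c(0, hi), tol = 1e-13)$root
  list(x = x_star, y = y_star, residual = abs(f1(x_star)))
}

#' Uniform state as a stacked vector
#'
#' @inheritParams cell_rhs
#' @return Numeric vector `c(rep(x*, N), rep(y*, N))`.
#' @export
uniform_state_vector <- function(params, topology) {
  ss <- uniform_steady_state(params)
  c(rep(ss$x, topology$N), rep(ss$y, topology$N))
}
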