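## Two-parameter continuation of codimension-one bifurcation points.
##
## Hopf curves use the minimally augmented system (F = 0, psi = 0) with
## psi the largest real part over complex-conjugate eigenvalue pairs;
## fold and symmetry-breaking (branch-point) curves use the
## Moore-Spence bordered system (F = 0, J v = 0, |v| = 1).  Both are
## driven by the same pseudo-arclength predictor-corrector.

hopf_test <- function(s, params, topology) {
  ev <- eigen(cell_jacobian(s, params, topology), only.values = TRUE)$values
  cp <- ev[Im(ev) > 1e-9]
  if (!length(cp)) return(list(psi = NA_real_, omega = NA_real_, n_cross = 0L))
  re <- Re(cp); im <- Im(cp)
  lead <- which.max(re)
  list(psi = re[lead], omega = im[lead],
       n_cross = sum(re > -1e-7))
}

## Generic pseudo-arclength machinery on fully scaled coordinates.
## `resid` maps the scaled vector to the (length m-1) residual; the
## corrector appends the moving-hyperplane equation and solves by
## finite-difference Newton.
curve_correct <- function(z_pred, tangent, resid, tol = 1e-9,
                          max_iter = 15L) {
  z <- z_pred
  m <- length(z)
  for (it in seq_len(max_iter)) {
    r <- c(resid(z), sum(tangent * (z - z_pred)))
    if (!all(is.finite(r))) return(NULL)
    if (max(abs(r)) < tol) return(z)
    A <- matrix(0, m, m)
    for (j in seq_len(m)) {
      h <- 1e-6
      zp <- z; zp[j] <- z[j] + h
      zm <- z; zm[j] <- z[j] - h
      A[seq_len(m - 1L), j] <- (resid(zp) - resid(zm)) / (2 * h)
    }
    A[m, ] <- tangent
    d <- tryCatch(solve(A, r), error = function(e) NULL)
    if (is.null(d)) return(NULL)
    z <- z - d
  }
  NULL
}

curve_trace_dir <- function(z_start, orient, resid, add, in_window,
                            step0, step_max, max_points,
                            stop_fun = NULL) {
  m <- length(z_start)
  z <- z_start
  tangent <- curve_tangent_fd(z, resid, m - 1L)
  if (sum(tangent * orient) < 0) tangent <- -tangent
  h <- step0
  count <- 1L
  add(z, "")
  fails <- 0L
  while (count < max_points) {
    z_pred <- z + h * tangent
    z_new <- curve_correct(z_pred, tangent, resid)
    ok <- !is.null(z_new) && in_window(z_new)
    if (ok) {
      ev <- if (is.null(stop_fun)) "" else stop_fun(z_new)
      tnew <- curve_tangent_fd(z_new, resid, m - 1L)
      if (sum(tnew * tangent) < 0) tnew <- -tnew
      tangent <- tnew
      z <- z_new
      add(z, ev)
      count <- count + 1L
      if (identical(ev, "bt")) break
      h <- min(h * 1.3, step_max)
      fails <- 0L
    } else {
      h <- h / 2
      fails <- fails + 1L
      if (h < 1e-7 || fails > 40L) break
    }
  }
}


## generic tangent: unit null vector of the FD Jacobian of `resid`
curve_tangent_fd <- function(z, resid, n_eq) {
  m <- length(z)
  A <- matrix(0, n_eq, m)
  for (j in seq_len(m)) {
    h <- 1e-6
    zp <- z; zp[j] <- z[j] + h
    zm <- z; zm[j] <- z[j] - h
    A[, j] <- (resid(zp) - resid(zm)) / (2 * h)
  }
  tv <- svd(A, nu = 0, nv = m)$v[, m]
  tv / sqrt(sum(tv^2))
}

#' Continue a codimension-one bifurcation point in two parameters
#'
#' Traces the curve of Hopf, fold or symmetry-breaking points through
#' the plane of two free parameters by pseudo-arclength continuation of
#' the corresponding augmented system: for Hopf points the minimally
#' augmented system (stationarity plus vanishing real part of the
#' leading complex eigenvalue pair), for folds and branch points the
#' Moore-Spence bordered system (stationarity, a Jacobian null vector,
#' and its normalisation).  Hopf curves terminate where the Hopf
#' frequency tends to zero (a Bogdanov-Takens point) and flag points
#' where more than one eigenvalue pair is near the imaginary axis
#' (double-Hopf proximity).
#'
#' @param bp a one-row tibble (or list) with `state` and `param` as
#'   produced by [detect_bifurcations()], located at `param_values` in
#'   the plane.
#' @param kind `"hopf"`, `"fold"` or `"branch_point"`.
#' @param params,topology model configuration.
#' @param parameter_pair character vector of two free parameter names;
#'   the first is the parameter of the branch that produced `bp`.
#' @param ranges list of two numeric length-2 windows.
#' @param param_values numeric length-2: coordinates of `bp` in the
#'   plane (second defaults to the current entry of `params`).
#' @param step0,step_max arclength steps (scaled units).
#' @param max_points cap on curve points per direction.
#' @param both_directions trace backwards as well and join.
#' @return A `codim1_curve` tibble: `p1`, `p2`, `state` (list), `omega`
#'   (Hopf only), `event` (`""`, `"bt"`, `"double_hopf"`), ordered
#'   along the curve, with the configuration in attributes.
#' @export
trace_codim1_curve <- function(bp, kind = c("hopf", "fold", "branch_point"),
                               params, topology, parameter_pair, ranges,
                               param_values = NULL,
                               step0 = 5e-3, step_max = 0.03,
                               max_points = 400L, both_directions = TRUE) {
  kind <- match.arg(kind)
  pars <- vapply(parameter_pair, match.arg, "", choices = free_parameters)
  stopifnot(length(pars) == 2L, length(ranges) == 2L)
  s_bp <- if (is.list(bp$state)) bp$state[[1L]] else bp$state
  if (is.null(param_values))
    param_values <- c(bp$param[[1L]], params[[pars[2L]]])
  scales <- vapply(ranges, diff, 0)
  if (kind == "hopf")
    curve_hopf(s_bp, param_values, params, topology, pars, ranges, scales,
               step0, step_max, max_points, both_directions)
  else
    curve_moore_spence(s_bp, param_values, params, topology, pars, ranges,
                       scales, step0, step_max, max_points, both_directions,
                       kind)
}

curve_hopf <- function(s0, pv, params, topology, pars, ranges, scales,
                       step0, step_max, max_points, both_directions) {
  n <- length(s0)
  sscale <- max(abs(s0), 1)
  w <- c(rep(sscale, n), scales)
  unpack <- function(z) {
    p <- set_free(params, pars[1L], z[n + 1L] * scales[1L])
    set_free(p, pars[2L], z[n + 2L] * scales[2L])
  }
  resid <- function(z) {
    p <- unpack(z)
    s <- z[seq_len(n)] * sscale
    c(cell_rhs(s, p, topology),
      hopf_test(s, p, topology)$psi)
  }
  in_window <- function(z) {
    p1 <- z[n + 1L] * scales[1L]; p2 <- z[n + 2L] * scales[2L]
    all(z[seq_len(n)] * sscale > -1e-8) &&
      p1 >= ranges[[1L]][1L] && p1 <= ranges[[1L]][2L] &&
      p2 >= ranges[[2L]][1L] && p2 <= ranges[[2L]][2L]
  }
  stop_fun <- function(z) {
    ht <- hopf_test(z[seq_len(n)] * sscale, unpack(z), topology)
    if (is.finite(ht$omega) && ht$omega < 1e-3) "bt"
    else if (ht$n_cross > 2L) "double_hopf"
    else ""
  }
  z0 <- c(s0 / sscale, pv[1L] / scales[1L], pv[2L] / scales[2L])
  t0 <- curve_tangent_fd(z0, resid, n + 1L)
  z0 <- curve_correct(z0, t0, resid) %||% z0
  pts <- list()
  mk_add <- function() function(z, event) {
    s <- z[seq_len(n)] * sscale
    ht <- hopf_test(s, unpack(z), topology)
    pts[[length(pts) + 1L]] <<- tibble::tibble(
      p1 = z[n + 1L] * scales[1L], p2 = z[n + 2L] * scales[2L],
      state = list(s), omega = ht$omega, event = event)
  }
  orient <- c(rep(0, n), 0, -1)
  add <- mk_add()
  curve_trace_dir(z0, orient, resid, add, in_window, step0, step_max,
                  max_points, stop_fun)
  fwd <- dplyr::bind_rows(pts)
  out <- fwd
  if (both_directions) {
    pts <- list()
    add <- mk_add()
    curve_trace_dir(z0, -orient, resid, add, in_window, step0, step_max,
                    max_points, stop_fun)
    bwd <- dplyr::bind_rows(pts)
    out <- dplyr::bind_rows(bwd[rev(seq_len(nrow(bwd))), ], fwd[-1L, ])
  }
  structure(out, class = c("codim1_curve", class(out)),
            kind = "hopf", params = params, topology = topology,
            parameter_pair = pars, ranges = ranges)
}

curve_moore_spence <- function(s0, pv, params, topology, pars, ranges,
                               scales, step0, step_max, max_points,
                               both_directions, kind) {
  n <- length(s0)
  sscale <- max(abs(s0), 1)
  p0 <- set_free(set_free(params, pars[1L], pv[1L]), pars[2L], pv[2L])
  v0 <- svd(cell_jacobian(s0, p0, topology))$v[, n]
  unpack <- function(z) {
    p <- set_free(params, pars[1L], z[2 * n + 1L] * scales[1L])
    set_free(p, pars[2L], z[2 * n + 2L] * scales[2L])
  }
  resid <- function(z) {
    p <- unpack(z)
    s <- z[seq_len(n)] * sscale
    v <- z[n + seq_len(n)]
    J <- cell_jacobian(s, p, topology)
    c(cell_rhs(s, p, topology), as.vector(J %*% v), (sum(v^2) - 1) / 2)
  }
  in_window <- function(z) {
    p1 <- z[2 * n + 1L] * scales[1L]; p2 <- z[2 * n + 2L] * scales[2L]
    all(z[seq_len(n)] * sscale > -1e-8) &&
      p1 >= ranges[[1L]][1L] && p1 <= ranges[[1L]][2L] &&
      p2 >= ranges[[2L]][1L] && p2 <= ranges[[2L]][2L]
  }
  z0 <- c(s0 / sscale, v0, pv[1L] / scales[1L], pv[2L] / scales[2L])
  t0 <- curve_tangent_fd(z0, resid, 2L * n + 1L)
  z0 <- curve_correct(z0, t0, resid) %||% z0
  pts <- list()
  mk_add <- function() function(z, event) {
    pts[[length(pts) + 1L]] <<- tibble::tibble(
      p1 = z[2 * n + 1L] * scales[1L], p2 = z[2 * n + 2L] * scales[2L],
      state = list(z[seq_len(n)] * sscale), omega = NA_real_, event = event)
  }
  orient <- c(rep(0, 2L * n), 0, 1)
  add <- mk_add()
  curve_trace_dir(z0, orient, resid, add, in_window, step0, step_max,
                  max_points)
  fwd <- dplyr::bind_rows(pts)
  out <- fwd
  if (both_directions) {
    pts <- list()
    add <- mk_add()
    curve_trace_dir(z0, -orient, resid, add, in_window, step0, step_max,
                    max_points)
    bwd <- dplyr::bind_rows(pts)
    out <- dplyr::bind_rows(bwd[rev(seq_len(nrow(bwd))), ], fwd[-1L, ])
  }
  structure(out, class = c("codim1_curve", class(out)),
            kind = kind, params = params, topology = topology,
            parameter_pair = pars, ranges = ranges)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
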