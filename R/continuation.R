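## Pseudo-arclength continuation of stationary states, bifurcation
## detection and two-parameter bifurcation curves.
##
## All routines work on the extended vector z = c(state, alpha) where
## alpha is the free parameter, internally scaled by the window width so
## that arclength steps are comparable across parameters.

free_parameters <- c("sigma_M", "sigma_inh", "k_ADP", "q")

set_free <- function(params, name, value) {
  params[[name]] <- value
  params
}

## F and its derivative with respect to the free parameter.
ext_F <- function(z, params, topology, par) {
  n <- length(z) - 1L
  cell_rhs(z[seq_len(n)], set_free(params, par, z[n + 1L]), topology)
}

ext_Fp <- function(z, params, topology, par, h = NULL) {
  n <- length(z) - 1L
  a <- z[n + 1L]
  if (is.null(h)) h <- 1e-6 * max(1, abs(a))
  (cell_rhs(z[seq_len(n)], set_free(params, par, a + h), topology) -
     cell_rhs(z[seq_len(n)], set_free(params, par, a - h), topology)) / (2 * h)
}

ext_J <- function(z, params, topology, par) {
  n <- length(z) - 1L
  cell_jacobian(z[seq_len(n)], set_free(params, par, z[n + 1L]), topology)
}

## Tangent: unit null vector of the scaled [J | Fp], oriented along
## `orient`.  `scales` is the length-(2N+1) vector of coordinate scales
## (state scale repeated, then the parameter window width).
branch_tangent <- function(z, params, topology, par, scales, orient = NULL) {
  n <- length(z) - 1L
  A <- cbind(ext_J(z, params, topology, par),
             ext_Fp(z, params, topology, par))
  A <- sweep(A, 2L, scales, `*`)
  tv <- svd(A, nu = 0, nv = n + 1L)$v[, n + 1L]
  tv <- tv / sqrt(sum(tv^2))
  if (!is.null(orient) && sum(tv * orient) < 0) tv <- -tv
  tv
}

## Corrector: Newton on (F = 0, t . (z_sc - z_sc_pred) = 0) in scaled
## coordinates z_sc = c(state, alpha / pscale).
arclength_correct <- function(z_pred_sc, tangent, params, topology, par,
                              scales, tol = 1e-10, max_iter = 12L) {
  z_sc <- z_pred_sc
  n <- length(z_sc) - 1L
  for (i in seq_len(max_iter)) {
    z <- z_sc * scales
    r <- c(ext_F(z, params, topology, par),
           sum(tangent * (z_sc - z_pred_sc)))
    if (!all(is.finite(r))) return(NULL)
    if (max(abs(r)) < tol) return(z_sc)
    A <- rbind(sweep(cbind(ext_J(z, params, topology, par),
                           ext_Fp(z, params, topology, par)),
                     2L, scales, `*`),
               tangent)
    d <- tryCatch(solve(A, r), error = function(e) NULL)
    if (is.null(d)) return(NULL)
    z_sc <- z_sc - d
  }
  NULL
}

#' Trace a branch of stationary states in one parameter
#'
#' Pseudo-arclength predictor-corrector continuation of `cell_rhs = 0`
#' in one of the four free parameters, with adaptive step control and a
#' full eigensolve at every accepted point.  The branch stops at the
#' window ends, after `max_points` points, or when the corrector fails
#' after a cascade of step halvings.
#'
#' @param start numeric state vector of length 2N, stationary at
#'   `param_value` (it is re-converged before tracing).
#' @param params a [kinetic_params()] object (the free parameter's entry
#'   is overridden along the branch).
#' @param topology a [cell_topology()] object.
#' @param free_parameter one of `"sigma_M"`, `"sigma_inh"`, `"k_ADP"`,
#'   `"q"`.
#' @param range numeric length-2 window for the free parameter.
#' @param param_value starting value (defaults to the current entry of
#'   `params`).
#' @param direction +1 / -1: initial direction of increasing or
#'   decreasing parameter.
#' @param step0,step_min,step_max arclength step sizes in scaled units
#'   (parameter scaled by the window width).
#' @param max_points cap on branch points.
#' @return A `cont_branch` tibble: one row per point with columns
#'   `step`, `param`, `state` (list), `max_re`, `max_re_complex`,
#'   `omega`, `stable`, `det_bordered`, `tangent_param` plus the
#'   configuration in attributes.
#' @export
trace_branch <- function(start, params, topology, free_parameter,
                         range, param_value = NULL, direction = 1,
                         step0 = 1e-2, step_min = 1e-6, step_max = 0.05,
                         max_points = 600L) {
  par <- match.arg(free_parameter, free_parameters)
  stopifnot(length(range) == 2L, range[2L] > range[1L])
  pscale <- diff(range)
  if (is.null(param_value)) param_value <- params[[par]]
  s0 <- solve_equilibrium(start, set_free(params, par, param_value), topology)
  if (is.null(s0))
    stop("starting state does not converge at ", par, " = ", param_value,
         call. = FALSE)
  n <- length(s0)
  sscale <- max(abs(s0), 1)
  scales <- c(rep(sscale, n), pscale)
  z_sc <- c(s0, param_value) / scales
  orient <- c(rep(0, n), direction)
  tangent <- branch_tangent(c(s0, param_value), params, topology, par,
                            scales, orient)
  rows <- list()
  add_point <- function(z_sc, tangent) {
    z <- z_sc * scales
    st <- assess_stability(z[seq_len(n)],
                           set_free(params, par, z[n + 1L]), topology)
    ev <- st$eigenvalues
    cplx <- ev[Im(ev) > 1e-9]
    lead_c <- if (length(cplx)) cplx[which.max(Re(cplx))] else NA_complex_
    A <- rbind(sweep(cbind(ext_J(z, params, topology, par),
                           ext_Fp(z, params, topology, par)),
                     2L, scales, `*`),
               tangent)
    dt <- determinant(A, logarithm = TRUE)
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      step = length(rows) + 1L,
      param = z[n + 1L],
      state = list(z[seq_len(n)]),
      max_re = max(Re(ev)),
      max_re_complex = if (length(cplx)) max(Re(cplx)) else NA_real_,
      omega = if (length(cplx)) abs(Im(lead_c)) else NA_real_,
      stable = st$stable,
      det_bordered = as.numeric(dt$sign) * exp(min(dt$modulus, 700)),
      tangent_param = tangent[n + 1L],
      tangent = list(tangent))
  }
  suppressWarnings(add_point(z_sc, tangent))
  h <- step0
  fails <- 0L
  while (length(rows) < max_points) {
    z_pred <- z_sc + h * tangent
    z_new <- arclength_correct(z_pred, tangent, params, topology, par, scales)
    ok <- !is.null(z_new) && all(z_new[seq_len(n)] * sscale > -1e-8)
    if (ok) {
      a_new <- z_new[n + 1L] * pscale
      if (a_new < range[1L] - 1e-12 || a_new > range[2L] + 1e-12) {
        ## clamp the end point onto the window boundary, then stop
        a_clamp <- min(max(a_new, range[1L]), range[2L])
        s_cl <- solve_equilibrium(z_new[seq_len(n)] * sscale,
                                  set_free(params, par, a_clamp), topology)
        if (!is.null(s_cl)) {
          z_cl <- c(s_cl, a_clamp) / scales
          tangent <- branch_tangent(c(s_cl, a_clamp), params, topology, par,
                                    scales, tangent)
          suppressWarnings(add_point(z_cl, tangent))
        }
        break
      }
      tangent <- branch_tangent(z_new * scales, params,
                                topology, par, scales, tangent)
      z_sc <- z_new
      suppressWarnings(add_point(z_sc, tangent))
      h <- min(h * 1.3, step_max)
      fails <- 0L
    } else {
      h <- h / 2
      fails <- fails + 1L
      if (h < step_min || fails > 40L) break
    }
  }
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("cont_branch", class(out)),
            params = params, topology = topology,
            free_parameter = par, range = range, pscale = pscale,
            scales = scales)
}

## bisection refinement in arclength between two consecutive branch
## points; `test` maps a corrected z_sc to a scalar whose sign change is
## being localised.
refine_between <- function(b, i, test, params, topology, par, scales,
                           tol = 1e-8, max_iter = 60L) {
  n <- length(b$state[[i]])
  pscale <- scales[n + 1L]
  z0 <- c(b$state[[i]], b$param[i]) / scales
  z1 <- c(b$state[[i + 1L]], b$param[i + 1L]) / scales
  f0 <- test(z0)
  f1 <- test(z1)
  if (!is.finite(f0) || !is.finite(f1) || f0 * f1 > 0) return(NULL)
  for (it in seq_len(max_iter)) {
    zm_pred <- (z0 + z1) / 2
    secant <- z1 - z0
    secant <- secant / sqrt(sum(secant^2))
    zm <- arclength_correct(zm_pred, secant, params, topology, par, scales)
    if (is.null(zm)) return(NULL)
    fm <- test(zm)
    if (!is.finite(fm)) return(NULL)
    if (f0 * fm <= 0) { z1 <- zm; f1 <- fm } else { z0 <- zm; f0 <- fm }
    if (abs(z1[n + 1L] - z0[n + 1L]) * pscale < tol &&
        max(abs(z1 - z0)) < 1e-7) break
  }
  zm <- (z0 + z1) / 2
  s <- solve_equilibrium(zm[seq_len(n)] * scales[1L],
                         set_free(params, par, zm[n + 1L] * pscale), topology)
  if (is.null(s)) return(NULL)
  list(state = s, param = zm[n + 1L] * pscale)
}

#' Detect bifurcations along a traced branch
#'
#' Scans consecutive branch points for sign changes of three test
#' functions: the parameter component of the tangent (fold), the
#' largest real part over complex-conjugate eigenvalue pairs (Hopf) and
#' the determinant of the bordered Jacobian (branch / symmetry-breaking
#' point), then sharpens each root by arclength bisection.
#'
#' @param branch a `cont_branch` from [trace_branch()].
#' @param tol parameter localisation tolerance.
#' @return A tibble with columns `kind` (`"hopf"`, `"fold"`,
#'   `"branch_point"`), `param`, `state` (list), `omega` (Hopf
#'   frequency, `NA` otherwise) and `between` (bracketing step index).
#' @export
detect_bifurcations <- function(branch, tol = 1e-8) {
  params <- attr(branch, "params")
  topology <- attr(branch, "topology")
  par <- attr(branch, "free_parameter")
  pscale <- attr(branch, "pscale")
  scales <- attr(branch, "scales")
  n <- length(branch$state[[1L]])
  out <- list()
  psi_hopf <- function(z_sc) {
    z <- z_sc * scales
    ev <- eigen(ext_J(z, params, topology, par), only.values = TRUE)$values
    cp <- ev[Im(ev) > 1e-9]
    if (!length(cp)) return(NA_real_)
    max(Re(cp))
  }
  psi_det <- function(z_sc) {
    z <- z_sc * scales
    tangent <- branch_tangent(z, params, topology, par, scales)
    A <- rbind(sweep(cbind(ext_J(z, params, topology, par),
                           ext_Fp(z, params, topology, par)),
                     2L, scales, `*`), tangent)
    dt <- determinant(A, logarithm = TRUE)
    as.numeric(dt$sign) * exp(min(dt$modulus - mean(dt$modulus), 200))
  }
  for (i in seq_len(nrow(branch) - 1L)) {
    h0 <- branch$max_re_complex[i]; h1 <- branch$max_re_complex[i + 1L]
    if (is.finite(h0) && is.finite(h1) && h0 * h1 < 0) {
      r <- refine_between(branch, i, psi_hopf, params, topology, par,
                          scales, tol)
      if (!is.null(r)) {
        ev <- eigen(cell_jacobian(r$state, set_free(params, par, r$param),
                                  topology), only.values = TRUE)$values
        cp <- ev[Im(ev) > 1e-9]
        om <- if (length(cp)) abs(Im(cp[which.max(Re(cp))])) else NA_real_
        out[[length(out) + 1L]] <- tibble::tibble(
          kind = "hopf", param = r$param, state = list(r$state),
          omega = om, between = i)
      }
    }
    d0 <- branch$det_bordered[i]; d1 <- branch$det_bordered[i + 1L]
    if (is.finite(d0) && is.finite(d1) && d0 * d1 < 0) {
      r <- refine_between(branch, i, psi_det, params, topology, par,
                          scales, tol)
      if (!is.null(r))
        out[[length(out) + 1L]] <- tibble::tibble(
          kind = "branch_point", param = r$param, state = list(r$state),
          omega = NA_real_, between = i)
    }
    t0 <- branch$tangent_param[i]; t1 <- branch$tangent_param[i + 1L]
    if (t0 * t1 < 0) {
      ## fold: extremum of the parameter along the branch
      r <- refine_fold(branch, i, params, topology, par, scales)
      if (!is.null(r))
        out[[length(out) + 1L]] <- tibble::tibble(
          kind = "fold", param = r$param, state = list(r$state),
          omega = NA_real_, between = i)
    }
  }
  ## Symmetry-breaking from the uniform branch: coupling modes can be
  ## degenerate (repeated Laplacian eigenvalues), making determinant
  ## tests blind to the even-multiplicity crossing.  On uniform
  ## segments, test each distinct coupling mode separately:
  ## det(J_cell - mu * diag(q k_ADP, k_ADP)) changes sign at the
  ## symmetry-breaking point of that mode.
  N <- topology$N
  autos <- automorphisms(topology)
  mus <- unique(round(laplacian_modes(topology), 9))
  mus <- mus[mus > 1e-9]
  mode_det <- function(a, mu) {
    pa <- set_free(params, par, a)
    ss <- tryCatch(uniform_steady_state(pa), error = function(e) NULL)
    if (is.null(ss)) return(NA_real_)
    jc <- cell_kinetics_jac(ss$x, ss$y, pa)
    (jc$fx_x - mu * pa$q * pa$k_ADP) * (jc$fy_y - mu * pa$k_ADP) -
      jc$fx_y * jc$fy_x
  }
  is_unif <- vapply(branch$state, function(s)
    symmetry_class(s, autos)$class == "uniform", logical(1))
  seen <- vapply(out, function(tb) tb$param, 0)
  for (i in seq_len(nrow(branch) - 1L)) {
    if (!is_unif[i] || !is_unif[i + 1L]) next
    a0 <- branch$param[i]; a1 <- branch$param[i + 1L]
    for (mu in mus) {
      d0 <- mode_det(a0, mu); d1 <- mode_det(a1, mu)
      if (!is.finite(d0) || !is.finite(d1) || d0 * d1 >= 0) next
      root <- stats::uniroot(function(a) mode_det(a, mu),
                             sort(c(a0, a1)), tol = tol)$root
      if (any(abs(seen - root) < 1e-6)) next
      seen <- c(seen, root)
      pa <- set_free(params, par, root)
      ss <- uniform_steady_state(pa)
      out[[length(out) + 1L]] <- tibble::tibble(
        kind = "branch_point", param = root,
        state = list(c(rep(ss$x, N), rep(ss$y, N))),
        omega = NA_real_, between = i)
    }
  }
  if (!length(out))
    return(tibble::tibble(kind = character(), param = numeric(),
                          state = list(), omega = numeric(),
                          between = integer()))
  dplyr::bind_rows(out)
}

## fold refinement: bisect on the tangent's parameter component.
refine_fold <- function(b, i, params, topology, par, scales,
                        max_iter = 60L) {
  n <- length(b$state[[1L]])
  psi <- function(z_sc) {
    z <- z_sc * scales
    tv <- branch_tangent(z, params, topology, par, scales,
                         orient = b$tangent[[i]])
    tv[n + 1L]
  }
  refine_between(b, i, psi, params, topology, par, scales)
}

#' Branch switching at a symmetry-breaking (branch) point
#'
#' Computes the kernel direction of the Jacobian transverse to the
#' branch tangent and produces corrected seed states on the bifurcating
#' branch on both sides of the point, at parameter values displaced by
#' `dp` either way.
#'
#' @param bp one row of the [detect_bifurcations()] output with
#'   `kind == "branch_point"` (or a list with `state`, `param`).
#' @param params,topology model configuration.
#' @param free_parameter the branch's free parameter.
#' @param dp parameter offset used when seeding the new branch.
#' @param eps displacement along the kernel direction.
#' @return A tibble of seeds (`state` list, `param`) that converged to
#'   states off the original branch; zero rows if switching failed.
#' @export
switch_branch <- function(bp, params, topology, free_parameter,
                          dp = 1e-3, eps = 1e-2) {
  par <- match.arg(free_parameter, free_parameters)
  s_bp <- if (is.list(bp$state)) bp$state[[1L]] else bp$state
  a_bp <- bp$param[[1L]]
  n <- length(s_bp)
  J <- cell_jacobian(s_bp, set_free(params, par, a_bp), topology)
  sv <- svd(J)
  ## kernel directions: singular vectors with near-zero singular values
  small <- which(sv$d < 1e-5 * max(sv$d))
  if (!length(small)) small <- which.min(sv$d)
  dirs <- sv$v[, small, drop = FALSE]
  dscale <- max(abs(s_bp), 1)
  seeds <- list()
  for (j in seq_len(ncol(dirs))) {
    v <- dirs[, j]
    for (sgn in c(1, -1)) for (da in c(dp, -dp) * max(1, abs(a_bp))) {
      g <- s_bp + sgn * eps * dscale * v
      s <- solve_equilibrium(g, set_free(params, par, a_bp + da), topology)
      if (is.null(s)) next
      ## reject seeds that fell back onto the original branch: compare
      ## with the original branch state re-converged at the same param
      s_orig <- solve_equilibrium(s_bp, set_free(params, par, a_bp + da),
                                  topology)
      if (!is.null(s_orig) && max(abs(s - s_orig)) / dscale < 1e-5) next
      dup <- any(vapply(seeds, function(e)
        abs(e$param - (a_bp + da)) < 1e-12 &&
          max(abs(e$state - s)) / dscale < 1e-6, logical(1)))
      if (!dup) seeds[[length(seeds) + 1L]] <- list(state = s, param = a_bp + da)
    }
  }
  if (!length(seeds))
    return(tibble::tibble(state = list(), param = numeric()))
  tibble::tibble(state = lapply(seeds, `[[`, "state"),
                 param = vapply(seeds, `[[`, 0, "param"))
}
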