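#' Damped-Newton solve for a stationary state
#'
#' Newton iteration on `cell_rhs = 0` with the analytic Jacobian and an
#' Armijo-style step halving.  Roots with negative concentrations are
#' rejected.
#'
#' @param guess numeric vector of length 2N (finite, non-negative).
#' @param params a [kinetic_params()] object.
#' @param topology a [cell_topology()] object.
#' @param tol residual tolerance (max norm).
#' @param max_iter iteration cap.
#' @return On success, a one-row `steady_state` tibble (see
#'   [enumerate_states()] for the columns); on failure, `NULL` with the
#'   final residual attached as attribute `residual`.
#' @export
newton_state <- function(guess, params, topology, tol = 1e-10,
                         max_iter = 50L) {
  res <- newton_core(guess, params, topology, tol, max_iter)
  if (is.null(res$state)) {
    warning("Newton did not converge in ", max_iter,
            " iterations; final residual ", signif(res$residual, 4),
            call. = FALSE)
    return(NULL)
  }
  state_row(res$state, params, topology)
}

newton_core <- function(guess, params, topology, tol = 1e-10,
                        max_iter = 50L) {
  s <- guess
  if (any(!is.finite(s))) return(list(state = NULL, residual = Inf))
  r <- cell_rhs(s, params, topology)
  for (i in seq_len(max_iter)) {
    if (max(abs(r)) < tol) break
    J <- cell_jacobian(s, params, topology)
    d <- tryCatch(solve(J, r), error = function(e) NULL)
    if (is.null(d)) return(list(state = NULL, residual = max(abs(r))))
    lam <- 1
    repeat {
      s2 <- s - lam * d
      r2 <- if (all(is.finite(s2))) cell_rhs(s2, params, topology) else Inf
      if (all(is.finite(r2)) &&
          max(abs(r2)) <= max(abs(r)) * (1 - 0.25 * lam) + 1e-14) break
      lam <- lam / 2
      if (lam < 1e-3) break
    }
    s <- s - lam * d
    r <- cell_rhs(s, params, topology)
  }
  if (max(abs(r)) >= tol) return(list(state = NULL, residual = max(abs(r))))
  if (any(s < -1e-8)) return(list(state = NULL, residual = max(abs(r))))
  s[s < 0] <- 0
  list(state = s, residual = max(abs(r)))
}

## bare vector version used in hot loops: state on success, NULL on failure
solve_equilibrium <- function(guess, params, topology, tol = 1e-10,
                              max_iter = 50L) {
  newton_core(guess, params, topology, tol, max_iter)$state
}

## Build the canonical one-row tibble describing a stationary state.
state_row <- function(s, params, topology, autos = NULL) {
  N <- topology$N
  ev <- eigen(cell_jacobian(s, params, topology), only.values = TRUE)$values
  ev <- ev[order(-Re(ev))]
  if (is.null(autos)) autos <- automorphisms(topology)
  sym <- symmetry_class(s, autos)
  y_star <- params$phi * params$nu / params$k_s
  tibble::tibble(
    state = list(s),
    x = list(s[seq_len(N)]),
    y = list(s[N + seq_len(N)]),
    residual = max(abs(cell_rhs(s, params, topology))),
    max_re = max(Re(ev)),
    eigenvalues = list(ev),
    stable = max(Re(ev)) < -1e-9,
    symmetry = sym$class,
    stabilizer_order = sym$stabilizer_order,
    orbit_size = sym$orbit_size,
    code = pattern_code(s[N + seq_len(N)], y_star))
}

#' Symmetry class of a state under the topology automorphisms
#'
#' A state is `uniform` when all cells agree within `tol`,
#' `symmetric_nonuniform` when some non-identity automorphism fixes it
#' within `tol`, and `asymmetric_nonuniform` otherwise.  The orbit size
#' is `|G| / |stabilizer|`.
#'
#' @param state numeric vector of length 2N.
#' @param autos list of automorphisms (from [automorphisms()]).
#' @param tol comparison tolerance (scaled max norm).
#' @return A list with `class`, `stabilizer_order`, `orbit_size`.
#' @export
symmetry_class <- function(state, autos, tol = 1e-6) {
  N <- length(autos[[1L]])
  scale <- max(abs(state), 1)
  xs <- state[seq_len(N)]; ys <- state[N + seq_len(N)]
  unif <- max(diff(range(xs)), diff(range(ys))) / scale < tol
  fixes <- vapply(autos, function(p)
    max(abs(permute_state(state, p) - state)) / scale < tol, logical(1))
  stab <- sum(fixes)
  cls <- if (unif) "uniform"
  else if (stab > 1L) "symmetric_nonuniform"
  else "asymmetric_nonuniform"
  list(class = cls, stabilizer_order = stab,
       orbit_size = length(autos) / stab)
}

#' Enumerate stationary states by multistart Newton
#'
#' Runs damped Newton from `n_starts` Latin-hypercube points in the box
#' `[0, box_mult * x*] x [0, box_mult * y*]` per cell (plus the uniform
#' state itself), closes the set of roots under the topology
#' automorphism group, and merges duplicates within `dedup_tol` in the
#' scaled max norm.  The multistart cannot guarantee completeness; the
#' `(m, n)` counts stabilise as `n_starts` grows and are cross-checked
#' against continuation in the test-suite.
#'
#' @inheritParams newton_state
#' @param n_starts number of random starting points.
#' @param box_mult box half-width in units of the uniform state.
#' @param seed RNG seed for the start points (logged in the result).
#' @param dedup_tol merge tolerance.
#' @return A `steady_state_set` tibble, one row per distinct state,
#'   sorted by symmetry class then pattern code, with columns
#'   `state` (list of 2N vectors), `x`, `y` (lists), `residual`,
#'   `max_re`, `eigenvalues` (list), `stable`, `symmetry`,
#'   `stabilizer_order`, `orbit_size`, `code`, `orbit_id`.
#' @examples
#' \donttest{
#' st <- enumerate_states(kinetic_params(), cell_topology("cyclic", 3),
#'                        n_starts = 100, seed = 1)
#' dplyr::count(st, symmetry, stable)
#' }
#' @export
enumerate_states <- function(params, topology, n_starts = 500L,
                             box_mult = 5, seed = 1L, dedup_tol = 1e-6) {
  N <- topology$N
  ss <- uniform_steady_state(params)
  autos <- automorphisms(topology)
  set.seed(seed)
  lh <- lhs::randomLHS(n_starts, 2L * N)
  starts <- sweep(lh, 2L, c(rep(box_mult * ss$x, N), rep(box_mult * ss$y, N)), `*`)
  roots <- list(c(rep(ss$x, N), rep(ss$y, N)))
  scale <- max(ss$x, ss$y)
  add_root <- function(s) {
    for (r in roots) if (max(abs(r - s)) / scale < dedup_tol) return(invisible())
    roots[[length(roots) + 1L]] <<- s
  }
  for (i in seq_len(n_starts)) {
    s <- solve_equilibrium(starts[i, ], params, topology)
    if (!is.null(s)) add_root(s)
  }
  ## close under the automorphism group
  repeat {
    n0 <- length(roots)
    for (r in roots) for (p in autos) add_root(permute_state(r, p))
    if (length(roots) == n0) break
  }
  rows <- dplyr::bind_rows(lapply(roots, state_row, params = params,
                                  topology = topology, autos = autos))
  ## orbit ids: states related by an automorphism share one id
  orbit_id <- integer(nrow(rows))
  next_id <- 0L
  for (i in seq_len(nrow(rows))) {
    if (orbit_id[i] > 0L) next
    next_id <- next_id + 1L
    si <- rows$state[[i]]
    for (j in seq(i, nrow(rows))) {
      if (orbit_id[j] > 0L) next
      sj <- rows$state[[j]]
      if (any(vapply(autos, function(p)
        max(abs(permute_state(si, p) - sj)) / scale < 10 * dedup_tol,
        logical(1))))
        orbit_id[j] <- next_id
    }
  }
  rows$orbit_id <- orbit_id
  ord <- order(factor(rows$symmetry,
                      levels = c("uniform", "symmetric_nonuniform",
                                 "asymmetric_nonuniform")), rows$code)
  rows <- rows[ord, ]
  structure(rows, class = c("steady_state_set", class(rows)),
            params = params, topology = topology, seed = seed,
            n_starts = n_starts)
}

#' Recompute the eigenvalue spectrum and stability of a state
#'
#' @param state numeric vector of length 2N (must satisfy the residual
#'   invariant).
#' @inheritParams newton_state
#' @return A list with `eigenvalues` (sorted by decreasing real part)
#'   and `stable`.
#' @export
assess_stability <- function(state, params, topology) {
  r <- max(abs(cell_rhs(state, params, topology)))
  if (r > 1e-8)
    warning("state residual ", signif(r, 3), " exceeds 1e-8; not stationary?")
  ev <- eigen(cell_jacobian(state, params, topology), only.values = TRUE)$values
  ev <- ev[order(-Re(ev))]
  list(eigenvalues = ev, stable = max(Re(ev)) < -1e-9)
}

#' Compact tabular view of a state set
#'
#' @param x a `steady_state_set`.
#' @param ... unused.
#' @return A tibble with one row per state: pattern code, per-cell ADP
#'   values (comma separated), leading eigenvalue real part, stability,
#'   symmetry class and orbit id.
#' @export
tidy.steady_state_set <- function(x, ...) {
  tibble::tibble(
    code = x$code,
    y = vapply(x$y, function(v) paste(signif(v, 6), collapse = ","), ""),
    max_re = x$max_re,
    stable = x$stable,
    symmetry = x$symmetry,
    orbit_id = x$orbit_id)
}

#' One-line summary of a state set
#'
#' @param x a `steady_state_set`.
#' @param ... unused.
#' @return A one-row tibble with `m` (total states), `n_stable`,
#'   and counts per symmetry class.
#' @export
glance.steady_state_set <- function(x, ...) {
  tibble::tibble(
    m = nrow(x),
    n_stable = sum(x$stable),
    n_uniform = sum(x$symmetry == "uniform"),
    n_symmetric = sum(x$symmetry == "symmetric_nonuniform"),
    n_asymmetric = sum(x$symmetry == "asymmetric_nonuniform"))
}

#' Write a state table to CSV
#'
#' One row per state: per-cell concentrations, leading eigenvalue,
#' stability, symmetry class, pattern code and orbit id.  Units: time in
#' s; concentrations dimensionless.
#'
#' @param states a `steady_state_set`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_states_csv <- function(states, file) {
  N <- attr(states, "topology")$N
  xm <- do.call(rbind, states$x)
  ym <- do.call(rbind, states$y)
  colnames(xm) <- paste0("x_", seq_len(N), "_dimensionless")
  colnames(ym) <- paste0("y_", seq_len(N), "_dimensionless")
  df <- cbind(as.data.frame(xm), as.data.frame(ym),
              data.frame(max_re_eigen_per_s = states$max_re,
                         stable = states$stable,
                         symmetry = states$symmetry,
                         pattern_code = states$code,
                         orbit_id = states$orbit_id))
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
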