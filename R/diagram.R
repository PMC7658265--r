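#' Map (m, n) stationary-state counts over a parameter plane
#'
#' Runs the multistart enumeration at every node of a rectangular grid
#' in two free parameters and records `m` (total stationary states) and
#' `n` (stable stationary states), the region labels used on
#' two-parameter bifurcation diagrams.
#'
#' @param params,topology model configuration.
#' @param parameter_pair character vector of two free parameter names.
#' @param ranges list of two numeric length-2 windows.
#' @param grid integer length-2: number of nodes per axis.
#' @param n_starts multistart count per node.
#' @param seed RNG seed.
#' @return A `region_map` tibble: `p1`, `p2`, `m`, `n`,
#'   `n_stable_nonuniform`, `region` (label "m-n").
#' @export
region_map <- function(params, topology, parameter_pair, ranges,
                       grid = c(20L, 20L), n_starts = 150L, seed = 1L) {
  pars <- vapply(parameter_pair, match.arg, "", choices = free_parameters)
  g1 <- seq(ranges[[1L]][1L], ranges[[1L]][2L], length.out = grid[1L])
  g2 <- seq(ranges[[2L]][1L], ranges[[2L]][2L], length.out = grid[2L])
  nodes <- expand.grid(p1 = g1, p2 = g2)
  res <- purrr::pmap_dfr(nodes, function(p1, p2) {
    p <- set_free(set_free(params, pars[1L], p1), pars[2L], p2)
    st <- tryCatch(
      enumerate_states(p, topology, n_starts = n_starts, seed = seed),
      error = function(e) NULL)
    if (is.null(st))
      return(tibble::tibble(p1 = p1, p2 = p2, m = 0L, n = 0L,
                            n_stable_nonuniform = 0L, region = "none"))
    m <- nrow(st)
    n <- sum(st$stable)
    tibble::tibble(p1 = p1, p2 = p2, m = m, n = n,
                   n_stable_nonuniform = sum(st$stable &
                                               st$symmetry != "uniform"),
                   region = paste0(m, "-", n))
  })
  structure(res, class = c("region_map", class(res)),
            params = params, topology = topology,
            parameter_pair = pars, ranges = ranges,
            n_starts = n_starts, seed = seed)
}

#' One-parameter solution diagram with recursive branch switching
#'
#' Traces the uniform stationary branch across a parameter window,
#' detects its bifurcations, switches onto the non-uniform branches
#' emanating from symmetry-breaking points, and repeats once on the
#' secondary branches.  The result collects every traced branch with
#' stability and pattern information, reproducing the structure of
#' one-parameter bifurcation diagrams (stationary value of ADP in a
#' chosen cell against the free parameter).
#'
#' @param params,topology model configuration.
#' @param free_parameter name of the varied parameter.
#' @param range numeric length-2 window.
#' @param depth how many generations of branch switching (1 = only
#'   branches bifurcating from the uniform branch, 2 adds
#'   secondary symmetry breaking).
#' @param max_points per-branch point cap.
#' @return A `solution_diagram` list with elements `branches` (tibble:
#'   `branch_id`, `level`, `param`, `y1`, `max_re`, `stable`,
#'   `symmetry`, `code`, `state` list), `bifurcations` (tibble with
#'   `branch_id`, `kind`, `param`, `omega`), and `windows` (tibble of
#'   contiguous stable windows: `branch_id`, `param_lo`, `param_hi`,
#'   `code`, `symmetry`).
#' @export
solution_diagram <- function(params, topology, free_parameter, range,
                             depth = 2L, max_points = 200L) {
  par <- match.arg(free_parameter, free_parameters)
  a0 <- mean(range)
  u0 <- tryCatch(uniform_state_vector(set_free(params, par, a0), topology),
                 error = function(e) NULL)
  if (is.null(u0)) {
    ## uniform state may not exist mid-window; probe a few locations
    for (a in seq(range[1L], range[2L], length.out = 9L)) {
      u0 <- tryCatch(uniform_state_vector(set_free(params, par, a), topology),
                     error = function(e) NULL)
      if (!is.null(u0)) { a0 <- a; break }
    }
    if (is.null(u0))
      stop("no uniform stationary state anywhere in the window", call. = FALSE)
  }
  branches <- list()
  bifs <- list()
  scale <- max(abs(u0), 1)
  autos <- automorphisms(topology)
  ## a candidate (state, param) is known if any existing branch,
  ## re-converged at that parameter, matches it up to an automorphism
  state_known <- function(s, a) {
    for (old in branches) {
      j <- which.min(abs(old$param - a))
      if (abs(old$param[j] - a) > 0.05 * diff(range)) next
      s_old <- solve_equilibrium(old$state[[j]], set_free(params, par, a),
                                 topology)
      if (is.null(s_old)) next
      for (pm in autos)
        if (max(abs(permute_state(s_old, pm) - s)) / scale < 1e-5)
          return(TRUE)
    }
    FALSE
  }
  branch_known <- function(b) {
    idx <- unique(round(seq(1L, nrow(b), length.out = min(5L, nrow(b)))))
    hits <- vapply(idx, function(i) state_known(b$state[[i]], b$param[i]),
                   logical(1))
    mean(hits) > 0.6
  }
  add_branch <- function(start, param_value, level) {
    s_chk <- solve_equilibrium(start, set_free(params, par, param_value),
                               topology)
    if (is.null(s_chk) || state_known(s_chk, param_value))
      return(invisible(NULL))
    halves <- list()
    for (dir in c(1, -1)) {
      b <- tryCatch(
        trace_branch(start, params, topology, par, range,
                     param_value = param_value, direction = dir,
                     max_points = max_points),
        error = function(e) NULL)
      if (!is.null(b) && nrow(b) > 1L) halves[[length(halves) + 1L]] <- b
    }
    if (!length(halves)) return(invisible(NULL))
    b <- if (length(halves) == 2L) {
      h1 <- halves[[2L]]  # decreasing direction, reversed
      joined <- dplyr::bind_rows(h1[rev(seq_len(nrow(h1))), ], halves[[1L]][-1L, ])
      attributes_keep <- attributes(halves[[1L]])
      out <- joined
      attr(out, "params") <- attributes_keep$params
      attr(out, "topology") <- attributes_keep$topology
      attr(out, "free_parameter") <- attributes_keep$free_parameter
      attr(out, "range") <- attributes_keep$range
      attr(out, "pscale") <- attributes_keep$pscale
      attr(out, "scales") <- attributes_keep$scales
      class(out) <- class(halves[[1L]])
      out
    } else halves[[1L]]
    if (branch_known(b)) return(invisible(NULL))
    branches[[length(branches) + 1L]] <<- b
    id <- length(branches)
    bf <- detect_bifurcations(b)
    if (nrow(bf)) {
      bf$branch_id <- id
      bf$level <- level
      bifs[[length(bifs) + 1L]] <<- bf
    }
    invisible(id)
  }
  add_branch(u0, a0, level = 1L)
  ## recursive switching
  processed <- 0L
  level <- 1L
  while (level < depth + 1L && length(bifs) > 0L) {
    all_bifs <- dplyr::bind_rows(bifs)
    todo <- all_bifs[all_bifs$level == level & all_bifs$kind == "branch_point", ]
    if (!nrow(todo)) break
    for (i in seq_len(nrow(todo))) {
      seeds <- switch_branch(todo[i, ], params, topology, par)
      for (j in seq_len(nrow(seeds)))
        add_branch(seeds$state[[j]], seeds$param[j], level = level + 1L)
    }
    level <- level + 1L
  }
  ## replicate traced representatives across the automorphism group so
  ## the diagram lists every pattern of each orbit
  N <- topology$N
  expanded <- list()
  for (b in branches) {
    keyset <- list()
    for (pm in autos) {
      bs <- lapply(b$state, permute_state, perm = pm)
      mid <- bs[[ceiling(length(bs) / 2)]]
      dup <- any(vapply(keyset, function(k) max(abs(k - mid)) / scale < 1e-6,
                        logical(1)))
      if (dup) next
      keyset[[length(keyset) + 1L]] <- mid
      b2 <- b
      b2$state <- bs
      expanded[[length(expanded) + 1L]] <- b2
    }
  }
  pts <- purrr::imap_dfr(expanded, function(b, id) {
    tibble::tibble(
      branch_id = id, level = NA_integer_, param = b$param,
      y1 = vapply(b$state, function(s) s[N + 1L], 0),
      max_re = b$max_re, stable = b$stable,
      symmetry = vapply(b$state, function(s) symmetry_class(s, autos)$class, ""),
      code = vapply(b$state, function(s)
        pattern_code(s[N + seq_len(N)], params$phi * params$nu / params$k_s), ""),
      state = b$state)
  })
  bif_tb <- if (length(bifs)) {
    tb <- dplyr::bind_rows(bifs)
    tibble::tibble(branch_id = tb$branch_id, kind = tb$kind,
                   param = tb$param, omega = tb$omega)
  } else tibble::tibble(branch_id = integer(), kind = character(),
                        param = numeric(), omega = numeric())
  windows <- stable_windows(pts)
  structure(list(branches = pts, bifurcations = bif_tb, windows = windows,
                 params = params, topology = topology,
                 free_parameter = par, range = range),
            class = "solution_diagram")
}

## contiguous runs of stable points per branch
stable_windows <- function(pts) {
  pts |>
    dplyr::group_by(.data$branch_id) |>
    dplyr::group_modify(function(df, key) {
      r <- rle(df$stable)
      ends <- cumsum(r$lengths)
      starts <- c(1L, utils::head(ends, -1L) + 1L)
      keep <- which(r$values)
      if (!length(keep))
        return(tibble::tibble(param_lo = numeric(), param_hi = numeric(),
                              code = character(), symmetry = character()))
      tibble::tibble(
        param_lo = pmin(df$param[starts[keep]], df$param[ends[keep]]),
        param_hi = pmax(df$param[starts[keep]], df$param[ends[keep]]),
        code = df$code[starts[keep]],
        symmetry = df$symmetry[starts[keep]])
    }) |>
    dplyr::ungroup()
}

#' @export
print.solution_diagram <- function(x, ...) {
  cat(sprintf("<solution_diagram> %s in [%g, %g]: %d branches, %d bifurcations\n",
              x$free_parameter, x$range[1L], x$range[2L],
              max(x$branches$branch_id), nrow(x$bifurcations)))
  invisible(x)
}

#' Export branches of a diagram or curve to CSV
#'
#' @param x a `solution_diagram`, `cont_branch` or `codim1_curve`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_diagram_csv <- function(x, file) {
  df <- if (inherits(x, "solution_diagram")) {
    d <- x$branches
    d$state <- NULL
    d
  } else if (inherits(x, "codim1_curve")) {
    tibble::tibble(p1 = x$p1, p2 = x$p2, omega = x$omega, event = x$event)
  } else {
    tibble::tibble(param = x$param, max_re = x$max_re, stable = x$stable)
  }
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
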