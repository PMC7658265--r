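#' Coupling topology of a cell array
#'
#' Constructs the symmetric structural matrix `delta` describing which
#' pairs of cells exchange mass.  Built-in kinds: `"linear"` (open chain,
#' cells i-1 -- i), `"cyclic"` (chain closed by the 1 -- N edge) and
#' `"t_shaped"` (N = 4 branched array with cell 2 as the hub coupled to
#' cells 1, 3 and 4).  Arbitrary arrays are supported through
#' `kind = "custom"` with an explicit `delta`.
#'
#' Cells are numbered 1..N in all user-facing input and output.
#'
#' @param kind one of `"linear"`, `"cyclic"`, `"t_shaped"`, `"custom"`.
#' @param N number of cells (>= 1; `t_shaped` requires `N = 4`).
#' @param delta for `kind = "custom"`: a symmetric N x N matrix of
#'   non-negative coupling weights with zero diagonal.
#'
#' @return An object of class `cell_topology` with fields `N`, `kind`,
#'   `delta` (structural matrix) and `laplacian` (graph Laplacian
#'   `diag(rowSums(delta)) - delta`).
#' @examples
#' topo <- cell_topology("cyclic", 3)
#' topo$delta
#' cell_topology("t_shaped", 4)
#' @export
cell_topology <- function(kind = c("linear", "cyclic", "t_shaped", "custom"),
                          N = NULL, delta = NULL) {
  kind <- match.arg(kind)
  if (kind == "custom") {
    if (is.null(delta)) stop("custom topology requires 'delta'", call. = FALSE)
    delta <- as.matrix(delta)
    N <- nrow(delta)
  }
  if (is.null(N) || N < 1 || N != round(N))
    stop("'N' must be an integer >= 1", call. = FALSE)
  N <- as.integer(N)
  if (kind == "t_shaped" && N != 4L)
    stop("t_shaped topology is defined for N = 4", call. = FALSE)
  if (kind != "custom") {
    delta <- matrix(0, N, N)
    if (kind %in% c("linear", "cyclic") && N > 1L)
      for (i in 2:N) delta[i, i - 1L] <- delta[i - 1L, i] <- 1
    if (kind == "cyclic") {
      if (N < 3L) stop("cyclic topology requires N >= 3", call. = FALSE)
      delta[1L, N] <- delta[N, 1L] <- 1
    }
    if (kind == "t_shaped") {
      delta[1, 2] <- delta[2, 1] <- 1
      delta[2, 3] <- delta[3, 2] <- 1
      delta[2, 4] <- delta[4, 2] <- 1
    }
  } else {
    if (ncol(delta) != N) stop("'delta' must be square", call. = FALSE)
    if (any(delta < 0)) stop("'delta' entries must be non-negative", call. = FALSE)
    if (any(abs(delta - t(delta)) > 1e-12))
      stop("'delta' must be symmetric", call. = FALSE)
    if (any(diag(delta) != 0))
      stop("'delta' must have zero diagonal", call. = FALSE)
  }
  structure(
    list(N = N, kind = kind, delta = delta,
         laplacian = diag(rowSums(delta), N) - delta),
    class = "cell_topology")
}

#' @export
print.cell_topology <- function(x, ...) {
  cat(sprintf("<cell_topology> %s array of %d cell%s, %d edge%s\n",
              x$kind, x$N, if (x$N > 1) "s" else "",
              nrow(topology_edges(x)), if (nrow(topology_edges(x)) != 1) "s" else ""))
  invisible(x)
}

#' Edge list of a topology
#'
#' @param topology a [cell_topology()] object.
#' @return A tibble with columns `from`, `to` (from < to) and `weight`.
#' @examples
#' topology_edges(cell_topology("linear", 4))
#' @export
topology_edges <- function(topology) {
  stopifnot(inherits(topology, "cell_topology"))
  idx <- which(upper.tri(topology$delta) & topology$delta != 0, arr.ind = TRUE)
  out <- tibble::tibble(from = as.integer(idx[, 1]), to = as.integer(idx[, 2]),
                        weight = topology$delta[idx])
  out[order(out$from, out$to), ]
}

#' Automorphism group of a cell-array topology
#'
#' Enumerates all cell permutations `p` that leave the structural matrix
#' invariant (`delta[p(i), p(j)] == delta[i, j]`).  Used to classify
#' stationary states into uniform, symmetric non-uniform and asymmetric
#' non-uniform patterns, and to close state enumerations under symmetry.
#'
#' The search is exhaustive over all `N!` permutations, which is the
#' intended regime here (arrays of a handful of cells).
#'
#' @param topology a [cell_topology()] object.
#' @return A list of integer permutation vectors; the first element is
#'   always the identity.
#' @examples
#' length(automorphisms(cell_topology("cyclic", 4)))  # dihedral, order 8
#' @export
automorphisms <- function(topology) {
  stopifnot(inherits(topology, "cell_topology"))
  N <- topology$N
  if (N == 1L) return(list(1L))
  if (N > 8L)
    stop("exhaustive automorphism search supports N <= 8", call. = FALSE)
  perms <- all_permutations(N)
  d <- topology$delta
  keep <- vapply(perms, function(p) all(d[p, p] == d), logical(1))
  res <- perms[keep]
  # identity first, for predictable downstream use
  is_id <- vapply(res, function(p) all(p == seq_len(N)), logical(1))
  c(res[is_id], res[!is_id])
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub)
    for (pos in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- as.integer(append(p, n, after = pos - 1L))
    }
  out
}

#' Apply a cell permutation to a stacked state vector
#'
#' States are stored as `c(x[1..N], y[1..N])`; a topology automorphism
#' acts on both blocks simultaneously.
#'
#' @param state numeric vector of length 2N.
#' @param perm integer permutation of 1..N (`perm[i]` = image of cell i).
#' @return The permuted state vector.
#' @export
permute_state <- function(state, perm) {
  N <- length(perm)
  stopifnot(length(state) == 2L * N)
  out <- state
  out[perm] <- state[seq_len(N)]
  out[N + perm] <- state[N + seq_len(N)]
  out
}

#' Eigenvalues of the graph Laplacian of a topology
#'
#' At a uniform state the 2N x 2N Jacobian decouples into N two-by-two
#' blocks `J_cell - mu * diag(q * k_ADP, k_ADP)`, one per Laplacian
#' eigenvalue `mu`; these modes drive both the primary Hopf and the
#' symmetry-breaking (Turing) instabilities.
#'
#' @param topology a [cell_topology()] object.
#' @return Sorted numeric vector of N Laplacian eigenvalues (first is 0).
#' @export
laplacian_modes <- function(topology) {
  stopifnot(inherits(topology, "cell_topology"))
  sort(eigen(topology$laplacian, symmetric = TRUE, only.values = TRUE)$values)
}

#' Write / read a structural matrix as dense CSV
#'
#' @param topology a [cell_topology()] object.
#' @param file path of the CSV file.
#' @return `write_delta_csv` returns `file` invisibly; `read_delta_csv`
#'   returns a `cell_topology` of kind `"custom"`.
#' @export
write_delta_csv <- function(topology, file) {
  stopifnot(inherits(topology, "cell_topology"))
  utils::write.table(topology$delta, file, sep = ",", row.names = FALSE,
                     col.names = paste0("cell_", seq_len(topology$N)))
  invisible(file)
}

#' @rdname write_delta_csv
#' @export
read_delta_csv <- function(file) {
  m <- as.matrix(utils::read.csv(file, check.names = FALSE))
  dimnames(m) <- NULL
  cell_topology("custom", delta = m)
}
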