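#' Kinetic parameters of the coupled glycolytic core model
#'
#' Builds the full parameter set of the two-variable (ATP `x`, ADP `y`)
#' glycolytic core model and its mass-coupling terms.  The fixed constants
#' default to the classical allosteric-enzyme values (`phi = 1`,
#' `nu = 1.84` s^-1, `L = 5e6`, `n = 4`, `M = 10`, `k_s = 0.06` s^-1);
#' the autocatalysis and inhibition rate coefficients `sigma_M`,
#' `sigma_inh` and the coupling pair `q`, `k_ADP` are the four parameters
#' routinely tuned in bifurcation studies, and default to the values used
#' throughout the chemical-computing configurations
#' (`sigma_M = 100`, `sigma_inh = 35`, `q = 1`, `k_ADP = 0.1`).
#'
#' @param nu ATP uptake rate (s^-1).
#' @param sigma_M rate coefficient of the autocatalytic
#'   (phosphofructokinase) step (s^-1).
#' @param sigma_inh rate coefficient of the inhibitory feedback step
#'   (s^-1).
#' @param M Michaelis constant of the inhibitory step (dimensionless).
#' @param n Hill coefficient of the inhibitory step (integer >= 1).
#' @param L allosteric constant of the enzyme (dimensionless).
#' @param phi ratio of the dissociation constants of ATP and ADP.
#' @param k_s removal rate coefficient of ADP (s^-1).
#' @param q ratio of the ATP transport coefficient to the ADP transport
#'   coefficient (dimensionless, >= 0).
#' @param k_ADP transport coefficient of ADP between coupled cells
#'   (s^-1, >= 0).
#'
#' @return An object of class `kinetic_params` (a named list).
#' @examples
#' p <- kinetic_params()
#' p$nu
#' kinetic_params(sigma_M = 10, q = 100)
#' @export
kinetic_params <- function(nu = 1.84, sigma_M = 100, sigma_inh = 35,
                           M = 10, n = 4L, L = 5e6, phi = 1,
                           k_s = 0.06, q = 1, k_ADP = 0.1) {
  num <- list(nu = nu, sigma_M = sigma_M, sigma_inh = sigma_inh, M = M,
              n = n, L = L, phi = phi, k_s = k_s, q = q, k_ADP = k_ADP)
  for (nm in names(num)) {
    v <- num[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
  }
  strict_pos <- c("nu", "sigma_M", "sigma_inh", "M", "n", "L", "phi", "k_s")
  for (nm in strict_pos)
    if (num[[nm]] <= 0)
      stop("parameter '", nm, "' must be strictly positive", call. = FALSE)
  if (q < 0 || k_ADP < 0)
    stop("'q' and 'k_ADP' must be non-negative", call. = FALSE)
  if (n < 1 || n != round(n))
    stop("'n' must be an integer >= 1", call. = FALSE)
  num$n <- as.integer(round(n))
  structure(num, class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params>\n")
  cat(sprintf("  nu = %g s^-1, sigma_M = %g s^-1, sigma_inh = %g s^-1\n",
              x$nu, x$sigma_M, x$sigma_inh))
  cat(sprintf("  M = %g, n = %d, L = %g, phi = %g, k_s = %g s^-1\n",
              x$M, x$n, x$L, x$phi, x$k_s))
  cat(sprintf("  coupling: q = %g, k_ADP = %g s^-1\n", x$q, x$k_ADP))
  invisible(x)
}

#' Update selected kinetic parameters
#'
#' Returns a copy of `params` with the named fields replaced, re-running
#' validation.  Convenient inside parameter scans.
#'
#' @param params a [kinetic_params()] object.
#' @param ... name-value pairs of fields to replace.
#' @return A `kinetic_params` object.
#' @examples
#' p <- kinetic_params()
#' update_params(p, sigma_inh = 50)
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "kinetic_params"))
  repl <- list(...)
  unknown <- setdiff(names(repl), names(unclass(params)))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  args <- utils::modifyList(unclass(params), repl)
  do.call(kinetic_params, args)
}

#' @export
as.data.frame.kinetic_params <- function(x, ...) {
  as.data.frame(unclass(x))
}

# tibble view used by result tables
params_tibble <- function(params) {
  tibble::as_tibble(as.data.frame(params))
}
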