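#' Plot a cell trajectory
#'
#' ADP (and optionally ATP) time series per cell, with pulse windows
#' shaded.
#'
#' @param object a `cell_trajectory`.
#' @param species `"y"` (ADP), `"x"` (ATP) or `"both"`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.cell_trajectory <- function(object, species = c("y", "x", "both"),
                                     ...) {
  species <- match.arg(species)
  df <- tidyr::pivot_longer(tibble::as_tibble(object), c("x", "y"),
                            names_to = "species", values_to = "value")
  if (species != "both") df <- df[df$species == species, ]
  sch <- attr(object, "schedule")
  gg <- ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value,
                                         colour = factor(.data$cell)))
  if (nrow(sch))
    gg <- gg + ggplot2::annotate("rect", xmin = sch$start,
                                 xmax = sch$start + sch$duration,
                                 ymin = -Inf, ymax = Inf, alpha = 0.15)
  gg + ggplot2::geom_line() +
    ggplot2::facet_wrap(~species, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (s)", y = "dimensionless concentration",
                  colour = "cell")
}

#' Plot a one-parameter solution diagram
#'
#' Stationary ADP of a chosen cell against the free parameter, solid
#' for stable and dashed for unstable points, coloured by symmetry
#' class, with bifurcation points marked.
#'
#' @param object a `solution_diagram`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.solution_diagram <- function(object, ...) {
  pts <- object$branches
  ggplot2::ggplot(pts, ggplot2::aes(.data$param, .data$y1,
                                    group = .data$branch_id,
                                    colour = .data$symmetry,
                                    linetype = .data$stable)) +
    ggplot2::geom_path() +
    ggplot2::scale_linetype_manual(values = c(`TRUE` = "solid",
                                              `FALSE` = "dashed")) +
    ggplot2::geom_vline(xintercept = object$bifurcations$param,
                        alpha = 0.25) +
    ggplot2::labs(x = object$free_parameter, y = "stationary ADP in cell 1",
                  colour = "symmetry", linetype = "stable")
}

#' Plot a two-parameter region map
#'
#' Tiles of the parameter plane labelled by their `m-n` counts (total /
#' stable stationary states).
#'
#' @param object a `region_map`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.region_map <- function(object, ...) {
  pars <- attr(object, "parameter_pair")
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$p1, .data$p2, fill = .data$region)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = pars[1L], y = pars[2L], fill = "m-n")
}

#' Plot a two-parameter bifurcation curve
#'
#' @param object a `codim1_curve`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.codim1_curve <- function(object, ...) {
  pars <- attr(object, "parameter_pair")
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$p1, .data$p2)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(data = tibble::as_tibble(object)[object$event != "", ],
                        colour = "red") +
    ggplot2::labs(x = pars[1L], y = pars[2L],
                  title = paste(attr(object, "kind"), "bifurcation curve"))
}
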