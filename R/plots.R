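#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the fitted population index
#'
#' Posterior median and 95% credible ribbon of the latent index
#' (`N_t / N_1`) with the observed counts (scaled by `N_1`) overlaid.
#'
#' @param object An `ipm_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ipm_fit <- function(object, ...) {
  idx <- posterior_index(object)
  obs <- tibble(year = object$data$years,
                index = object$data$counts / object$n0)
  ggplot2::ggplot(idx, ggplot2::aes(x = .data$year)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$`q2.5`,
                                      ymax = .data$`q97.5`),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$median)) +
    ggplot2::geom_point(data = obs, ggplot2::aes(y = .data$index),
                        na.rm = TRUE, shape = 1) +
    ggplot2::geom_hline(yintercept = 1, linetype = 3) +
    ggplot2::labs(x = "year", y = "population index",
                  title = paste0("Fitted index, region '", object$region, "'")) +
    ggplot2::theme_minimal()
}

#' Plot a growth-rate surface
#'
#' Shaded expected growth over the (survival, productivity) plane with the
#' per-region yearly posterior-mean points overlaid; the contour at
#' `lambda = 1` separates growth from decline.
#'
#' @param object An [growth_surface()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ipm_growth_surface <- function(object, ...) {
  pts <- attr(object, "points")
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$phi_ad, y = .data$fpba)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$lambda)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$lambda), breaks = 1,
                          colour = "white") +
    ggplot2::geom_point(data = pts, ggplot2::aes(shape = .data$region),
                        colour = "black", fill = "white") +
    ggplot2::scale_shape_manual(values = c(21, 19)) +
    ggplot2::scale_fill_viridis_c(name = expression(lambda)) +
    ggplot2::labs(x = "annual adult survival",
                  y = "fledglings per breeding attempt") +
    ggplot2::theme_minimal()
}

#' Plot a substituted counterfactual trajectory
#'
#' Baseline fitted index and the substituted re-projection from the
#' substitution year onward, with 95% intervals.
#'
#' @param object An [substitute_trajectory()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ipm_substitution <- function(object, ...) {
  d <- as_tibble(object)
  from <- attr(object, "from_year")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$year)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$substituted_lo,
                                      ymax = .data$substituted_hi),
                         fill = "grey85") +
    ggplot2::geom_line(ggplot2::aes(y = .data$baseline_median,
                                    linetype = "baseline")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$substituted_median,
                                    linetype = "substituted")) +
    ggplot2::geom_vline(xintercept = from, linetype = 3) +
    ggplot2::geom_hline(yintercept = 1, linetype = 3) +
    ggplot2::labs(x = "year", y = "population index", linetype = NULL,
                  title = sprintf("%s-substituted trajectory (from %d)",
                                  attr(object, "substituted_rate"), from)) +
    ggplot2::theme_minimal()
}
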