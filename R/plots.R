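# ggplot2 methods for the fitted objects. These are diagnostic figures in
# the style of the field: hydroscape scatter with the 1:1 line, PLC against
# tension, 1/psi transform of the PV curve, gs decline.

#' @export
autoplot.hydroscape_fit <- function(object, ...) {
  d <- object$data
  lims <- range(c(d$psi_pd, d$psi_min, object$b), finite = TRUE)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$psi_pd, y = .data$psi_min)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_abline(slope = object$sigma, intercept = object$a,
                         colour = "red") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::coord_equal(xlim = lims, ylim = lims) +
    ggplot2::labs(
      x = expression(Psi[pd] ~ "(MPa)"), y = expression(Psi[min] ~ "(MPa)"),
      title = sprintf("Hydroscape: %.2f MPa^2 (sigma = %.3f)",
                      object$area, object$sigma)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.wp_piecewise_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble::tibble(psi_pd = seq(object$range[1], object$range[2],
                                      length.out = 200))
  grid$psi_min <- predict(object, grid)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$psi_pd, y = .data$psi_min)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_line(data = grid, colour = "blue") +
    ggplot2::geom_vline(xintercept = object$theta, linetype = 3) +
    ggplot2::labs(x = expression(Psi[pd] ~ "(MPa)"),
                  y = expression(Psi[min] ~ "(MPa)"),
                  title = "Piecewise water-potential curve") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.weibull_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble::tibble(
    pressure_mpa = seq(0, max(d$pressure_mpa), length.out = 200))
  grid$plc <- 100 * (1 - exp(-(grid$pressure_mpa / object$b)^object$c))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pressure_mpa, y = .data$plc)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$stem_id), alpha = 0.7) +
    ggplot2::geom_line(data = grid, colour = "red") +
    ggplot2::geom_vline(xintercept = -object$p50, linetype = 3) +
    ggplot2::labs(x = "Applied tension (MPa)", y = "PLC (%)",
                  title = sprintf("Weibull vulnerability curve: P50 = %.2f MPa",
                                  object$p50)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.gs_kinetic_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble::tibble(psi_min = seq(min(d$psi_min), max(d$psi_min),
                                       length.out = 200))
  grid$gs <- object$g_min + object$g0 * exp(object$k * grid$psi_min)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$psi_min, y = .data$gs)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_line(data = grid, colour = "red") +
    ggplot2::labs(x = expression(Psi[min] ~ "(MPa)"),
                  y = expression(g[s] ~ "(mmol" ~ m^-2 ~ s^-1 * ")"),
                  title = "Kinetic stomatal decline") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pv_fit <- function(object, ...) {
  d <- object$series
  d$inv_psi <- 1 / d$psi
  d$deficit <- 100 - d$rwc
  tail_line <- tibble::tibble(
    deficit = range(d$deficit))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$deficit, y = .data$inv_psi)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = 100 - object$rwc_tlp, linetype = 3) +
    ggplot2::labs(x = "100 - RWC (%)", y = expression(1 / Psi ~ "(MPa"^-1 * ")"),
                  title = sprintf("PV curve: TLP at %.2f MPa (RWC %.1f%%)",
                                  object$psi_tlp, object$rwc_tlp)) +
    ggplot2::theme_minimal()
}
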