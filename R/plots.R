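#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 views of the package's result
#' objects: spectra (with optional pool components), spectral densities,
#' pool population traces and 2D maps (optionally on an arcsin contrast
#' scale, a display transform only - stored data are never rescaled).
#'
#' @param object result object.
#' @param ... unused.
#' @return a ggplot.
#' @name autoplot-excitonic
NULL

#' @rdname autoplot-excitonic
#' @exportS3Method ggplot2::autoplot
autoplot.exciton_spectrum <- function(object, ...) {
  comp_cols <- setdiff(names(object), c("omega", "intensity"))
  d <- tidyr::pivot_longer(tibble::as_tibble(object),
                           cols = c("intensity", comp_cols),
                           names_to = "component", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$omega, y = .data$value,
                                  colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(omega ~ (cm^-1)), y = "absorption (a.u.)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-excitonic
#' @exportS3Method ggplot2::autoplot
autoplot.spectral_density <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$omega, y = .data$J)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(omega ~ (cm^-1)),
                  y = expression(J(omega) ~ (cm^-1))) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-excitonic
#' @exportS3Method ggplot2::autoplot
autoplot.pool_populations <- function(object, ...) {
  d <- tidyr::pivot_longer(tibble::as_tibble(object),
                           cols = c("P_stay_donor", "P_acceptor"),
                           names_to = "pool", values_to = "P")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$P,
                                  colour = .data$pool)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "t (fs)", y = "population", colour = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-excitonic
#' @param t2 which waiting time (fs) to draw.
#' @param arcsin use arcsin contrast scaling for display.
#' @exportS3Method ggplot2::autoplot
autoplot.spectrum2d <- function(object, t2 = object$t2_fs[1], arcsin = FALSE,
                                ...) {
  i <- which(object$t2_fs == t2)[1]
  if (is.na(i)) stop("waiting time ", t2, " fs not in this spectrum")
  S <- object$signal[[i]]
  z <- as.vector(S / max(abs(S)))
  if (arcsin) z <- asin(pmax(pmin(z, 1), -1)) / (pi / 2)
  d <- tibble::tibble(
    omega1 = rep(object$omega1, times = length(object$omega3)),
    omega3 = rep(object$omega3, each = length(object$omega1)),
    signal = z)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$omega1, y = .data$omega3,
                                  fill = .data$signal)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "red", mid = "white", high = "blue") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         linewidth = 0.3) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = expression(omega[1] ~ (cm^-1)),
                  y = expression(omega[3] ~ (cm^-1)),
                  fill = "signal",
                  subtitle = paste0("t2 = ", object$t2_fs[i], " fs")) +
    ggplot2::theme_minimal()
}
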