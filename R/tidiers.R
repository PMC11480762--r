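#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a windowed conductance estimate
#'
#' @param x a `conductance_estimate`.
#' @param ... unused.
#' @return a one-row tibble with the estimate and its context.
#' @method tidy conductance_estimate
#' @export
tidy.conductance_estimate <- function(x, ...) {
  tibble(conductance_pS = x$mean_pS, se_pS = x$se_pS,
         n_events = x$n_events, n_windows = x$n_windows)
}

#' @rdname tidy.conductance_estimate
#' @method glance conductance_estimate
#' @export
glance.conductance_estimate <- function(x, ...) {
  tibble(t_total_ns = x$t_total_ns, voltage_mV = x$voltage_mV,
         window_ns = x$window_ns, stride_ns = x$stride_ns,
         n_windows = x$n_windows)
}

#' Tidy an excess-SSI result
#'
#' @param x an `ssi_result`.
#' @param ... unused.
#' @return a one-row tibble with SSI, threshold and exSSI in bits.
#' @method tidy ssi_result
#' @export
tidy.ssi_result <- function(x, ...) {
  tibble(ssi_bits = x$ssi_bits,
         noise_threshold_bits = x$noise_threshold_bits,
         exssi_bits = x$exssi_bits, se_bits = x$se_bits)
}

#' @rdname tidy.ssi_result
#' @method glance ssi_result
#' @export
glance.ssi_result <- function(x, ...) {
  tibble(n_frames = as.integer(x$n_frames), n_replicas = x$n_replicas,
         n_shuffles = x$n_shuffles, quantile_p = x$quantile_p,
         single_replica = x$single_replica)
}

#' Tidy a WHAM potential of mean force
#'
#' @param x a `pmf_profile`.
#' @param ... unused.
#' @return the per-bin tibble (`z_A`, `pmf_kbt`, `se_kbt`).
#' @method tidy pmf_profile
#' @export
tidy.pmf_profile <- function(x, ...) {
  as_tibble(x)
}

#' @rdname tidy.pmf_profile
#' @method glance pmf_profile
#' @export
glance.pmf_profile <- function(x, ...) {
  tibble(iterations = attr(x, "iterations"),
         residual = attr(x, "residual"),
         converged = attr(x, "converged"),
         bin_width_A = attr(x, "bin_width_A"),
         temperature_K = attr(x, "temperature_K"))
}

#' Permeation-trace figure
#'
#' Plots the z coordinate of (by default only fully permeating) ions over
#' time, with the two constriction planes shaded, in the style standard for
#' single-channel permeation analyses.
#'
#' @param tracks an [ion_tracks()] table.
#' @param geometry a [pore_geometry()]; when supplied, non-permeating ions
#'   are dropped unless `permeants_only = FALSE` and the planes are drawn.
#' @param permeants_only show only ions that complete a traversal.
#' @return a ggplot object.
#' @export
plot_tracks <- function(tracks, geometry = NULL, permeants_only = !is.null(geometry)) {
  tab <- as_tibble(unwrap_tracks(tracks))
  if (permeants_only) {
    ev <- detect_events(tracks, geometry)
    tab <- tab[tab$ion_id %in% unique(ev$ion_id), , drop = FALSE]
  }
  p <- ggplot2::ggplot(tab, ggplot2::aes(.data$time_ns, .data$z_A,
                                         group = .data$ion_id,
                                         colour = .data$species)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "time (ns)", y = "z (Å)", colour = "species") +
    ggplot2::theme_minimal()
  if (!is.null(geometry)) {
    p <- p +
      ggplot2::geom_hline(yintercept = c(geometry$z_sf, geometry$z_gate),
                          linetype = "dashed", colour = "grey40")
  }
  p
}

#' @method autoplot density_profile
#' @export
autoplot.density_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$z_A, .data$count,
                               colour = .data$species)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "z (Å)", y = "count") +
    ggplot2::theme_minimal()
}

#' @method autoplot energy_profile
#' @export
autoplot.energy_profile <- function(object, ...) {
  tab <- as_tibble(object)
  ggplot2::ggplot(tab[!tab$mask, ],
                  ggplot2::aes(.data$z_A, .data$energy_kbt,
                               colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "z (Å)", y = "energy (kBT)") +
    ggplot2::theme_minimal()
}

#' @method autoplot solvation_profile
#' @export
autoplot.solvation_profile <- function(object, ...) {
  tab <- as_tibble(object)
  ggplot2::ggplot(tab[!tab$mask, ],
                  ggplot2::aes(.data$z_A, .data$mean_waters,
                               colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "z (Å)", y = "first-shell waters") +
    ggplot2::theme_minimal()
}

#' @method autoplot pmf_profile
#' @export
autoplot.pmf_profile <- function(object, ...) {
  tab <- as_tibble(object)
  tab <- tab[is.finite(tab$pmf_kbt), ]
  ggplot2::ggplot(tab, ggplot2::aes(.data$z_A, .data$pmf_kbt)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$pmf_kbt - .data$se_kbt,
                                      ymax = .data$pmf_kbt + .data$se_kbt),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "z (Å)", y = "PMF (kBT)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
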