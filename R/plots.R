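# --- ggplot2 autoplot methods ----------------------------------------------

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a DSB track
#'
#' Step plot of isolated, complex and total break counts over time.
#'
#' @param object a `dsb_track`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.dsb_track <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("idsb", "cdsb", "total"),
                              names_to = "class", values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_h, .data$count,
                                     color = .data$class)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time (h)", y = "DSB count", color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a simulated cell trajectory
#'
#' p53 level with the DSB forcing underneath.
#'
#' @param object a `p53_trajectory` from [simulate_cell()].
#' @param species which species to show.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.p53_trajectory <- function(object, species = c("p53", "dsb"), ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              dplyr::all_of(species),
                              names_to = "species", values_to = "level")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_h, .data$level)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~species, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a bifurcation scan
#'
#' Oscillation amplitude (and period) against the scanned input.
#'
#' @param object a `scan_result` from [bifurcation_scan()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.scan_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$parameter, .data$amplitude)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$oscillating)) +
    ggplot2::labs(x = "input signal", y = "oscillation amplitude") +
    ggplot2::theme_minimal()
}

#' Plot ensemble pulse statistics
#'
#' Pulse-count histogram and pooled IPI histogram for a simulated
#' population.
#'
#' @param object a `p53_ensemble` from [run_ensemble()].
#' @param ... unused.
#' @return A ggplot object (patchable list of two panels via facets).
#' @export
autoplot.p53_ensemble <- function(object, ...) {
  counts <- tibble::tibble(metric = "pulses per cell",
                           value = as.numeric(object$cells$n_pulses))
  ipis <- tibble::tibble(metric = "inter-pulse interval (h)",
                         value = object$ipis$all)
  df <- dplyr::bind_rows(counts, ipis)
  ggplot2::ggplot(df, ggplot2::aes(.data$value)) +
    ggplot2::geom_histogram(bins = 20, fill = "grey35") +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = NULL, y = "cells / intervals") +
    ggplot2::theme_minimal()
}

#' Plot a responsiveness map
#'
#' Pulse probability over the dose-by-Wip1 plane.
#'
#' @param object a `responsiveness_map`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.responsiveness_map <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$N_s, .data$wip1_rate,
                               fill = .data$p_pulse)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "maximal inflicted DSBs", y = "Wip1 production rate",
                  fill = "P(pulse < 6 h)") +
    ggplot2::theme_minimal()
}
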