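#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a thermodynamic profile into its density of states
#' @param x A `thermo_profile`.
#' @param ... Unused.
#' @return Tibble with columns `energy`, `ln_g`.
#' @export
tidy.thermo_profile <- function(x, ...) {
  tibble::tibble(energy = x$energy, ln_g = x$ln_g)
}

#' One-row summary of a thermodynamic profile
#' @param x A `thermo_profile`.
#' @param T_grid Temperature grid for peak detection (default spans
#'   the sampled ladder, 400 points).
#' @param ... Unused.
#' @return Tibble with `t_melt` (major specific-heat peak, reduced),
#'   `t_melt_kelvin`, `n_peaks`, `iterations`, `residual`.
#' @export
glance.thermo_profile <- function(x, T_grid = NULL, ...) {
  if (is.null(T_grid)) {
    T_grid <- seq(min(x$temperatures) * 0.8, max(x$temperatures) * 1.2,
                  length.out = 400)
  }
  cv <- specific_heat(x, T_grid)
  peaks <- find_melting_events(cv)
  tm <- if (nrow(peaks)) peaks$temperature[peaks$major][1] else NA_real_
  tibble::tibble(t_melt = tm,
                 t_melt_kelvin = if (is.na(tm)) NA_real_ else reduced_to_kelvin(tm),
                 n_peaks = nrow(peaks),
                 iterations = x$iterations, residual = x$residual)
}

#' Tidy per-round values of a stability estimate
#' @param x A `ddg_result`.
#' @param ... Unused.
#' @return Tibble with columns `round`, `ddg`.
#' @export
tidy.ddg_result <- function(x, ...) {
  tibble::tibble(round = seq_along(x$per_round), ddg = x$per_round)
}

#' One-row summary of a stability estimate
#' @param x A `ddg_result`.
#' @param ... Unused.
#' @return Tibble with site, target, mode, mean, sd, n_rounds.
#' @export
glance.ddg_result <- function(x, ...) {
  tibble::tibble(site = paste0(x$wt, x$resno), chain = x$chain,
                 target = x$target, mode = x$mode,
                 ddg_mean = x$mean, ddg_sd = x$sd, n_rounds = x$n_rounds)
}

#' Plot a specific-heat melting curve with detected peaks
#' @param object A `thermo_profile`.
#' @param T_grid Temperature grid (default as in
#'   [glance.thermo_profile()]).
#' @param min_prominence Peak prominence threshold.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.thermo_profile <- function(object, T_grid = NULL,
                                    min_prominence = 0.1, ...) {
  if (is.null(T_grid)) {
    T_grid <- seq(min(object$temperatures) * 0.8,
                  max(object$temperatures) * 1.2, length.out = 400)
  }
  cv <- specific_heat(object, T_grid)
  peaks <- find_melting_events(cv, min_prominence)
  p <- ggplot2::ggplot(cv, ggplot2::aes(x = .data$temperature, y = .data$cv)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "reduced temperature (kcal/mol)",
                  y = expression(C[V] ~ "(" * k[B] * ")"))
  if (nrow(peaks)) {
    p <- p + ggplot2::geom_vline(data = peaks,
                                 ggplot2::aes(xintercept = .data$temperature),
                                 linetype = ifelse(peaks$major, "solid",
                                                   "dotted"),
                                 colour = "grey40")
  }
  p
}

#' Plot the energy trace of a trajectory
#' @param object A `dmd_trajectory`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dmd_trajectory <- function(object, ...) {
  d <- trajectory_energies(object) |>
    tidyr::pivot_longer(c("pe", "ke"), names_to = "component",
                        values_to = "energy")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$energy,
                                  colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (reduced units)", y = "energy (kcal/mol)")
}

#' Heat map of a correlation map or difference map
#' @param object A `correlation_map` (or labelled square matrix, e.g.
#'   from [difference_map()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.correlation_map <- function(object, ...) {
  d <- tidy.correlation_map(object)
  lv <- unique(d$res_i)
  d$res_i <- factor(d$res_i, levels = lv)
  d$res_j <- factor(d$res_j, levels = lv)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$res_i, y = .data$res_j,
                                  fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "lightyellow",
                                  high = "red", limits = c(-1, 1) *
                                    max(abs(d$value))) +
    ggplot2::labs(x = NULL, y = NULL, fill = "C") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Compare per-residue flexibility of two trajectories
#'
#' @param wt,variant `dmd_trajectory` objects over the same beads.
#' @param site Optional modified-site index to mark.
#' @param ... Passed to [rmsf()].
#' @return A ggplot of the two RMSF profiles.
#' @export
plot_rmsf_comparison <- function(wt, variant, site = NULL, ...) {
  d <- dplyr::bind_rows(
    dplyr::mutate(rmsf(wt, ...), system = "wild type"),
    dplyr::mutate(rmsf(variant, ...), system = "variant"))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$atom, y = .data$rmsf,
                                       colour = .data$system)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "residue", y = "RMSF (Å)")
  if (!is.null(site)) {
    p <- p + ggplot2::geom_vline(xintercept = site, linetype = "dotted")
  }
  p
}
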