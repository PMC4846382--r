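# ggplot2 views of the standard result types: rasters, population
# histograms with classified bursts, quantal-regime heat maps, reduced-model
# output traces, and phase-plane geometry.

#' Raster plot of a network simulation
#'
#' Spike times per neuron, with neurons ordered by excitability (most
#' negative leak reversal at the bottom) as in the standard display
#' convention.
#'
#' @param sim An `mmo_sim`.
#' @param sort_by_e_l Order neurons by ascending `e_l`.
#' @return A ggplot.
#' @export
plot_raster <- function(sim, sort_by_e_l = TRUE) {
  sp <- sim$spikes
  if (sort_by_e_l) {
    ord <- sort_by_excitability(sim$network$population)
    sp$row <- match(sp$neuron_id, ord$neuron_id)
  } else sp$row <- sp$neuron_id
  ggplot2::ggplot(sp, ggplot2::aes(x = .data$time / 1000, y = .data$row)) +
    ggplot2::geom_point(shape = ".", alpha = 0.6) +
    ggplot2::labs(x = "time (s)", y = "neuron (sorted by E_L)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mmo_hist <- function(object, bursts = NULL, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$bin_mid / 1000, y = .data$count)) +
    ggplot2::geom_col(width = attr(object, "bin_width") / 1000) +
    ggplot2::labs(x = "time (s)", y = "spikes / bin") +
    ggplot2::theme_minimal()
  if (!is.null(bursts) && nrow(bursts)) {
    p <- p + ggplot2::geom_rect(
      data = bursts,
      ggplot2::aes(xmin = .data$onset / 1000, xmax = .data$offset / 1000,
                   ymin = -Inf, ymax = Inf, fill = .data$class),
      inherit.aes = FALSE, alpha = 0.15)
  }
  p
}

#' Population histogram with classified bursts
#'
#' @param hist An `mmo_hist`.
#' @param bursts Optional classified burst tibble to shade.
#' @return A ggplot.
#' @export
plot_histogram <- function(hist, bursts = NULL) autoplot(hist, bursts = bursts)

#' Quantal-regime heat map from a sweep table
#'
#' @param sweep Result of [heatmap_sweep()].
#' @param x,y Names of the two swept columns.
#' @return A ggplot tiling `n_per_la` (events per LA period) over the grid.
#' @export
plot_regime_map <- function(sweep, x = "w", y = "p") {
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data[[x]], y = .data[[y]],
                                      fill = factor(.data$n_per_la))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_d(name = "events / LA period", na.value = "grey80") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mmo_reduced <- function(object, ...) {
  n <- sum(grepl("^f[0-9]+$", names(object)))
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("time", paste0("f", seq_len(n)), "f_sum")],
    -"time", names_to = "unit", values_to = "f")
  long$unit <- factor(long$unit,
                      levels = c(paste0("f", seq_len(n)), "f_sum"),
                      labels = c(paste0("unit ", seq_len(n)), "sum"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time / 1000, y = .data$f)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$unit)) +
    ggplot2::labs(x = "time (s)", y = "output f(V)") +
    ggplot2::theme_minimal()
}

#' Output traces of a reduced-model run
#' @param traj An `mmo_reduced` trajectory.
#' @return A ggplot of each unit's `f(V)` and the summed output.
#' @export
plot_reduced_output <- function(traj) autoplot(traj)

#' Phase-plane portrait of one reduced neuron
#'
#' V-nullclines at the requested drive levels, the h-nullcline, knees, and
#' optionally a simulated `(v, h)` trajectory.
#'
#' @param e_l Leak reversal of the unit (mV).
#' @param drives Drive levels at which to draw V-nullclines.
#' @param trajectory Optional tibble with columns `v`, `h`.
#' @param params [reduced_params()].
#' @param v_grid Sampling grid.
#' @return A ggplot.
#' @export
plot_phase_plane <- function(e_l, drives = 0, trajectory = NULL,
                             params = reduced_params(),
                             v_grid = seq(-72, -20, length.out = 1001)) {
  vn <- dplyr::bind_rows(lapply(drives, function(d) {
    out <- v_nullcline(e_l, d, v_grid, params)
    out$drive <- d
    tibble::as_tibble(out)
  }))
  hn <- h_nullcline(v_grid, params)
  kn <- dplyr::bind_rows(lapply(drives, function(d) find_knees(e_l, d, params)))
  p <- ggplot2::ggplot(vn, ggplot2::aes(x = .data$v, y = .data$h,
                                        colour = factor(.data$drive))) +
    ggplot2::geom_line() +
    ggplot2::geom_line(data = hn, ggplot2::aes(colour = NULL), linetype = "dotted") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "V (mV)", y = "h_NaP", colour = "drive") +
    ggplot2::theme_minimal()
  if (nrow(kn))
    p <- p + ggplot2::geom_point(data = kn, ggplot2::aes(colour = factor(.data$drive)),
                                 shape = 4, size = 2)
  if (!is.null(trajectory))
    p <- p + ggplot2::geom_path(data = trajectory,
                                ggplot2::aes(colour = NULL), colour = "red",
                                linewidth = 0.3)
  p
}
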