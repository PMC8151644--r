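#' Tidy a simulation trajectory
#'
#' @param x A `tme_sim` from [run_simulation()].
#' @param ... Unused.
#' @return The trajectory tibble: one row per recorded MCS with the energy
#'   breakdown, type counts, bond counts, event tallies and morphometrics.
#' @export
tidy.tme_sim <- function(x, ...) x$trajectory

#' One-row summary of a simulation
#'
#' @inheritParams tidy.tme_sim
#' @return A one-row tibble: run length, final energy, final cell counts,
#'   total event tallies, and the final morphometric indices.
#' @export
glance.tme_sim <- function(x, ...) {
  tr <- x$trajectory
  last <- tr[nrow(tr), ]
  tibble(
    n_mcs = x$lattice$mcs,
    E_initial = tr$E_total[1],
    E_final = last$E_total,
    N2_final = last$N2,
    N3_final = last$N3,
    proliferations = sum(tr$ev_proliferation),
    moves_accepted = sum(tr$ev_move_accepted),
    moves_rejected = sum(tr$ev_move_rejected),
    infiltration_index = last$infiltration_index,
    wrapping_index = last$wrapping_index,
    escape_fraction = last$escape_fraction,
    mean_cluster_size = last$mean_cluster_size
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulation trajectory
#'
#' Facets the adhesion energy, the cell populations, and the morphometric
#' indices against Monte Carlo time.
#'
#' @param object A `tme_sim`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tme_sim <- function(object, ...) {
  tr <- object$trajectory
  long <- dplyr::bind_rows(
    tibble(mcs = tr$mcs, panel = "energy (ET)", series = "E_total",
           value = tr$E_total),
    tibble(mcs = tr$mcs, panel = "cells", series = "peritumoral",
           value = tr$N2),
    tibble(mcs = tr$mcs, panel = "cells", series = "cancer", value = tr$N3),
    tibble(mcs = tr$mcs, panel = "morphometrics", series = "infiltration",
           value = tr$infiltration_index),
    tibble(mcs = tr$mcs, panel = "morphometrics", series = "wrapping",
           value = tr$wrapping_index),
    tibble(mcs = tr$mcs, panel = "morphometrics", series = "escape",
           value = tr$escape_fraction)
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$mcs, .data$value,
                                     color = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "MCS", y = NULL, color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a lattice slice
#'
#' Raster of one z-slice of the configuration (default: the mid-plane),
#' colored by particle type.
#'
#' @param object A [tme_lattice()].
#' @param z Slice index (0-based); defaults to the middle plane.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tme_lattice <- function(object, z = NULL, ...) {
  if (is.null(z)) z <- (object$dims[3] - 1L) %/% 2L
  sl <- object$types[, , z + 1L]
  df <- tibble(
    x = as.vector(row(sl)) - 1L,
    y = as.vector(col(sl)) - 1L,
    type = factor(as.vector(sl), levels = 0:4,
                  labels = c("medium", "hydrogel", "peritumoral",
                             "cancer", "biomaterial"))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$type)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(
      values = c(medium = "white", hydrogel = "grey80",
                 peritumoral = "forestgreen", cancer = "firebrick",
                 biomaterial = "orange"),
      drop = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("z = %d, MCS %d", z, object$mcs)) +
    ggplot2::theme_minimal()
}
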