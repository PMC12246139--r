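# ggplot2 presentations of the result types.

#' Plot per-residue interaction fractions
#'
#' Stacked bars of the interaction fraction by residue and type, in the style
#' of the customary binding-mode bar charts; key residues (total fraction
#' above 0.5) are marked.
#'
#' @param object A [aggregate_fractions()] result.
#' @param min_total Only residues with total fraction above this are drawn
#'   (default 0.2, the conventional display threshold).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bindmode_fractions <- function(object, min_total = 0.2, ...) {
  df <- as_tibble(object) %>%
    filter(.data$total > min_total) %>%
    mutate(residue = stats::reorder(paste0(.data$resname, .data$resno), -.data$total))
  keys <- distinct(df, .data$residue, .data$total, .data$key)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$residue, y = .data$fraction,
                                   fill = .data$type)) +
    ggplot2::geom_col() +
    ggplot2::geom_point(data = keys[keys$key, ],
                        ggplot2::aes(x = .data$residue, y = .data$total + 0.05),
                        inherit.aes = FALSE, shape = 18, size = 2) +
    ggplot2::labs(x = NULL, y = "interaction fraction", fill = "type",
                  caption = "diamonds mark key residues (total > 0.5)") +
    ggplot2::theme_minimal()
}

#' Plot a water-site occupancy trace
#'
#' Occupancy raster over time by replica.
#'
#' @param object An [occupancy_trace()] result (replicas may be pooled).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bindmode_occupancy <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$time_ns, y = factor(.data$replica),
                               fill = .data$occupied)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "steelblue", `FALSE` = "grey90")) +
    ggplot2::labs(x = "time (ns)", y = "replica", fill = "site occupied") +
    ggplot2::theme_minimal()
}

#' Plot a masked descriptor density grid
#'
#' Heat map of the (distance, angle) density with masked cells transparent and
#' their individual observations overdrawn as points.
#'
#' @param object A [density_grid()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bindmode_density <- function(object, ...) {
  g <- object$grid
  ggplot2::ggplot() +
    ggplot2::geom_rect(data = g[!g$masked, ],
                       ggplot2::aes(xmin = .data$distance_lo, xmax = .data$distance_hi,
                                    ymin = .data$angle_lo, ymax = .data$angle_hi,
                                    fill = .data$fraction)) +
    ggplot2::geom_point(data = object$points,
                        ggplot2::aes(x = .data$distance, y = .data$angle),
                        color = "darkblue", size = 0.4, alpha = 0.6) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "distance (Angstrom)", y = "angle (degrees)",
                  fill = "fraction of frames") +
    ggplot2::theme_minimal()
}

#' Plot a time series trace
#'
#' @param object A `bindmode_trace` (from [rmsd_trace()] or
#'   [min_distance_trace()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bindmode_trace <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$time_ns, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ns)",
                  y = paste0(attr(object, "label") %||% "value",
                             " (", attr(object, "unit") %||% "", ")")) +
    ggplot2::theme_minimal()
}

#' @export
tidy.bindmode_superposition <- function(x, ...) {
  tibble(axis = c("x", "y", "z"),
         r1 = x$rotation[, 1], r2 = x$rotation[, 2], r3 = x$rotation[, 3],
         translation = x$translation)
}

#' @export
glance.bindmode_superposition <- function(x, ...) {
  tibble(rmsd = x$rmsd, rotation_det = det(x$rotation))
}
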