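# ggplot2 visualization of meshes, stress fields, sweeps and enrichment
# tables.

# mesh polygons as a long tibble for geom_polygon
.mesh_polygons <- function(mesh, values = NULL) {
  el <- mesh$elements
  m <- nrow(el)
  df <- tibble::tibble(
    element = rep(seq_len(m), each = 4L),
    x = as.vector(t(matrix(mesh$nodes[el, 1], ncol = 4L))),
    y = as.vector(t(matrix(mesh$nodes[el, 2], ncol = 4L))),
    region = rep(mesh$region, each = 4L))
  if (!is.null(values)) df$value <- rep(values, each = 4L)
  df
}

#' Plot a mesh colored by region
#'
#' @param object a `planar_mesh`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot planar_mesh
#' @export
autoplot.planar_mesh <- function(object, ...) {
  df <- .mesh_polygons(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, group = .data$element,
                                   fill = .data$region)) +
    ggplot2::geom_polygon(color = NA) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)", fill = "region") +
    ggplot2::theme_minimal()
}

#' Plot the maximum principal stress field of a solution
#'
#' Elements are drawn on the deformed geometry (displacements exaggerated
#' by `scale`) and filled by maximum principal stress.
#'
#' @param solution a `fem_solution`.
#' @param mesh the mesh it was solved on.
#' @param scale displacement exaggeration factor.
#' @return A ggplot.
#' @export
plot_stress_field <- function(solution, mesh, scale = 1) {
  mesh_def <- mesh
  mesh_def$nodes <- mesh$nodes + scale * solution$displacements
  df <- .mesh_polygons(mesh_def, values = solution$stress$s1)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, group = .data$element,
                                   fill = .data$value)) +
    ggplot2::geom_polygon(color = NA) +
    ggplot2::scale_fill_viridis_c(name = "s1 (Pa)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)",
                  title = sprintf("max principal stress (displacements x%g)",
                                  scale)) +
    ggplot2::theme_minimal()
}

#' Dose-response plot of a softening sweep
#'
#' @param object a `softening_sweep`.
#' @param ... unused.
#' @return A ggplot of outer-wall distension against softening factor, one
#'   line per disc radius.
#' @method autoplot softening_sweep
#' @export
autoplot.softening_sweep <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$factor, .data$max_distension_um,
                                   color = factor(.data$radius),
                                   group = factor(.data$radius))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "softening factor f", y = "max distension (um)",
                  color = "radius (um)") +
    ggplot2::theme_minimal()
}

#' Bar plot of relative enrichment by compartment
#'
#' Mean +- SD of cell-level relative enrichment per compartment and
#' treatment (sections averaged within cells first).
#'
#' @param object an `enrichment_table`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot enrichment_table
#' @export
autoplot.enrichment_table <- function(object, ...) {
  df <- object |>
    dplyr::filter(!is.na(.data$relative_enrichment)) |>
    dplyr::group_by(.data$treatment, .data$cell, .data$compartment) |>
    dplyr::summarise(re = mean(.data$relative_enrichment),
                     .groups = "drop") |>
    dplyr::group_by(.data$treatment, .data$compartment) |>
    dplyr::summarise(mean_re = mean(.data$re), sd_re = sd(.data$re),
                     .groups = "drop")
  df$compartment <- factor(df$compartment,
                           levels = c("outer_border", "inner_border",
                                      "interior"))
  ggplot2::ggplot(df, ggplot2::aes(.data$compartment, .data$mean_re,
                                   fill = .data$treatment)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_re - .data$sd_re,
                                        ymax = .data$mean_re + .data$sd_re),
                           position = ggplot2::position_dodge(0.9),
                           width = 0.2) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = NULL, y = "relative enrichment") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
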