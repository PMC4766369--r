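#' Specify a file of idealized epidermal cells
#'
#' Describes the 2D cross-section of a row of box-shaped epidermal cells:
#' an outer periclinal wall facing the organ surface, an inner periclinal
#' wall, and `n_cells + 1` anticlinal walls joining them. Adjacent cells
#' share a single anticlinal wall. All lengths are in micrometres.
#' `cell_width` and `cell_height` are the outer envelope of one cell,
#' walls included, so a 10x10 cell with 1 um walls encloses an 8x8 lumen.
#'
#' @param n_cells number of cells in the file (>= 1).
#' @param cell_width,cell_height outer envelope of one cell, um.
#' @param outer_wall_thickness thickness of the outer periclinal wall, um.
#' @param anticlinal_wall_thickness thickness of each anticlinal wall, um.
#' @param inner_wall_thickness thickness of the inner periclinal wall, um.
#' @return An object of class `cell_row_spec`.
#' @export
#' @examples
#' cell_row_spec(n_cells = 3)
cell_row_spec <- function(n_cells = 5,
                          cell_width = 20,
                          cell_height = 20,
                          outer_wall_thickness = 0.5,
                          anticlinal_wall_thickness = 0.3,
                          inner_wall_thickness = 0.3) {
  spec <- list(
    n_cells = as.integer(n_cells),
    cell_width = cell_width,
    cell_height = cell_height,
    outer_wall_thickness = outer_wall_thickness,
    anticlinal_wall_thickness = anticlinal_wall_thickness,
    inner_wall_thickness = inner_wall_thickness
  )
  class(spec) <- "cell_row_spec"
  validate_cell_row_spec(spec)
  spec
}

validate_cell_row_spec <- function(spec) {
  len <- unlist(spec[c("cell_width", "cell_height", "outer_wall_thickness",
                       "anticlinal_wall_thickness", "inner_wall_thickness")])
  if (any(!is.finite(len)) || any(len <= 0)) {
    stop("all cell-row lengths must be positive and finite", call. = FALSE)
  }
  if (spec$n_cells < 1L) stop("n_cells must be >= 1", call. = FALSE)
  thick <- len[3:5]
  if (any(thick >= spec$cell_width / 2) || any(thick >= spec$cell_height / 2)) {
    stop("wall thicknesses must be < cell_width/2 and < cell_height/2",
         call. = FALSE)
  }
  # lumen must have positive extent or walls self-intersect
  if (spec$cell_width - 2 * spec$anticlinal_wall_thickness <= 0 ||
      spec$cell_height - spec$outer_wall_thickness -
        spec$inner_wall_thickness <= 0) {
    stop("invalid thickness combination: lumen would be empty ",
         "(walls self-intersect)", call. = FALSE)
  }
  invisible(spec)
}

#' @export
print.cell_row_spec <- function(x, ...) {
  cat(sprintf(
    "<cell_row_spec> %d cell(s), %g x %g um envelope; walls (um): outer %g, anticlinal %g, inner %g\n",
    x$n_cells, x$cell_width, x$cell_height, x$outer_wall_thickness,
    x$anticlinal_wall_thickness, x$inner_wall_thickness))
  invisible(x)
}

#' Build the wall domain of a cell file
#'
#' Lays out the watertight multi-rectangle wall domain for a
#' [cell_row_spec()]: one full-width outer and inner periclinal wall strip,
#' `n_cells + 1` anticlinal walls, and one lumen rectangle per cell.
#' Vertex points are the intersections of the anticlinal wall midlines with
#' the periclinal wall midlines, on both the outer and the inner side; they
#' are the cross-sectional traces of the cells' 3D geometric edges.
#'
#' @param spec a [cell_row_spec()].
#' @return An object of class `wall_domain` with elements `regions`
#'   (tibble of axis-aligned rectangles with region labels), `lumens`
#'   (tibble, one rectangle per cell), `vertex_points` (tibble with `x`,
#'   `y`, `side`), `width`, `height` and the originating `spec`.
#' @export
#' @examples
#' dom <- build_cell_row(cell_row_spec(n_cells = 3))
#' wall_area(dom)
build_cell_row <- function(spec) {
  validate_cell_row_spec(spec)
  n <- spec$n_cells
  w <- spec$cell_width; H <- spec$cell_height
  to <- spec$outer_wall_thickness
  ta <- spec$anticlinal_wall_thickness
  ti <- spec$inner_wall_thickness
  pitch <- w - ta                       # shared-wall cell pitch
  W <- n * w - (n - 1) * ta             # total envelope width
  xa <- (0:n) * pitch                   # left face of each anticlinal wall

  regions <- dplyr::bind_rows(
    tibble::tibble(region = "periclinal_outer",
                   x0 = 0, x1 = W, y0 = H - to, y1 = H),
    tibble::tibble(region = "periclinal_inner",
                   x0 = 0, x1 = W, y0 = 0, y1 = ti),
    tibble::tibble(region = "anticlinal",
                   x0 = xa, x1 = xa + ta, y0 = ti, y1 = H - to)
  )
  lumens <- tibble::tibble(
    cell = seq_len(n),
    x0 = xa[seq_len(n)] + ta, x1 = xa[seq_len(n) + 1L],
    y0 = ti, y1 = H - to
  )
  vertex_points <- dplyr::bind_rows(
    tibble::tibble(x = xa + ta / 2, y = H - to / 2, side = "outer"),
    tibble::tibble(x = xa + ta / 2, y = ti / 2, side = "inner")
  )
  structure(list(regions = regions, lumens = lumens,
                 vertex_points = vertex_points,
                 width = W, height = H, spec = spec),
            class = "wall_domain")
}

#' @export
print.wall_domain <- function(x, ...) {
  cat(sprintf("<wall_domain> %g x %g um, %d cell(s), wall area %.4g um^2\n",
              x$width, x$height, x$spec$n_cells, wall_area(x)))
  invisible(x)
}

#' Total and per-region wall area of a domain
#'
#' @param domain a [build_cell_row()] domain.
#' @return `wall_area()`: total wall cross-sectional area (um^2).
#'   `region_areas()`: tibble of exact polygon area per region label.
#'   Anticlinal rectangles exclude the periclinal strips, so region areas
#'   sum to the total without double counting.
#' @export
wall_area <- function(domain) {
  envelope <- domain$width * domain$height
  lum <- sum((domain$lumens$x1 - domain$lumens$x0) *
               (domain$lumens$y1 - domain$lumens$y0))
  envelope - lum
}

#' @rdname wall_area
#' @export
region_areas <- function(domain) {
  domain$regions |>
    dplyr::mutate(area = (.data$x1 - .data$x0) * (.data$y1 - .data$y0)) |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(area = sum(.data$area), .groups = "drop")
}

#' Vertex softening parameters
#'
#' The softened discs emulate reduced wall stiffness where anticlinal walls
#' intersect the periclinal walls. `factor` divides the elastic modulus in
#' the affected elements; `radius` is the disc radius around each vertex
#' point.
#'
#' @param factor stiffness divisor f, dimensionless, >= 1.
#' @param radius disc radius around each vertex point, um, >= 0.
#' @return An object of class `softening_spec`.
#' @export
softening_spec <- function(factor = 3, radius = 0.5) {
  if (!is.finite(factor) || factor < 1) stop("factor must be >= 1", call. = FALSE)
  if (!is.finite(radius) || radius < 0) stop("radius must be >= 0", call. = FALSE)
  structure(list(factor = factor, radius = radius), class = "softening_spec")
}
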