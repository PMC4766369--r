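# Plain-text interfaces: key-value config files, VTK legacy export of
# meshes and solutions, CSV export.

#' Read or write a wall model configuration
#'
#' Plain-text `key = value` configuration (lengths in um, pressures in
#' bar, moduli in Pa; `#` starts a comment). Recognized keys:
#' `n_cells`, `cell_width_um`, `cell_height_um`, `outer_wall_thickness_um`,
#' `anticlinal_wall_thickness_um`, `inner_wall_thickness_um`,
#' `elastic_modulus_pa`, `poisson_ratio`, `turgor_pressure_bar`,
#' `soften_factor`, `soften_radius_um`, `target_h_um`. Missing keys fall
#' back to the package defaults.
#'
#' @param path file path.
#' @return `read_wall_config()`: a list with `spec` ([cell_row_spec()]),
#'   `material` ([wall_material()]), `load` ([load_case()]), `softening`
#'   ([softening_spec()]) and `target_h`.
#' @export
read_wall_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) {
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  }
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- as.numeric(trimws(vapply(kv, `[[`, "", 2L)))
  cfg <- as.list(setNames(vals, keys))
  g <- function(key, default) cfg[[key]] %||% default
  spec <- cell_row_spec(
    n_cells = g("n_cells", 5),
    cell_width = g("cell_width_um", 20),
    cell_height = g("cell_height_um", 20),
    outer_wall_thickness = g("outer_wall_thickness_um", 0.5),
    anticlinal_wall_thickness = g("anticlinal_wall_thickness_um", 0.3),
    inner_wall_thickness = g("inner_wall_thickness_um", 0.3))
  list(spec = spec,
       material = wall_material(g("elastic_modulus_pa", 5e8),
                                g("poisson_ratio", 0.45)),
       load = load_case(g("turgor_pressure_bar", 5) * 1e5),
       softening = softening_spec(g("soften_factor", 3),
                                  g("soften_radius_um", 0.5)),
       target_h = g("target_h_um", 0.1))
}

#' @rdname read_wall_config
#' @param config list as returned by `read_wall_config()`.
#' @export
write_wall_config <- function(config, path) {
  sp <- config$spec; mt <- config$material
  ld <- config$load; sf <- config$softening
  lines <- c(
    "# wall model configuration (lengths um, pressure bar, modulus Pa)",
    sprintf("n_cells = %d", sp$n_cells),
    sprintf("cell_width_um = %g", sp$cell_width),
    sprintf("cell_height_um = %g", sp$cell_height),
    sprintf("outer_wall_thickness_um = %g", sp$outer_wall_thickness),
    sprintf("anticlinal_wall_thickness_um = %g", sp$anticlinal_wall_thickness),
    sprintf("inner_wall_thickness_um = %g", sp$inner_wall_thickness),
    sprintf("elastic_modulus_pa = %g", mt$elastic_modulus),
    sprintf("poisson_ratio = %g", mt$poisson_ratio),
    sprintf("turgor_pressure_bar = %g", ld$turgor_pressure / 1e5),
    sprintf("soften_factor = %g", sf$factor),
    sprintf("soften_radius_um = %g", sf$radius),
    sprintf("target_h_um = %g", config$target_h))
  writeLines(lines, path)
  invisible(path)
}

#' Export a mesh (and optional solution) to legacy VTK
#'
#' Writes an ASCII VTK unstructured grid with quad cells, cell-data region
#' labels and, when a solution is supplied, point-data displacement vectors
#' and cell-data principal stresses.
#'
#' @param mesh a `planar_mesh`.
#' @param path output `.vtk` path.
#' @param solution optional `fem_solution` on the same mesh.
#' @return Invisibly, `path`.
#' @export
write_vtk <- function(mesh, path, solution = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); m <- nrow(mesh$elements)
  writeLines(c("# vtk DataFile Version 3.0",
               "pressurized wall cross-section", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.9g %.9g 0", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines(sprintf("CELLS %d %d", m, 5L * m), con)
  writeLines(sprintf("4 %d %d %d %d", mesh$elements[, 1] - 1L,
                     mesh$elements[, 2] - 1L, mesh$elements[, 3] - 1L,
                     mesh$elements[, 4] - 1L), con)
  writeLines(c(sprintf("CELL_TYPES %d", m),
               as.character(rep(9L, m))), con)
  region_codes <- as.integer(factor(mesh$region))
  writeLines(c(sprintf("CELL_DATA %d", m),
               "SCALARS region int 1", "LOOKUP_TABLE default",
               as.character(region_codes - 1L)), con)
  if (!is.null(solution)) {
    writeLines(c("SCALARS s1 double 1", "LOOKUP_TABLE default",
                 sprintf("%.9g", solution$stress$s1),
                 "SCALARS s2 double 1", "LOOKUP_TABLE default",
                 sprintf("%.9g", solution$stress$s2)), con)
    writeLines(c(sprintf("POINT_DATA %d", n),
                 "VECTORS displacement double",
                 sprintf("%.9g %.9g 0", solution$displacements[, 1],
                         solution$displacements[, 2])), con)
  }
  invisible(path)
}

#' Export a mesh as a CSV pair
#'
#' @param mesh a `planar_mesh`.
#' @param dir output directory; writes `nodes.csv` (node, x, y) and
#'   `elements.csv` (element, n1..n4, region).
#' @return Invisibly, the two paths.
#' @export
write_mesh_csv <- function(mesh, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nodes <- tibble::tibble(node = seq_len(nrow(mesh$nodes)),
                          x = mesh$nodes[, 1], y = mesh$nodes[, 2])
  elements <- tibble::tibble(element = seq_len(nrow(mesh$elements)),
                             n1 = mesh$elements[, 1], n2 = mesh$elements[, 2],
                             n3 = mesh$elements[, 3], n4 = mesh$elements[, 4],
                             region = mesh$region)
  pn <- file.path(dir, "nodes.csv"); pe <- file.path(dir, "elements.csv")
  write.csv(nodes, pn, row.names = FALSE)
  write.csv(elements, pe, row.names = FALSE)
  invisible(c(nodes = pn, elements = pe))
}

#' Write a softening sweep to CSV
#'
#' Deterministic CSV of the sweep rows (metric metadata is written as
#' leading comment lines).
#'
#' @param sweep a [run_softening_sweep()] result.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_sweep_csv <- function(sweep, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# distension_metric: ",
                      attr(sweep, "distension_metric")),
               paste0("# stress_summary: ", attr(sweep, "stress_summary"))),
             con)
  df <- as.data.frame(sweep)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}
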