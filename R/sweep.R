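# In-silico softening experiment: vary stiffness divisor and disc radius at
# the outer vertices and quantify radial distension and load relocation.

#' Maximum radial distension of the outer wall
#'
#' Maximum outward-normal displacement over the nodes of the outer
#' periclinal wall. For the cell-file cross-section the outward normal of
#' the outer wall is +y, so this is the largest upward nodal displacement;
#' it is non-negative under internal pressure. The mean outward
#' displacement is available via `mean_distension()` as a
#' delocalization-insensitive alternative readout.
#'
#' @param sol a `fem_solution`.
#' @param mesh the mesh it was solved on.
#' @return Distension in um.
#' @export
radial_distension <- function(sol, mesh) {
  nodes <- mesh$node_sets$outer_wall
  if (is.null(nodes) || length(nodes) == 0L) {
    stop("mesh has no outer_wall node set", call. = FALSE)
  }
  max(0, max(sol$displacements[nodes, 2]))
}

#' @rdname radial_distension
#' @export
mean_distension <- function(sol, mesh) {
  nodes <- mesh$node_sets$outer_wall
  mean(pmax(sol$displacements[nodes, 2], 0))
}

# area-weighted mean and max of s1 for the elements in `sel`
.region_s1 <- function(stress, sel) {
  if (!any(sel)) return(c(mean = NA_real_, max = NA_real_))
  c(mean = sum(stress$s1[sel] * stress$area[sel]) / sum(stress$area[sel]),
    max = max(stress$s1[sel]))
}

#' Sweep vertex softening factor and radius
#'
#' Runs the softening experiment: for every disc radius the mesh is
#' re-labelled, and for every stiffness divisor `f` (including the `f = 1`
#' baseline) the pressurized problem is solved. Per case the sweep records
#' the outer-wall distension (max and mean outward displacement) and the
#' area-weighted mean and max of the maximum principal stress `s1` in the
#' vertex discs and in the remaining outer-face elements.
#'
#' @param spec a [cell_row_spec()].
#' @param material base [wall_material()] of the unsoftened wall.
#' @param load a [load_case()].
#' @param factors stiffness divisors; must include 1 (the baseline).
#' @param radii softening disc radii, um.
#' @param target_h mesh size, um.
#' @param sides vertex sides to soften (see [tag_vertex_regions()]).
#' @return A `softening_sweep` tibble with one row per (factor, radius):
#'   columns `factor`, `radius`, `n_elements`, `max_distension_um`,
#'   `mean_distension_um`, `s1_vertex_mean`, `s1_vertex_max`,
#'   `s1_face_mean`, `s1_face_max` (Pa), plus metric metadata attributes
#'   `distension_metric` and `stress_summary`.
#' @export
#' @examples
#' \donttest{
#' sw <- run_softening_sweep(cell_row_spec(n_cells = 2), target_h = 0.15,
#'                           factors = c(1, 10), radii = 1)
#' }
run_softening_sweep <- function(spec, material = wall_material(),
                                load = load_case(),
                                factors = c(1, 3, 10),
                                radii = c(0.5, 1.0),
                                target_h = 0.1,
                                sides = "outer") {
  if (!any(abs(factors - 1) < 1e-12)) {
    stop("factors must include 1 (the unsoftened baseline)", call. = FALSE)
  }
  dom <- build_cell_row(spec)
  base_mesh <- mesh_domain(dom, target_h)
  rows <- list()
  solutions <- list()
  for (r in radii) {
    mesh <- tag_vertex_regions(base_mesh, r, sides = sides)
    for (f in sort(factors)) {
      mats <- softened_materials(material, softening_spec(f, r))
      sol <- tryCatch(solve_wall(mesh, mats, load), error = function(e) {
        stop(sprintf("solve failed at (factor = %g, radius = %g): %s",
                     f, r, conditionMessage(e)), call. = FALSE)
      })
      st <- sol$stress
      vx <- st$region == "vertex"
      face <- st$region == "periclinal_outer"
      v <- .region_s1(st, vx); fa <- .region_s1(st, face)
      key <- sprintf("f%g_r%g", f, r)
      solutions[[key]] <- sol
      rows[[key]] <- tibble::tibble(
        factor = f, radius = r, n_elements = nrow(mesh$elements),
        max_distension_um = radial_distension(sol, mesh),
        mean_distension_um = mean_distension(sol, mesh),
        s1_vertex_mean = v[["mean"]], s1_vertex_max = v[["max"]],
        s1_face_mean = fa[["mean"]], s1_face_max = fa[["max"]])
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "distension_metric") <-
    "max outward-normal nodal displacement of the outer periclinal wall"
  attr(out, "stress_summary") <-
    "area-weighted mean and max of s1 per region; face = periclinal_outer minus vertex discs"
  attr(out, "solutions") <- solutions
  attr(out, "mesh_h") <- target_h
  class(out) <- c("softening_sweep", class(out))
  out
}

#' Load relocation between wall regions
#'
#' Change in area-weighted mean maximum principal stress per region between
#' a baseline and a softened solution on the same mesh. Relocation of load
#' from the vertices to the faces is confirmed when the vertex change is
#' negative and the outer-face change positive.
#'
#' @param baseline,softened `fem_solution`s solved on `mesh`.
#' @param mesh the shared `planar_mesh` (with vertex labels applied).
#' @return A tibble with one row per region: `region`, `s1_baseline`,
#'   `s1_softened`, `delta_s1` (Pa), and a logical attribute
#'   `relocation_confirmed`.
#' @export
load_relocation <- function(baseline, softened, mesh) {
  if (baseline$n_elements != nrow(mesh$elements) ||
      softened$n_elements != nrow(mesh$elements)) {
    stop("solutions were not computed on the supplied mesh", call. = FALSE)
  }
  regions <- c("vertex", "periclinal_outer", "anticlinal", "periclinal_inner")
  regions <- intersect(regions, unique(mesh$region))
  rows <- purrr::map(regions, function(rg) {
    sel <- mesh$region == rg
    b <- .region_s1(baseline$stress, sel)[["mean"]]
    s <- .region_s1(softened$stress, sel)[["mean"]]
    tibble::tibble(region = rg, s1_baseline = b, s1_softened = s,
                   delta_s1 = s - b)
  })
  out <- dplyr::bind_rows(rows)
  dv <- out$delta_s1[out$region == "vertex"]
  df <- out$delta_s1[out$region == "periclinal_outer"]
  attr(out, "relocation_confirmed") <-
    length(dv) == 1L && length(df) == 1L && !is.na(dv) && dv < 0 && df > 0
  out
}
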