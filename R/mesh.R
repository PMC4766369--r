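# Structured all-quad meshing of the wall cross-section and generic
# planar_mesh plumbing shared by the FEM layer.

new_planar_mesh <- function(nodes, elements, region,
                            pressure_edges = NULL,
                            constrained_nodes = integer(),
                            node_sets = list(), h = NA_real_,
                            domain = NULL) {
  structure(list(nodes = nodes, elements = elements,
                 region = region, base_region = region,
                 pressure_edges = pressure_edges,
                 constrained_nodes = constrained_nodes,
                 node_sets = node_sets, h = h, domain = domain),
            class = "planar_mesh")
}

#' @export
print.planar_mesh <- function(x, ...) {
  cat(sprintf("<planar_mesh> %d nodes, %d quad elements; regions: %s\n",
              nrow(x$nodes), nrow(x$elements),
              paste(names(table(x$region)), table(x$region),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

# subdivide [a, b] into >= n_min intervals of size close to h
.subdivide <- function(a, b, h, n_min = 1L) {
  n <- max(n_min, as.integer(ceiling((b - a) / h - 1e-9)))
  seq(a, b, length.out = n + 1L)
}

#' Mesh a wall domain with linear quadrilaterals
#'
#' Generates a structured, conforming all-quad mesh of the wall
#' cross-section by laying a tensor grid over the envelope, with grid lines
#' snapped to every wall face, and keeping the grid cells whose centroid
#' lies in wall material. Every wall strip receives at least two elements
#' across its thickness. The mesh is deterministic for a fixed domain and
#' target size.
#'
#' Boundary bookkeeping produced alongside the mesh:
#' * `pressure_edges` — all lumen-facing element edges, with the edge
#'   length, the id of the lumen (cell) they bound and the outward normal
#'   of the wall material (pointing into the lumen),
#' * `constrained_nodes` — all nodes of the inner periclinal wall strip
#'   (the fully constrained boundary of the standard load case),
#' * `node_sets$outer_wall` — all nodes of the outer periclinal strip,
#'   whose outward normal is +y.
#'
#' @param domain a [build_cell_row()] wall domain.
#' @param target_h target element size, um; must be positive and no larger
#'   than the thinnest wall.
#' @return A `planar_mesh`: `nodes` (n x 2 matrix, um), `elements`
#'   (m x 4 integer matrix, counterclockwise), per-element `region` labels in
#'   `{periclinal_outer, periclinal_inner, anticlinal, vertex}`, and the
#'   boundary sets above.
#' @export
#' @examples
#' msh <- mesh_domain(build_cell_row(cell_row_spec(n_cells = 1)), target_h = 0.25)
mesh_domain <- function(domain, target_h) {
  stopifnot(inherits(domain, "wall_domain"))
  sp <- domain$spec
  thinnest <- min(sp$outer_wall_thickness, sp$anticlinal_wall_thickness,
                  sp$inner_wall_thickness)
  if (!is.finite(target_h) || target_h <= 0) {
    stop("target_h must be positive", call. = FALSE)
  }
  if (target_h > thinnest + 1e-12) {
    stop(sprintf("target_h (%g um) exceeds the thinnest wall (%g um)",
                 target_h, thinnest), call. = FALSE)
  }
  n <- sp$n_cells
  ta <- sp$anticlinal_wall_thickness
  xa <- (0:n) * (sp$cell_width - ta)
  x_break <- sort(unique(c(xa, xa + ta)))
  y_break <- c(0, sp$inner_wall_thickness,
               domain$height - sp$outer_wall_thickness, domain$height)

  # walls need >= 2 elements across; identify which intervals are walls
  xs <- ys <- list()
  for (i in seq_len(length(x_break) - 1L)) {
    is_wall <- any(abs(x_break[i] - xa) < 1e-9)  # [xa, xa + ta] intervals
    xs[[i]] <- .subdivide(x_break[i], x_break[i + 1L], target_h,
                          n_min = if (is_wall) 2L else 1L)
  }
  for (j in 1:3) {
    is_wall <- j != 2L
    ys[[j]] <- .subdivide(y_break[j], y_break[j + 1L], target_h,
                          n_min = if (is_wall) 2L else 1L)
  }
  xg <- sort(unique(round(unlist(xs), 12)))
  yg <- sort(unique(round(unlist(ys), 12)))
  nx <- length(xg) - 1L; ny <- length(yg) - 1L

  # candidate grid cells: keep those with centroid in wall material
  cx <- (xg[-1] + xg[-length(xg)]) / 2
  cy <- (yg[-1] + yg[-length(yg)]) / 2
  cc <- expand.grid(i = seq_len(nx), j = seq_len(ny))
  ccx <- cx[cc$i]; ccy <- cy[cc$j]
  in_lumen <- rep(FALSE, nrow(cc))
  for (k in seq_len(nrow(domain$lumens))) {
    lm <- domain$lumens[k, ]
    in_lumen <- in_lumen |
      (ccx > lm$x0 & ccx < lm$x1 & ccy > lm$y0 & ccy < lm$y1)
  }
  keep <- which(!in_lumen)
  cc <- cc[keep, , drop = FALSE]
  ccx <- ccx[keep]; ccy <- ccy[keep]

  node_id <- function(i, j) (j - 1L) * (nx + 1L) + i  # grid numbering
  el <- cbind(node_id(cc$i, cc$j), node_id(cc$i + 1L, cc$j),
              node_id(cc$i + 1L, cc$j + 1L), node_id(cc$i, cc$j + 1L))
  used <- sort(unique(as.vector(el)))
  remap <- integer(max(used)); remap[used] <- seq_along(used)
  elements <- matrix(remap[el], ncol = 4L)
  nodes <- cbind(x = xg[((used - 1L) %% (nx + 1L)) + 1L],
                 y = yg[((used - 1L) %/% (nx + 1L)) + 1L])

  region <- ifelse(ccy > y_break[3], "periclinal_outer",
                   ifelse(ccy < y_break[2], "periclinal_inner", "anticlinal"))

  mesh <- new_planar_mesh(nodes, elements, region, h = target_h,
                          domain = domain)
  mesh$pressure_edges <- .lumen_boundary_edges(mesh, domain)
  tol <- 1e-9
  mesh$constrained_nodes <-
    which(nodes[, 2] <= sp$inner_wall_thickness + tol)
  mesh$node_sets <- list(
    outer_wall = which(nodes[, 2] >=
                         domain$height - sp$outer_wall_thickness - tol),
    outer_surface = which(abs(nodes[, 2] - domain$height) < tol)
  )
  mesh
}

# boundary edges of the mesh lying on a lumen perimeter, with outward
# (into-lumen) normals derived from the counterclockwise element ordering
.lumen_boundary_edges <- function(mesh, domain) {
  el <- mesh$elements
  m <- nrow(el)
  loc_a <- c(1L, 2L, 3L, 4L); loc_b <- c(2L, 3L, 4L, 1L)
  edges <- do.call(rbind, lapply(1:4, function(k) {
    cbind(elem = seq_len(m), local = k,
          n1 = el[, loc_a[k]], n2 = el[, loc_b[k]])
  }))
  key <- paste(pmin(edges[, "n1"], edges[, "n2"]),
               pmax(edges[, "n1"], edges[, "n2"]))
  bnd <- edges[key %in% names(which(table(key) == 1L)), , drop = FALSE]
  p1 <- mesh$nodes[bnd[, "n1"], , drop = FALSE]
  p2 <- mesh$nodes[bnd[, "n2"], , drop = FALSE]
  mx <- (p1[, 1] + p2[, 1]) / 2; my <- (p1[, 2] + p2[, 2]) / 2
  cell <- rep(NA_integer_, nrow(bnd))
  tol <- 1e-9
  for (k in seq_len(nrow(domain$lumens))) {
    lm <- domain$lumens[k, ]
    on_per <- ((abs(my - lm$y0) < tol | abs(my - lm$y1) < tol) &
                 mx > lm$x0 - tol & mx < lm$x1 + tol) |
      ((abs(mx - lm$x0) < tol | abs(mx - lm$x1) < tol) &
         my > lm$y0 - tol & my < lm$y1 + tol)
    cell[on_per] <- lm$cell
  }
  sel <- !is.na(cell)
  bnd <- bnd[sel, , drop = FALSE]
  dx <- p2[sel, 1] - p1[sel, 1]; dy <- p2[sel, 2] - p1[sel, 2]
  len <- sqrt(dx^2 + dy^2)
  tibble::tibble(elem = bnd[, "elem"], local = bnd[, "local"],
                 n1 = bnd[, "n1"], n2 = bnd[, "n2"],
                 len = len, nx = dy / len, ny = -dx / len,
                 cell = cell[sel])
}

#' Element centroids and areas
#'
#' @param mesh a `planar_mesh`.
#' @return `element_centroids()`: m x 2 matrix; `element_areas()`: numeric
#'   vector of quadrilateral areas (shoelace formula, um^2).
#' @export
element_centroids <- function(mesh) {
  el <- mesh$elements
  cbind(rowMeans(matrix(mesh$nodes[el, 1], ncol = 4L)),
        rowMeans(matrix(mesh$nodes[el, 2], ncol = 4L)))
}

#' @rdname element_centroids
#' @export
element_areas <- function(mesh) {
  el <- mesh$elements
  x <- matrix(mesh$nodes[el, 1], ncol = 4L)
  y <- matrix(mesh$nodes[el, 2], ncol = 4L)
  nxt <- c(2L, 3L, 4L, 1L)
  0.5 * abs(rowSums(x * y[, nxt] - x[, nxt] * y))
}

#' Label vertex regions of a mesh
#'
#' Re-labels as `"vertex"` every element whose centroid lies within
#' `radius` of a vertex point (the trace of a geometric edge); all other
#' elements keep their original region label. Labelling is by centroid
#' membership, giving an unambiguous partition. By default only outer-side
#' vertices are softened, matching softening applied where anticlinal walls
#' intersect the outer wall; `sides = c("outer", "inner")` covers both.
#'
#' @param mesh a `planar_mesh` built by [mesh_domain()].
#' @param radius disc radius, um; `radius = 0` labels nothing.
#' @param sides which vertex points to use, subset of `c("outer", "inner")`.
#' @param vertex_points optional tibble with `x`, `y` (and `side`) columns
#'   overriding the domain's own vertex points.
#' @return The mesh with its `region` labels updated (base labels kept in
#'   `base_region`).
#' @export
tag_vertex_regions <- function(mesh, radius, sides = "outer",
                               vertex_points = NULL) {
  stopifnot(inherits(mesh, "planar_mesh"), radius >= 0)
  vp <- vertex_points %||% mesh$domain$vertex_points
  if (!is.null(vp$side)) vp <- vp[vp$side %in% sides, , drop = FALSE]
  region <- mesh$base_region
  if (radius > 0 && nrow(vp) > 0) {
    cen <- element_centroids(mesh)
    d2min <- rep(Inf, nrow(cen))
    for (k in seq_len(nrow(vp))) {
      d2 <- (cen[, 1] - vp$x[k])^2 + (cen[, 2] - vp$y[k])^2
      d2min <- pmin(d2min, d2)
    }
    region[d2min <= radius^2] <- "vertex"
  }
  mesh$region <- region
  mesh$vertex_radius <- radius
  mesh
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Audit a mesh for validity
#'
#' Checks that every element has a positive Jacobian at all four Gauss
#' points and that the free boundary edges form closed loops (every
#' boundary node is met by exactly two boundary edges).
#'
#' @param mesh a `planar_mesh`.
#' @return A list with `min_jacobian`, `closed_boundary` (logical) and
#'   `n_boundary_edges`.
#' @export
mesh_check <- function(mesh) {
  gp <- 1 / sqrt(3)
  pts <- rbind(c(-gp, -gp), c(gp, -gp), c(gp, gp), c(-gp, gp))
  el <- mesh$elements
  x <- matrix(mesh$nodes[el, 1], ncol = 4L)
  y <- matrix(mesh$nodes[el, 2], ncol = 4L)
  minJ <- Inf
  for (g in 1:4) {
    d <- .shape_derivs(pts[g, 1], pts[g, 2])
    j11 <- x %*% d[, 1]; j12 <- y %*% d[, 1]
    j21 <- x %*% d[, 2]; j22 <- y %*% d[, 2]
    minJ <- min(minJ, j11 * j22 - j12 * j21)
  }
  m <- nrow(el)
  loc_a <- c(1L, 2L, 3L, 4L); loc_b <- c(2L, 3L, 4L, 1L)
  a <- as.vector(el[, loc_a]); b <- as.vector(el[, loc_b])
  key <- paste(pmin(a, b), pmax(a, b))
  bnd <- key %in% names(which(table(key) == 1L))
  deg <- table(c(a[bnd], b[bnd]))
  list(min_jacobian = as.numeric(minJ),
       closed_boundary = all(deg == 2L),
       n_boundary_edges = sum(bnd) / 1L)
}

# bilinear quad shape-function derivatives wrt (xi, eta); 4 x 2
.shape_derivs <- function(xi, eta) {
  matrix(c(-(1 - eta), (1 - eta), (1 + eta), -(1 + eta),
           -(1 - xi), -(1 + xi), (1 + xi), (1 - xi)) / 4,
         ncol = 2L)
}

#' Structured quad meshes of simple shapes
#'
#' `mesh_annulus()` meshes a thick-walled ring (used to validate the solver
#' against the closed-form pressurized-cylinder solution); its
#' `pressure_edges` cover the inner circle. `mesh_rectangle()` meshes a
#' rectangle with `pressure_edges` on the side named by `load_side`.
#'
#' @param r_inner,r_outer ring radii, um.
#' @param n_radial,n_theta elements radially / circumferentially.
#' @param width,height rectangle size, um.
#' @param nx,ny rectangle subdivisions.
#' @param load_side rectangle side carrying `pressure_edges`.
#' @return A `planar_mesh` with region `"wall"` and no constrained nodes
#'   (set boundary conditions in the load case).
#' @export
mesh_annulus <- function(r_inner, r_outer, n_radial, n_theta) {
  stopifnot(r_outer > r_inner, r_inner > 0, n_radial >= 1, n_theta >= 3)
  r <- seq(r_inner, r_outer, length.out = n_radial + 1L)
  th <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  nid <- function(i, j) (j - 1L) * (n_radial + 1L) + i   # i radial, j angular
  nodes <- cbind(x = as.vector(outer(r, th, function(r, t) r * cos(t))),
                 y = as.vector(outer(r, th, function(r, t) r * sin(t))))
  ij <- expand.grid(i = seq_len(n_radial), j = seq_len(n_theta))
  jn <- ifelse(ij$j == n_theta, 1L, ij$j + 1L)
  # counterclockwise: (i, j) -> (i+1, j) -> (i+1, j+1) -> (i, j+1)
  elements <- cbind(nid(ij$i, ij$j), nid(ij$i + 1L, ij$j),
                    nid(ij$i + 1L, jn), nid(ij$i, jn))
  mesh <- new_planar_mesh(nodes, elements,
                          region = rep("wall", nrow(elements)),
                          h = (r_outer - r_inner) / n_radial)
  inner <- which(ij$i == 1L)
  n1 <- elements[inner, 1L]; n2 <- elements[inner, 4L]  # inner edge 4-1 CCW?
  # local edge 4 runs node4 -> node1; traversed CCW around the element the
  # inner arc is node4(i, j+1) -> node1(i, j): outward normal points inward
  p1 <- nodes[elements[inner, 4L], , drop = FALSE]
  p2 <- nodes[elements[inner, 1L], , drop = FALSE]
  dx <- p2[, 1] - p1[, 1]; dy <- p2[, 2] - p1[, 2]
  len <- sqrt(dx^2 + dy^2)
  mesh$pressure_edges <- tibble::tibble(
    elem = inner, local = 4L,
    n1 = elements[inner, 4L], n2 = elements[inner, 1L],
    len = len, nx = dy / len, ny = -dx / len, cell = 1L)
  mesh
}

#' @rdname mesh_annulus
#' @export
mesh_rectangle <- function(width, height, nx, ny, load_side = "right") {
  xg <- seq(0, width, length.out = nx + 1L)
  yg <- seq(0, height, length.out = ny + 1L)
  nid <- function(i, j) (j - 1L) * (nx + 1L) + i
  nodes <- cbind(x = rep(xg, ny + 1L), y = rep(yg, each = nx + 1L))
  ij <- expand.grid(i = seq_len(nx), j = seq_len(ny))
  elements <- cbind(nid(ij$i, ij$j), nid(ij$i + 1L, ij$j),
                    nid(ij$i + 1L, ij$j + 1L), nid(ij$i, ij$j + 1L))
  mesh <- new_planar_mesh(nodes, elements,
                          region = rep("wall", nrow(elements)),
                          h = width / nx)
  side <- match.arg(load_side, c("right", "left", "top", "bottom"))
  pick <- switch(side,
    right = list(which(ij$i == nx), 2L),
    left = list(which(ij$i == 1L), 4L),
    top = list(which(ij$j == ny), 3L),
    bottom = list(which(ij$j == 1L), 1L))
  el <- pick[[1]]; loc <- pick[[2]]
  loc_a <- c(1L, 2L, 3L, 4L); loc_b <- c(2L, 3L, 4L, 1L)
  n1 <- elements[el, loc_a[loc]]; n2 <- elements[el, loc_b[loc]]
  p1 <- nodes[n1, , drop = FALSE]; p2 <- nodes[n2, , drop = FALSE]
  dx <- p2[, 1] - p1[, 1]; dy <- p2[, 2] - p1[, 2]
  len <- sqrt(dx^2 + dy^2)
  mesh$pressure_edges <- tibble::tibble(elem = el, local = loc,
                                        n1 = n1, n2 = n2, len = len,
                                        nx = dy / len, ny = -dx / len,
                                        cell = 1L)
  mesh
}
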