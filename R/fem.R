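# Displacement finite elements for the pressurized wall cross-section.
#
# Bilinear quadrilaterals with selective reduced integration: the
# shear/deviatoric (mu) part of the constitutive matrix is integrated at
# 2x2 Gauss points, the dilatational (lambda) part at the element centroid.
# This avoids volumetric locking at nu = 0.45 without introducing hourglass
# modes. Geometry enters in micrometres and is converted to metres
# internally; stresses are in Pa, displacements are returned in um.

UM <- 1e-6

#' Isotropic wall material
#'
#' @param elastic_modulus Young's modulus E, Pa.
#' @param poisson_ratio Poisson ratio nu, in (0, 0.5). The default 0.45
#'   treats the hydrated wall as quasi-incompressible while staying clear of
#'   the incompressible limit.
#' @return An object of class `wall_material`.
#' @export
wall_material <- function(elastic_modulus = 5e8, poisson_ratio = 0.45) {
  if (!is.finite(elastic_modulus) || elastic_modulus <= 0) {
    stop("elastic_modulus must be > 0", call. = FALSE)
  }
  if (!is.finite(poisson_ratio) || poisson_ratio <= 0 || poisson_ratio >= 0.5) {
    stop("poisson_ratio must lie strictly between 0 and 0.5", call. = FALSE)
  }
  structure(list(elastic_modulus = elastic_modulus,
                 poisson_ratio = poisson_ratio),
            class = "wall_material")
}

#' Turgor load case
#'
#' @param turgor_pressure turgor pressure, Pa (5 bar = `5e5` Pa default).
#' @param constrained_nodes node indices with both displacement components
#'   fixed; defaults to the mesh's inner-periclinal node set.
#' @param fixed_x,fixed_y node indices with only that component fixed
#'   (roller supports; used e.g. on symmetry lines).
#' @param cells restrict pressurization to these lumen ids (`NULL` = the
#'   interior of every cell).
#' @return An object of class `load_case`.
#' @export
load_case <- function(turgor_pressure = 5e5, constrained_nodes = NULL,
                      fixed_x = integer(), fixed_y = integer(),
                      cells = NULL) {
  if (!is.finite(turgor_pressure) || turgor_pressure < 0) {
    stop("turgor_pressure must be >= 0", call. = FALSE)
  }
  structure(list(turgor_pressure = turgor_pressure,
                 constrained_nodes = constrained_nodes,
                 fixed_x = fixed_x, fixed_y = fixed_y, cells = cells),
            class = "load_case")
}

# per-element Lame parameters from a region -> material map
.element_lame <- function(mesh, materials, plane) {
  regions <- unique(mesh$region)
  if (inherits(materials, "wall_material")) {
    materials <- setNames(rep(list(materials), length(regions)), regions)
  }
  missing <- setdiff(regions, names(materials))
  if (length(missing)) {
    stop("no material for region(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  E <- unname(vapply(materials, function(m) m$elastic_modulus, 0)[mesh$region])
  nu <- unname(vapply(materials, function(m) m$poisson_ratio, 0)[mesh$region])
  mu <- E / (2 * (1 + nu))
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  if (plane == "stress") lam <- 2 * lam * mu / (lam + 2 * mu)
  list(lambda = lam, mu = mu)
}

# accumulate w * B_a' D B_b over elements for constitutive coefficients
# (d11 = d22, d12, d33), given dNdx/dNdy (m x 4) and w*detJ (length m).
.ke_accumulate <- function(ke, dNdx, dNdy, wdet, d11, d12, d33) {
  for (i in 1:4) {
    for (j in 1:4) {
      gxi <- dNdx[, i]; gyi <- dNdy[, i]
      gxj <- dNdx[, j]; gyj <- dNdy[, j]
      a <- 2L * i - 1L; b <- 2L * j - 1L
      ke[, (b - 1L) * 8L + a] <- ke[, (b - 1L) * 8L + a] +
        wdet * (d11 * gxi * gxj + d33 * gyi * gyj)
      ke[, b * 8L + a] <- ke[, b * 8L + a] +
        wdet * (d12 * gxi * gyj + d33 * gyi * gxj)
      ke[, (b - 1L) * 8L + a + 1L] <- ke[, (b - 1L) * 8L + a + 1L] +
        wdet * (d12 * gyi * gxj + d33 * gxi * gyj)
      ke[, b * 8L + a + 1L] <- ke[, b * 8L + a + 1L] +
        wdet * (d11 * gyi * gyj + d33 * gxi * gxj)
    }
  }
  ke
}

# geometry factors at a parent point: dNdx, dNdy (m x 4) and detJ (m)
.grad_at <- function(x, y, xi, eta) {
  d <- .shape_derivs(xi, eta)
  j11 <- as.vector(x %*% d[, 1]); j12 <- as.vector(y %*% d[, 1])
  j21 <- as.vector(x %*% d[, 2]); j22 <- as.vector(y %*% d[, 2])
  detJ <- j11 * j22 - j12 * j21
  # inverse Jacobian rows applied to parent gradients
  dNdx <- (outer(j22, d[, 1]) - outer(j12, d[, 2])) / detJ
  dNdy <- (outer(-j21, d[, 1]) + outer(j11, d[, 2])) / detJ
  list(dNdx = dNdx, dNdy = dNdy, detJ = detJ)
}

#' Assemble the global stiffness matrix
#'
#' Assembles the sparse symmetric stiffness of the plane linear-elastic
#' problem with selective reduced integration (dilatational term at the
#' element centroid, remaining term at 2x2 Gauss points).
#'
#' @param mesh a `planar_mesh`.
#' @param materials a single [wall_material()] applied everywhere, or a
#'   named list mapping each region label to a material.
#' @param plane `"strain"` (default; cross-sections of elongated cells) or
#'   `"stress"`.
#' @return A list with the sparse symmetric `K` (2n x 2n, N/m per unit
#'   thickness), and the per-element `lambda`/`mu` used.
#' @export
assemble_system <- function(mesh, materials, plane = c("strain", "stress")) {
  plane <- match.arg(plane)
  lame <- .element_lame(mesh, materials, plane)
  el <- mesh$elements
  x <- matrix(mesh$nodes[el, 1], ncol = 4L) * UM
  y <- matrix(mesh$nodes[el, 2], ncol = 4L) * UM
  m <- nrow(el)
  ke <- matrix(0, m, 64L)
  gp <- 1 / sqrt(3)
  for (g in seq_len(4L)) {
    xi <- c(-gp, gp, gp, -gp)[g]; eta <- c(-gp, -gp, gp, gp)[g]
    gg <- .grad_at(x, y, xi, eta)
    if (any(gg$detJ <= 0)) {
      stop("non-positive Jacobian in element(s): ",
           paste(utils::head(which(gg$detJ <= 0)), collapse = ", "),
           call. = FALSE)
    }
    ke <- .ke_accumulate(ke, gg$dNdx, gg$dNdy, gg$detJ,
                         d11 = 2 * lame$mu, d12 = 0, d33 = lame$mu)
  }
  gg <- .grad_at(x, y, 0, 0)
  ke <- .ke_accumulate(ke, gg$dNdx, gg$dNdy, 4 * gg$detJ,
                       d11 = lame$lambda, d12 = lame$lambda, d33 = 0)

  dof <- matrix(0L, m, 8L)
  dof[, seq(1L, 8L, 2L)] <- 2L * el - 1L
  dof[, seq(2L, 8L, 2L)] <- 2L * el
  ii <- dof[, rep(1:8, times = 8L)]
  jj <- dof[, rep(1:8, each = 8L)]
  n_dof <- 2L * nrow(mesh$nodes)
  K <- Matrix::sparseMatrix(i = as.vector(ii), j = as.vector(jj),
                            x = as.vector(ke), dims = c(n_dof, n_dof))
  K <- Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
  list(K = K, lambda = lame$lambda, mu = lame$mu, plane = plane)
}

#' Consistent nodal forces from lumen pressure
#'
#' Converts a uniform pressure on the mesh's lumen-facing boundary edges to
#' nodal forces (dead load on the undeformed geometry). Each edge of length
#' L carries total force `P * L` per unit thickness directed from the lumen
#' into the wall, split equally between its two end nodes.
#'
#' @param mesh a `planar_mesh` with `pressure_edges`.
#' @param load a [load_case()].
#' @return Nodal force vector of length `2 * n_nodes` (N per unit
#'   thickness).
#' @export
apply_pressure <- function(mesh, load) {
  pe <- mesh$pressure_edges
  if (is.null(pe) || nrow(pe) == 0L) {
    stop("mesh has no pressure boundary edges", call. = FALSE)
  }
  if (!is.null(load$cells)) pe <- pe[pe$cell %in% load$cells, , drop = FALSE]
  if (any(pe$len <= 0)) stop("zero-length boundary edge", call. = FALSE)
  f <- numeric(2L * nrow(mesh$nodes))
  if (load$turgor_pressure == 0 || nrow(pe) == 0L) return(f)
  # edge normals point out of the wall material (into the lumen); the
  # pressure pushes the wall the opposite way
  fx <- -load$turgor_pressure * pe$len * UM * pe$nx / 2
  fy <- -load$turgor_pressure * pe$len * UM * pe$ny / 2
  for (k in seq_len(nrow(pe))) {
    for (nd in c(pe$n1[k], pe$n2[k])) {
      f[2L * nd - 1L] <- f[2L * nd - 1L] + fx[k]
      f[2L * nd] <- f[2L * nd] + fy[k]
    }
  }
  f
}

#' Solve the pressurized-wall problem
#'
#' Assembles, constrains and solves `K u = f` by sparse Cholesky
#' factorization, then recovers the element-centroid stress tensors and
#' principal stresses. Fails loudly if the constrained system is singular
#' (insufficient constraints leave rigid-body modes) or if the residual
#' exceeds `1e-8` relative.
#'
#' @inheritParams assemble_system
#' @param load a [load_case()]; its `constrained_nodes` default to the
#'   mesh's inner-wall node set.
#' @param extra_forces optional additional nodal force vector (length
#'   `2 n`), e.g. boundary tractions assembled by the caller.
#' @return A `fem_solution`: `displacements` (n x 2 matrix, um),
#'   `stress` tibble (element, region, area, sxx, syy, sxy, s1, s2, Pa),
#'   `reactions` at constrained dofs, strain `energy` (J per unit
#'   thickness), and the relative `residual`.
#' @export
solve_wall <- function(mesh, materials, load = load_case(),
                       plane = c("strain", "stress"), extra_forces = NULL) {
  plane <- match.arg(plane)
  sys <- assemble_system(mesh, materials, plane)
  constrained <- load$constrained_nodes %||% mesh$constrained_nodes
  if (length(constrained) == 0L && length(load$fixed_x) == 0L &&
      length(load$fixed_y) == 0L) {
    stop("no constrained nodes: system has rigid-body modes", call. = FALSE)
  }
  f <- apply_pressure(mesh, load)
  if (!is.null(extra_forces)) f <- f + extra_forces
  n_dof <- 2L * nrow(mesh$nodes)
  fixed <- sort(unique(c(2L * constrained - 1L, 2L * constrained,
                         2L * load$fixed_x - 1L, 2L * load$fixed_y)))
  free <- setdiff(seq_len(n_dof), fixed)
  Kff <- sys$K[free, free, drop = FALSE]
  uf <- tryCatch(
    as.vector(Matrix::solve(Matrix::Cholesky(Kff, LDL = FALSE), f[free])),
    error = function(e) {
      stop("stiffness factorization failed (singular system / rigid-body ",
           "modes): ", conditionMessage(e), call. = FALSE)
    })
  u <- numeric(n_dof)
  u[free] <- uf
  res <- sqrt(sum((as.vector(sys$K %*% u)[free] - f[free])^2))
  fnorm <- sqrt(sum(f[free]^2))
  residual <- if (fnorm > 0) res / fnorm else res
  if (fnorm > 0 && residual > 1e-8) {
    stop(sprintf("solver residual %.3e exceeds 1e-8", residual),
         call. = FALSE)
  }
  stress <- .recover_stress(mesh, sys, u)
  reac <- as.vector(sys$K %*% u) - f
  sol <- structure(list(
    displacements = matrix(u, ncol = 2L, byrow = TRUE) / UM,
    stress = stress,
    reactions = tibble::tibble(node = rep(seq_len(nrow(mesh$nodes)),
                                          each = 2L)[fixed],
                               dof = rep(c("x", "y"),
                                         nrow(mesh$nodes))[fixed],
                               force = reac[fixed]),
    energy = 0.5 * sum(u * as.vector(sys$K %*% u)),
    residual = residual,
    load = load, plane = plane, n_nodes = nrow(mesh$nodes),
    n_elements = nrow(mesh$elements)),
    class = "fem_solution")
  sol
}

# centroid strain -> stress through the full (unsplit) constitutive matrix
.recover_stress <- function(mesh, sys, u) {
  el <- mesh$elements
  x <- matrix(mesh$nodes[el, 1], ncol = 4L) * UM
  y <- matrix(mesh$nodes[el, 2], ncol = 4L) * UM
  gg <- .grad_at(x, y, 0, 0)
  ux <- matrix(u[2L * el - 1L], ncol = 4L)
  uy <- matrix(u[2L * el], ncol = 4L)
  exx <- rowSums(gg$dNdx * ux)
  eyy <- rowSums(gg$dNdy * uy)
  gxy <- rowSums(gg$dNdy * ux) + rowSums(gg$dNdx * uy)
  lam <- sys$lambda; mu <- sys$mu
  sxx <- (lam + 2 * mu) * exx + lam * eyy
  syy <- lam * exx + (lam + 2 * mu) * eyy
  sxy <- mu * gxy
  pr <- principal_stresses(sxx, syy, sxy)
  tibble::tibble(element = seq_len(nrow(el)), region = mesh$region,
                 area = element_areas(mesh),
                 sxx = sxx, syy = syy, sxy = sxy,
                 s1 = pr$s1, s2 = pr$s2)
}

#' Principal stresses of 2D stress tensors
#'
#' Eigenvalues of the symmetric tensor `[[sxx, sxy], [sxy, syy]]`, with
#' `s1 >= s2`. `s1` is the maximum principal stress, the readout used to
#' quantify load relocation between wall regions.
#'
#' @param sxx,syy,sxy stress components (vectors), Pa. Alternatively pass a
#'   `fem_solution` as `sxx` to use its element stresses.
#' @return A tibble with columns `s1`, `s2` (and `element` for a solution
#'   input).
#' @export
principal_stresses <- function(sxx, syy = NULL, sxy = NULL) {
  if (inherits(sxx, "fem_solution")) {
    st <- sxx$stress
    return(dplyr::bind_cols(tibble::tibble(element = st$element),
                            principal_stresses(st$sxx, st$syy, st$sxy)))
  }
  mean_s <- (sxx + syy) / 2
  rad <- sqrt(((sxx - syy) / 2)^2 + sxy^2)
  tibble::tibble(s1 = mean_s + rad, s2 = mean_s - rad)
}

#' @export
print.fem_solution <- function(x, ...) {
  cat(sprintf(
    "<fem_solution> %d nodes, %d elements (%s); max |u| = %.4g um, max s1 = %.4g Pa\n",
    x$n_nodes, x$n_elements, x$plane,
    max(sqrt(rowSums(x$displacements^2))), max(x$stress$s1)))
  invisible(x)
}

#' Spatial convergence study
#'
#' Solves the standard cell-file problem on successively finer meshes and
#' reports the distension metric and strain energy, with the relative
#' change between successive refinements. Convergence is flagged when the
#' final successive change in the metric drops below `tol`.
#'
#' @param spec a [cell_row_spec()].
#' @param materials region materials as in [assemble_system()].
#' @param load a [load_case()].
#' @param h_sequence strictly decreasing element sizes, um (>= 2 values;
#'   use >= 3 to estimate an order).
#' @param softening optional [softening_spec()] applied at outer vertices.
#' @param tol successive-change threshold declaring convergence.
#' @return A tibble with one row per `h`: `h`, `n_elements`, `distension`
#'   (um), `energy`, `rel_change` in distension vs the previous row, and
#'   `converged`.
#' @export
convergence_study <- function(spec, materials, load = load_case(),
                              h_sequence = c(0.25, 0.125, 0.0625),
                              softening = NULL, tol = 0.02) {
  stopifnot(length(h_sequence) >= 2L, all(diff(h_sequence) <= 0))
  dom <- build_cell_row(spec)
  rows <- purrr::map(h_sequence, function(h) {
    mesh <- mesh_domain(dom, h)
    mats <- materials
    if (!is.null(softening)) {
      mesh <- tag_vertex_regions(mesh, softening$radius)
      mats <- softened_materials(materials, softening)
    }
    sol <- solve_wall(mesh, mats, load)
    tibble::tibble(h = h, n_elements = nrow(mesh$elements),
                   distension = radial_distension(sol, mesh),
                   energy = sol$energy)
  })
  out <- dplyr::bind_rows(rows)
  out$rel_change <- c(NA, abs(diff(out$distension)) /
                        pmax(abs(out$distension[-nrow(out)]), 1e-300))
  out$converged <- !is.na(out$rel_change) & out$rel_change < tol
  out
}

# region -> material map with the vertex region softened by factor f
softened_materials <- function(base, softening) {
  if (!inherits(base, "wall_material")) {
    stop("softened_materials expects a single base wall_material",
         call. = FALSE)
  }
  soft <- wall_material(base$elastic_modulus / softening$factor,
                        base$poisson_ratio)
  list(periclinal_outer = base, periclinal_inner = base,
       anticlinal = base, wall = base, vertex = soft)
}
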