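# Shared fixtures, built in code. Heavy objects are created once per test
# run and reused across files.

default_spec <- function(n_cells = 2) {
  cell_row_spec(n_cells = n_cells)
}

# small cell-file mesh used by several FEM tests
small_mesh <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- mesh_domain(build_cell_row(default_spec()), target_h = 0.25)
    }
    cache
  }
})

# shoelace polygon area, independent of the package's area code
shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# independent dense stiffness of one bilinear quad with selective reduced
# integration: loop-based B matrices, 2x2 Gauss for the mu term, centroid
# for the lambda term (all in SI units; coords in m)
oracle_quad_stiffness <- function(xy, E, nu, plane = "strain") {
  mu <- E / (2 * (1 + nu))
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  if (plane == "stress") lam <- 2 * lam * mu / (lam + 2 * mu)
  dshape <- function(xi, eta) {
    cbind(c(-(1 - eta), (1 - eta), (1 + eta), -(1 + eta)) / 4,
          c(-(1 - xi), -(1 + xi), (1 + xi), (1 - xi)) / 4)
  }
  # J[i,j] = sum_a dN[a,j] * xy[a,i]
  grad <- function(xi, eta) {
    dN <- dshape(xi, eta)
    J <- matrix(0, 2, 2)
    for (a in 1:4) {
      J[1, 1] <- J[1, 1] + xy[a, 1] * dN[a, 1]
      J[1, 2] <- J[1, 2] + xy[a, 1] * dN[a, 2]
      J[2, 1] <- J[2, 1] + xy[a, 2] * dN[a, 1]
      J[2, 2] <- J[2, 2] + xy[a, 2] * dN[a, 2]
    }
    detJ <- det(J)
    dNxy <- matrix(0, 4, 2)
    for (a in 1:4) {
      dNxy[a, ] <- solve(t(J), dN[a, ])
    }
    list(dNxy = dNxy, detJ = detJ)
  }
  B <- function(dNxy) {
    out <- matrix(0, 3, 8)
    for (a in 1:4) {
      out[1, 2 * a - 1] <- dNxy[a, 1]
      out[2, 2 * a] <- dNxy[a, 2]
      out[3, 2 * a - 1] <- dNxy[a, 2]
      out[3, 2 * a] <- dNxy[a, 1]
    }
    out
  }
  Dmu <- diag(c(2 * mu, 2 * mu, mu))
  Dlam <- lam * matrix(c(1, 1, 0), 3) %*% t(matrix(c(1, 1, 0), 3))
  K <- matrix(0, 8, 8)
  g <- 1 / sqrt(3)
  for (xi in c(-g, g)) for (eta in c(-g, g)) {
    gr <- grad(xi, eta)
    Bm <- B(gr$dNxy)
    K <- K + t(Bm) %*% Dmu %*% Bm * gr$detJ
  }
  gr <- grad(0, 0)
  Bm <- B(gr$dNxy)
  K + 4 * t(Bm) %*% Dlam %*% Bm * gr$detJ
}

# closed-form radial displacement of a plane-strain thick-walled cylinder
# under internal pressure P, outer boundary free (lengths in um, P and E
# consistent in Pa; returns um)
lame_radial_displacement <- function(r, a, b, P, E, nu) {
  (1 + nu) / E * P * a^2 / (b^2 - a^2) * ((1 - 2 * nu) * r + b^2 / r)
}

solve_lame_ring <- function(n_radial, a = 5, b = 10, P = 5e5,
                            E = 5e8, nu = 0.45) {
  ring <- mesh_annulus(a, b, n_radial, 4L * n_radial)
  nod <- ring$nodes
  on_x <- which(abs(nod[, 2]) < 1e-9)
  on_y <- which(abs(nod[, 1]) < 1e-9)
  lc <- load_case(P, constrained_nodes = integer(),
                  fixed_x = on_y, fixed_y = on_x)
  sol <- solve_wall(ring, wall_material(E, nu), lc)
  r <- sqrt(rowSums(nod^2))
  ur <- rowSums(sol$displacements * nod / r)
  list(mesh = ring, sol = sol, r = r, ur = ur,
       ur_exact = lame_radial_displacement(r, a, b, P, E, nu))
}

# tiny synthetic stack reused by enrichment/coloc tests
tiny_stack <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_stack(
        grid = c(2, 1, 1), cell_size = c(8, 8, 6.4), voxel_size = 0.2,
        model = puncta_model(n_puncta = 30, edge_fraction = 0.9,
                             rng_seed = 42),
        seed = 42)
    }
    cache
  }
})
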