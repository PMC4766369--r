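# Synthetic confocal stacks: axis-aligned polyhedral cells with analytic
# faces and edges, membrane-proximal puncta, Gaussian rendering and a
# Poisson + Gaussian noise model. Every downstream statistic in the package
# can therefore be checked against exact ground truth.

#' Generate a grid of box-shaped cells with analytic geometry
#'
#' Builds a 3D label volume of `grid[1] x grid[2] x grid[3]` axis-aligned
#' box cells with shared walls, surrounded by an exterior margin (label 0),
#' together with the analytic face planes and edge segments of every cell.
#' Axis-aligned boxes keep all edges and faces exact, so statistics
#' computed on the rendered stacks have closed-form ground truth.
#'
#' @param grid integer vector (nx, ny, nz) of cells per axis.
#' @param cell_size cell edge lengths, um (scalar or 3-vector).
#' @param voxel_size voxel pitch, um (scalar or 3-vector); default
#'   `c(0.1, 0.1, 0.3)` emulates confocal anisotropy.
#' @param margin exterior padding around the cell block, um.
#' @return A `cell_geometry` list: `labels` (integer array, 0 = exterior),
#'   `voxel_size`, `origin`, `cells` (tibble of box bounds), `edges`
#'   (tibble of 12 segments per cell), `faces` (tibble of 6 face planes per
#'   cell) and `n_distinct_faces` (shared faces counted once).
#' @export
generate_cells <- function(grid = c(1L, 1L, 1L), cell_size = 8,
                           voxel_size = c(0.1, 0.1, 0.3), margin = 0.6) {
  grid <- as.integer(rep(grid, length.out = 3L))
  cell_size <- rep(cell_size, length.out = 3L)
  voxel_size <- rep(voxel_size, length.out = 3L)
  if (any(grid < 1L)) stop("degenerate grid", call. = FALSE)
  if (any(cell_size < 4 * voxel_size)) {
    stop("cell_size must span at least 4 voxels per axis", call. = FALSE)
  }
  extent <- grid * cell_size + 2 * margin
  nv <- pmax(1L, as.integer(round(extent / voxel_size)))

  # voxel-center coordinate -> cell index per axis (0 outside the block)
  ax_index <- function(axis) {
    centers <- (seq_len(nv[axis]) - 0.5) * voxel_size[axis]
    idx <- floor((centers - margin) / cell_size[axis])
    idx[centers < margin | idx >= grid[axis]] <- NA
    idx
  }
  ix <- ax_index(1); iy <- ax_index(2); iz <- ax_index(3)
  lab_line <- function(i, j, k) {
    out <- i + grid[1] * j + grid[1] * grid[2] * k + 1L
    out[is.na(out)] <- 0L
    out
  }
  labels <- array(0L, dim = nv)
  IX <- array(rep(ix, times = nv[2] * nv[3]), dim = nv)
  IY <- array(rep(rep(iy, each = nv[1]), times = nv[3]), dim = nv)
  IZ <- array(rep(iz, each = nv[1] * nv[2]), dim = nv)
  labels[] <- lab_line(as.vector(IX), as.vector(IY), as.vector(IZ))

  idx <- expand.grid(ix = 0:(grid[1] - 1L), iy = 0:(grid[2] - 1L),
                     iz = 0:(grid[3] - 1L))
  cells <- tibble::tibble(
    cell = seq_len(nrow(idx)),
    x0 = margin + idx$ix * cell_size[1], x1 = margin + (idx$ix + 1) * cell_size[1],
    y0 = margin + idx$iy * cell_size[2], y1 = margin + (idx$iy + 1) * cell_size[2],
    z0 = margin + idx$iz * cell_size[3], z1 = margin + (idx$iz + 1) * cell_size[3])

  edges <- dplyr::bind_rows(purrr::map(seq_len(nrow(cells)), function(ci) {
    b <- cells[ci, ]
    xs <- c(b$x0, b$x1); ys <- c(b$y0, b$y1); zs <- c(b$z0, b$z1)
    rows <- list(); e <- 0L
    for (y in ys) for (z in zs) {            # 4 edges along x
      e <- e + 1L
      rows[[e]] <- tibble::tibble(cell = b$cell, edge = e, axis = 1L,
                                  x0 = b$x0, y0 = y, z0 = z,
                                  x1 = b$x1, y1 = y, z1 = z)
    }
    for (x in xs) for (z in zs) {            # 4 edges along y
      e <- e + 1L
      rows[[e]] <- tibble::tibble(cell = b$cell, edge = e, axis = 2L,
                                  x0 = x, y0 = b$y0, z0 = z,
                                  x1 = x, y1 = b$y1, z1 = z)
    }
    for (x in xs) for (y in ys) {            # 4 edges along z
      e <- e + 1L
      rows[[e]] <- tibble::tibble(cell = b$cell, edge = e, axis = 3L,
                                  x0 = x, y0 = y, z0 = b$z0,
                                  x1 = x, y1 = y, z1 = b$z1)
    }
    dplyr::bind_rows(rows)
  }))

  faces <- dplyr::bind_rows(purrr::map(seq_len(nrow(cells)), function(ci) {
    b <- cells[ci, ]
    tibble::tibble(cell = b$cell, face = 1:6,
                   axis = c(1L, 1L, 2L, 2L, 3L, 3L),
                   level = c(b$x0, b$x1, b$y0, b$y1, b$z0, b$z1),
                   inward = c(1, -1, 1, -1, 1, -1))
  }))

  n_distinct_faces <- (grid[1] + 1L) * grid[2] * grid[3] +
    grid[1] * (grid[2] + 1L) * grid[3] +
    grid[1] * grid[2] * (grid[3] + 1L)

  structure(list(labels = labels, voxel_size = voxel_size, origin = c(0, 0, 0),
                 grid = grid, cell_size = cell_size, margin = margin,
                 cells = cells, edges = edges, faces = faces,
                 n_distinct_faces = n_distinct_faces),
            class = "cell_geometry")
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf("<cell_geometry> %s cells of %s um in a %s-voxel volume\n",
              paste(x$grid, collapse = "x"),
              paste(x$cell_size, collapse = "x"),
              paste(dim(x$labels), collapse = "x")))
  invisible(x)
}

#' Puncta population model
#'
#' Parameters of the punctate compartment population rendered into
#' synthetic stacks. Defaults reproduce the immuno-EM characterization of
#' the edge-associated vesicle compartments: mean sectional diameter
#' 150 +- 35 nm, and mean plasma-membrane distance 93 +- 36 nm.
#' `edge_fraction` is the free knob of the simulation: 1 places every
#' punctum in the tube around a geometric edge (the edge-clustered
#' phenotype), 0 disperses all puncta uniformly through the cell interior
#' (the brefeldin-A-like dispersed control).
#'
#' @param n_puncta puncta per cell.
#' @param edge_fraction probability a punctum targets an edge, in [0, 1].
#' @param diameter_mean,diameter_sd punctum diameter distribution, um
#'   (normal, truncated at 0).
#' @param pm_distance_mean,pm_distance_sd distance from punctum centre to
#'   the plasma membrane, um (normal, truncated at 0).
#' @param psf_sigma Gaussian PSF sigma per axis, um.
#' @param intensity_per_punctum total integrated intensity contributed by
#'   one punctum, arbitrary units.
#' @param background_level mean background intensity per voxel.
#' @param read_noise_sd additive Gaussian read noise sigma.
#' @param rng_seed seed for all stochastic stages.
#' @return An object of class `puncta_model`.
#' @export
puncta_model <- function(n_puncta = 40L, edge_fraction = 0.9,
                         diameter_mean = 0.15, diameter_sd = 0.035,
                         pm_distance_mean = 0.093, pm_distance_sd = 0.036,
                         psf_sigma = c(0.1, 0.1, 0.25),
                         intensity_per_punctum = 2000,
                         background_level = 5, read_noise_sd = 2,
                         rng_seed = 1L) {
  stopifnot(edge_fraction >= 0, edge_fraction <= 1,
            diameter_mean > 0, diameter_sd >= 0,
            pm_distance_mean > 0, pm_distance_sd >= 0,
            all(psf_sigma > 0), intensity_per_punctum > 0,
            background_level >= 0, read_noise_sd >= 0)
  structure(list(n_puncta = as.integer(n_puncta),
                 edge_fraction = edge_fraction,
                 diameter_mean = diameter_mean, diameter_sd = diameter_sd,
                 pm_distance_mean = pm_distance_mean,
                 pm_distance_sd = pm_distance_sd,
                 psf_sigma = rep(psf_sigma, length.out = 3L),
                 intensity_per_punctum = intensity_per_punctum,
                 background_level = background_level,
                 read_noise_sd = read_noise_sd,
                 rng_seed = as.integer(rng_seed)),
            class = "puncta_model")
}

# normal truncated at zero by rejection
.rtnorm0 <- function(n, mean, sd) {
  if (sd == 0 || n == 0L) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  bad <- which(x < 0)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < 0]
  }
  x
}

#' Place puncta in a cell geometry
#'
#' Samples punctum centres per cell: with probability `edge_fraction` a
#' punctum is assigned to a geometric edge — a uniform position along an
#' edge chosen with probability proportional to its length, displaced
#' inward so that its distance to each of the two faces meeting at that
#' edge equals a sampled PM distance — otherwise it is uniform in the cell
#' interior. Fully reproducible for a fixed seed.
#'
#' @param model a [puncta_model()].
#' @param geom a [generate_cells()] geometry.
#' @param seed overrides `model$rng_seed`.
#' @return A tibble with one row per punctum: `cell`, `punctum`, `x`, `y`,
#'   `z` (um), `compartment` (`"edge"` or `"interior"`), `edge` (edge id or
#'   `NA`), `pm_distance` (sampled offset, `NA` for interior) and
#'   `diameter`.
#' @export
place_puncta <- function(model, geom, seed = model$rng_seed) {
  stopifnot(inherits(model, "puncta_model"), inherits(geom, "cell_geometry"))
  withr::with_seed(seed, {
    out <- purrr::map(seq_len(nrow(geom$cells)), function(ci) {
      b <- geom$cells[ci, ]
      n <- model$n_puncta
      is_edge <- runif(n) < model$edge_fraction
      diam <- .rtnorm0(n, model$diameter_mean, model$diameter_sd)
      x <- y <- z <- numeric(n)
      edge_id <- rep(NA_integer_, n)
      pmd <- rep(NA_real_, n)
      ne <- sum(is_edge)
      if (ne > 0) {
        ed <- geom$edges[geom$edges$cell == b$cell, ]
        lens <- sqrt((ed$x1 - ed$x0)^2 + (ed$y1 - ed$y0)^2 +
                       (ed$z1 - ed$z0)^2)
        pick <- sample.int(nrow(ed), ne, replace = TRUE, prob = lens)
        t <- runif(ne)
        d <- .rtnorm0(ne, model$pm_distance_mean, model$pm_distance_sd)
        px <- ed$x0[pick] + t * (ed$x1[pick] - ed$x0[pick])
        py <- ed$y0[pick] + t * (ed$y1[pick] - ed$y0[pick])
        pz <- ed$z0[pick] + t * (ed$z1[pick] - ed$z0[pick])
        ctr <- c((b$x0 + b$x1) / 2, (b$y0 + b$y1) / 2, (b$z0 + b$z1) / 2)
        # displace inward along the two axes fixed by the edge
        for (ax in 1:3) {
          p <- list(px, py, pz)[[ax]]
          fixed <- ed$axis[pick] != ax
          sgn <- ifelse(p < ctr[ax], 1, -1)
          p[fixed] <- p[fixed] + sgn[fixed] * d[fixed]
          if (ax == 1) px <- p else if (ax == 2) py <- p else pz <- p
        }
        x[is_edge] <- px; y[is_edge] <- py; z[is_edge] <- pz
        edge_id[is_edge] <- ed$edge[pick]
        pmd[is_edge] <- d
      }
      ni <- n - ne
      if (ni > 0) {
        x[!is_edge] <- runif(ni, b$x0, b$x1)
        y[!is_edge] <- runif(ni, b$y0, b$y1)
        z[!is_edge] <- runif(ni, b$z0, b$z1)
      }
      tibble::tibble(cell = b$cell, punctum = seq_len(n), x = x, y = y,
                     z = z,
                     compartment = ifelse(is_edge, "edge", "interior"),
                     edge = edge_id, pm_distance = pmd, diameter = diam)
    })
    dplyr::bind_rows(out)
  })
}

#' Classify punctum centres against the analytic geometry
#'
#' Recovers each punctum's compartment from its coordinates alone: a
#' punctum is `"edge"` if its centre lies within `tube_radius` of any
#' analytic edge segment of its cell, otherwise `"interior"`. Used to audit
#' the generator's recorded compartments.
#'
#' @param puncta tibble from [place_puncta()].
#' @param geom the matching [generate_cells()] geometry.
#' @param tube_radius edge-tube radius, um (default 0.3, about twice the
#'   punctum diameter).
#' @return The puncta tibble with `edge_distance` and `classified` columns.
#' @export
classify_puncta <- function(puncta, geom, tube_radius = 0.3) {
  dmin <- purrr::map_dbl(seq_len(nrow(puncta)), function(i) {
    p <- c(puncta$x[i], puncta$y[i], puncta$z[i])
    ed <- geom$edges[geom$edges$cell == puncta$cell[i], ]
    a <- cbind(ed$x0, ed$y0, ed$z0)
    bb <- cbind(ed$x1, ed$y1, ed$z1)
    ab <- bb - a
    t <- rowSums(sweep(a, 2, p, function(av, pv) (pv - av)) * ab) /
      rowSums(ab^2)
    t <- pmin(pmax(t, 0), 1)
    proj <- a + ab * t
    min(sqrt(rowSums(sweep(proj, 2, p)^2)))
  })
  puncta$edge_distance <- dmin
  puncta$classified <- ifelse(dmin <= tube_radius, "edge", "interior")
  puncta
}

#' Render an intensity stack from placed puncta
#'
#' Renders each punctum as a separable 3D Gaussian blob whose per-axis
#' sigma combines the punctum's own footprint (diameter treated as FWHM)
#' with the PSF sigma, normalized so every punctum contributes exactly
#' `intensity_per_punctum` of integrated signal. Optionally adds a membrane
#' signal on label boundaries, then background plus Poisson shot noise and
#' additive Gaussian read noise (clamped at 0).
#'
#' @param geom a [generate_cells()] geometry.
#' @param puncta tibble from [place_puncta()].
#' @param model a [puncta_model()] (noise and intensity parameters).
#' @param noise add the Poisson + Gaussian noise model?
#' @param membrane_intensity per-voxel intensity added on cell boundary
#'   voxels (0 disables the membrane channel).
#' @param seed noise seed; defaults to `model$rng_seed + 1`.
#' @return Numeric 3D intensity array matching `geom$labels`; attribute
#'   `clipped` counts puncta whose centres fell outside the volume (these
#'   are skipped with a warning).
#' @export
render_stack <- function(geom, puncta, model, noise = TRUE,
                         membrane_intensity = 0,
                         seed = model$rng_seed + 1L) {
  nv <- dim(geom$labels)
  vs <- geom$voxel_size
  img <- array(0, dim = nv)
  fwhm <- 2 * sqrt(2 * log(2))
  clipped <- 0L
  for (i in seq_len(nrow(puncta))) {
    ctr <- c(puncta$x[i], puncta$y[i], puncta$z[i])
    vox <- ctr / vs + 0.5           # voxel-centre coordinate system
    if (any(vox < 0.5) || any(vox > nv + 0.5)) {
      clipped <- clipped + 1L
      next
    }
    sig <- sqrt((puncta$diameter[i] / fwhm)^2 + model$psf_sigma^2) / vs
    w <- lapply(1:3, function(ax) {
      lo <- max(1L, floor(vox[ax] - 4 * sig[ax]))
      hi <- min(nv[ax], ceiling(vox[ax] + 4 * sig[ax]))
      g <- exp(-((lo:hi - vox[ax])^2) / (2 * sig[ax]^2))
      list(idx = lo:hi, g = g)
    })
    blob <- outer(outer(w[[1]]$g, w[[2]]$g), w[[3]]$g)
    blob <- blob * (model$intensity_per_punctum / sum(blob))
    img[w[[1]]$idx, w[[2]]$idx, w[[3]]$idx] <-
      img[w[[1]]$idx, w[[2]]$idx, w[[3]]$idx] + blob
  }
  if (clipped > 0L) {
    warning(sprintf("%d puncta outside the volume were clipped", clipped))
  }
  if (membrane_intensity > 0) {
    img <- img + membrane_intensity * boundary_mask(geom$labels)
  }
  if (noise) {
    img <- withr::with_seed(seed, {
      shot <- rpois(length(img), lambda = img + model$background_level)
      pmax(0, shot + rnorm(length(img), 0, model$read_noise_sd))
    })
    img <- array(img, dim = nv)
  } else if (model$background_level > 0) {
    img <- img + model$background_level
  }
  attr(img, "clipped") <- clipped
  img
}

# voxels adjacent (6-neighborhood) to a differing label
boundary_mask <- function(labels) {
  nv <- dim(labels)
  bm <- array(FALSE, dim = nv)
  shift_neq <- function(ax, by) {
    idx <- lapply(nv, seq_len)
    jdx <- idx
    idx[[ax]] <- seq_len(nv[ax] - 1L)
    jdx[[ax]] <- 1L + seq_len(nv[ax] - 1L)
    a <- do.call(`[`, c(list(labels), idx))
    b <- do.call(`[`, c(list(labels), jdx))
    neq <- array(a != b, dim = dim(a))
    bm[idx[[1]], idx[[2]], idx[[3]]] <<- bm[idx[[1]], idx[[2]], idx[[3]]] | neq
    bm[jdx[[1]], jdx[[2]], jdx[[3]]] <<- bm[jdx[[1]], jdx[[2]], jdx[[3]]] | neq
  }
  for (ax in 1:3) shift_neq(ax)
  bm
}

#' Simulate a complete synthetic confocal stack
#'
#' One-call wrapper chaining [generate_cells()], [place_puncta()] and
#' [render_stack()].
#'
#' @inheritParams generate_cells
#' @param model a [puncta_model()].
#' @param noise,membrane_intensity passed to [render_stack()].
#' @param seed master seed; the placement uses `seed`, the noise
#'   `seed + 1`.
#' @return A `synthetic_stack`: `intensity`, `labels`, `voxel_size`,
#'   `geometry`, `puncta` (ground truth) and `model`.
#' @export
#' @examples
#' st <- simulate_stack(grid = c(1, 1, 1), cell_size = 4,
#'                      model = puncta_model(n_puncta = 10), seed = 7)
simulate_stack <- function(grid = c(1L, 1L, 1L), cell_size = 8,
                           voxel_size = c(0.1, 0.1, 0.3), margin = 0.6,
                           model = puncta_model(), noise = TRUE,
                           membrane_intensity = 0,
                           seed = model$rng_seed) {
  geom <- generate_cells(grid, cell_size, voxel_size, margin)
  puncta <- place_puncta(model, geom, seed = seed)
  intensity <- render_stack(geom, puncta, model, noise = noise,
                            membrane_intensity = membrane_intensity,
                            seed = seed + 1L)
  structure(list(intensity = intensity, labels = geom$labels,
                 voxel_size = geom$voxel_size, geometry = geom,
                 puncta = puncta, model = model, seed = seed),
            class = "synthetic_stack")
}

#' @export
print.synthetic_stack <- function(x, ...) {
  cat(sprintf(
    "<synthetic_stack> %s voxels @ %s um; %d cells, %d puncta (edge fraction %.2f)\n",
    paste(dim(x$intensity), collapse = "x"),
    paste(x$voxel_size, collapse = "x"),
    nrow(x$geometry$cells), nrow(x$puncta), x$model$edge_fraction))
  invisible(x)
}

#' Simulate a two-channel colocalization experiment
#'
#' Renders two channels over the same cell geometry in which a fraction
#' `rho` of channel-A puncta are co-placed (identical centres) in channel
#' B; the remaining channel-B puncta are placed independently. The planted
#' `rho` is the ground truth recovered by [reciprocal_coloc()].
#'
#' @param rho planted co-placement fraction in [0, 1].
#' @inheritParams simulate_stack
#' @return A list with `a` and `b` (two `synthetic_stack`s sharing labels)
#'   and `rho`.
#' @export
simulate_coloc_stacks <- function(rho, grid = c(2L, 2L, 1L), cell_size = 8,
                                  voxel_size = c(0.1, 0.1, 0.3),
                                  margin = 0.6, model = puncta_model(),
                                  seed = 1L) {
  stopifnot(rho >= 0, rho <= 1)
  geom <- generate_cells(grid, cell_size, voxel_size, margin)
  pa <- place_puncta(model, geom, seed = seed)
  pb_ind <- place_puncta(model, geom, seed = seed + 1000L)
  pb <- withr::with_seed(seed + 2000L, {
    dplyr::bind_rows(purrr::map(unique(pa$cell), function(ci) {
      ac <- pa[pa$cell == ci, ]
      bc <- pb_ind[pb_ind$cell == ci, ]
      n_co <- round(rho * nrow(ac))
      co <- ac[sample.int(nrow(ac), n_co), ]
      dplyr::bind_rows(co, bc[seq_len(nrow(ac) - n_co), ])
    }))
  })
  ia <- render_stack(geom, pa, model, seed = seed + 1L)
  ib <- render_stack(geom, pb, model, seed = seed + 3000L)
  mk <- function(int, pt) {
    structure(list(intensity = int, labels = geom$labels,
                   voxel_size = geom$voxel_size, geometry = geom,
                   puncta = pt, model = model, seed = seed),
              class = "synthetic_stack")
  }
  list(a = mk(ia, pa), b = mk(ib, pb), rho = rho)
}

#' Write a synthetic stack to disk
#'
#' Writes the intensity volume as a 16-bit multi-page TIFF, the label
#' volume as a second TIFF, the puncta ground truth as CSV and a JSON
#' metadata sidecar (voxel size, model parameters, seed; the acquisition
#' parameters are synthetic stand-ins, recorded as such).
#'
#' @param stack a `synthetic_stack`.
#' @param dir output directory (created if needed).
#' @param name base file name.
#' @return Invisibly, the paths written.
#' @export
write_stack <- function(stack, dir, name = "stack") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scale <- max(stack$intensity, 1)
  pages <- lapply(seq_len(dim(stack$intensity)[3]), function(z) {
    t(stack$intensity[, , z]) / scale
  })
  p_int <- file.path(dir, paste0(name, "_intensity.tif"))
  tiff::writeTIFF(pages, p_int, bits.per.sample = 16L)
  lab_scale <- max(stack$labels, 1)
  lpages <- lapply(seq_len(dim(stack$labels)[3]), function(z) {
    t(stack$labels[, , z]) / lab_scale
  })
  p_lab <- file.path(dir, paste0(name, "_labels.tif"))
  tiff::writeTIFF(lpages, p_lab, bits.per.sample = 16L)
  p_csv <- file.path(dir, paste0(name, "_puncta.csv"))
  write.csv(stack$puncta, p_csv, row.names = FALSE)
  meta <- list(voxel_size_um = stack$voxel_size,
               intensity_scale = scale, label_scale = lab_scale,
               seed = stack$seed,
               model = unclass(stack$model),
               provenance = "synthetic stack; acquisition parameters are simulated stand-ins")
  p_json <- file.path(dir, paste0(name, "_meta.json"))
  jsonlite::write_json(meta, p_json, auto_unbox = TRUE, digits = NA)
  invisible(c(intensity = p_int, labels = p_lab, puncta = p_csv,
              meta = p_json))
}
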