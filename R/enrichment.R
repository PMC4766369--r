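# Shell-based membrane-enrichment quantification: consecutive sections
# parallel to the outer cell surface, distance bands from the plasma
# membrane, relative enrichment, its two-way ANOVA stage, and the
# puncta distance-to-periphery statistic.

#' Euclidean distance to the plasma membrane
#'
#' Exact anisotropic 3D Euclidean distance transform of one cell's voxels:
#' the distance of every voxel centre of `cell` to the nearest voxel centre
#' outside the cell. Distances are computed from the full 3D cell boundary,
#' not slice-wise, in physical units.
#'
#' @param labels integer 3D label array (0 = exterior).
#' @param cell cell id.
#' @param voxel_size voxel pitch per axis, um.
#' @return Numeric array of distances; voxels outside the cell carry 0
#'   (they are the seeds of the transform).
#' @export
distance_to_pm <- function(labels, cell, voxel_size) {
  voxel_size <- rep(voxel_size, length.out = 3L)
  mask <- labels == cell
  if (!any(mask)) stop("no voxels carry label ", cell, call. = FALSE)
  # crop to the cell's bounding box plus one voxel: the enclosing shell of
  # non-cell voxels makes the cropped transform exact inside the cell
  w <- which(mask, arr.ind = TRUE)
  nv <- dim(labels)
  lo <- pmax(1L, apply(w, 2, min) - 1L)
  hi <- pmin(nv, apply(w, 2, max) + 1L)
  sub <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  dsub <- .edt3d_cpp(as.logical(sub), dim(sub), as.numeric(voxel_size))
  out <- array(0, dim = nv)
  out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- dsub
  out[!mask] <- 0
  out
}

# depth of each voxel centre below the cell's outer face, along `axis`
.outer_depth <- function(stack, cell, axis = 3L, direction = 1L) {
  b <- stack$geometry$cells[stack$geometry$cells$cell == cell, ]
  if (nrow(b) == 0L) stop("no such cell: ", cell, call. = FALSE)
  vs <- stack$voxel_size[axis]
  nvax <- dim(stack$labels)[axis]
  centers <- (seq_len(nvax) - 0.5) * vs
  outer_level <- if (direction > 0) {
    b[[c("x1", "y1", "z1")[axis]]]
  } else {
    b[[c("x0", "y0", "z0")[axis]]]
  }
  depth_line <- if (direction > 0) outer_level - centers else centers - outer_level
  list(depth_line = depth_line, outer_level = outer_level, axis = axis)
}

#' Cut consecutive sections parallel to the outer surface
#'
#' Splits a cell's voxels into `n_sections` consecutive slabs of
#' `thickness` um, measured inward from the cell's outer surface along its
#' outward-normal axis. The outer surface of a synthetic box cell defaults
#' to its +z face (the face nearest the top of the volume, standing in for
#' the organ surface).
#'
#' @param stack a `synthetic_stack` (or list with `labels`, `voxel_size`,
#'   `geometry`).
#' @param cell cell id.
#' @param n_sections number of slabs.
#' @param thickness slab thickness, um.
#' @param axis outward-normal axis (1 = x, 2 = y, 3 = z).
#' @param direction +1 if the outer face is the high end of `axis`.
#' @return A list of integer voxel-index vectors, one per section (ordered
#'   outermost first), with attributes `boundaries_um` (section depths) and
#'   `cell`.
#' @export
cut_sections <- function(stack, cell, n_sections = 3L, thickness = 2,
                         axis = 3L, direction = 1L) {
  b <- stack$geometry$cells[stack$geometry$cells$cell == cell, ]
  if (nrow(b) == 0L) stop("no such cell: ", cell, call. = FALSE)
  lo <- b[[c("x0", "y0", "z0")[axis]]]
  hi <- b[[c("x1", "y1", "z1")[axis]]]
  need <- n_sections * thickness
  if (hi - lo < need - 1e-9) {
    stop(sprintf("cell %d is %.3g um deep along axis %d; %g um required",
                 cell, hi - lo, axis, need), call. = FALSE)
  }
  od <- .outer_depth(stack, cell, axis, direction)
  nv <- dim(stack$labels)
  ax_idx <- slice.index(array(seq_len(nv[axis]) == 0, dim = nv), axis)
  depth <- od$depth_line[ax_idx]
  in_cell <- stack$labels == cell
  sections <- lapply(seq_len(n_sections), function(s) {
    which(in_cell & depth > (s - 1) * thickness & depth <= s * thickness)
  })
  attr(sections, "boundaries_um") <- seq_len(n_sections) * thickness
  attr(sections, "cell") <- cell
  sections
}

#' Distance-band compartments of a section
#'
#' Partitions a section's cell voxels into the three distance bands used
#' by the enrichment statistic: an outer border 0-1 um from the plasma
#' membrane, an inner border 1-2 um, and the remaining cell interior.
#' Distances come from the full 3D cell boundary ([distance_to_pm()]), so
#' voxels near anticlinal faces fall in the border bands too.
#'
#' @param stack a `synthetic_stack`.
#' @param cell cell id.
#' @param section_voxels integer voxel indices of one section.
#' @param dist optional precomputed [distance_to_pm()] array for `cell`.
#' @param bands outer limits of the border bands, um.
#' @return Named list of voxel-index vectors `outer_border`,
#'   `inner_border`, `interior` (a band absent from the cell is an empty
#'   vector).
#' @export
shell_compartments <- function(stack, cell, section_voxels, dist = NULL,
                               bands = c(1, 2)) {
  if (is.null(dist)) {
    dist <- distance_to_pm(stack$labels, cell, stack$voxel_size)
  }
  d <- dist[section_voxels]
  list(outer_border = section_voxels[d <= bands[1]],
       inner_border = section_voxels[d > bands[1] & d <= bands[2]],
       interior = section_voxels[d > bands[2]])
}

#' Relative enrichment of intensity in membrane shells
#'
#' For each of `n_sections` consecutive sections of a cell, computes the
#' mean intensity of each distance-band compartment divided by the mean
#' intensity of the whole section: the relative enrichment. A uniform image
#' gives exactly 1 everywhere, and the voxel-count-weighted mean of the
#' three enrichments is exactly 1 per section for any image. Empty
#' compartments yield an explicit `NA`, never a silent zero.
#'
#' @inheritParams cut_sections
#' @param treatment label attached to the rows.
#' @return A tibble with one row per (section, compartment): `cell`,
#'   `section`, `compartment`, `n_voxels`, `mean_intensity`,
#'   `relative_enrichment`, `treatment`.
#' @export
relative_enrichment <- function(stack, cell, n_sections = 3L, thickness = 2,
                                axis = 3L, direction = 1L,
                                treatment = "control") {
  sections <- cut_sections(stack, cell, n_sections, thickness, axis,
                           direction)
  dist <- distance_to_pm(stack$labels, cell, stack$voxel_size)
  rows <- purrr::imap(sections, function(sv, s) {
    comp <- shell_compartments(stack, cell, sv, dist = dist)
    total_mean <- mean(stack$intensity[sv])
    purrr::imap(comp, function(idx, nm) {
      mi <- if (length(idx)) mean(stack$intensity[idx]) else NA_real_
      tibble::tibble(cell = cell, section = s, compartment = nm,
                     n_voxels = length(idx), mean_intensity = mi,
                     relative_enrichment = mi / total_mean,
                     treatment = treatment)
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(rows)
}

#' Enrichment table over all cells of a stack
#'
#' @inheritParams relative_enrichment
#' @param cells cell ids (default: all cells in the stack).
#' @return Row-bound [relative_enrichment()] tibble, class
#'   `enrichment_table`.
#' @export
enrichment_table <- function(stack, cells = NULL, n_sections = 3L,
                             thickness = 2, axis = 3L, direction = 1L,
                             treatment = "control") {
  cells <- cells %||% stack$geometry$cells$cell
  out <- dplyr::bind_rows(purrr::map(cells, function(ci) {
    relative_enrichment(stack, ci, n_sections, thickness, axis, direction,
                        treatment)
  }))
  class(out) <- c("enrichment_table", class(out))
  out
}

#' Two-way ANOVA of relative enrichment
#'
#' Fixed-effects two-way ANOVA of cell-level relative enrichment on
#' compartment, treatment and their interaction, with a Tukey HSD post hoc
#' stage. Sections are averaged within cell x compartment first, so cells
#' are the replicate unit (the factors and replicate unit are recorded in
#' the result).
#'
#' @param table an [enrichment_table()] containing >= 2 treatments.
#' @return An `enrichment_anova` list: `anova` tibble (term, df, sumsq,
#'   statistic, p.value), `tukey` tibble of pairwise comparisons, `fit`
#'   (the `aov` object) and `design` metadata.
#' @export
enrichment_anova <- function(table) {
  df <- table |>
    dplyr::filter(!is.na(.data$relative_enrichment)) |>
    dplyr::group_by(.data$treatment, .data$cell, .data$compartment) |>
    dplyr::summarise(relative_enrichment = mean(.data$relative_enrichment),
                     .groups = "drop")
  if (length(unique(df$treatment)) < 2L) {
    stop("enrichment_anova needs at least two treatments", call. = FALSE)
  }
  if (length(unique(df$compartment)) < 2L) {
    stop("enrichment_anova needs at least two compartment levels",
         call. = FALSE)
  }
  combos <- tidyr::expand_grid(treatment = unique(df$treatment),
                               compartment = unique(df$compartment))
  present <- dplyr::distinct(df, .data$treatment, .data$compartment)
  missing <- dplyr::anti_join(combos, present,
                              by = c("treatment", "compartment"))
  if (nrow(missing) > 0L) {
    stop("empty design cells: ",
         paste(missing$treatment, missing$compartment, sep = ":",
               collapse = ", "), call. = FALSE)
  }
  df$compartment <- factor(df$compartment,
                           levels = c("outer_border", "inner_border",
                                      "interior"))
  df$treatment <- factor(df$treatment)
  fit <- aov(relative_enrichment ~ compartment * treatment, data = df)
  sm <- summary(fit)[[1]]
  anova_tbl <- tibble::tibble(term = trimws(rownames(sm)),
                              df = sm$Df, sumsq = sm$`Sum Sq`,
                              statistic = sm$`F value`,
                              p.value = sm$`Pr(>F)`)
  tk <- TukeyHSD(fit)
  tukey_tbl <- dplyr::bind_rows(purrr::imap(tk, function(m, term) {
    tibble::tibble(term = term, contrast = rownames(m),
                   estimate = m[, "diff"], conf.low = m[, "lwr"],
                   conf.high = m[, "upr"], adj.p.value = m[, "p adj"])
  }))
  structure(list(anova = anova_tbl, tukey = tukey_tbl, fit = fit,
                 design = paste("two-way fixed effects:",
                                "compartment x treatment;",
                                "replicate unit = cell",
                                "(sections averaged within cell)")),
            class = "enrichment_anova")
}

#' @export
print.enrichment_anova <- function(x, ...) {
  cat("<enrichment_anova>", x$design, "\n")
  print(x$anova)
  invisible(x)
}

#' Distance of puncta to the cell periphery
#'
#' Euclidean distance of each punctum centre to the nearest point of its
#' cell's plasma membrane. For synthetic box cells the distance is the
#' analytic distance to the nearest face plane; puncta may also come from
#' intensity-based detection ([detect_puncta()]).
#'
#' @param stack a `synthetic_stack`.
#' @param puncta tibble with `cell`, `x`, `y`, `z` (defaults to the
#'   stack's ground-truth puncta).
#' @return The puncta tibble with a `periphery_distance` column (um).
#' @export
puncta_periphery_distance <- function(stack, puncta = stack$puncta) {
  if (is.null(puncta) || nrow(puncta) == 0L) {
    warning("no puncta: empty distance distribution")
    return(tibble::tibble(cell = integer(), x = numeric(), y = numeric(),
                          z = numeric(), periphery_distance = numeric()))
  }
  cells <- stack$geometry$cells
  b <- cells[match(puncta$cell, cells$cell), ]
  puncta$periphery_distance <- pmin(
    puncta$x - b$x0, b$x1 - puncta$x,
    puncta$y - b$y0, b$y1 - puncta$y,
    puncta$z - b$z0, b$z1 - puncta$z)
  puncta
}

#' Compare two periphery-distance distributions
#'
#' Wilcoxon rank-sum comparison of the per-punctum periphery distances of
#' two markers (e.g. an edge-clustered compartment versus dispersed
#' organelles), with summary quantiles per marker.
#'
#' @param d1,d2 numeric distance vectors (um).
#' @param names marker names for the summary.
#' @return A list with `summary` tibble (marker, n, quartiles) and `test`
#'   tibble (statistic, p.value).
#' @export
periphery_distance_test <- function(d1, d2, names = c("marker1", "marker2")) {
  qs <- function(d) quantile(d, c(0.25, 0.5, 0.75), names = FALSE)
  s <- tibble::tibble(marker = names, n = c(length(d1), length(d2)),
                      q25 = c(qs(d1)[1], qs(d2)[1]),
                      median = c(qs(d1)[2], qs(d2)[2]),
                      q75 = c(qs(d1)[3], qs(d2)[3]))
  wt <- wilcox.test(d1, d2)
  list(summary = s,
       test = tibble::tibble(method = "Wilcoxon rank-sum",
                             statistic = unname(wt$statistic),
                             p.value = wt$p.value))
}

#' Detect puncta as thresholded local maxima
#'
#' Finds voxels that exceed the background threshold
#' `mean(bg) + k * sd(bg)` and are local maxima in their 6-neighborhood;
#' returns their centre coordinates. Background is taken from exterior
#' (label 0) voxels.
#'
#' @param stack a `synthetic_stack`.
#' @param k SD multiplier above mean background.
#' @param min_separation greedy non-maximum suppression radius, um:
#'   detections closer than this to a brighter detection are dropped.
#'   Shot-noise voxels can exceed the threshold and be local maxima, so
#'   detections should be ranked by intensity when precision matters.
#' @return Tibble with `cell`, `x`, `y`, `z` (um) and `intensity`, ordered
#'   by decreasing intensity.
#' @export
detect_puncta <- function(stack, k = 2, min_separation = 0.5) {
  img <- stack$intensity
  bg <- img[stack$labels == 0L]
  thr <- mean(bg) + k * sd(bg)
  nv <- dim(img)
  is_max <- img > thr
  for (ax in 1:3) {
    n <- nv[ax]
    idx <- lapply(nv, seq_len); jdx <- idx
    idx[[ax]] <- seq_len(n - 1L); jdx[[ax]] <- 1L + seq_len(n - 1L)
    a <- do.call(`[`, c(list(img), idx))
    b <- do.call(`[`, c(list(img), jdx))
    lower <- array(a < b, dim = dim(a))
    is_max[idx[[1]], idx[[2]], idx[[3]]] <-
      is_max[idx[[1]], idx[[2]], idx[[3]]] & !lower
    is_max[jdx[[1]], jdx[[2]], jdx[[3]]] <-
      is_max[jdx[[1]], jdx[[2]], jdx[[3]]] & lower
  }
  w <- which(is_max, arr.ind = TRUE)
  out <- tibble::tibble(cell = stack$labels[is_max],
                        x = (w[, 1] - 0.5) * stack$voxel_size[1],
                        y = (w[, 2] - 0.5) * stack$voxel_size[2],
                        z = (w[, 3] - 0.5) * stack$voxel_size[3],
                        intensity = img[is_max])
  out <- out[order(-out$intensity), ]
  if (min_separation > 0 && nrow(out) > 1L) {
    keep <- logical(nrow(out))
    kx <- ky <- kz <- numeric(0)
    for (i in seq_len(nrow(out))) {
      if (length(kx) == 0L ||
          min((kx - out$x[i])^2 + (ky - out$y[i])^2 +
                (kz - out$z[i])^2) >= min_separation^2) {
        keep[i] <- TRUE
        kx <- c(kx, out$x[i]); ky <- c(ky, out$y[i]); kz <- c(kz, out$z[i])
      }
    }
    out <- out[keep, ]
  }
  out
}
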