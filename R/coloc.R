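# Reciprocal thresholded colocalization between two channels and the exact
# 2x2 contingency test for phenotype specificity.

#' Threshold a channel against its background
#'
#' Builds the binary signal mask of a channel: a voxel is signal iff its
#' intensity exceeds `mean(background) + k * sd(background)`. The
#' background region defaults to the exterior (label 0) voxels at least
#' `clearance` voxels away from any cell, so that signal bleeding across
#' the cell surface (PSF tails of membrane-proximal puncta) does not
#' inflate the background statistics; it must be disjoint from the cells.
#' A zero-variance background degenerates to a pure mean threshold, with a
#' warning.
#'
#' @param intensity 3D intensity array (or a `synthetic_stack`).
#' @param labels label array (taken from the stack if omitted).
#' @param k SD multiplier, typically 1 or 2.
#' @param background optional logical array / voxel indices overriding the
#'   default background region.
#' @param clearance exterior voxels closer than this many voxels to a cell
#'   are excluded from the default background region.
#' @return Logical array of the same shape; attributes `threshold`,
#'   `bg_mean`, `bg_sd`, `k`.
#' @export
threshold_mask <- function(intensity, labels = NULL, k = 2,
                           background = NULL, clearance = 5L) {
  if (inherits(intensity, "synthetic_stack")) {
    labels <- labels %||% intensity$labels
    intensity <- intensity$intensity
  }
  if (is.null(background)) {
    if (is.null(labels)) stop("need labels or an explicit background region",
                              call. = FALSE)
    background <- labels == 0L
    if (clearance > 0) {
      d <- array(.edt3d_cpp(as.logical(background), dim(labels),
                            c(1, 1, 1)), dim(labels))
      eroded <- background & d > clearance
      # only adopt the eroded region when it is large enough for stable
      # mean/SD estimates; otherwise fall back to the full exterior
      if (sum(eroded) >= 500L) background <- eroded
    }
  }
  bg <- intensity[background]
  if (length(bg) == 0L) stop("background region is empty", call. = FALSE)
  m <- mean(bg); s <- sd(bg)
  if (is.na(s) || s == 0) {
    warning("zero-variance background: thresholding at the mean only")
    s <- 0
  }
  thr <- m + k * s
  mask <- intensity > thr
  attr(mask, "threshold") <- thr
  attr(mask, "bg_mean") <- m
  attr(mask, "bg_sd") <- s
  attr(mask, "k") <- k
  mask
}

#' Reciprocal colocalization of two thresholded channels
#'
#' Manders-style voxel-overlap colocalization: per cell, the fraction of
#' channel-A signal voxels that are also channel-B signal, and the
#' reciprocal. Fractions with an empty denominator are reported as `NA`.
#' An object-based alternative (`object_coloc()`) reports the fraction of
#' discrete channel-A puncta whose centre falls in the B mask.
#'
#' @param mask_a,mask_b logical arrays from [threshold_mask()].
#' @param labels cell label array of the same shape.
#' @return A `coloc_result` tibble: `cell`, `n_a`, `n_b`, `n_overlap`,
#'   `frac_a_in_b`, `frac_b_in_a`, plus the thresholds as attributes.
#' @export
reciprocal_coloc <- function(mask_a, mask_b, labels) {
  if (!identical(dim(mask_a), dim(mask_b)) ||
      !identical(dim(mask_a), dim(labels))) {
    stop("mask and label shapes differ", call. = FALSE)
  }
  cells <- sort(setdiff(unique(as.vector(labels)), 0L))
  rows <- purrr::map(cells, function(ci) {
    sel <- labels == ci
    a <- mask_a[sel]; b <- mask_b[sel]
    na <- sum(a); nb <- sum(b); nab <- sum(a & b)
    tibble::tibble(cell = ci, n_a = na, n_b = nb, n_overlap = nab,
                   frac_a_in_b = if (na > 0) nab / na else NA_real_,
                   frac_b_in_a = if (nb > 0) nab / nb else NA_real_)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "k_a") <- attr(mask_a, "k")
  attr(out, "k_b") <- attr(mask_b, "k")
  class(out) <- c("coloc_result", class(out))
  out
}

#' @rdname reciprocal_coloc
#' @param puncta_a tibble of channel-A punctum centres (`cell`, `x`, `y`,
#'   `z`, um).
#' @param voxel_size voxel pitch, um.
#' @details `object_coloc()` also reports `frac_corrected`, the hit
#'   fraction corrected for chance co-occurrence:
#'   `(raw - q) / (1 - q)` with `q` the fraction of the cell's voxels
#'   covered by the B mask (the expected hit rate of a randomly placed
#'   object). The corrected value estimates the planted co-placement
#'   fraction without bias from mask coverage or background false
#'   positives.
#' @export
object_coloc <- function(puncta_a, mask_b, labels, voxel_size) {
  voxel_size <- rep(voxel_size, length.out = 3L)
  nv <- dim(mask_b)
  vi <- pmin(pmax(ceiling(puncta_a$x / voxel_size[1]), 1L), nv[1])
  vj <- pmin(pmax(ceiling(puncta_a$y / voxel_size[2]), 1L), nv[2])
  vk <- pmin(pmax(ceiling(puncta_a$z / voxel_size[3]), 1L), nv[3])
  hit <- mask_b[cbind(vi, vj, vk)]
  cov <- tibble::tibble(cell = as.vector(labels), in_b = as.vector(mask_b)) |>
    dplyr::filter(.data$cell > 0L) |>
    dplyr::group_by(.data$cell) |>
    dplyr::summarise(q_chance = mean(.data$in_b), .groups = "drop")
  tibble::tibble(cell = puncta_a$cell, in_b = hit) |>
    dplyr::group_by(.data$cell) |>
    dplyr::summarise(n_objects = dplyr::n(),
                     frac_objects_in_b = mean(.data$in_b),
                     .groups = "drop") |>
    dplyr::left_join(cov, by = "cell") |>
    dplyr::mutate(frac_corrected = (.data$frac_objects_in_b - .data$q_chance) /
                    (1 - .data$q_chance))
}

#' Group summary of colocalization fractions
#'
#' @param result a [reciprocal_coloc()] tibble.
#' @return One-row tibble with mean and SD of both reciprocal fractions
#'   across cells.
#' @export
coloc_summary <- function(result) {
  tibble::tibble(
    n_cells = nrow(result),
    mean_frac_a_in_b = mean(result$frac_a_in_b, na.rm = TRUE),
    sd_frac_a_in_b = sd(result$frac_a_in_b, na.rm = TRUE),
    mean_frac_b_in_a = mean(result$frac_b_in_a, na.rm = TRUE),
    sd_frac_b_in_a = sd(result$frac_b_in_a, na.rm = TRUE))
}

#' Exact test of a 2x2 contingency table
#'
#' Fisher's exact test computed by full hypergeometric enumeration: all
#' tables with the observed margins are enumerated, the one-sided p-value
#' sums the upper tail (tables with `a` at least as large as observed), and
#' the two-sided p-value sums the probabilities of all tables no more
#' probable than the observed one (the minimum-likelihood rule). A
#' degenerate margin (all-zero row or column) returns p = 1 with a
#' warning.
#'
#' @param a,b,c,d the table counts: rows are the two groups (e.g.
#'   genotype), columns phenotype present / absent; or pass a 2x2 matrix
#'   as `a`.
#' @return A tibble: `p_one_sided`, `p_two_sided`, `odds_ratio`
#'   (sample odds ratio, `Inf` when `b * c = 0`), and the counts.
#' @export
#' @examples
#' fisher_exact(16, 13, 0, 26)
fisher_exact <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(identical(dim(a), c(2L, 2L)))
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  n <- sum(counts)
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    warning("degenerate margin: p = 1")
    return(tibble::tibble(p_one_sided = 1, p_two_sided = 1,
                          odds_ratio = NA_real_, a = a, b = b, c = c, d = d))
  }
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  support <- lo:hi
  pr <- dhyper(support, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  p_one <- sum(pr[support >= a])
  p_two <- sum(pr[pr <= p_obs * (1 + 1e-7)])
  or <- if (b * c == 0) {
    if (a * d == 0) NA_real_ else Inf
  } else {
    (a * d) / (b * c)
  }
  tibble::tibble(p_one_sided = p_one, p_two_sided = min(1, p_two),
                 odds_ratio = or, a = a, b = b, c = c, d = d)
}
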