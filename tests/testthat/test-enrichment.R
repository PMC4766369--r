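# Shell enrichment statistic, its ANOVA stage, and periphery distances.

test_that("distance transform matches the analytic box-distance oracle", {
  g <- generate_cells(c(1, 1, 1), cell_size = c(4, 4, 3),
                      voxel_size = c(0.2, 0.2, 0.3))
  d <- distance_to_pm(g$labels, 1, g$voxel_size)
  w <- which(g$labels == 1L, arr.ind = TRUE)
  vs <- g$voxel_size
  b <- g$cells[1, ]
  # analytic: distance to nearest voxel centre outside the box, axis-wise
  steps_out <- function(coord, lo, hi, pitch) {
    pmin(coord - lo + pitch / 2, hi - coord + pitch / 2)
  }
  cx <- (w[, 1] - 0.5) * vs[1]
  cy <- (w[, 2] - 0.5) * vs[2]
  cz <- (w[, 3] - 0.5) * vs[3]
  # nearest outside voxel centre along each axis, rounded to the voxel grid
  dx <- ceiling((pmin(cx - b$x0, b$x1 - cx)) / vs[1] - 0.5 + 1e-9) * vs[1]
  dy <- ceiling((pmin(cy - b$y0, b$y1 - cy)) / vs[2] - 0.5 + 1e-9) * vs[2]
  dz <- ceiling((pmin(cz - b$z0, b$z1 - cz)) / vs[3] - 0.5 + 1e-9) * vs[3]
  oracle <- pmin(dx, dy, dz)
  expect_equal(d[g$labels == 1L], oracle, tolerance = 1e-9)
  # face-adjacent voxels are within a voxel diagonal of the membrane
  expect_lte(min(d[g$labels == 1L]), sqrt(sum(vs^2)))
})

test_that("cube shell volumes match the analytic expectation", {
  g <- generate_cells(c(1, 1, 1), cell_size = 10, voxel_size = 0.1,
                      margin = 0.3)
  d <- distance_to_pm(g$labels, 1, g$voxel_size)
  inside <- g$labels == 1L
  v_outer <- sum(inside & d <= 1) * 0.1^3
  v_inner <- sum(inside & d > 1 & d <= 2) * 0.1^3
  expect_equal(v_outer, 10^3 - 8^3, tolerance = 0.05)
  expect_equal(v_inner, 8^3 - 6^3, tolerance = 0.05)
})

test_that("sections tile the cell depth and partition its voxels", {
  st <- tiny_stack()           # cells 8 x 8 x 6.4 um
  secs <- cut_sections(st, 1, n_sections = 3, thickness = 2)
  expect_equal(length(secs), 3L)
  # pairwise disjoint, union within the cell
  all_idx <- unlist(secs)
  expect_equal(anyDuplicated(all_idx), 0L)
  expect_true(all(st$labels[all_idx] == 1L))
  # boundaries at 2 and 4 um from the outer face, within half a voxel
  b <- st$geometry$cells[1, ]
  zc <- (slice.index(st$labels, 3)[all_idx] - 0.5) * st$voxel_size[3]
  depth <- b$z1 - zc
  s_id <- rep(seq_along(secs), lengths(secs))
  for (s in 1:3) {
    rng <- range(depth[s_id == s])
    expect_lt(abs(rng[1] - (2 * (s - 1))), st$voxel_size[3] / 2 + 1e-9)
    expect_lt(abs(rng[2] - 2 * s), st$voxel_size[3] / 2 + 1e-9)
  }
  # depth 6.4 um: three 2-um sections fit; six do not
  expect_error(cut_sections(st, 1, n_sections = 6, thickness = 2),
               "required")
  expect_error(cut_sections(st, 99), "no such cell")
})

test_that("shell compartments partition each section by PM distance", {
  st <- tiny_stack()
  secs <- cut_sections(st, 2)
  dist <- distance_to_pm(st$labels, 2, st$voxel_size)
  for (sv in secs) {
    comp <- shell_compartments(st, 2, sv, dist = dist)
    expect_equal(sort(unname(unlist(comp))), sort(sv))
    expect_true(all(dist[comp$outer_border] <= 1))
    if (length(comp$inner_border)) {
      expect_true(all(dist[comp$inner_border] > 1 &
                        dist[comp$inner_border] <= 2))
    }
    if (length(comp$interior)) expect_true(all(dist[comp$interior] > 2))
  }
  # a thin cell has no interior band
  g <- generate_cells(c(1, 1, 1), cell_size = c(3.8, 3.8, 6.4),
                      voxel_size = 0.2)
  stthin <- list(labels = g$labels, voxel_size = g$voxel_size, geometry = g,
                 intensity = array(1, dim(g$labels)))
  class(stthin) <- "synthetic_stack"
  sthin <- cut_sections(stthin, 1)
  compthin <- shell_compartments(stthin, 1, sthin[[1]])
  expect_equal(length(compthin$interior), 0L)
})

test_that("uniform images give enrichment exactly 1 and scale invariance holds", {
  st <- tiny_stack()
  stu <- st
  stu$intensity <- array(3.7, dim(st$intensity))
  et <- enrichment_table(stu)
  expect_equal(et$relative_enrichment[!is.na(et$relative_enrichment)],
               rep(1, sum(!is.na(et$relative_enrichment))))

  # multiplying any image by c > 0 leaves enrichment unchanged
  et1 <- enrichment_table(st)
  st2 <- st
  st2$intensity <- st$intensity * 17.3
  et2 <- enrichment_table(st2)
  expect_equal(et1$relative_enrichment, et2$relative_enrichment,
               tolerance = 1e-12)
})

test_that("voxel-weighted mean enrichment is exactly 1 per section", {
  et <- enrichment_table(tiny_stack())
  chk <- et |>
    dplyr::filter(!is.na(.data$relative_enrichment)) |>
    dplyr::group_by(.data$cell, .data$section) |>
    dplyr::summarise(wm = sum(.data$relative_enrichment * .data$n_voxels) /
                       sum(.data$n_voxels), .groups = "drop")
  expect_equal(chk$wm, rep(1, nrow(chk)), tolerance = 1e-12)
})

test_that("signal confined to the outer band gives enrichment 1/phi", {
  st <- tiny_stack()
  secs <- cut_sections(st, 1)
  dist <- distance_to_pm(st$labels, 1, st$voxel_size)
  img <- array(0, dim(st$labels))
  sv <- secs[[1]]
  comp <- shell_compartments(st, 1, sv, dist = dist)
  img[comp$outer_border] <- 5
  stx <- st
  stx$intensity <- img
  et <- relative_enrichment(stx, 1)
  row <- et[et$section == 1 & et$compartment == "outer_border", ]
  phi <- length(comp$outer_border) / length(sv)
  expect_equal(row$relative_enrichment, 1 / phi, tolerance = 1e-12)
})

test_that("edge-localized stacks are enriched at the outer border, dispersed are flat", {
  model_e <- puncta_model(n_puncta = 40, edge_fraction = 0.9, rng_seed = 31)
  st_e <- simulate_stack(grid = c(3, 2, 1), cell_size = c(12, 12, 6.4),
                         voxel_size = 0.2, model = model_e, seed = 31)
  et_e <- enrichment_table(st_e, treatment = "edge_localized")
  model_d <- puncta_model(n_puncta = 40, edge_fraction = 0, rng_seed = 32)
  st_d <- simulate_stack(grid = c(3, 2, 1), cell_size = c(12, 12, 6.4),
                         voxel_size = 0.2, model = model_d, seed = 32)
  et_d <- enrichment_table(st_d, treatment = "dispersed")

  mean_by <- function(et, comp) {
    mean(et$relative_enrichment[et$compartment == comp], na.rm = TRUE)
  }
  # edge group: outer border above 1, interior below, outer above inner;
  # the combined 0-2 um border exceeds the interior
  expect_gt(mean_by(et_e, "outer_border"), 1)
  expect_lt(mean_by(et_e, "interior"), 1)
  expect_gt(mean_by(et_e, "outer_border"), mean_by(et_e, "inner_border"))
  border_e <- et_e |>
    dplyr::filter(.data$compartment != "interior",
                  !is.na(.data$relative_enrichment)) |>
    dplyr::summarise(m = sum(.data$relative_enrichment * .data$n_voxels) /
                       sum(.data$n_voxels))
  expect_gt(border_e$m, mean_by(et_e, "interior"))
  # dispersed group: all compartments near 1
  re_d <- et_d$relative_enrichment[!is.na(et_d$relative_enrichment)]
  expect_true(all(re_d > 0.8 & re_d < 1.2))
})

test_that("two-way ANOVA matches a direct sum-of-squares decomposition", {
  # balanced synthetic design with known shifts
  withr::with_seed(77, {
    df <- tidyr::expand_grid(treatment = c("t1", "t2"),
                             compartment = c("outer_border", "inner_border",
                                             "interior"),
                             cell = 1:12)
    shift <- with(df, 0.4 * (treatment == "t2") +
                    0.3 * (compartment == "outer_border") +
                    0.5 * (treatment == "t2" &
                             compartment == "outer_border"))
    df$relative_enrichment <- 1 + shift + rnorm(nrow(df), 0, 0.1)
    df$section <- 1L
    df$n_voxels <- 100L
    df$mean_intensity <- 1
  })
  an <- enrichment_anova(df)

  # independent oracle: textbook balanced two-way fixed-effects SS
  y <- df$relative_enrichment
  A <- factor(df$compartment); B <- factor(df$treatment)
  gm <- mean(y)
  ssa <- sum(tapply(y, A, function(v) length(v) * (mean(v) - gm)^2))
  ssb <- sum(tapply(y, B, function(v) length(v) * (mean(v) - gm)^2))
  cellm <- tapply(y, interaction(A, B), mean)
  nab <- tapply(y, interaction(A, B), length)
  sscell <- sum(nab * (cellm - gm)^2)
  ssab <- sscell - ssa - ssb
  sse <- sum((y - ave(y, interaction(A, B)))^2)
  dfa <- nlevels(A) - 1; dfb <- nlevels(B) - 1
  dfab <- dfa * dfb; dfe <- length(y) - nlevels(A) * nlevels(B)
  f_oracle <- c((ssa / dfa) / (sse / dfe), (ssb / dfb) / (sse / dfe),
                (ssab / dfab) / (sse / dfe))
  got <- an$anova$statistic[match(c("compartment", "treatment",
                                    "compartment:treatment"),
                                  an$anova$term)]
  expect_equal(got, f_oracle, tolerance = 1e-10)
  expect_lt(glance(an)$interaction_p, 0.001)
  expect_true(any(grepl(":", an$tukey$term)))
})

test_that("identical groups give F near zero and p near one", {
  df <- tidyr::expand_grid(treatment = c("a", "b"),
                           compartment = c("outer_border", "inner_border",
                                           "interior"),
                           cell = 1:8)
  base <- rep(c(1.1, 0.95, 0.9), times = 1)
  df$relative_enrichment <- rep(1, nrow(df))
  df$section <- 1L
  # add identical per-compartment structure but no treatment difference and
  # tiny symmetric noise so the residual SS is nonzero
  eps <- rep(c(-0.01, 0.01), length.out = nrow(df))
  df$relative_enrichment <- df$relative_enrichment + eps
  an <- enrichment_anova(df)
  p_treat <- an$anova$p.value[an$anova$term == "treatment"]
  expect_gt(p_treat, 0.9)
})

test_that("anova rejects degenerate designs", {
  df <- tibble::tibble(treatment = "only", compartment = "outer_border",
                       cell = 1:3, section = 1L,
                       relative_enrichment = c(1, 1.1, 0.9))
  expect_error(enrichment_anova(df), "two treatments")
  df2 <- tidyr::expand_grid(treatment = c("a", "b"),
                            compartment = c("outer_border", "interior"),
                            cell = 1:3, section = 1L)
  df2$relative_enrichment <- 1
  df2 <- df2[!(df2$treatment == "b" & df2$compartment == "interior"), ]
  expect_error(enrichment_anova(df2), "empty design cells")
})

test_that("periphery distances: trivial geometry cases", {
  g <- generate_cells(c(1, 1, 1), cell_size = 10, voxel_size = 0.2,
                      margin = 0.4)
  st <- list(labels = g$labels, voxel_size = g$voxel_size, geometry = g,
             intensity = array(0, dim(g$labels)), puncta = NULL)
  class(st) <- "synthetic_stack"
  b <- g$cells[1, ]
  pts <- tibble::tibble(cell = 1L,
                        x = c(b$x0, (b$x0 + b$x1) / 2),
                        y = c(5, (b$y0 + b$y1) / 2),
                        z = c(5, (b$z0 + b$z1) / 2))
  d <- puncta_periphery_distance(st, pts)
  expect_equal(d$periphery_distance, c(0, 5))
})

test_that("periphery distance distributions separate edge and dispersed markers", {
  g <- generate_cells(c(1, 1, 1), cell_size = 8, voxel_size = 0.2)
  pe <- place_puncta(puncta_model(n_puncta = 1500, edge_fraction = 1,
                                  rng_seed = 41), g)
  pu <- place_puncta(puncta_model(n_puncta = 2000, edge_fraction = 0,
                                  rng_seed = 42), g)
  st <- list(labels = g$labels, voxel_size = g$voxel_size, geometry = g)
  class(st) <- "synthetic_stack"
  de <- puncta_periphery_distance(st, pe)$periphery_distance
  du <- puncta_periphery_distance(st, pu)$periphery_distance
  # edge population: median at the PM-distance parameter
  expect_equal(median(de), 0.093, tolerance = 0.1)
  # uniform population: median from the closed form
  # P(D > t) = prod(1 - 2 t / L_i); solve for the median
  med_exact <- uniroot(function(t) (1 - 2 * t / 8)^3 - 0.5,
                       c(0, 4))$root
  expect_equal(median(du), med_exact, tolerance = 0.05)
  tst <- periphery_distance_test(de, du, names = c("edge", "uniform"))
  expect_lt(tst$test$p.value, 1e-10)
  expect_lt(tst$summary$median[1], tst$summary$median[2])
})

test_that("empty puncta sets are flagged, not crashed on", {
  st <- tiny_stack()
  expect_warning(out <- puncta_periphery_distance(st, st$puncta[0, ]),
                 "no puncta")
  expect_equal(nrow(out), 0L)
})

test_that("detected puncta approximate the planted centres", {
  m <- puncta_model(n_puncta = 12, edge_fraction = 0, rng_seed = 55,
                    intensity_per_punctum = 5000)
  st <- simulate_stack(grid = c(1, 1, 1), cell_size = 8, voxel_size = 0.2,
                       model = m, seed = 55)
  det <- detect_puncta(st, k = 2)
  expect_gt(nrow(det), 0)
  # recall: every planted punctum has a detection nearby
  drec <- vapply(seq_len(nrow(st$puncta)), function(i) {
    min(sqrt((det$x - st$puncta$x[i])^2 + (det$y - st$puncta$y[i])^2 +
               (det$z - st$puncta$z[i])^2))
  }, 0)
  expect_gt(mean(drec < 0.5), 0.8)
  # precision of the brightest detections: shot noise can create dim local
  # maxima above threshold, but the top-ranked peaks are the real puncta
  top <- det[seq_len(min(12L, nrow(det))), ]
  dtop <- vapply(seq_len(nrow(top)), function(i) {
    min(sqrt((st$puncta$x - top$x[i])^2 + (st$puncta$y - top$y[i])^2 +
               (st$puncta$z - top$z[i])^2))
  }, 0)
  expect_gt(mean(dtop < 0.5), 0.8)
})
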