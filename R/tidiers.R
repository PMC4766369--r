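# broom-style tidiers for the package's fitted/solved objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a finite-element solution
#'
#' @param x a `fem_solution`.
#' @param ... unused.
#' @return One row per element: region, area, stress components and
#'   principal stresses (Pa).
#' @method tidy fem_solution
#' @export
tidy.fem_solution <- function(x, ...) {
  x$stress
}

#' @rdname tidy.fem_solution
#' @method glance fem_solution
#' @export
glance.fem_solution <- function(x, ...) {
  tibble::tibble(n_nodes = x$n_nodes, n_elements = x$n_elements,
                 plane = x$plane,
                 max_displacement_um = max(sqrt(rowSums(x$displacements^2))),
                 max_s1 = max(x$stress$s1),
                 energy = x$energy, residual = x$residual)
}

#' Tidy a softening sweep
#'
#' @param x a `softening_sweep`.
#' @param ... unused.
#' @return The sweep rows as a plain tibble.
#' @method tidy softening_sweep
#' @export
tidy.softening_sweep <- function(x, ...) {
  out <- x
  attributes(out)[c("solutions", "distension_metric",
                    "stress_summary", "mesh_h")] <- NULL
  class(out) <- c("tbl_df", "tbl", "data.frame")
  out
}

#' @rdname tidy.softening_sweep
#' @method glance softening_sweep
#' @export
glance.softening_sweep <- function(x, ...) {
  base <- x$max_distension_um[x$factor == 1][1]
  tibble::tibble(n_cases = nrow(x),
                 baseline_distension_um = base,
                 max_fold_distension = max(x$max_distension_um) / base,
                 mesh_h = attr(x, "mesh_h"))
}

#' Tidy an enrichment ANOVA
#'
#' @param x an `enrichment_anova`.
#' @param ... unused.
#' @return The ANOVA table (term, df, sumsq, statistic, p.value).
#' @method tidy enrichment_anova
#' @export
tidy.enrichment_anova <- function(x, ...) {
  x$anova
}

#' @rdname tidy.enrichment_anova
#' @method glance enrichment_anova
#' @export
glance.enrichment_anova <- function(x, ...) {
  inter <- x$anova[grepl(":", x$anova$term), ]
  tibble::tibble(interaction_f = inter$statistic[1],
                 interaction_p = inter$p.value[1],
                 n_terms = nrow(x$anova))
}
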