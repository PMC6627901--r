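#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a dose-response fit
#'
#' @param x A `dr_fit` from [fit_4pl()].
#' @param ... Unused.
#' @return One row per model parameter: `term`, `estimate`.
#' @method tidy dr_fit
#' @export
tidy.dr_fit <- function(x, ...) {
  tibble(
    term = c("top", "bottom", "ic50_M", "hill"),
    estimate = c(x$top, x$bottom, x$ic50, x$hill)
  )
}

#' @rdname tidy.dr_fit
#' @return `glance()`: a one-row tibble of fit descriptors (`top`, `bottom`,
#'   `ic50_M`, `hill`, `auc_raw`, `auc_norm`, `fit_r`, `converged`).
#' @method glance dr_fit
#' @export
glance.dr_fit <- function(x, ...) {
  tibble(
    top = x$top, bottom = x$bottom, ic50_M = x$ic50, hill = x$hill,
    auc_raw = x$auc_raw, auc_norm = x$auc_norm, fit_r = x$fit_r,
    converged = x$converged
  )
}

#' Tidy a Bliss synergy result
#'
#' @param x A `synergy_result` from [bliss_synergy_score()].
#' @param ... Unused.
#' @return Long tibble of combination cells: `row_conc_index`,
#'   `col_conc_index`, `expected`, `excess`.
#' @method tidy synergy_result
#' @export
tidy.synergy_result <- function(x, ...) {
  combo <- which(row(x$excess) > 1 & col(x$excess) > 1, arr.ind = TRUE)
  tibble(
    row_conc_index = combo[, 1] - 1L,
    col_conc_index = combo[, 2] - 1L,
    expected = x$expected[combo],
    excess = x$excess[combo]
  )
}

#' @rdname tidy.synergy_result
#' @return `glance()`: one-row summary (`cell_line`, `drug_row`, `drug_col`,
#'   `score`, `n_cells`, `n_missing`, `unreliable`).
#' @method glance synergy_result
#' @export
glance.synergy_result <- function(x, ...) {
  tibble(
    cell_line = x$cell_line, drug_row = x$drug_row, drug_col = x$drug_col,
    score = x$score, n_cells = x$n_cells, n_missing = x$n_missing,
    unreliable = x$unreliable
  )
}

#' Tidy a centroid set
#'
#' @param x A `centroid_set` from [build_centroids()].
#' @param ... Unused.
#' @return Long tibble `gene`, `subtype`, `centroid`.
#' @method tidy centroid_set
#' @export
tidy.centroid_set <- function(x, ...) {
  tibble(
    gene = rep(x$genes, times = length(x$subtypes)),
    subtype = rep(x$subtypes, each = length(x$genes)),
    centroid = as.vector(x$centroid_matrix)
  )
}
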