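#' Two-drug dose matrix container
#'
#' Holds a percent-inhibition grid for a drug pair. The first row and first
#' column (concentration 0) are the single-agent axes; entry (1, 1) is the
#' untreated well and must be 0.
#'
#' @param inhibition Numeric matrix of percent inhibition in `[0, 100]`
#'   (NAs allowed in combination cells).
#' @param row_concs,col_concs Molar concentrations including the leading 0.
#' @param drug_row,drug_col Drug names for the two axes.
#' @param cell_line Cell line label.
#' @return An object of class `dose_matrix`.
#' @export
dose_matrix <- function(inhibition, row_concs, col_concs,
                        drug_row, drug_col, cell_line = NA_character_) {
  if (!is.matrix(inhibition)) abort("`inhibition` must be a matrix")
  if (nrow(inhibition) != length(row_concs) ||
      ncol(inhibition) != length(col_concs)) {
    abort("matrix dimensions must match concentration vectors")
  }
  if (row_concs[1] != 0) abort("missing single-agent axis: row concentrations must start at 0")
  if (col_concs[1] != 0) abort("missing single-agent axis: column concentrations must start at 0")
  if (is.na(inhibition[1, 1]) || abs(inhibition[1, 1]) > 1e-9) {
    abort("untreated well (0, 0) must have inhibition 0")
  }
  rng <- range(inhibition, na.rm = TRUE)
  if (rng[1] < -1e-9 || rng[2] > 100 + 1e-9) {
    abort("inhibition must lie in [0, 100]; clip before constructing")
  }
  dimnames(inhibition) <- list(
    format(row_concs, digits = 4, scientific = TRUE),
    format(col_concs, digits = 4, scientific = TRUE)
  )
  structure(
    list(cell_line = cell_line, drug_row = drug_row, drug_col = drug_col,
         row_concs = row_concs, col_concs = col_concs,
         inhibition = inhibition),
    class = "dose_matrix"
  )
}

#' @export
print.dose_matrix <- function(x, ...) {
  cat("<dose_matrix>", x$cell_line, ":", x$drug_row, "x", x$drug_col,
      sprintf("(%d x %d incl. single agents)\n",
              length(x$row_concs), length(x$col_concs)))
  invisible(x)
}

#' Bliss independence expectation
#'
#' Expected combined percent inhibition of two non-interacting drugs with
#' single-agent inhibitions `ya` and `yb`: `ya + yb - ya * yb / 100`.
#'
#' @param ya,yb Percent inhibitions in `[0, 100]` (vectorized).
#' @return Expected combined percent inhibition.
#' @examples
#' bliss_expected(50, 50) # 75
#' @export
bliss_expected <- function(ya, yb) {
  ok <- function(y) all(is.na(y) | (y >= -1e-9 & y <= 100 + 1e-9))
  if (!ok(ya) || !ok(yb)) abort("inhibitions must lie in [0, 100]")
  ya + yb - ya * yb / 100
}

#' Bliss synergy score of a dose matrix
#'
#' For every combination cell (both concentrations > 0) the expected
#' inhibition is computed from the corresponding single-agent entries via
#' [bliss_expected()]; the excess is observed minus expected, and the score
#' is the arithmetic mean of the excess over all non-missing combination
#' cells. Positive scores indicate synergy, 0 independence, negative
#' antagonism. A result with more than half of its combination cells missing
#' is flagged unreliable.
#'
#' @param m A [dose_matrix()].
#' @return An object of class `synergy_result` with elements `score`,
#'   `expected`, `excess`, `n_cells`, `n_missing`, `unreliable`.
#' @export
bliss_synergy_score <- function(m) {
  stopifnot(inherits(m, "dose_matrix"))
  inh <- m$inhibition
  if (length(m$row_concs) < 2 || length(m$col_concs) < 2) {
    abort("need at least one combination cell")
  }
  single_row <- inh[, 1] # drug_row alone, by row concentration
  single_col <- inh[1, ] # drug_col alone, by column concentration
  if (anyNA(single_row)) warn("missing single-agent entries on the row axis")
  if (anyNA(single_col)) warn("missing single-agent entries on the column axis")
  expected <- outer(single_row, single_col, bliss_expected)
  excess <- inh - expected
  combo <- row(inh) > 1 & col(inh) > 1
  exc <- excess[combo]
  n_missing <- sum(is.na(exc))
  if (all(is.na(exc))) abort("every combination cell is missing")
  structure(
    list(
      cell_line = m$cell_line, drug_row = m$drug_row, drug_col = m$drug_col,
      score = mean(exc, na.rm = TRUE),
      expected = expected, excess = excess,
      n_cells = length(exc), n_missing = n_missing,
      unreliable = n_missing > length(exc) / 2
    ),
    class = "synergy_result"
  )
}

#' @export
print.synergy_result <- function(x, ...) {
  cat("<synergy_result>", x$cell_line, ":", x$drug_row, "+", x$drug_col,
      sprintf("score=%.2f (%d cells, %d missing%s)\n", x$score,
              x$n_cells, x$n_missing,
              if (x$unreliable) ", UNRELIABLE" else ""))
  invisible(x)
}

#' Compare synergy scores between two groups
#'
#' Two-sample t-test (Welch by default) of per-line Bliss scores between
#' groups, e.g. basal vs non-basal, dropping missing scores and reporting
#' how many were dropped.
#'
#' @param data Tibble with one score per cell line.
#' @param score,group Column names (tidy-eval) holding the numeric score and
#'   the two-level group label.
#' @param variant `"welch"` (default) or `"pooled"`.
#' @param p_threshold Flagging threshold for the p-value.
#' @return A one-row association tibble (see [two_sample_t()]) with an
#'   `n_missing` column.
#' @export
compare_synergy_by_group <- function(data, score, group,
                                     variant = c("welch", "pooled"),
                                     p_threshold = 0.1) {
  data <- as_tibble(data)
  s <- dplyr::pull(data, {{ score }})
  g <- dplyr::pull(data, {{ group }})
  n_missing <- sum(is.na(s))
  keep <- !is.na(s) & !is.na(g)
  s <- s[keep]
  g <- as.character(g[keep])
  lev <- sort(unique(g))
  if (length(lev) != 2) abort("`group` must have exactly 2 levels")
  x <- s[g == lev[1]]
  y <- s[g == lev[2]]
  if (length(x) < 2 || length(y) < 2) {
    abort("each group needs at least 2 non-missing scores")
  }
  out <- two_sample_t(x, y, variant = variant, p_threshold = p_threshold)
  out$group_a <- lev[1]
  out$group_b <- lev[2]
  out$n_missing <- n_missing
  out
}
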