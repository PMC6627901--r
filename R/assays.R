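#' Relative expression by the 2^-ddCt method
#'
#' Normalizes the target Ct to the arithmetic mean of the reference-gene Ct
#' values (equivalent to geometric-mean normalization on the linear scale),
#' takes the treated-minus-control difference of these delta-Ct values, and
#' returns `2^-ddCt`. Assumes amplification efficiency 2.
#'
#' @param ct_target_treated,ct_target_control Target-gene Ct values (cycles).
#' @param ct_refs_treated,ct_refs_control Named numeric vectors of
#'   reference-gene Ct values; the two reference sets must name the same
#'   genes.
#' @return Fold change of the target in treated relative to control.
#' @examples
#' ddct_fold_change(26, c(RPLP0 = 18), 25, c(RPLP0 = 18)) # 0.5
#' @export
ddct_fold_change <- function(ct_target_treated, ct_refs_treated,
                             ct_target_control, ct_refs_control) {
  if (length(ct_refs_treated) == 0) abort("at least one reference gene required")
  if (!is.null(names(ct_refs_treated)) || !is.null(names(ct_refs_control))) {
    if (!setequal(names(ct_refs_treated), names(ct_refs_control))) {
      abort("treated and control reference gene sets differ")
    }
    ct_refs_control <- ct_refs_control[names(ct_refs_treated)]
  } else if (length(ct_refs_treated) != length(ct_refs_control)) {
    abort("treated and control reference gene sets differ")
  }
  all_ct <- c(ct_target_treated, ct_refs_treated,
              ct_target_control, ct_refs_control)
  if (any(all_ct <= 0) || any(all_ct >= 45)) {
    abort("Ct values must lie in (0, 45)")
  }
  d_treated <- ct_target_treated - mean(ct_refs_treated)
  d_control <- ct_target_control - mean(ct_refs_control)
  2^-(d_treated - d_control)
}

#' Summarize a Ct table into fold changes per condition
#'
#' Averages replicate Ct values per (condition, gene) and applies
#' [ddct_fold_change()] of every condition against the control condition.
#'
#' @param ct_data Tibble `condition`, `gene`, `ct` (and optionally
#'   `replicate`), as written by [simulate_qpcr()].
#' @param target Target gene name.
#' @param reference_genes Reference gene names.
#' @param control_condition Condition used as the calibrator.
#' @return Tibble `condition`, `delta_ct`, `fold_change`, `pct_inhibition`.
#' @export
ddct_table <- function(ct_data, target = "EREG",
                       reference_genes = c("RPLP0", "UBB"),
                       control_condition = "control") {
  ct_data <- as_tibble(ct_data)
  mean_ct <- ct_data |>
    dplyr::summarise(ct = mean(.data$ct), .by = c("condition", "gene"))
  get_ct <- function(cond, g) {
    v <- mean_ct$ct[mean_ct$condition == cond & mean_ct$gene %in% g]
    if (length(v) != length(g)) abort(paste("missing Ct for", cond))
    stats::setNames(v, mean_ct$gene[mean_ct$condition == cond &
                                      mean_ct$gene %in% g])
  }
  ref_ctrl <- get_ct(control_condition, reference_genes)
  tgt_ctrl <- get_ct(control_condition, target)
  conds <- setdiff(unique(mean_ct$condition), control_condition)
  purrr::map_dfr(conds, function(cond) {
    refs <- get_ct(cond, reference_genes)
    tgt <- get_ct(cond, target)
    fold <- ddct_fold_change(tgt, refs, tgt_ctrl, ref_ctrl)
    tibble(
      condition = cond,
      delta_ct = unname(tgt - mean(refs)),
      fold_change = unname(fold),
      pct_inhibition = unname(100 * (1 - fold))
    )
  })
}

#' Clonogenic plating efficiency
#'
#' Colonies formed without treatment divided by cells seeded.
#'
#' @param colonies_untreated Colony count (>64 cells each) in untreated
#'   wells.
#' @param cells_seeded Cells seeded per well (> 0).
#' @return Plating efficiency fraction; a zero count returns 0 with a
#'   warning since downstream surviving fractions are then undefined.
#' @examples
#' plating_efficiency(100, 250) # 0.4
#' @export
plating_efficiency <- function(colonies_untreated, cells_seeded) {
  if (any(cells_seeded <= 0)) abort("`cells_seeded` must be positive")
  if (any(colonies_untreated > cells_seeded)) {
    abort("more colonies than cells seeded")
  }
  if (any(colonies_untreated < 0)) abort("negative colony count")
  if (any(colonies_untreated == 0)) {
    warn("zero untreated colonies: surviving fractions will be undefined")
  }
  colonies_untreated / cells_seeded
}

#' Clonogenic surviving fraction
#'
#' Colonies formed under treatment divided by cells seeded times the plating
#' efficiency; self-normalizing across seeding densities.
#'
#' @param colonies_treated Colony count under treatment.
#' @param cells_seeded Cells seeded per treated well.
#' @param pe Plating efficiency from [plating_efficiency()] (> 0).
#' @return Surviving fraction (can exceed 1 by sampling noise).
#' @examples
#' surviving_fraction(50, 250, 0.4) # 0.5
#' @export
surviving_fraction <- function(colonies_treated, cells_seeded, pe) {
  if (any(pe <= 0)) abort("`pe` must be positive")
  if (any(cells_seeded <= 0)) abort("`cells_seeded` must be positive")
  if (any(colonies_treated < 0)) abort("negative colony count")
  colonies_treated / (cells_seeded * pe)
}

#' Summarize a clonogenic assay table
#'
#' Estimates the plating efficiency from the untreated wells and the
#' surviving fraction of every treated condition, averaging replicates.
#'
#' @param data Tibble `condition`, `cells_seeded`, `colonies` as written by
#'   [simulate_clonogenic()].
#' @param control_condition Name of the untreated condition.
#' @return Tibble `condition`, `pe`, `sf` (with `sf = 1` for the control by
#'   construction).
#' @export
clonogenic_table <- function(data, control_condition = "untreated") {
  data <- as_tibble(data)
  ctrl <- dplyr::filter(data, .data$condition == control_condition)
  if (nrow(ctrl) == 0) abort("control condition absent")
  pe <- mean(plating_efficiency(ctrl$colonies, ctrl$cells_seeded))
  data |>
    dplyr::summarise(
      sf = mean(surviving_fraction(.data$colonies, .data$cells_seeded, pe)),
      .by = "condition"
    ) |>
    dplyr::mutate(pe = pe, .after = "condition")
}
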