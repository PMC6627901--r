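# Association machinery: every test returns a one-row tibble with a common
# column set so results bind into tidy tables.

association_result <- function(test, statistic, p_value,
                               effect_direction = NA_real_,
                               n1 = NA_integer_, n2 = NA_integer_,
                               p_threshold = 0.1) {
  tibble(
    test = test,
    statistic = unname(statistic),
    p_value = unname(p_value),
    effect_direction = unname(effect_direction),
    n1 = n1, n2 = n2,
    flagged = unname(p_value) < p_threshold
  )
}

#' Two-sample t-test
#'
#' Welch (default, robust to the unequal group sizes and variances typical of
#' 10-vs-15 screen arms) or pooled-variance two-sided t-test.
#'
#' @param x,y Numeric vectors, each with at least 2 values.
#' @param variant `"welch"` or `"pooled"`.
#' @param p_threshold Flagging threshold.
#' @return One-row association tibble: `test`, `statistic`, `p_value`,
#'   `effect_direction` (sign of mean(x) - mean(y)), `n1`, `n2`, `flagged`.
#' @examples
#' two_sample_t(c(1, 2, 3), c(4, 5, 6), variant = "pooled")
#' @export
two_sample_t <- function(x, y, variant = c("welch", "pooled"),
                         p_threshold = 0.1) {
  variant <- match.arg(variant)
  if (length(x) < 2 || length(y) < 2) abort("each group needs >= 2 values")
  if (stats::sd(c(x, y)) == 0) {
    # identical constant groups: no evidence of a difference
    return(association_result("t", 0, 1, 0, length(x), length(y), p_threshold))
  }
  ht <- stats::t.test(x, y, var.equal = variant == "pooled")
  association_result(
    "t", ht$statistic, ht$p.value,
    effect_direction = sign(mean(x) - mean(y)),
    n1 = length(x), n2 = length(y), p_threshold = p_threshold
  )
}

#' One-way ANOVA
#'
#' Classical equal-variance one-way analysis of variance across k groups.
#'
#' @param groups A named or unnamed list of numeric vectors, each with at
#'   least 2 values.
#' @param p_threshold Flagging threshold.
#' @return One-row association tibble (`statistic` is the F value).
#' @export
one_way_anova <- function(groups, p_threshold = 0.1) {
  if (length(groups) < 2) abort("need at least 2 groups")
  if (any(vapply(groups, length, 1L) < 2)) {
    abort("every group needs at least 2 values")
  }
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), times = vapply(groups, length, 1L)))
  ht <- stats::oneway.test(values ~ g, var.equal = TRUE)
  association_result("anova", ht$statistic, ht$p.value,
                     p_threshold = p_threshold)
}

#' Chi-squared test with Yates continuity correction
#'
#' 2x2 chi-squared with the continuity correction
#' `sum((|O - E| - 0.5)^2 / E)` on 1 degree of freedom.
#'
#' @param tab 2x2 matrix of non-negative integer counts with all row and
#'   column margins positive.
#' @param p_threshold Flagging threshold.
#' @return One-row association tibble.
#' @examples
#' chi2_yates(matrix(c(6, 2, 4, 13), 2)) # p ~ 0.044
#' @export
chi2_yates <- function(tab, p_threshold = 0.1) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) abort("`tab` must be 2x2")
  if (any(tab < 0) || any(tab != round(tab))) {
    abort("`tab` must hold non-negative integers")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("all margins must be positive")
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
  association_result("chi2_yates", ht$statistic, ht$p.value,
                     p_threshold = p_threshold)
}

#' Fisher exact test for a 2x2 table
#'
#' Two-sided p-value by summation of the probabilities of all tables (with
#' the observed margins) no more probable than the observed one.
#'
#' @param tab 2x2 matrix of non-negative integers.
#' @param p_threshold Flagging threshold.
#' @return One-row association tibble (`statistic` is the conditional
#'   odds-ratio estimate).
#' @export
fisher_exact <- function(tab, p_threshold = 0.1) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) abort("`tab` must be 2x2")
  if (any(tab < 0) || any(tab != round(tab))) {
    abort("`tab` must hold non-negative integers")
  }
  ht <- stats::fisher.test(tab)
  association_result("fisher", ht$estimate, ht$p.value,
                     p_threshold = p_threshold)
}

#' Hypergeometric enrichment test
#'
#' Upper-tail test of over-representation: the probability of observing at
#' least `hits_in_set` annotated genes in a drawn set, under sampling without
#' replacement from the universe. The workhorse of gene-list vs pathway
#' association.
#'
#' @param hits_in_set Annotated genes observed in the set.
#' @param set_size Size of the drawn gene set.
#' @param hits_total Annotated genes in the universe.
#' @param universe Universe size.
#' @param p_threshold Flagging threshold.
#' @return One-row association tibble (`statistic` is `hits_in_set`).
#' @examples
#' hypergeometric_enrichment(5, 5, 5, 10) # p = 1/252
#' @export
hypergeometric_enrichment <- function(hits_in_set, set_size, hits_total,
                                      universe, p_threshold = 0.1) {
  if (hits_in_set > min(set_size, hits_total)) {
    abort("`hits_in_set` cannot exceed set_size or hits_total")
  }
  if (universe < max(set_size, hits_total) || any(c(
    hits_in_set, set_size, hits_total, universe
  ) < 0)) {
    abort("inconsistent counts")
  }
  p <- stats::phyper(hits_in_set - 1, hits_total, universe - hits_total,
                     set_size, lower.tail = FALSE)
  association_result("hypergeom", hits_in_set, p, p_threshold = p_threshold)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' @param p Numeric vector of p-values.
#' @return Monotone step-up adjusted p-values controlling the FDR.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Associate mutation status with drug response
#'
#' For each gene with at least `min_group` mutated and `min_group` wild-type
#' cell lines, tests per drug whether the mutated lines' AUCs differ from the
#' wild-type lines', using [moderated_t()] with variance moderation pooled
#' across the drug panel. A negative effect direction means the mutation
#' sensitizes (mutated mean AUC lower). Genes with too few lines in either
#' arm are skipped with a message and listed in the `"skipped"` attribute.
#'
#' @param auc_table Long tibble `cell_line`, `drug`, `auc`.
#' @param mutation_table Long tibble `cell_line`, `gene`, `status` (0/1).
#' @param p_threshold Flagging threshold (default 0.1, the screening
#'   convention for candidate associations).
#' @param min_features Minimum panel size for moderation; the default 2
#'   keeps moderation active for a 6-drug panel.
#' @param min_group Minimum lines per arm.
#' @return Tidy tibble: `gene`, `drug`, `test`, `statistic`, `p_value`,
#'   `effect_direction`, `n_mut`, `n_wt`, `flagged`.
#' @export
mutation_association <- function(auc_table, mutation_table, p_threshold = 0.1,
                                 min_features = 2, min_group = 2) {
  auc_table <- as_tibble(auc_table)
  mutation_table <- as_tibble(mutation_table)
  if (nrow(auc_table) == 0 || nrow(mutation_table) == 0) {
    abort("empty input table")
  }
  auc_wide <- auc_table |>
    tidyr::pivot_wider(names_from = "cell_line", values_from = "auc")
  mat <- as.matrix(auc_wide[, -1])
  rownames(mat) <- auc_wide$drug
  skipped <- character()
  res <- purrr::map_dfr(unique(mutation_table$gene), function(g) {
    mt <- dplyr::filter(mutation_table, .data$gene == g,
                        .data$cell_line %in% colnames(mat))
    mut <- mt$cell_line[mt$status == 1]
    wt <- mt$cell_line[mt$status == 0]
    if (length(mut) < min_group || length(wt) < min_group) {
      inform(paste0("skipping ", g, ": ", length(mut), " mutated / ",
                    length(wt), " wild-type lines"))
      skipped <<- c(skipped, g)
      return(NULL)
    }
    mt_res <- moderated_t(mat[, mut, drop = FALSE], mat[, wt, drop = FALSE],
                          min_features = min_features,
                          p_threshold = p_threshold)
    tibble(
      gene = g, drug = mt_res$feature, test = "moderated_t",
      statistic = mt_res$statistic, p_value = mt_res$p_value,
      effect_direction = mt_res$effect_direction,
      n_mut = length(mut), n_wt = length(wt), flagged = mt_res$flagged
    )
  })
  attr(res, "skipped") <- skipped
  res
}
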