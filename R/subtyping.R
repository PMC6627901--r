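#' Standardize cohorts and aggregate them over shared genes
#'
#' Within each dataset every gene is standardized to mean 0 and SD 1 across
#' samples (population SD, divisor n), removing per-dataset batch scale and
#' offset; the standardized matrices are then column-bound over the genes
#' common to all datasets. Genes with zero variance in any dataset cannot be
#' standardized there and are dropped with a message. Sample ids are prefixed
#' with their dataset id to stay unique; the origin is kept alongside the
#' subtype labels.
#'
#' @param datasets List of [expr_dataset()] objects.
#' @return An [expr_dataset()] with `dataset_id = "aggregated"` and an
#'   `origin` attribute (named character, sample -> source dataset).
#' @export
scale_and_aggregate <- function(datasets) {
  if (length(datasets) == 0) abort("no datasets supplied")
  shared <- Reduce(intersect, lapply(datasets, function(d) rownames(d$values)))
  if (length(shared) == 0) abort("datasets share no genes")
  scaled <- lapply(datasets, function(d) {
    v <- d$values[shared, , drop = FALSE]
    mu <- rowMeans(v)
    sdev <- sqrt(rowMeans((v - mu)^2)) # population SD
    drop <- sdev == 0
    if (any(drop)) {
      inform(paste0(d$dataset_id, ": dropping ", sum(drop),
                    " zero-variance gene(s)"))
    }
    list(values = (v - mu) / ifelse(sdev == 0, NA, sdev), drop = rownames(v)[drop])
  })
  dropped <- unique(unlist(lapply(scaled, `[[`, "drop")))
  keep <- setdiff(shared, dropped)
  if (length(keep) == 0) abort("no genes left after dropping zero-variance genes")
  mats <- purrr::map2(scaled, datasets, function(s, d) {
    m <- s$values[keep, , drop = FALSE]
    colnames(m) <- paste(d$dataset_id, colnames(m), sep = ".")
    m
  })
  values <- do.call(cbind, mats)
  subtypes <- unlist(unname(lapply(datasets, function(d) {
    if (is.null(d$subtypes)) return(NULL)
    stats::setNames(d$subtypes, paste(d$dataset_id, names(d$subtypes), sep = "."))
  })))
  origin <- unlist(unname(lapply(datasets, function(d) {
    stats::setNames(rep(d$dataset_id, ncol(d$values)),
                    paste(d$dataset_id, colnames(d$values), sep = "."))
  })))
  out <- expr_dataset("aggregated", values,
                      subtypes = if (is.null(subtypes)) NULL else subtypes)
  attr(out, "origin") <- origin
  out
}

#' Identify genes differentially expressed across subtypes in every cohort
#'
#' In each labelled dataset, tests every gene for differential expression --
#' either a moderated t-test of basal versus all other samples
#' (`method = "moderated_t"`) or a one-way ANOVA across all subtype groups
#' (`method = "anova"`, which also captures markers of the non-basal
#' subtypes and is what centroid construction needs) -- controls the FDR per
#' dataset with Benjamini-Hochberg, and returns the genes significant in
#' every dataset with a concordant basal-vs-rest effect direction, ordered
#' by decreasing mean absolute log2 fold change.
#'
#' @param datasets List of labelled [expr_dataset()] objects sharing genes.
#' @param fdr Per-dataset Benjamini-Hochberg threshold.
#' @param basal_label Subtype label treated as basal.
#' @param method Per-gene test: basal-vs-rest moderated t, or one-way ANOVA
#'   over all subtype groups.
#' @return Character vector of concordantly differential genes; the
#'   per-dataset result tables are attached as attribute `"per_dataset"`.
#' @export
identify_common_de_genes <- function(datasets, fdr = 0.05,
                                     basal_label = "basal",
                                     method = c("moderated_t", "anova")) {
  method <- match.arg(method)
  if (length(datasets) == 0) abort("no datasets supplied")
  shared <- Reduce(intersect, lapply(datasets, function(d) rownames(d$values)))
  if (length(shared) == 0) abort("datasets share no genes")
  per <- lapply(datasets, function(d) {
    if (is.null(d$subtypes)) abort(paste0(d$dataset_id, " has no subtype labels"))
    is_basal <- d$subtypes == basal_label
    if (all(is_basal) || !any(is_basal)) {
      abort(paste0(d$dataset_id, " has a single subtype; cannot contrast"))
    }
    v <- d$values[shared, , drop = FALSE]
    if (method == "moderated_t") {
      res <- moderated_t(v[, is_basal, drop = FALSE],
                         v[, !is_basal, drop = FALSE])
    } else {
      f <- row_anova(v, d$subtypes[colnames(v)])
      res <- tibble(
        feature = rownames(v),
        mean_diff = rowMeans(v[, is_basal, drop = FALSE]) -
          rowMeans(v[, !is_basal, drop = FALSE]),
        statistic = f$statistic, df = f$df2, p_value = f$p_value,
        effect_direction = sign(rowMeans(v[, is_basal, drop = FALSE]) -
                                  rowMeans(v[, !is_basal, drop = FALSE])),
        flagged = f$p_value < 0.1
      )
    }
    res$q_value <- bh_adjust(res$p_value)
    res
  })
  sig_sets <- lapply(per, function(r) r$feature[r$q_value <= fdr])
  common <- Reduce(intersect, sig_sets)
  if (length(common) > 0) {
    dirs <- vapply(per, function(r) {
      stats::setNames(r$effect_direction, r$feature)[common]
    }, numeric(length(common)))
    dirs <- matrix(dirs, nrow = length(common))
    concordant <- apply(dirs, 1, function(x) length(unique(x)) == 1)
    common <- common[concordant]
  }
  mean_abs_lfc <- rowMeans(vapply(per, function(r) {
    stats::setNames(r$mean_diff, r$feature)[common]
  }, numeric(length(common))))
  out <- common[order(-abs(mean_abs_lfc))]
  attr(out, "per_dataset") <- per
  out
}

#' Subtype centroid set
#'
#' Builds per-subtype centroids: for each subtype, the per-gene arithmetic
#' mean of its member samples' expression. Meant to be applied to
#' standardized (aggregated) data so that centroids are comparable across
#' source datasets.
#'
#' @param dataset A labelled [expr_dataset()].
#' @param genes Optional gene subset (e.g. the common differential genes);
#'   defaults to all genes.
#' @return An object of class `centroid_set`: `subtypes`, `genes`,
#'   `centroid_matrix` (genes x subtypes), `source`.
#' @export
build_centroids <- function(dataset, genes = NULL) {
  if (is.null(dataset$subtypes)) abort("dataset has no subtype labels")
  genes <- genes %||% rownames(dataset$values)
  missing <- setdiff(genes, rownames(dataset$values))
  if (length(missing) > 0) {
    abort(paste("genes absent from dataset:", paste(missing, collapse = ", ")))
  }
  if (length(genes) == 0) abort("empty gene list")
  subtypes <- sort(unique(dataset$subtypes))
  v <- dataset$values[genes, , drop = FALSE]
  cm <- vapply(subtypes, function(s) {
    members <- names(dataset$subtypes)[dataset$subtypes == s]
    if (length(members) == 0) abort(paste0("subtype ", s, " has no samples"))
    rowMeans(v[, members, drop = FALSE])
  }, numeric(length(genes)))
  cm <- matrix(cm, nrow = length(genes),
               dimnames = list(genes, subtypes))
  structure(
    list(subtypes = subtypes, genes = genes, centroid_matrix = cm,
         source = dataset$dataset_id),
    class = "centroid_set"
  )
}

#' @export
print.centroid_set <- function(x, ...) {
  cat("<centroid_set>", x$source, ":", length(x$genes), "genes x subtypes",
      paste(x$subtypes, collapse = ", "), "\n")
  invisible(x)
}

#' Pearson correlation between two centroid sets
#'
#' Entry (i, j) is the Pearson correlation of centroid i of `set_a` with
#' centroid j of `set_b` over their shared genes. A centroid with zero
#' variance over the shared genes yields NA entries and a warning.
#'
#' @param set_a,set_b [build_centroids()] results sharing at least 3 genes.
#' @return Numeric matrix, subtypes of `set_a` x subtypes of `set_b`.
#' @export
compare_centroids <- function(set_a, set_b) {
  shared <- intersect(set_a$genes, set_b$genes)
  if (length(shared) < 3) abort("centroid sets share fewer than 3 genes")
  a <- set_a$centroid_matrix[shared, , drop = FALSE]
  b <- set_b$centroid_matrix[shared, , drop = FALSE]
  flat <- c(colnames(a)[apply(a, 2, stats::sd) == 0],
            colnames(b)[apply(b, 2, stats::sd) == 0])
  if (length(flat) > 0) {
    warn(paste("zero-variance centroid(s) over shared genes:",
               paste(unique(flat), collapse = ", ")))
  }
  suppressWarnings(stats::cor(a, b))
}

#' Nearest-centroid subtype prediction
#'
#' Correlates each sample profile with every subtype centroid (Pearson) and
#' predicts the subtype with the highest correlation. Pearson correlation is
#' invariant to affine rescaling of the profile, so raw and standardized
#' profiles give the same call. Ties are broken by the centroid order in
#' `centroids$subtypes` and flagged.
#'
#' @param x An [expr_dataset()] or a genes x samples matrix.
#' @param centroids A [build_centroids()] result; at least 3 genes must be
#'   shared with `x`.
#' @return A tibble with one row per sample: `sample_id`, one `r_<subtype>`
#'   correlation column per subtype, `predicted`, `margin` (best minus
#'   second-best correlation) and `tie`.
#' @export
predict_subtypes <- function(x, centroids) {
  v <- if (inherits(x, "expr_dataset")) x$values else as.matrix(x)
  shared <- intersect(rownames(v), centroids$genes)
  if (length(shared) < 3) abort("fewer than 3 genes shared with the centroids")
  v <- v[shared, , drop = FALSE]
  cm <- centroids$centroid_matrix[shared, , drop = FALSE]
  flat <- apply(v, 2, stats::sd) == 0
  if (any(flat)) {
    abort(paste("zero-variance sample profile(s):",
                paste(colnames(v)[flat], collapse = ", ")))
  }
  r <- suppressWarnings(stats::cor(v, cm)) # samples x subtypes
  best_idx <- apply(r, 1, which.max) # which.max takes the first on ties
  sorted <- apply(r, 1, function(z) sort(z, decreasing = TRUE)[1:2])
  ties <- apply(r, 1, function(z) sum(z == max(z)) > 1)
  out <- as_tibble(r, .name_repair = ~ paste0("r_", centroids$subtypes))
  dplyr::bind_cols(
    tibble(sample_id = colnames(v)),
    out,
    tibble(
      predicted = centroids$subtypes[best_idx],
      margin = sorted[1, ] - sorted[2, ],
      tie = ties
    )
  )
}

#' Consensus basal call across two cell-line datasets
#'
#' Truth table (vectorized over pairs of calls in
#' `{"basal", "non-basal", "absent"}`):
#' basal/basal -> basal; non-basal/non-basal -> non-basal;
#' non-basal with the line absent from the other dataset -> non-basal;
#' discordant (basal/non-basal) or basal with the line absent ->
#' unclassified. A line absent from both datasets is an error.
#'
#' @param call1,call2 Character vectors of per-dataset calls.
#' @return Character vector in `{"basal", "non-basal", "unclassified"}`.
#' @examples
#' consensus_basal_call(c("basal", "non-basal"), c("basal", "absent"))
#' @export
consensus_basal_call <- function(call1, call2) {
  valid <- c("basal", "non-basal", "absent")
  if (!all(call1 %in% valid) || !all(call2 %in% valid)) {
    abort('calls must be "basal", "non-basal" or "absent"')
  }
  if (any(call1 == "absent" & call2 == "absent")) {
    abort("a cell line cannot be absent from both datasets")
  }
  dplyr::case_when(
    call1 == "basal" & call2 == "basal" ~ "basal",
    call1 == "non-basal" & call2 == "non-basal" ~ "non-basal",
    call1 == "non-basal" & call2 == "absent" ~ "non-basal",
    call1 == "absent" & call2 == "non-basal" ~ "non-basal",
    .default = "unclassified"
  )
}

#' Empirical ROC AUC
#'
#' Probability that a random positive case scores higher than a random
#' negative case, computed from the Mann-Whitney U statistic with midranks,
#' so ties contribute 1/2.
#'
#' @param values Numeric scores.
#' @param labels Binary labels (logical, or 0/1) marking the positive class.
#' @return AUC in `[0, 1]`.
#' @examples
#' roc_auc(c(1, 3, 2, 4), c(0, 0, 1, 1)) # 0.75
#' @export
roc_auc <- function(values, labels) {
  labels <- as.logical(labels)
  if (length(values) != length(labels)) abort("length mismatch")
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) abort("both classes must be present")
  r <- rank(values)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Score and select basal marker genes
#'
#' Per gene, the log2 fold change (basal mean minus non-basal mean; the
#' expression is assumed log2 already) and the ROC AUC of the gene's
#' expression as a basal classifier. A gene is selected when both the fold
#' change and the AUC reach their thresholds. Results are ordered by AUC
#' (descending), ties by absolute fold change.
#'
#' @param x An [expr_dataset()] or genes x samples matrix.
#' @param labels Binary basal labels per sample (logical or 0/1); defaults to
#'   the dataset's own labels compared against `basal_label`.
#' @param fc_threshold Minimum log2 fold change.
#' @param auc_threshold Minimum ROC AUC.
#' @param basal_label Label treated as basal when `labels` is `NULL`.
#' @return Tibble: `gene`, `log2_fold_change`, `roc_auc`, `selected`.
#' @export
select_markers <- function(x, labels = NULL, fc_threshold = 1,
                           auc_threshold = 0.8, basal_label = "basal") {
  v <- if (inherits(x, "expr_dataset")) x$values else as.matrix(x)
  if (is.null(labels)) {
    if (!inherits(x, "expr_dataset") || is.null(x$subtypes)) {
      abort("`labels` required when `x` carries no subtype labels")
    }
    labels <- x$subtypes[colnames(v)] == basal_label
  }
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) abort("both classes must be present")
  if (auc_threshold < 0 || auc_threshold > 1) {
    abort("`auc_threshold` must lie in [0, 1]")
  }
  lfc <- rowMeans(v[, labels, drop = FALSE]) -
    rowMeans(v[, !labels, drop = FALSE])
  auc <- apply(v, 1, roc_auc, labels = labels)
  tibble(
    gene = rownames(v),
    log2_fold_change = unname(lfc),
    roc_auc = unname(auc),
    selected = unname(lfc >= fc_threshold & auc >= auc_threshold)
  ) |>
    dplyr::arrange(dplyr::desc(.data$roc_auc),
                   dplyr::desc(abs(.data$log2_fold_change)))
}


# vectorized gene-wise one-way ANOVA (between/within sums of squares)
row_anova <- function(v, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  n <- ncol(v)
  gm <- rowMeans(v)
  ssb <- 0
  ssw <- 0
  for (lev in levels(groups)) {
    cols <- groups == lev
    m_g <- rowMeans(v[, cols, drop = FALSE])
    ssb <- ssb + sum(cols) * (m_g - gm)^2
    ssw <- ssw + rowSums((v[, cols, drop = FALSE] - m_g)^2)
  }
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(statistic = f, df1 = k - 1, df2 = n - k,
       p_value = stats::pf(f, k - 1, n - k, lower.tail = FALSE))
}
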