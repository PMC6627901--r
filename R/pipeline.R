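#' Pipeline configuration
#'
#' Bundles every stage toggle and module parameter of the end-to-end
#' synthetic analysis. Stage dependencies are validated before anything
#' runs: classification needs the simulated cohorts, dose-response and
#' synergy need the classified panel, association needs dose-response
#' results.
#'
#' @param seed Root seed; also seeds the embedded [sim_config()] unless one
#'   is supplied.
#' @param sim A [sim_config()]; the default uses three 40-sample cohorts of
#'   150 genes, sized so the full pipeline runs in seconds.
#' @param stages Named logical toggles: `simulate`, `classify`,
#'   `doseresponse`, `synergy`, `associate`, `assays`.
#' @param n_cell_lines Size of the simulated screening panel.
#' @param n_absent_panel2 Lines dropped from the second cell-line dataset to
#'   exercise the absent branch of the consensus rule.
#' @param fdr Per-dataset FDR for differential gene discovery.
#' @param p_threshold Flagging threshold for association tests.
#' @param combinations Tibble of drug pairs (`drug_row`, `drug_col`) to
#'   score; defaults to the nine pairs of EGFR-directed drugs with the three
#'   partner drugs.
#' @param qpcr_folds Named true fold changes for the knockdown round trip.
#' @param clonogenic Named list `pe`, `sf_true`, `n_seeded`.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            sim = NULL,
                            stages = c(simulate = TRUE, classify = TRUE,
                                       doseresponse = TRUE, synergy = TRUE,
                                       associate = TRUE, assays = TRUE),
                            n_cell_lines = 25L,
                            n_absent_panel2 = 3L,
                            fdr = 0.05,
                            p_threshold = 0.1,
                            combinations = NULL,
                            qpcr_folds = c(siEREG1 = 0.08, siEREG2 = 0.06,
                                           siEREG3 = 0.05),
                            clonogenic = list(pe = 0.4, sf_true = 0.5,
                                              n_seeded = 250L)) {
  sim <- sim %||% sim_config(seed = seed, n_genes = 150L,
                             n_samples_per_dataset = 40L, n_datasets = 3L,
                             noise_sd = 0.5)
  stopifnot(inherits(sim, "sim_config"))
  need <- c("simulate", "classify", "doseresponse", "synergy", "associate",
            "assays")
  if (!all(need %in% names(stages))) {
    abort(paste("`stages` must name:", paste(need, collapse = ", ")))
  }
  deps <- list(
    classify = "simulate", doseresponse = c("simulate", "classify"),
    synergy = c("simulate", "classify"),
    associate = c("simulate", "classify", "doseresponse"),
    assays = "simulate"
  )
  for (st in names(deps)) {
    if (stages[[st]] && !all(stages[deps[[st]]])) {
      abort(paste0("stage '", st, "' requires: ",
                   paste(deps[[st]], collapse = ", ")))
    }
  }
  partners <- c("Cobimetinib", "Gedatolisib", "Trastuzumab")
  egfr <- c("Afatinib", "Cetuximab", "Erlotinib")
  combinations <- combinations %||%
    tidyr::expand_grid(drug_row = egfr, drug_col = partners)
  assert_count(n_cell_lines, "n_cell_lines")
  if (n_absent_panel2 < 0 || n_absent_panel2 >= n_cell_lines) {
    abort("`n_absent_panel2` must be in [0, n_cell_lines)")
  }
  structure(
    list(seed = as.integer(seed), sim = sim, stages = stages,
         n_cell_lines = as.integer(n_cell_lines),
         n_absent_panel2 = as.integer(n_absent_panel2),
         fdr = fdr, p_threshold = p_threshold,
         combinations = combinations, qpcr_folds = qpcr_folds,
         clonogenic = clonogenic),
    class = "pipeline_config"
  )
}

#' Run the end-to-end synthetic screen
#'
#' Executes simulate -> classify -> dose-response -> synergy -> associate ->
#' assays on fully synthetic data and returns every intermediate and result
#' table, plus a manifest recording the seed and configuration hash, so a
#' rerun with the same config is identical.
#'
#' Stages: (1) simulate labelled tumor cohorts; (2) find genes concordantly
#' up in basal tumors, standardize and aggregate the cohorts, build subtype
#' centroids, profile a cell-line panel twice (the second dataset missing a
#' few lines) and call consensus basal status; (3) simulate and fit
#' single-agent viability plates, collect AUCs; (4) score Bliss synergy of
#' drug combinations per line and compare by consensus group; (5) test
#' subtype-AUC and mutation-AUC associations; (6) knockdown qPCR and
#' clonogenic round trips.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `basal_report`: a named list of result tables
#'   (`de_genes`, `centroids`, `calls`, `fits`, `auc_by_subtype`,
#'   `synergy_scores`, `synergy_by_group`, `mutation_assoc`, `qpcr`,
#'   `clonogenic`, `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  on <- config$stages
  rep <- list(config = config)

  cohorts <- if (on[["simulate"]]) simulate_expression(config$sim)

  if (on[["classify"]]) {
    de_genes <- identify_common_de_genes(cohorts, fdr = config$fdr,
                                        method = "anova")
    if (length(de_genes) < 3) {
      abort("classify stage: fewer than 3 concordant differential genes")
    }
    agg <- scale_and_aggregate(cohorts)
    centroids <- build_centroids(agg, genes = de_genes)

    panel <- with_stream_seed(config$seed, "panel", {
      tibble(
        cell_line = sprintf("CL%02d", seq_len(config$n_cell_lines)),
        subtype = sample(names(config$sim$subtype_proportions),
                         config$n_cell_lines, replace = TRUE,
                         prob = config$sim$subtype_proportions)
      )
    })
    panel_sim <- config$sim
    panel_sim$n_samples_per_dataset <- config$n_cell_lines
    panel_sim$n_datasets <- 2L
    panel_data <- simulate_expression(
      panel_sim,
      sample_ids = panel$cell_line,
      subtype_labels = stats::setNames(panel$subtype, panel$cell_line),
      dataset_ids = c("lines1", "lines2")
    )
    absent <- utils::tail(panel$cell_line, config$n_absent_panel2)
    if (length(absent) > 0) {
      keep <- setdiff(colnames(panel_data$lines2$values), absent)
      panel_data$lines2 <- expr_dataset(
        "lines2", panel_data$lines2$values[, keep, drop = FALSE],
        panel_data$lines2$subtypes[keep]
      )
    }
    to_call <- function(pred, lines) {
      call <- ifelse(pred$predicted == "basal", "basal", "non-basal")
      stats::setNames(call, pred$sample_id)[lines]
    }
    pred1 <- predict_subtypes(scale_and_aggregate(panel_data["lines1"]), centroids)
    pred1$sample_id <- sub("^lines1\\.", "", pred1$sample_id)
    pred2 <- predict_subtypes(scale_and_aggregate(panel_data["lines2"]), centroids)
    pred2$sample_id <- sub("^lines2\\.", "", pred2$sample_id)
    call1 <- to_call(pred1, panel$cell_line)
    call2 <- to_call(pred2, panel$cell_line)
    call2[is.na(call2)] <- "absent"
    calls <- tibble(
      cell_line = panel$cell_line,
      true_subtype = panel$subtype,
      call_dataset1 = unname(call1),
      call_dataset2 = unname(call2),
      consensus = consensus_basal_call(unname(call1), unname(call2))
    )
    rep$de_genes <- de_genes
    rep$centroids <- centroids
    rep$calls <- calls
  }

  if (on[["doseresponse"]]) {
    plate <- simulate_dose_response(config$sim, panel)
    fits <- fit_dose_response(plate)
    auc_long <- dplyr::select(fits, "cell_line", "drug", auc = "auc_norm")
    grp <- dplyr::left_join(auc_long,
                            dplyr::select(calls, "cell_line", "consensus"),
                            by = "cell_line") |>
      dplyr::filter(.data$consensus != "unclassified")
    auc_by_subtype <- grp |>
      dplyr::group_by(.data$drug) |>
      dplyr::group_modify(function(d, key) {
        two_sample_t(d$auc[d$consensus == "basal"],
                     d$auc[d$consensus == "non-basal"],
                     p_threshold = config$p_threshold)
      }) |>
      dplyr::ungroup()
    rep$fits <- fits
    rep$auc_table <- auc_long
    rep$auc_by_subtype <- auc_by_subtype
  }

  if (on[["synergy"]]) {
    grid <- tidyr::expand_grid(
      cell_line = panel$cell_line,
      config$combinations
    ) |>
      dplyr::left_join(panel, by = "cell_line")
    scores <- purrr::pmap_dfr(
      list(grid$cell_line, grid$subtype, grid$drug_row, grid$drug_col),
      function(cl, st, dr, dc) {
        m <- simulate_combination_matrix(config$sim, cl, st, dr, dc)
        glance(bliss_synergy_score(m))
      }
    )
    scores <- dplyr::left_join(
      scores, dplyr::select(calls, "cell_line", "consensus"), by = "cell_line"
    )
    synergy_by_group <- scores |>
      dplyr::filter(.data$consensus != "unclassified") |>
      dplyr::mutate(combination = paste(.data$drug_row, .data$drug_col,
                                        sep = "+")) |>
      dplyr::group_by(.data$combination) |>
      dplyr::group_modify(function(d, key) {
        compare_synergy_by_group(d, score, consensus,
                                 p_threshold = config$p_threshold)
      }) |>
      dplyr::ungroup()
    rep$synergy_scores <- scores
    rep$synergy_by_group <- synergy_by_group
  }

  if (on[["associate"]]) {
    mutations <- simulate_mutations(config$sim, panel)
    rep$mutations <- mutations
    rep$mutation_assoc <- mutation_association(
      rep$auc_table, mutations, p_threshold = config$p_threshold
    )
  }

  if (on[["assays"]]) {
    ct <- simulate_qpcr(config$sim, config$qpcr_folds)
    rep$qpcr <- ddct_table(ct)
    colonies <- simulate_clonogenic(
      config$sim, pe = config$clonogenic$pe,
      sf_true = c(treated = config$clonogenic$sf_true),
      n_seeded = config$clonogenic$n_seeded
    )
    rep$clonogenic <- clonogenic_table(colonies)
  }

  rep$manifest <- tibble(
    seed = config$seed,
    config_hash = rlang::hash(config),
    package_version = as.character(utils::packageVersion("basalscreen"))
  )
  structure(rep, class = "basal_report")
}

#' @export
print.basal_report <- function(x, ...) {
  cat("<basal_report> seed", x$config$seed, "\n")
  if (!is.null(x$calls)) {
    cat("  consensus:", sum(x$calls$consensus == "basal"), "basal /",
        sum(x$calls$consensus == "non-basal"), "non-basal /",
        sum(x$calls$consensus == "unclassified"), "unclassified\n")
  }
  if (!is.null(x$auc_by_subtype)) {
    cat("  AUC basal-vs-non-basal p-values:",
        paste(sprintf("%s=%.3g", x$auc_by_subtype$drug,
                      x$auc_by_subtype$p_value), collapse = " "), "\n")
  }
  if (!is.null(x$synergy_by_group)) {
    cat("  synergy group tests:", nrow(x$synergy_by_group), "combinations\n")
  }
  invisible(x)
}
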