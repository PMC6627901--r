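#' Simulation configuration for the synthetic HNSCC screen
#'
#' One object holds every tunable parameter of the synthetic-data generators,
#' so that a single root `seed` fully determines all simulated inputs of the
#' pipeline (expression cohorts, viability plates, combination matrices,
#' mutation calls, qPCR Ct values, colony counts).
#'
#' Defaults emulate the structure of published HNSCC panels: four molecular
#' subtypes with roughly 30% basal tumors, basal-marker genes (including
#' `EREG` and `AREG`) shifted up by 2 log2 units, per-dataset batch scale and
#' offset, subtype-biased mutation frequencies (e.g. `CDKN2A` at 0.6 in basal
#' vs 0.13 in non-basal lines), a one-decade IC50 potency shift of basal lines
#' under EGFR-directed drugs, and an injectable Bliss excess for synergistic
#' combinations.
#'
#' @param seed Integer root seed. Each generator draws from its own named
#'   stream derived from this seed, so generators are mutually independent.
#' @param n_genes Number of genes per expression dataset.
#' @param n_samples_per_dataset Samples per simulated cohort.
#' @param n_datasets Number of cohorts produced by [simulate_expression()].
#' @param subtype_proportions Named fractions over the four subtypes
#'   (must sum to 1).
#' @param marker_genes Gene names receiving the basal up-regulation; the
#'   first entries are the canonical EGFR-ligand markers.
#' @param subtype_markers Named list of marker blocks for the non-basal
#'   subtypes, each up-regulated by `marker_effect` in its own subtype. These
#'   give every subtype an identifiable expression shape, without which a
#'   correlation-based nearest-centroid classifier has no pattern to match.
#'   Set to `list()` to simulate a basal-only signal.
#' @param marker_effect Log2 expression shift of marker genes in basal
#'   samples.
#' @param noise_sd SD of Gaussian expression noise (log2 units).
#' @param batch_scale_range Range of the per-dataset multiplicative batch
#'   scale.
#' @param mutation_rates Named list `gene -> c(rate_basal, rate_nonbasal)`.
#' @param potency_shift log10 IC50 shift (decades) of basal lines under
#'   EGFR-targeting drugs; positive means more sensitive.
#' @param synergy_delta Default injected Bliss excess (percentage points) for
#'   synergistic (subtype, combination) pairs.
#' @param viability_clip Bounds applied to normalized viability fractions,
#'   mimicking fluorescence overshoot.
#' @param signal_noise_sd SD of plate-signal noise as a fraction of the
#'   control minus blank window.
#' @param ct_noise_sd SD of qPCR Ct noise (cycles).
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 50, n_samples_per_dataset = 20)
#' cfg$subtype_proportions
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 200L,
                       n_samples_per_dataset = 60L,
                       n_datasets = 4L,
                       subtype_proportions = c(
                         basal = 0.30, classical = 0.25,
                         mesenchymal = 0.25, atypical = 0.20
                       ),
                       marker_genes = c("EREG", "AREG", sprintf("BSL%02d", 3:10)),
                       subtype_markers = list(
                         classical = sprintf("CLA%02d", 1:8),
                         mesenchymal = sprintf("MES%02d", 1:8),
                         atypical = sprintf("ATY%02d", 1:8)
                       ),
                       marker_effect = 2,
                       noise_sd = 1,
                       batch_scale_range = c(0.8, 1.25),
                       mutation_rates = list(
                         CDKN2A = c(0.60, 0.13),
                         PTEN = c(0.30, 0.10),
                         EGFR = c(0.20, 0.07),
                         HIST1H3B = c(0.10, 0.20)
                       ),
                       potency_shift = 1,
                       synergy_delta = 10,
                       viability_clip = c(-0.05, 1.2),
                       signal_noise_sd = 0.02,
                       ct_noise_sd = 0.15) {
  assert_count(seed, "seed")
  assert_count(n_genes, "n_genes")
  assert_count(n_samples_per_dataset, "n_samples_per_dataset")
  assert_count(n_datasets, "n_datasets")
  if (abs(sum(subtype_proportions) - 1) > 1e-9) {
    abort("`subtype_proportions` must sum to 1")
  }
  assert_fraction(subtype_proportions, "subtype_proportions")
  if (is.null(names(subtype_proportions))) {
    abort("`subtype_proportions` must be named by subtype")
  }
  for (g in names(mutation_rates)) {
    r <- mutation_rates[[g]]
    if (length(r) != 2) abort("each mutation rate must be c(rate_basal, rate_nonbasal)")
    assert_fraction(r, paste0("mutation_rates$", g))
  }
  if (noise_sd < 0 || signal_noise_sd < 0 || ct_noise_sd < 0) {
    abort("noise SDs must be non-negative")
  }
  if (length(batch_scale_range) != 2 || diff(batch_scale_range) < 0 ||
      any(batch_scale_range <= 0)) {
    abort("`batch_scale_range` must be an increasing positive pair")
  }
  if (length(subtype_markers) > 0 &&
      (is.null(names(subtype_markers)) ||
         !all(names(subtype_markers) %in% names(subtype_proportions)))) {
    abort("`subtype_markers` must be named by subtype")
  }
  structure(
    list(
      seed = as.integer(seed), n_genes = as.integer(n_genes),
      n_samples_per_dataset = as.integer(n_samples_per_dataset),
      n_datasets = as.integer(n_datasets),
      subtype_proportions = subtype_proportions,
      marker_genes = marker_genes, subtype_markers = subtype_markers,
      marker_effect = marker_effect,
      noise_sd = noise_sd, batch_scale_range = batch_scale_range,
      mutation_rates = mutation_rates, potency_shift = potency_shift,
      synergy_delta = synergy_delta, viability_clip = viability_clip,
      signal_noise_sd = signal_noise_sd, ct_noise_sd = ct_noise_sd
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed", x$seed, "|", x$n_datasets, "datasets x",
      x$n_samples_per_dataset, "samples x", x$n_genes, "genes\n")
  cat("  subtypes:", paste(sprintf("%s=%.2f", names(x$subtype_proportions),
                                   x$subtype_proportions), collapse = " "), "\n")
  cat("  marker effect", x$marker_effect, "log2 | noise sd", x$noise_sd,
      "| potency shift", x$potency_shift, "decades\n")
  invisible(x)
}

#' Expression dataset container
#'
#' A light container for one cohort: a log2 expression matrix (genes in rows,
#' samples in columns), the dataset identity, and optional per-sample subtype
#' labels.
#'
#' @param dataset_id Character label for the cohort.
#' @param values Numeric matrix, genes x samples, with dimnames.
#' @param subtypes Optional named character vector of per-sample subtype
#'   labels (names = sample ids).
#' @return An object of class `expr_dataset`.
#' @export
expr_dataset <- function(dataset_id, values, subtypes = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || anyNA(rownames(values)) ||
      any(rownames(values) == "")) {
    abort("`values` must have complete gene rownames")
  }
  if (is.null(colnames(values))) abort("`values` must have sample colnames")
  if (!all(is.finite(values))) abort("expression values must be finite")
  if (!is.null(subtypes)) {
    subtypes <- subtypes[colnames(values)]
    if (anyNA(subtypes)) abort("`subtypes` must cover every sample")
  }
  structure(
    list(dataset_id = dataset_id, values = values, subtypes = subtypes),
    class = "expr_dataset"
  )
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat("<expr_dataset>", x$dataset_id, ":", nrow(x$values), "genes x",
      ncol(x$values), "samples",
      if (!is.null(x$subtypes)) "(labelled)" else "(unlabelled)", "\n")
  invisible(x)
}

#' @method as_tibble expr_dataset
#' @export
as_tibble.expr_dataset <- function(x, ...) {
  out <- tibble(
    dataset_id = x$dataset_id,
    gene = rep(rownames(x$values), times = ncol(x$values)),
    sample = rep(colnames(x$values), each = nrow(x$values)),
    expression = as.vector(x$values)
  )
  if (!is.null(x$subtypes)) out$subtype <- x$subtypes[out$sample]
  out
}

#' Simulate log2 expression cohorts with a basal marker signal
#'
#' Generates `n_datasets` cohorts sharing a common gene-level biology
#' (baseline means) but each with its own batch scale and offset. Samples are
#' assigned one of the four subtypes at the configured proportions; the
#' configured marker genes are shifted up by `marker_effect` log2 units in
#' basal samples. The marker shift is applied after the batch scale, so the
#' within-dataset basal-vs-rest expectation equals `marker_effect` exactly.
#'
#' @param config A [sim_config()].
#' @param sample_ids Optional character vector of sample names shared by all
#'   datasets (e.g. a cell-line panel); length must be
#'   `n_samples_per_dataset`.
#' @param subtype_labels Optional named character vector fixing each sample's
#'   subtype (names must match `sample_ids`); when supplied the same labels
#'   are used in every dataset, emulating repeated profiling of one panel.
#' @param dataset_ids Optional character vector of dataset names.
#' @return A named list of [expr_dataset()] objects with ground-truth labels.
#' @examples
#' cohorts <- simulate_expression(sim_config(seed = 7, n_genes = 40,
#'                                           n_samples_per_dataset = 20,
#'                                           n_datasets = 2))
#' cohorts[[1]]
#' @export
simulate_expression <- function(config, sample_ids = NULL,
                                subtype_labels = NULL, dataset_ids = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n_g <- config$n_genes
  n_s <- config$n_samples_per_dataset
  blocks <- c(list(basal = config$marker_genes), config$subtype_markers)
  n_marked <- length(unlist(blocks))
  if (n_marked > n_g) abort("more marker genes than genes")
  genes <- c(unlist(blocks, use.names = FALSE),
             sprintf("GENE%04d", seq_len(n_g - n_marked)))
  if (anyDuplicated(genes)) abort("duplicate marker gene names")
  dataset_ids <- dataset_ids %||% sprintf("cohort%d", seq_len(config$n_datasets))
  if (length(dataset_ids) != config$n_datasets) {
    abort("`dataset_ids` must have length n_datasets")
  }
  if (!is.null(sample_ids) && length(sample_ids) != n_s) {
    abort("`sample_ids` must have length n_samples_per_dataset")
  }
  with_stream_seed(config$seed, "expression", {
    base_mean <- stats::rnorm(n_g, mean = 7, sd = 1)
    out <- lapply(seq_along(dataset_ids), function(d) {
      scale_d <- stats::runif(1, config$batch_scale_range[1],
                              config$batch_scale_range[2])
      offset_d <- stats::rnorm(1, 0, 0.5)
      samples <- sample_ids %||% sprintf("%s_S%03d", dataset_ids[d], seq_len(n_s))
      if (!is.null(subtype_labels)) {
        subt <- subtype_labels[samples]
        if (anyNA(subt)) abort("`subtype_labels` must cover every sample id")
      } else {
        subt <- sample(names(config$subtype_proportions), n_s, replace = TRUE,
                       prob = config$subtype_proportions)
        names(subt) <- samples
      }
      vals <- offset_d + scale_d * base_mean +
        matrix(stats::rnorm(n_g * n_s, 0, config$noise_sd), n_g, n_s)
      for (st in names(blocks)) {
        in_block <- genes %in% blocks[[st]]
        vals[in_block, subt == st] <- vals[in_block, subt == st] +
          config$marker_effect
      }
      dimnames(vals) <- list(genes, samples)
      expr_dataset(dataset_ids[d], vals, subt)
    })
    names(out) <- dataset_ids
    out
  })
}

#' Default single-agent drug panel
#'
#' The six-compound screening panel with 13-point, 2.5-fold dilution series:
#' small molecules from 0.5 nM to ~30 uM, Cetuximab from 0.1 nM to ~5.7 uM,
#' Trastuzumab from 0.4 nM to ~24 uM. `targets_egfr` marks the three
#' EGFR-directed agents whose potency is subtype-shifted in basal lines.
#'
#' @return A tibble with columns `drug`, `targets_egfr`, `c_min_M`,
#'   `dilution`, `n_conc`.
#' @export
default_drug_panel <- function() {
  tibble(
    drug = c("Afatinib", "Erlotinib", "Cetuximab",
             "Gedatolisib", "Cobimetinib", "Trastuzumab"),
    targets_egfr = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    c_min_M = c(0.5e-9, 0.5e-9, 0.1e-9, 0.5e-9, 0.5e-9, 0.4e-9),
    dilution = 2.5,
    n_conc = 13L
  )
}

#' Simulate a single-agent viability plate
#'
#' For each (cell line, drug) pair the generator draws a true four-parameter
#' logistic curve (top 1, bottom 0, hill 1, log10 IC50 ~ Normal around the
#' mid-range concentration) and emits raw fluorescence signals at every
#' concentration in triplicate:
#' `signal = blank + (control - blank) * viability + noise`.
#' Basal lines have their log10 IC50 lowered by `config$potency_shift` for
#' EGFR-targeting drugs, making them more sensitive.
#'
#' @param config A [sim_config()].
#' @param cell_lines Tibble/data frame with columns `cell_line` and `subtype`.
#' @param drugs Drug panel tibble as from [default_drug_panel()].
#' @param control_signal,blank_signal Plate control levels (arbitrary
#'   fluorescence units).
#' @param n_replicates Technical replicates per well.
#' @param ic50_sd SD of the per-line log10 IC50 draw (decades).
#' @return A long tibble (`cell_line`, `drug`, `concentration_M`, `replicate`,
#'   `signal`, `control_signal`, `blank_signal`) carrying the true curve
#'   parameters as attribute `"truth"`; see [sim_truth()].
#' @export
simulate_dose_response <- function(config, cell_lines,
                                   drugs = default_drug_panel(),
                                   control_signal = 1000, blank_signal = 50,
                                   n_replicates = 3L, ic50_sd = 0.3) {
  stopifnot(inherits(config, "sim_config"))
  cell_lines <- as_tibble(cell_lines)
  if (nrow(drugs) == 0) abort("empty drug panel")
  if (!all(c("cell_line", "subtype") %in% names(cell_lines))) {
    abort("`cell_lines` needs columns cell_line and subtype")
  }
  with_stream_seed(config$seed, "dose", {
    grid <- tidyr::expand_grid(
      cell_line = cell_lines$cell_line,
      drug = drugs$drug
    )
    grid <- dplyr::left_join(grid, cell_lines, by = "cell_line")
    grid <- dplyr::left_join(grid, drugs, by = "drug")
    mid <- log10(grid$c_min_M) + (grid$n_conc - 1) / 2 * log10(grid$dilution)
    grid$log10_ic50 <- stats::rnorm(nrow(grid), mid, ic50_sd) -
      ifelse(grid$subtype == "basal" & grid$targets_egfr,
             config$potency_shift, 0)
    truth <- tibble(
      cell_line = grid$cell_line, drug = grid$drug,
      top = 1, bottom = 0, ic50_M = 10^grid$log10_ic50, hill = 1
    )
    plate <- purrr::pmap_dfr(
      list(grid$cell_line, grid$drug, grid$c_min_M, grid$dilution,
           grid$n_conc, grid$log10_ic50),
      function(cl, dr, cmin, dil, k, lic50) {
        conc <- cmin * dil^(0:(k - 1))
        viab <- four_pl(conc, top = 1, bottom = 0, ic50 = 10^lic50, hill = 1)
        tibble(
          cell_line = cl, drug = dr,
          concentration_M = rep(conc, each = n_replicates),
          replicate = rep(seq_len(n_replicates), times = k),
          signal = blank_signal +
            (control_signal - blank_signal) * rep(viab, each = n_replicates) +
            stats::rnorm(k * n_replicates, 0,
                         config$signal_noise_sd * (control_signal - blank_signal)),
          control_signal = control_signal, blank_signal = blank_signal
        )
      }
    )
    attr(plate, "truth") <- truth
    plate
  })
}

#' Ground truth attached to a simulated object
#'
#' @param x A simulated plate or matrix carrying a `"truth"` attribute.
#' @return The ground-truth tibble recorded by the generator.
#' @export
sim_truth <- function(x) attr(x, "truth")

#' Simulate a two-drug combination dose matrix
#'
#' Builds a (6+1) x (6+1) inhibition grid (concentration 0 rows/columns are
#' the single-agent axes). Single-agent inhibitions follow each drug's true
#' logistic curve; combination cells equal the Bliss independence expectation
#' plus `synergy_delta` percentage points plus noise, clipped to \[0, 100\].
#'
#' @param config A [sim_config()].
#' @param cell_line,subtype Identity of the line being screened.
#' @param drug_row,drug_col Drug names for the two axes.
#' @param synergy_delta Injected Bliss excess in percentage points; defaults
#'   to `config$synergy_delta` for basal lines and 0 otherwise.
#' @param row_c_min,col_c_min Lowest non-zero concentration per axis (molar).
#' @param dilution Fold dilution between consecutive concentrations.
#' @param n_conc Non-zero concentrations per axis.
#' @param log10_ic50_row,log10_ic50_col Optional fixed true log10 IC50s;
#'   drawn around mid-range when `NULL`.
#' @param noise_sd SD of inhibition noise in percentage points; defaults to
#'   `100 * config$signal_noise_sd`.
#' @return A [dose_matrix()] with attribute `"truth"` (true IC50s and delta).
#' @export
simulate_combination_matrix <- function(config, cell_line, subtype,
                                        drug_row, drug_col,
                                        synergy_delta = NULL,
                                        row_c_min = 1.3e-9, col_c_min = 1.3e-9,
                                        dilution = 6, n_conc = 6L,
                                        log10_ic50_row = NULL,
                                        log10_ic50_col = NULL,
                                        noise_sd = NULL) {
  stopifnot(inherits(config, "sim_config"))
  synergy_delta <- synergy_delta %||%
    if (identical(subtype, "basal")) config$synergy_delta else 0
  noise_sd <- noise_sd %||% (100 * config$signal_noise_sd)
  salt <- salt_from(cell_line, drug_row, drug_col)
  with_stream_seed(config$seed, "combination", salt = salt, {
    mid_r <- log10(row_c_min) + (n_conc - 1) / 2 * log10(dilution)
    mid_c <- log10(col_c_min) + (n_conc - 1) / 2 * log10(dilution)
    lr <- log10_ic50_row %||% stats::rnorm(1, mid_r, 0.3)
    lc <- log10_ic50_col %||% stats::rnorm(1, mid_c, 0.3)
    row_concs <- c(0, row_c_min * dilution^(0:(n_conc - 1)))
    col_concs <- c(0, col_c_min * dilution^(0:(n_conc - 1)))
    inh_row <- c(0, 100 * (1 - four_pl(row_concs[-1], 1, 0, 10^lr, 1)))
    inh_col <- c(0, 100 * (1 - four_pl(col_concs[-1], 1, 0, 10^lc, 1)))
    inh <- outer(inh_row, inh_col, bliss_expected)
    combo <- row(inh) > 1 & col(inh) > 1
    inh[combo] <- inh[combo] + synergy_delta
    noise <- matrix(stats::rnorm(length(inh), 0, noise_sd), nrow(inh))
    noise[1, 1] <- 0
    inh <- pmin(pmax(inh + noise, 0), 100)
    m <- dose_matrix(inh, row_concs, col_concs,
                     drug_row = drug_row, drug_col = drug_col,
                     cell_line = cell_line)
    attr(m, "truth") <- list(log10_ic50_row = lr, log10_ic50_col = lc,
                             synergy_delta = synergy_delta)
    m
  })
}

#' Simulate binary mutation calls with subtype-biased frequencies
#'
#' Bernoulli draws per (cell line, gene) at the basal or non-basal rate from
#' `config$mutation_rates`, emulating hotspot-panel calls where drivers such
#' as CDKN2A are enriched in basal lines.
#'
#' @param config A [sim_config()].
#' @param cell_lines Tibble with columns `cell_line` and `subtype`.
#' @return Long tibble `cell_line`, `gene`, `status` (0/1).
#' @export
simulate_mutations <- function(config, cell_lines) {
  stopifnot(inherits(config, "sim_config"))
  cell_lines <- as_tibble(cell_lines)
  with_stream_seed(config$seed, "mutation", {
    purrr::imap_dfr(config$mutation_rates, function(rates, gene) {
      p <- ifelse(cell_lines$subtype == "basal", rates[1], rates[2])
      tibble(
        cell_line = cell_lines$cell_line, gene = gene,
        status = stats::rbinom(nrow(cell_lines), 1, p)
      )
    })
  })
}

#' Simulate qPCR Ct tables for a delta-delta-Ct round trip
#'
#' Target Ct values are `base_ct - log2(fold change)` plus noise; reference
#' genes sit at fixed Ct levels. The control condition carries fold change 1
#' by construction, so the delta-delta-Ct pipeline should recover
#' `true_fold_changes` exactly at zero noise.
#'
#' @param config A [sim_config()].
#' @param true_fold_changes Named numeric vector: condition -> fold change
#'   relative to the control condition.
#' @param target Target gene name.
#' @param reference_ct Named numeric vector of reference-gene Ct levels.
#' @param base_ct Target Ct in the control condition.
#' @param control_condition Name of the control condition.
#' @param n_replicates Technical replicates per (condition, gene).
#' @return Tibble `condition`, `gene`, `replicate`, `ct`.
#' @export
simulate_qpcr <- function(config, true_fold_changes, target = "EREG",
                          reference_ct = c(RPLP0 = 18, UBB = 19),
                          base_ct = 25, control_condition = "control",
                          n_replicates = 3L) {
  stopifnot(inherits(config, "sim_config"))
  if (any(true_fold_changes <= 0)) abort("fold changes must be positive")
  conds <- c(stats::setNames(1, control_condition), true_fold_changes)
  with_stream_seed(config$seed, "qpcr", {
    purrr::imap_dfr(conds, function(fold, cond) {
      genes <- c(stats::setNames(base_ct - log2(fold), target), reference_ct)
      tidyr::expand_grid(gene = names(genes), replicate = seq_len(n_replicates)) |>
        dplyr::mutate(
          condition = cond,
          ct = genes[.data$gene] +
            stats::rnorm(dplyr::n(), 0, config$ct_noise_sd),
          .before = 1
        )
    })
  })
}

#' Simulate clonogenic colony counts
#'
#' Colony counts are binomial: untreated wells score successes at the plating
#' efficiency `pe`, treated wells at `pe * sf_true`.
#'
#' @param config A [sim_config()].
#' @param pe True plating efficiency in (0, 1].
#' @param sf_true Named numeric vector: treated condition -> true surviving
#'   fraction.
#' @param n_seeded Cells seeded per well.
#' @param n_replicates Wells per condition.
#' @param control_condition Name of the untreated condition.
#' @return Tibble `condition`, `replicate`, `cells_seeded`, `colonies`.
#' @export
simulate_clonogenic <- function(config, pe, sf_true, n_seeded,
                                n_replicates = 3L,
                                control_condition = "untreated") {
  stopifnot(inherits(config, "sim_config"))
  if (n_seeded < 0) abort("`n_seeded` must be non-negative")
  assert_fraction(pe, "pe")
  if (any(pe * sf_true < 0) || any(pe * sf_true > 1)) {
    abort("`pe * sf_true` must lie in [0, 1]")
  }
  probs <- c(stats::setNames(pe, control_condition), pe * sf_true)
  with_stream_seed(config$seed, "clonogenic", {
    purrr::imap_dfr(probs, function(p, cond) {
      tibble(
        condition = cond, replicate = seq_len(n_replicates),
        cells_seeded = n_seeded,
        colonies = stats::rbinom(n_replicates, n_seeded, p)
      )
    })
  })
}
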