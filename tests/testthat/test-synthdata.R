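test_that("every generator is byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 11, n_genes = 40, n_samples_per_dataset = 12,
                    n_datasets = 2)
  lines <- tibble::tibble(cell_line = c("A", "B", "C"),
                          subtype = c("basal", "classical", "basal"))
  expect_identical(simulate_expression(cfg), simulate_expression(cfg))
  expect_identical(simulate_dose_response(cfg, lines),
                   simulate_dose_response(cfg, lines))
  expect_identical(simulate_mutations(cfg, lines),
                   simulate_mutations(cfg, lines))
  expect_identical(
    simulate_combination_matrix(cfg, "A", "basal", "Afatinib", "Trastuzumab"),
    simulate_combination_matrix(cfg, "A", "basal", "Afatinib", "Trastuzumab")
  )
  expect_identical(simulate_qpcr(cfg, c(kd = 0.1)),
                   simulate_qpcr(cfg, c(kd = 0.1)))
  expect_identical(simulate_clonogenic(cfg, 0.4, c(t = 0.5), 250),
                   simulate_clonogenic(cfg, 0.4, c(t = 0.5), 250))
})

test_that("config validation rejects malformed parameters", {
  expect_error(sim_config(n_genes = 0), "positive integer")
  expect_error(sim_config(subtype_proportions = c(basal = 0.5, classical = 0.4)),
               "sum to 1")
  expect_error(sim_config(mutation_rates = list(G = c(1.2, 0))), "\\[0, 1\\]")
})

test_that("marker effect is absent under the null and recovered when injected", {
  # null: marker_effect = 0 -> basal-vs-rest difference within 3 SE of 0
  cfg0 <- sim_config(seed = 5, n_genes = 60, n_samples_per_dataset = 50,
                     n_datasets = 1, marker_effect = 0, noise_sd = 1,
                     subtype_markers = list())
  d0 <- simulate_expression(cfg0)[[1]]
  basal <- d0$subtypes == "basal"
  diffs <- rowMeans(d0$values[cfg0$marker_genes, basal, drop = FALSE]) -
    rowMeans(d0$values[cfg0$marker_genes, !basal, drop = FALSE])
  se <- 1 * sqrt(1 / sum(basal) + 1 / sum(!basal))
  expect_lt(abs(mean(diffs)), 3 * se / sqrt(length(diffs)))

  # injected: effect 2, noise 0.5, 50 samples -> EREG difference 2 within 3 SE
  cfg2 <- sim_config(seed = 6, n_genes = 60, n_samples_per_dataset = 50,
                     n_datasets = 1, marker_effect = 2, noise_sd = 0.5)
  d2 <- simulate_expression(cfg2)[[1]]
  basal <- d2$subtypes == "basal"
  diff_ereg <- mean(d2$values["EREG", basal]) - mean(d2$values["EREG", !basal])
  se <- 0.5 * sqrt(1 / sum(basal) + 1 / sum(!basal))
  expect_lt(abs(diff_ereg - 2), 3 * se)
})

test_that("dilution series match the screening ranges", {
  panel <- default_drug_panel()
  top_conc <- panel$c_min_M * panel$dilution^(panel$n_conc - 1)
  # drugs 0.5 nM -> ~30 uM; Cetuximab 0.1 nM -> ~5.7 uM; Trastuzumab -> ~24 uM
  expect_equal(top_conc[panel$drug == "Afatinib"], 0.5e-9 * 2.5^12)
  expect_equal(round(top_conc[panel$drug == "Afatinib"] / 1e-6, 1), 29.8)
  expect_equal(round(top_conc[panel$drug == "Cetuximab"] / 1e-6, 1), 6.0)
  expect_equal(round(top_conc[panel$drug == "Trastuzumab"] / 1e-6, 1), 23.8)
})

test_that("noiseless plates share viability across lines when potency is flat", {
  cfg <- sim_config(seed = 9, signal_noise_sd = 0, potency_shift = 0)
  lines <- tibble::tibble(cell_line = c("L1", "L2"),
                          subtype = c("basal", "classical"))
  plate <- simulate_dose_response(cfg, lines, ic50_sd = 0)
  v <- normalize_viability(plate$signal, plate$control_signal,
                           plate$blank_signal)
  by_well <- tapply(v, list(plate$cell_line,
                            paste(plate$drug, plate$concentration_M)), mean)
  expect_equal(unname(by_well["L1", ]), unname(by_well["L2", ]),
               tolerance = 1e-12)
})

test_that("fitting a noiseless generated curve recovers the true IC50 within 1%", {
  cfg <- sim_config(seed = 10, signal_noise_sd = 0)
  lines <- tibble::tibble(cell_line = "L1", subtype = "classical")
  plate <- simulate_dose_response(cfg, lines)
  truth <- sim_truth(plate)
  fits <- fit_dose_response(plate)
  both <- merge(fits, truth, by = c("cell_line", "drug"))
  expect_true(all(both$converged))
  expect_true(all(abs(both$ic50_M.x / both$ic50_M.y - 1) < 0.01))
})

test_that("combination generator round-trips the injected Bliss excess", {
  base <- list(row_c_min = 1.3e-9, col_c_min = 1.3e-9, dilution = 6)
  # high IC50s keep expected + delta below the 100% clip
  hi <- log10(1.3e-9 * 6^5 * 100)
  cfg <- sim_config(seed = 12, signal_noise_sd = 0)
  m0 <- simulate_combination_matrix(cfg, "L", "classical", "A", "B",
                                    synergy_delta = 0,
                                    log10_ic50_row = hi, log10_ic50_col = hi)
  expect_equal(bliss_synergy_score(m0)$score, 0, tolerance = 1e-12)
  m10 <- simulate_combination_matrix(cfg, "L", "classical", "A", "B",
                                     synergy_delta = 10,
                                     log10_ic50_row = hi, log10_ic50_col = hi)
  expect_equal(bliss_synergy_score(m10)$score, 10, tolerance = 1e-12)
})

test_that("mutation counts follow the subtype-specific binomial expectation", {
  lines <- tibble::tibble(
    cell_line = sprintf("CL%02d", 1:25),
    subtype = rep(c("basal", "classical"), c(10, 15))
  )
  # rate (1, 0): all basal mutated, no non-basal
  cfg1 <- sim_config(seed = 3, mutation_rates = list(G = c(1, 0)))
  mut1 <- simulate_mutations(cfg1, lines)
  expect_true(all(mut1$status[1:10] == 1))
  expect_true(all(mut1$status[11:25] == 0))
  # rate (0.6, 0.13): mean counts near 6 and 2 over 500 replicate draws
  counts <- vapply(1:500, function(s) {
    cfg <- sim_config(seed = s, mutation_rates = list(CDKN2A = c(0.6, 0.13)))
    mut <- simulate_mutations(cfg, lines)
    c(sum(mut$status[1:10]), sum(mut$status[11:25]))
  }, numeric(2))
  se_b <- sqrt(10 * 0.6 * 0.4 / 500)
  se_n <- sqrt(15 * 0.13 * 0.87 / 500)
  expect_lt(abs(mean(counts[1, ]) - 6), 3 * se_b)
  expect_lt(abs(mean(counts[2, ]) - 1.95), 3 * se_n)
})

test_that("assay generators round-trip their configured truth at zero noise", {
  cfg <- sim_config(seed = 4, ct_noise_sd = 0)
  ct <- simulate_qpcr(cfg, c(none = 1, half = 0.5))
  folds <- ddct_table(ct)
  expect_equal(folds$fold_change[folds$condition == "none"], 1)
  expect_equal(folds$fold_change[folds$condition == "half"], 0.5)

  # binomial colony mean: pe 0.4, sf 0.5, 250 seeded -> 50 within 3 SE
  col <- simulate_clonogenic(sim_config(seed = 8), pe = 0.4,
                             sf_true = c(t = 0.5), n_seeded = 250,
                             n_replicates = 10000)
  treated <- col$colonies[col$condition == "t"]
  se <- sqrt(250 * 0.2 * 0.8 / 10000)
  expect_lt(abs(mean(treated) - 50), 3 * se)
  expect_error(simulate_clonogenic(sim_config(), pe = 0.9,
                                   sf_true = c(t = 1.2), n_seeded = 10),
               "\\[0, 1\\]")
})
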