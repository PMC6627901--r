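test_that("standardization removes batch scale and aggregation keeps shared genes", {
  d1 <- make_labelled_dataset("d1", seed = 1)
  d2 <- make_labelled_dataset("d2", seed = 2)
  agg <- scale_and_aggregate(list(d1, d2))
  # per-dataset, per-gene mean 0 and population SD 1 by definition
  cols1 <- grepl("^d1\\.", colnames(agg$values))
  expect_lt(max(abs(rowMeans(agg$values[, cols1]))), 1e-12)
  expect_lt(max(abs(sqrt(rowMeans(agg$values[, cols1]^2)) - 1)), 1e-12)

  # a global x10 batch scale standardizes to the identical values
  d1_scaled <- expr_dataset("d1s", d1$values * 10, d1$subtypes)
  agg_twin <- scale_and_aggregate(list(d1_scaled, d2))
  expect_equal(unname(agg_twin$values[, grepl("^d1s\\.", colnames(agg_twin$values))]),
               unname(agg$values[, cols1]), tolerance = 1e-12)

  # disjoint extra genes are dropped: output restricted to the intersection
  extra <- matrix(rnorm(24), 1, 24,
                  dimnames = list("ONLY1", colnames(d1$values)))
  d1_ext <- expr_dataset("d1", rbind(d1$values, extra), d1$subtypes)
  agg_ext <- scale_and_aggregate(list(d1_ext, d2))
  expect_setequal(rownames(agg_ext$values),
                  intersect(rownames(d1_ext$values), rownames(d2$values)))
})

test_that("common differential genes recover the injected basal signature", {
  n_seeds <- 10
  hits <- logical(n_seeds)
  clean <- logical(n_seeds)
  for (s in seq_len(n_seeds)) {
    cfg <- sim_config(seed = 100 + s, n_genes = 100,
                      n_samples_per_dataset = 60, n_datasets = 3,
                      marker_effect = 2, noise_sd = 0.5,
                      subtype_markers = list())
    ds <- simulate_expression(cfg)
    de <- identify_common_de_genes(ds, fdr = 0.05)
    hits[s] <- all(cfg$marker_genes %in% de)
    clean[s] <- length(setdiff(de, cfg$marker_genes)) == 0
  }
  expect_true(all(hits))
  expect_gte(mean(clean), 0.9)
})

test_that("null data yields an empty cross-dataset intersection", {
  empty <- vapply(1:5, function(s) {
    cfg <- sim_config(seed = 200 + s, n_genes = 100,
                      n_samples_per_dataset = 40, n_datasets = 3,
                      marker_effect = 0, subtype_markers = list())
    length(identify_common_de_genes(simulate_expression(cfg), fdr = 0.05)) == 0
  }, logical(1))
  expect_true(all(empty))
})

test_that("a single dataset degenerates to its own significant set", {
  d1 <- make_labelled_dataset("solo", seed = 3, effect = 3, noise = 0.3)
  de <- identify_common_de_genes(list(d1), fdr = 0.05)
  per <- attr(de, "per_dataset")[[1]]
  expect_setequal(as.character(de), per$feature[per$q_value <= 0.05])
  expect_error(identify_common_de_genes(list()), "no datasets")
})

test_that("centroids are the member means and compare by Pearson correlation", {
  d <- make_labelled_dataset("c", seed = 4, n_samples = 8)
  cen <- build_centroids(d)
  # one sample per subtype duplicated: brute-force column means
  for (st in cen$subtypes) {
    members <- names(d$subtypes)[d$subtypes == st]
    expect_equal(unname(cen$centroid_matrix[, st]),
                 unname(rowMeans(d$values[, members, drop = FALSE])))
  }
  # one sample per subtype -> centroid equals that sample
  d4 <- expr_dataset("one", d$values[, 1:4], d$subtypes[1:4])
  cen4 <- build_centroids(d4)
  for (st in cen4$subtypes) {
    s <- names(d4$subtypes)[d4$subtypes == st]
    expect_equal(unname(cen4$centroid_matrix[, st]), unname(d4$values[, s]))
  }

  self <- compare_centroids(cen, cen)
  expect_equal(unname(diag(self)), rep(1, 4))
  # brute-force Pearson agreement on random centroids
  cen_b <- build_centroids(make_labelled_dataset("cb", seed = 5, n_samples = 8))
  cmp <- compare_centroids(cen, cen_b)
  expect_equal(cmp["basal", "classical"],
               oracle_pearson(cen$centroid_matrix[, "basal"],
                              cen_b$centroid_matrix[, "classical"]),
               tolerance = 1e-12)
  # mirrored centroid correlates at exactly -1
  flipped <- cen
  flipped$centroid_matrix[, "basal"] <- -cen$centroid_matrix[, "basal"]
  expect_equal(compare_centroids(cen, flipped)["basal", "basal"], -1)
})

test_that("nearest-centroid prediction is exact, affine-invariant and accurate", {
  d <- make_labelled_dataset("p", seed = 6, n_samples = 16)
  cen <- build_centroids(d)
  # a profile equal to a centroid predicts that subtype with r = 1
  prof <- matrix(cen$centroid_matrix[, "basal"], ncol = 1,
                 dimnames = list(cen$genes, "probe"))
  call <- predict_subtypes(prof, cen)
  expect_equal(call$predicted, "basal")
  expect_equal(call$r_basal, 1)
  # correlations match the brute-force formula
  expect_equal(
    predict_subtypes(d$values[, 1, drop = FALSE], cen)$r_classical,
    oracle_pearson(d$values[, 1], cen$centroid_matrix[, "classical"]),
    tolerance = 1e-12
  )
  # Pearson invariance under positive affine transforms of the profile
  shifted <- d$values * 3.7 + 12
  expect_equal(predict_subtypes(shifted, cen)$predicted,
               predict_subtypes(d$values, cen)$predicted)
  expect_error(
    predict_subtypes(matrix(1, nrow(d$values), 1,
                            dimnames = list(rownames(d$values), "flat")), cen),
    "zero-variance"
  )
})

test_that("classification accuracy is high and rises with the marker effect", {
  acc_at <- function(effect, seed) {
    cfg <- sim_config(seed = seed, n_genes = 80, n_samples_per_dataset = 40,
                      n_datasets = 2, marker_effect = effect, noise_sd = 0.5)
    ds <- simulate_expression(cfg)
    agg <- scale_and_aggregate(ds)
    markers <- c(cfg$marker_genes, unlist(cfg$subtype_markers))
    cen <- build_centroids(agg, genes = markers)
    pred <- predict_subtypes(agg, cen)
    mean(pred$predicted == agg$subtypes[pred$sample_id])
  }
  seeds <- 301:310
  acc2 <- vapply(seeds, function(s) acc_at(2, s), numeric(1))
  expect_gte(mean(acc2), 0.95)
  # monotone in effect size at fixed noise
  acc05 <- vapply(seeds, function(s) acc_at(0.5, s), numeric(1))
  acc1 <- vapply(seeds, function(s) acc_at(1, s), numeric(1))
  expect_lte(mean(acc05), mean(acc1))
  expect_lte(mean(acc1), mean(acc2))
})

test_that("consensus truth table is honored for every valid input pair", {
  expect_equal(consensus_basal_call("basal", "basal"), "basal")
  expect_equal(consensus_basal_call("non-basal", "non-basal"), "non-basal")
  expect_equal(consensus_basal_call("non-basal", "absent"), "non-basal")
  expect_equal(consensus_basal_call("absent", "non-basal"), "non-basal")
  expect_equal(consensus_basal_call("basal", "non-basal"), "unclassified")
  expect_equal(consensus_basal_call("non-basal", "basal"), "unclassified")
  expect_equal(consensus_basal_call("basal", "absent"), "unclassified")
  expect_equal(consensus_basal_call("absent", "basal"), "unclassified")
  expect_error(consensus_basal_call("absent", "absent"), "absent from both")
  expect_error(consensus_basal_call("maybe", "basal"), "calls must be")
})

test_that("ROC AUC matches exhaustive pair counting and its complement rule", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(c(1, 3, 2, 4), c(0, 0, 1, 1)), 0.75)
  expect_equal(roc_auc(rep(2, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  set.seed(77)
  for (i in 1:20) {
    v <- rnorm(15)
    l <- sample(c(0, 1), 15, replace = TRUE)
    if (sum(l) %in% c(0, 15)) next
    expect_equal(roc_auc(v, l), oracle_roc_auc(v, l))
    expect_equal(roc_auc(v, l) + roc_auc(-v, l), 1)
  }
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("marker selection applies both thresholds and orders by AUC", {
  d <- make_labelled_dataset("m", seed = 8, n_samples = 40, effect = 2,
                             noise = 0.4)
  basal <- d$subtypes == "basal"
  sc <- select_markers(d, labels = basal, fc_threshold = 1,
                       auc_threshold = 0.8)
  top <- sc[sc$gene %in% c("EREG", "AREG", "M3", "M4"), ]
  expect_true(all(top$selected))
  expect_true(all(top$roc_auc > 0.9))
  # null genes hover near AUC 0.5 and fail the threshold
  null_auc <- sc$roc_auc[!sc$gene %in% c("EREG", "AREG", "M3", "M4")]
  expect_true(all(!sc$selected[!sc$gene %in% c("EREG", "AREG", "M3", "M4")]))
  expect_lt(abs(mean(null_auc) - 0.5), 3 * sd(null_auc) / sqrt(length(null_auc)) + 0.05)
  # infinite fold-change threshold empties the selection
  expect_false(any(select_markers(d, labels = basal,
                                  fc_threshold = Inf)$selected))
  expect_true(!is.unsorted(rev(sc$roc_auc)))
})
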