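test_that("two-sample t matches the textbook pooled computation", {
  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # hand computation: means 2 and 5, pooled var 1, se = sqrt(2/3)
  pooled <- two_sample_t(c(1, 2, 3), c(4, 5, 6), variant = "pooled")
  expect_equal(pooled$statistic, -3 / sqrt(2 / 3), tolerance = 1e-6)
  expect_equal(round(pooled$statistic, 3), -3.674)
  expect_equal(round(pooled$p_value, 4), 0.0213)
  expect_equal(pooled$effect_direction, -1)
  expect_error(two_sample_t(1, c(1, 2)), ">= 2 values")
})

test_that("moderated t reduces to ordinary t at d0 = 0 and stays calibrated", {
  set.seed(31)
  a <- matrix(rnorm(50 * 6), 50, dimnames = list(sprintf("f%02d", 1:50), NULL))
  b <- matrix(rnorm(50 * 8), 50, dimnames = list(sprintf("f%02d", 1:50), NULL))
  plain <- moderated_t(a, b, d0 = 0)
  for (i in c(1, 17, 50)) {
    ht <- t.test(a[i, ], b[i, ], var.equal = TRUE)
    expect_equal(plain$statistic[i], unname(ht$statistic), tolerance = 1e-9)
    expect_equal(plain$p_value[i], ht$p.value, tolerance = 1e-9)
  }
  # type-I error at alpha = 0.05 over 2000 null features
  set.seed(32)
  a2 <- matrix(rnorm(2000 * 8), 2000)
  b2 <- matrix(rnorm(2000 * 10), 2000)
  res <- moderated_t(a2, b2)
  t1 <- mean(res$p_value < 0.05)
  expect_gte(t1, 0.03)
  expect_lte(t1, 0.07)
  # shared true variance at large n: shrunken variances approach the pooled one
  expect_gt(attr(res, "d0"), 50)

  # injected signal ranks at the top
  set.seed(33)
  ranks_ok <- vapply(1:20, function(s) {
    set.seed(400 + s)
    a3 <- matrix(rnorm(500 * 15), 500)
    b3 <- matrix(rnorm(500 * 15), 500)
    a3[1:10, ] <- a3[1:10, ] + 2
    r <- moderated_t(a3, b3)
    all(rank(-abs(r$statistic))[1:10] <= 15)
  }, logical(1))
  expect_gte(mean(ranks_ok), 0.95)
})

test_that("moderated t agrees with an independent empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  set.seed(34)
  a <- matrix(rnorm(300 * 7, sd = rep(sqrt(rchisq(300, 4) / 4), 7)), 300)
  b <- matrix(rnorm(300 * 9, sd = rep(sqrt(rchisq(300, 4) / 4), 9)), 300) + 0.3
  res <- moderated_t(a, b)
  fit <- limma::eBayes(limma::lmFit(cbind(a, b),
                                    cbind(1, c(rep(1, 7), rep(0, 9)))))
  expect_gt(cor(res$statistic, fit$t[, 2]), 0.9999)
  expect_equal(attr(res, "d0"), fit$df.prior, tolerance = 0.05)
})

test_that("ANOVA F matches brute-force sums of squares", {
  ident <- one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(ident$statistic, 0)
  groups <- list(c(1, 2, 3), c(2, 3, 4), c(10, 11, 12))
  res <- one_way_anova(groups)
  expect_equal(res$statistic, oracle_anova_f(groups), tolerance = 1e-9)
  expect_error(one_way_anova(list(1, c(1, 2))), "at least 2 values")

  # marker gene across four simulated subtypes: strong group effect
  sig <- vapply(1:5, function(s) {
    cfg <- sim_config(seed = 500 + s, n_genes = 60,
                      n_samples_per_dataset = 40, n_datasets = 1,
                      marker_effect = 2, noise_sd = 0.5)
    d <- simulate_expression(cfg)[[1]]
    g <- split(d$values["EREG", ], d$subtypes)
    one_way_anova(g)$p_value < 0.001
  }, logical(1))
  expect_true(all(sig))
})

test_that("Yates-corrected chi-squared reproduces the screen's mutation anchor", {
  # 6/10 basal mutated vs 2/15 non-basal
  tab <- matrix(c(6, 2, 4, 13), 2)
  res <- chi2_yates(tab)
  expect_equal(res$statistic, 4.05, tolerance = 0.01)
  expect_lt(abs(res$p_value - 0.044), 0.001)
  # proportional rows: fully corrected to 0
  prop <- chi2_yates(matrix(c(5, 10, 5, 10), 2))
  expect_equal(prop$statistic, 0)
  expect_equal(prop$p_value, 1)
  # hand formula on random tables
  set.seed(41)
  for (i in 1:20) {
    t2 <- matrix(rpois(4, 12) + 1, 2)
    expect_equal(chi2_yates(t2)$statistic, oracle_chi2_yates(t2),
                 tolerance = 1e-9)
  }
  expect_error(chi2_yates(matrix(c(0, 0, 3, 4), 2)), "margins")
})

test_that("Fisher exact p sums hypergeometric probabilities", {
  expect_equal(fisher_exact(matrix(c(2, 0, 0, 2), 2))$p_value, 1 / 3)
  expect_equal(fisher_exact(matrix(c(1, 1, 1, 1), 2))$p_value, 1)
  # asymptotic agreement with chi-squared for large expected counts
  big <- matrix(c(50, 40, 45, 60), 2)
  expect_lt(abs(fisher_exact(big)$p_value - chi2_yates(big)$p_value), 0.05)
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  expect_equal(hypergeometric_enrichment(0, 5, 8, 30)$p_value, 1)
  expect_equal(hypergeometric_enrichment(5, 5, 5, 10)$p_value, 1 / choose(10, 5))
  for (q in 0:4) {
    expect_equal(
      hypergeometric_enrichment(q, 6, 8, 20)$p_value,
      oracle_hyper_upper(q, m = 8, k = 6, n_universe = 20),
      tolerance = 1e-12
    )
  }
  expect_error(hypergeometric_enrichment(6, 5, 8, 20), "cannot exceed")
})

test_that("BH adjustment matches the step-up definition", {
  set.seed(51)
  for (i in 1:10) {
    p <- runif(25)
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(adj <= 1))
  }
})

test_that("p-values are symmetric under group swap", {
  set.seed(52)
  x <- rnorm(8)
  y <- rnorm(12, 1)
  fwd <- two_sample_t(x, y)
  rev <- two_sample_t(y, x)
  expect_equal(fwd$statistic, -rev$statistic)
  expect_equal(fwd$p_value, rev$p_value)
  a <- matrix(rnorm(60), 12)
  b <- matrix(rnorm(72, 0.5), 12)
  mf <- moderated_t(a, b)
  mr <- moderated_t(b, a)
  expect_equal(mf$statistic, -mr$statistic, tolerance = 1e-12)
  expect_equal(mf$p_value, mr$p_value, tolerance = 1e-12)
})

test_that("mutation association flags the null at the configured rate", {
  lines <- sprintf("CL%02d", 1:25)
  flags <- vapply(1:200, function(s) {
    set.seed(600 + s)
    auc <- tidyr::expand_grid(cell_line = lines, drug = paste0("D", 1:6))
    auc$auc <- rnorm(nrow(auc))
    mut <- tibble::tibble(cell_line = lines, gene = "G1",
                          status = rbinom(25, 1, 0.35))
    r <- suppressMessages(mutation_association(auc, mut, p_threshold = 0.1))
    if (nrow(r) == 0) return(NA_real_)
    mean(r$flagged)
  }, numeric(1))
  rate <- mean(flags, na.rm = TRUE)
  # 3 SE band around the nominal 0.1 (tests within a run are correlated
  # through the shared moderation, so use the per-run SD)
  se <- sd(flags, na.rm = TRUE) / sqrt(sum(!is.na(flags)))
  expect_lt(abs(rate - 0.1), 3 * se + 0.01)
})

test_that("a sensitizing mutation is recovered with negative direction", {
  hits <- vapply(1:20, function(s) {
    set.seed(700 + s)
    lines <- sprintf("CL%02d", 1:25)
    mutated <- lines[1:8]
    auc <- tidyr::expand_grid(cell_line = lines, drug = paste0("D", 1:6))
    auc$auc <- rnorm(nrow(auc), 4, 0.3) -
      ifelse(auc$cell_line %in% mutated, 1, 0)
    mut <- tibble::tibble(cell_line = lines, gene = "G1",
                          status = as.integer(lines %in% mutated))
    r <- suppressMessages(mutation_association(auc, mut, p_threshold = 0.1))
    all(r$flagged) && all(r$effect_direction == -1)
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # a gene mutated in one line is skipped with a message
  lines <- sprintf("CL%02d", 1:10)
  auc <- tidyr::expand_grid(cell_line = lines, drug = paste0("D", 1:3))
  auc$auc <- seq_len(nrow(auc))
  mut <- tibble::tibble(cell_line = lines, gene = "RARE",
                        status = c(1, rep(0, 9)))
  expect_message(res <- mutation_association(auc, mut), "skipping RARE")
  expect_equal(nrow(res), 0)
  expect_equal(attr(res, "skipped"), "RARE")
})
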