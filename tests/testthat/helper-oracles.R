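# Independent brute-force oracles used to freeze expected values. Each is a
# direct transcription of the defining formula, kept free of the package's
# own computational paths.

# Pearson correlation from the textbook formula
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

# ROC AUC by exhaustive pair counting (ties count 1/2)
oracle_roc_auc <- function(values, labels) {
  pos <- values[as.logical(labels)]
  neg <- values[!as.logical(labels)]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Yates-corrected chi-squared from the hand formula sum((|O-E|-0.5)^2 / E),
# with the correction capped so proportional tables give 0
oracle_chi2_yates <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum(pmax(abs(tab - e) - 0.5, 0)^2 / e)
}

# hypergeometric upper tail P(X >= q) by enumeration over all feasible counts
oracle_hyper_upper <- function(q, m, k, n_universe) {
  # m annotated in universe, k drawn
  xs <- max(0, k - (n_universe - m)):min(k, m)
  probs <- choose(m, xs) * choose(n_universe - m, k - xs) / choose(n_universe, k)
  sum(probs[xs >= q])
}

# Benjamini-Hochberg from the step-up definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# one-way ANOVA F from between/within sums of squares
oracle_anova_f <- function(groups) {
  all_v <- unlist(groups)
  gm <- mean(all_v)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  k <- length(groups)
  n <- length(all_v)
  (ssb / (k - 1)) / (ssw / (n - k))
}

# trapezoid integral oracle
oracle_trapz <- function(x, y) {
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

# small labelled dataset builder for subtyping tests
make_labelled_dataset <- function(id, n_genes = 30, n_samples = 24,
                                  effect = 2, noise = 0.5, seed = 1,
                                  markers = c("EREG", "AREG", "M3", "M4")) {
  set.seed(seed)
  genes <- c(markers, sprintf("G%03d", seq_len(n_genes - length(markers))))
  subt <- rep(c("basal", "classical", "mesenchymal", "atypical"),
              length.out = n_samples)
  names(subt) <- sprintf("%s_S%02d", id, seq_len(n_samples))
  vals <- matrix(rnorm(n_genes * n_samples, 7, noise), n_genes, n_samples,
                 dimnames = list(genes, names(subt)))
  vals[genes %in% markers, subt == "basal"] <-
    vals[genes %in% markers, subt == "basal"] + effect
  expr_dataset(id, vals, subt)
}
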