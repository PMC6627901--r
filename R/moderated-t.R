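# Empirical-Bayes variance moderation.
#
# Feature-wise sample variances s2_g on d residual df are modelled as
# s2_g | sigma2_g ~ sigma2_g * chisq(d)/d with a scaled inverse chi-squared
# prior (d0, s02). The prior is estimated by moment matching on log sample
# variances: E[log s2] and Var[log s2] have closed forms in digamma/trigamma,
# so d0 solves trigamma(d0/2) = var(log s2) - trigamma(d/2).

trigamma_inverse <- function(x) {
  if (x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (abs(dif) < 1e-10 * y) break
  }
  y
}

fit_variance_prior <- function(s2, df) {
  s2 <- s2[s2 > 0]
  if (length(s2) < 2) return(list(d0 = 0, s02 = mean(s2)))
  z <- log(s2)
  e_z <- mean(z)
  v_z <- stats::var(z)
  resid_var <- v_z - trigamma(df / 2)
  if (resid_var > 1e-10) {
    d0 <- 2 * trigamma_inverse(resid_var)
    s02 <- exp(e_z - digamma(df / 2) + log(df / 2) +
                 digamma(d0 / 2) - log(d0 / 2))
  } else {
    # observed spread no larger than chi-squared sampling noise: variances
    # look exchangeable, shrink fully to the common value
    d0 <- Inf
    s02 <- exp(e_z - digamma(df / 2) + log(df / 2))
  }
  list(d0 = d0, s02 = s02)
}

#' Moderated two-sample t-test across features
#'
#' Feature-wise (e.g. gene-wise) two-sample t-tests with empirical-Bayes
#' variance shrinkage: each feature's pooled variance `s2` on `d` residual
#' degrees of freedom is replaced by
#' `s2_tilde = (d0 * s02 + d * s2) / (d0 + d)`, where the prior `(d0, s02)`
#' is estimated by moment matching on the log sample variances. The statistic
#' is referred to a t distribution on `d0 + d` degrees of freedom. With fewer
#' than `min_features` features the prior cannot be estimated stably and the
#' function falls back to ordinary t-tests (`d0 = 0`), with a message.
#'
#' @param a,b Numeric matrices, features x samples, with matching rownames;
#'   columns are the two groups' samples.
#' @param d0 Optional prior degrees of freedom override; `0` forces ordinary
#'   t-tests, `Inf` full shrinkage to the common variance.
#' @param min_features Minimum number of features for moderation.
#' @param p_threshold Flagging threshold.
#' @return A tibble with one row per feature: `feature`, `mean_diff`
#'   (group a minus group b), `statistic`, `df`, `p_value`,
#'   `effect_direction`, `flagged`; prior estimates are attached as
#'   attributes `d0` and `s02`.
#' @export
moderated_t <- function(a, b, d0 = NULL, min_features = 10,
                        p_threshold = 0.1) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  if (nrow(a) != nrow(b)) abort("`a` and `b` must have the same features")
  if (!is.null(rownames(a)) && !is.null(rownames(b)) &&
      !identical(rownames(a), rownames(b))) {
    abort("feature names of `a` and `b` differ")
  }
  na <- ncol(a)
  nb <- ncol(b)
  d <- na + nb - 2
  if (d <= 0) abort("zero residual degrees of freedom")
  n_feat <- nrow(a)
  va <- apply(a, 1, stats::var)
  vb <- apply(b, 1, stats::var)
  if (na == 1) va <- 0
  if (nb == 1) vb <- 0
  s2 <- ((na - 1) * va + (nb - 1) * vb) / d
  if (is.null(d0)) {
    if (n_feat < min_features) {
      inform(paste0("only ", n_feat, " feature(s): falling back to ordinary t"))
      d0 <- 0
      s02 <- NA_real_
    } else {
      prior <- fit_variance_prior(s2, d)
      d0 <- prior$d0
      s02 <- prior$s02
    }
  } else {
    s02 <- if (d0 > 0) fit_variance_prior(s2, d)$s02 else NA_real_
  }
  s2_tilde <- if (is.infinite(d0)) rep(s02, n_feat) else {
    if (d0 > 0) (d0 * s02 + d * s2) / (d0 + d) else s2
  }
  diff <- rowMeans(a) - rowMeans(b)
  se <- sqrt(s2_tilde * (1 / na + 1 / nb))
  stat <- diff / se
  df_total <- min(d0 + d, 1e6)
  p <- 2 * stats::pt(-abs(stat), df = df_total)
  out <- tibble(
    feature = rownames(a) %||% sprintf("feature%d", seq_len(n_feat)),
    mean_diff = unname(diff),
    statistic = unname(stat),
    df = df_total,
    p_value = unname(p),
    effect_direction = sign(unname(diff)),
    flagged = unname(p) < p_threshold
  )
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  out
}
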