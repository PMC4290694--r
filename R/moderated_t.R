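# Empirical-Bayes moderated two-sample t statistic.
#
# Per feature g the ordinary pooled-variance statistic is shrunk by replacing
# s_g^2 with s~_g^2 = (d0*s0^2 + dg*s_g^2) / (d0 + dg), where (d0, s0^2) are
# hyperparameters of a scaled inverse-chi-square prior on the residual
# variances, estimated by moment matching on log s_g^2 (digamma/trigamma
# inversion). The moderated t gains d0 degrees of freedom: p-values come from
# a t distribution on d0 + dg df.

# Invert the trigamma function by Newton iteration (monotone decreasing on
# (0, Inf); converges to machine precision from the standard starting value).
trigamma_inverse <- function(y) {
  stopifnot(length(y) == 1L, is.finite(y), y > 0)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (iter in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (-dif / x < 1e-14) break
  }
  x
}

#' Estimate the empirical-Bayes variance prior
#'
#' Fits a scaled inverse-chi-square prior (`d0` degrees of freedom, scale
#' `s0_sq`) to a set of observed residual variances on `dg` degrees of
#' freedom each, by matching the mean and variance of `log(s^2)` to their
#' theoretical values under the hierarchical model. When the observed
#' log-variances are no more dispersed than sampling alone explains, the
#' prior degrees of freedom are infinite and every variance shrinks to the
#' common value `s0_sq`.
#'
#' @param s2 Numeric vector of per-feature variances (non-negative).
#' @param dg Residual degrees of freedom, a single value or one per feature.
#' @return List with elements `d0` (may be `Inf`) and `s0_sq`.
#' @export
estimate_eb_prior <- function(s2, dg) {
  dg <- rep_len(dg, length(s2))
  ok <- is.finite(s2) & s2 > 0 & dg > 0
  if (sum(ok) < 2L) {
    warning("fewer than 2 positive variances; shrinkage disabled (d0 = 0)",
            call. = FALSE)
    return(list(d0 = 0, s0_sq = if (any(ok)) mean(s2[ok]) else 1))
  }
  s2 <- s2[ok]; dg <- dg[ok]
  G <- length(s2)
  e <- log(s2) - digamma(dg / 2) + log(dg / 2)
  emean <- mean(e)
  evar <- mean((e - emean)^2 * G / (G - 1) - trigamma(dg / 2))
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Rank features by the moderated t statistic
#'
#' Computes, for every row of `expr`, the two-sample statistic
#' `(mean_PP - mean_GP) / (s~ * sqrt(1/n1 + 1/n2))` with the empirical-Bayes
#' moderated standard deviation `s~` (see [estimate_eb_prior()]), and ranks
#' rows by two-sided p-value ascending (ties broken by identifier
#' ascending). Setting `d0 = 0` turns shrinkage off and reproduces the
#' ordinary pooled-variance t test exactly.
#'
#' @param expr Numeric matrix (features x samples) with dimnames.
#' @param labels GP/PP labels, one per column of `expr`.
#' @param d0,s0_sq Optional prior overrides; when `NULL` (default) both are
#'   estimated from the data.
#' @return A `ranked_features` object (`method = "mod_t"`, p-value ordered).
#'   Its `table` element holds `feature_id`, `mean_diff`, `statistic`,
#'   `p_value`, `df`; the fitted prior is stored in `$prior`.
#' @export
moderated_t <- function(expr, labels, d0 = NULL, s0_sq = NULL) {
  labels <- as_prognosis(labels)
  if (ncol(expr) != length(labels)) abort("labels must match expression columns")
  n1 <- sum(labels == "GP"); n2 <- sum(labels == "PP")
  if (n1 < 2L || n2 < 2L) abort("need at least 2 samples per class")
  gp <- expr[, labels == "GP", drop = FALSE]
  pp <- expr[, labels == "PP", drop = FALSE]
  m1 <- rowMeans(gp); m2 <- rowMeans(pp)
  ss1 <- rowSums((gp - m1)^2); ss2 <- rowSums((pp - m2)^2)
  dgf <- n1 + n2 - 2L
  s2 <- (ss1 + ss2) / dgf
  if (is.null(d0)) {
    prior <- estimate_eb_prior(s2, dgf)
  } else {
    stopifnot(d0 >= 0)
    if (d0 > 0 && is.null(s0_sq)) abort("s0_sq required when d0 > 0 is forced")
    prior <- list(d0 = d0, s0_sq = s0_sq %||% 0)
  }
  if (is.finite(prior$d0)) {
    s2_mod <- (prior$d0 * prior$s0_sq + dgf * s2) / (prior$d0 + dgf)
  } else {
    s2_mod <- rep_len(prior$s0_sq, length(s2))
  }
  diff <- m2 - m1
  se <- sqrt(s2_mod * (1 / n1 + 1 / n2))
  tt <- diff / se
  df_total <- prior$d0 + dgf
  pv <- 2 * stats::pt(-abs(tt), df = df_total)
  if (any(!is.finite(tt))) {
    bad <- rownames(expr)[!is.finite(tt)]
    warning("zero moderated variance; ranked last: ",
            paste(bad, collapse = ", "), call. = FALSE)
    pv[!is.finite(tt)] <- NA_real_
    tt[!is.finite(tt)] <- NA_real_
  }
  ids <- rownames(expr)
  ord <- order(is.na(pv), pv, ids, method = "radix")
  tab <- data.frame(feature_id = ids[ord], mean_diff = diff[ord],
                    statistic = tt[ord], p_value = pv[ord],
                    df = rep(df_total, length(ids)),
                    stringsAsFactors = FALSE)
  out <- new_ranked_features("mod_t", ids[ord], pv[ord], "p_value", table = tab)
  out$prior <- prior
  out
}
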