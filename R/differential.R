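## Empirical-Bayes moderated two-group testing of log2 quantity matrices,
## with locally weighted normalization, Benjamini-Hochberg adjustment, the
## regulation rule (|log2 ratio| > 0.1 and p < 0.01) and joint
## stability/abundance classification.

#' Normalize a log2 intensity matrix across samples
#'
#' Two-step global normalization of a complete log2 quantity matrix:
#' each sample column is first median-centred to the global median, then a
#' locally weighted regression (span 0.4, 2 robustness iterations) of each
#' sample's deviation from the row mean against the row mean intensity is
#' subtracted, removing intensity-dependent bow. Columns are re-centred so
#' all column medians agree after normalization.
#'
#' @param matrix Numeric matrix of log2 quantities, proteins x samples,
#'   complete (no missing values).
#' @param span Smoother span passed to the locally weighted regression.
#' @return Normalized matrix of the same dimensions and dimnames.
#' @export
normalize_log_intensities <- function(matrix, span = 0.4) {
  m <- as.matrix(matrix)
  if (!is.numeric(m)) stop("'matrix' must be numeric", call. = FALSE)
  if (anyNA(m) || any(!is.finite(m)))
    stop(paste("matrix contains missing or non-finite values;",
               "filter to complete rows before normalizing"), call. = FALSE)
  if (ncol(m) < 2L) return(m)

  grand <- stats::median(m)
  for (j in seq_len(ncol(m))) m[, j] <- m[, j] - stats::median(m[, j]) + grand

  ## the correction of one column leaks into the row means, so cycle the
  ## column loop a few times until the trend is gone
  for (pass in 1:3) {
    rm_ <- rowMeans(m)
    for (j in seq_len(ncol(m))) {
      dev <- m[, j] - rm_
      if (stats::sd(dev) > 0) {
        sm <- stats::lowess(rm_, dev, f = span, iter = 2L)
        m[, j] <- m[, j] - stats::approx(sm$x, sm$y, xout = rm_, rule = 2L)$y
      }
      rm_ <- rowMeans(m)
    }
  }
  for (j in seq_len(ncol(m))) m[, j] <- m[, j] - stats::median(m[, j]) + grand
  m
}

## Newton inversion of the trigamma function (solve trigamma(x) = y);
## the iteration is on 1/trigamma, which is nearly linear
.trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (iter in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-8) break
  }
  x
}

## moment-matching estimate of the scaled-F prior (d0, s0^2) from log
## sample variances with common residual df
.estimate_variance_prior <- function(s2, df) {
  s2 <- pmax(s2, 1e-12)               # variance floor before taking logs
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) * (length(e) - 1) / length(e) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0) {
    d0 <- Inf
    s0_2 <- exp(emean)
  } else {
    d0 <- 2 * .trigamma_inverse(evar)
    s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  }
  list(prior_df = d0, prior_var = s0_2)
}

#' Moderated two-group t-test with variance shrinkage
#'
#' Per-protein two-group comparison on a log2 quantity matrix with
#' empirical-Bayes variance moderation. The per-protein pooled variance
#' \eqn{s_g^2} on \eqn{d_g = n_a + n_b - 2} degrees of freedom is shrunk
#' toward a prior \eqn{(d_0, s_0^2)} estimated by matching the moments of
#' \eqn{\log s_g^2} to a log scaled-F distribution (digamma/trigamma
#' moments; \eqn{d_0} by Newton inversion of the trigamma function). The
#' posterior variance is
#' \eqn{\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g)} and the
#' moderated t statistic is referred to a Student t distribution on
#' \eqn{d_0 + d_g} degrees of freedom (normal when \eqn{d_0 = \infty}).
#'
#' @param matrix Log2 quantity matrix with sample columns, complete rows.
#' @param group_a,group_b Column names (or indices) of the two groups;
#'   each group needs >= 2 samples. `log2fc` is mean(a) - mean(b), so pass
#'   the treated arm as `group_a`.
#' @param prior_df Optional override of the estimated prior degrees of
#'   freedom: `0` gives the ordinary pooled two-sample t-test, `Inf` a
#'   common-variance statistic.
#' @return Data frame with columns `protein_id`, `log2fc`, `t`, `p`,
#'   `df_total`; the shrinkage estimate is attached as attribute
#'   `"shrinkage"` (list with `prior_df`, `prior_var`).
#' @export
moderated_t_test <- function(matrix, group_a, group_b, prior_df = NULL) {
  m <- as.matrix(matrix)
  if (anyNA(m)) stop("matrix must be complete (no NA rows)", call. = FALSE)
  a <- m[, group_a, drop = FALSE]
  b <- m[, group_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  if (na < 2L || nb < 2L)
    stop("each group needs >= 2 samples", call. = FALSE)
  dg <- na + nb - 2

  mean_a <- rowMeans(a)
  mean_b <- rowMeans(b)
  ss_a <- rowSums((a - mean_a)^2)
  ss_b <- rowSums((b - mean_b)^2)
  s2 <- (ss_a + ss_b) / dg

  if (all(s2 <= 1e-12))
    warning("zero within-group variance for every protein; variance floor applied",
            call. = FALSE)

  if (is.null(prior_df)) {
    prior <- .estimate_variance_prior(s2, dg)
  } else {
    s2f <- pmax(s2, 1e-12)
    prior <- list(prior_df = prior_df,
                  prior_var = if (is.finite(prior_df) && prior_df == 0)
                    NA_real_ else mean(s2f))
  }
  d0 <- prior$prior_df
  s2 <- pmax(s2, 1e-12)

  s2_post <- if (is.infinite(d0)) {
    rep(prior$prior_var, length(s2))
  } else if (d0 == 0) {
    s2
  } else {
    (d0 * prior$prior_var + dg * s2) / (d0 + dg)
  }
  se <- sqrt(s2_post * (1 / na + 1 / nb))
  tstat <- (mean_a - mean_b) / se
  df_total <- d0 + dg
  p <- if (is.infinite(df_total)) 2 * stats::pnorm(-abs(tstat))
       else 2 * stats::pt(-abs(tstat), df_total)

  ids <- rownames(m)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(m)))
  out <- data.frame(protein_id = ids, log2fc = mean_a - mean_b,
                    t = tstat, p = p, df_total = df_total,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "shrinkage") <- prior
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validating wrapper around the standard step-up false-discovery-rate
#' adjustment; values are returned in input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values in input order.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Call regulation from effect size and p-value
#'
#' The standard PISA regulation rule: `up` when `log2fc > fc_threshold` and
#' `p < p_threshold`; `down` when `log2fc < -fc_threshold` and
#' `p < p_threshold`; otherwise `none`. Defaults are the conventional
#' thresholds (log2 ratio 0.1, p 0.01).
#'
#' @param log2fc,p Numeric vectors (recycled to common length).
#' @param fc_threshold,p_threshold Positive thresholds.
#' @return Character vector in `{"up", "down", "none"}`.
#' @export
call_regulated <- function(log2fc, p, fc_threshold = 0.1, p_threshold = 0.01) {
  if (fc_threshold <= 0 || p_threshold <= 0)
    stop("thresholds must be positive", call. = FALSE)
  out <- rep("none", length(log2fc))
  out[log2fc > fc_threshold & p < p_threshold] <- "up"
  out[log2fc < -fc_threshold & p < p_threshold] <- "down"
  out
}

#' Joint stability/abundance classification
#'
#' Separates genuine thermal-stability changes from expression changes by
#' combining the regulation calls of the stability and abundance channels:
#' `stability_only` when only the stability channel is regulated;
#' `abundance_only` for the converse; `concordant_both` when both are
#' regulated with the same sign and the two effect sizes agree within
#' `concordance_margin` (interpreted as abundance-driven, as when proteins
#' apparently destabilized turn out to have simply decreased in abundance);
#' `discordant` when both are regulated with opposite signs or differ by
#' more than the margin; otherwise `none`.
#'
#' @param reg_stability,reg_abundance Regulation calls (`up`/`down`/`none`)
#'   for the two channels, same proteins, same order.
#' @param log2fc_stability,log2fc_abundance Matching effect sizes.
#' @param concordance_margin Maximum |difference| of the two log2 effects
#'   still considered the same change (default 0.1).
#' @return Character vector in `{"stability_only", "abundance_only",
#'   "concordant_both", "discordant", "none"}`.
#' @export
joint_stability_abundance_classify <- function(reg_stability, reg_abundance,
                                               log2fc_stability,
                                               log2fc_abundance,
                                               concordance_margin = 0.1) {
  n <- length(reg_stability)
  if (length(reg_abundance) != n || length(log2fc_stability) != n ||
      length(log2fc_abundance) != n)
    stop("both channels must cover the same proteins", call. = FALSE)
  s_reg <- reg_stability != "none"
  a_reg <- reg_abundance != "none"
  out <- rep("none", n)
  out[s_reg & !a_reg] <- "stability_only"
  out[!s_reg & a_reg] <- "abundance_only"
  both <- s_reg & a_reg
  same_sign <- reg_stability == reg_abundance
  close <- abs(log2fc_stability - log2fc_abundance) <= concordance_margin
  out[both & same_sign & close] <- "concordant_both"
  out[both & (!same_sign | !close)] <- "discordant"
  out
}

#' Per-channel differential analysis of a simulated or measured experiment
#'
#' Convenience wrapper running normalization, the moderated test, BH
#' adjustment and the regulation call on one channel matrix whose columns
#' follow the `<condition>_<channel>_rep<k>` convention.
#'
#' @param matrix Log2 quantity matrix.
#' @param treated,control Condition labels identifying the two arms in the
#'   column names.
#' @param normalize Run [normalize_log_intensities()] first (default TRUE).
#' @param fc_threshold,p_threshold Regulation thresholds.
#' @param prior_df Optional prior-df override (see [moderated_t_test()]).
#' @return Data frame with `protein_id`, `log2fc`, `t`, `p`, `fdr`,
#'   `regulated`.
#' @export
diff_channel <- function(matrix, treated = "treated", control = "control",
                         normalize = TRUE, fc_threshold = 0.1,
                         p_threshold = 0.01, prior_df = NULL) {
  cols <- colnames(matrix)
  if (is.null(cols)) stop("matrix must have sample column names", call. = FALSE)
  ga <- grep(paste0("^", treated, "_"), cols, value = TRUE)
  gb <- grep(paste0("^", control, "_"), cols, value = TRUE)
  if (length(ga) == 0L || length(gb) == 0L)
    stop("condition labels not found in column names", call. = FALSE)
  m <- if (normalize) normalize_log_intensities(matrix) else as.matrix(matrix)
  res <- moderated_t_test(m, ga, gb, prior_df = prior_df)
  res$fdr <- bh_adjust(res$p)
  res$regulated <- call_regulated(res$log2fc, res$p, fc_threshold, p_threshold)
  res
}
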