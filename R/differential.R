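# Simplified negative-binomial differential testing for genes, ATAC peaks
# and eRNAs. Deliberately lighter than a full shrinkage-based package:
# median-of-ratios normalisation, per-feature method-of-moments dispersion
# shrunk 50/50 toward a mean-dispersion trend, an NB log-linear fit with
# condition and donor terms, and a Wald test on the condition coefficient.
# Validation is by parameter recovery on simulated truth, not by matching
# any particular published implementation.

#' Filter genes by minimum expression
#'
#' Keeps a gene when at least `min_fraction` of samples have at least
#' `min_count` reads (both thresholds non-strict).
#'
#' @param cm RNA `SummarizedExperiment`.
#' @param min_count minimum read count per sample (default 5).
#' @param min_fraction minimum fraction of samples reaching it (default
#'   0.10).
#' @return The filtered `SummarizedExperiment`.
#' @export
filter_expressed_genes <- function(cm, min_count = 5, min_fraction = 0.10) {
  m <- assay(cm, "counts")
  if (nrow(m) == 0) stop("empty count matrix")
  keep <- rowSums(m >= min_count) >= min_fraction * ncol(m)
  ern_log("expression filter: ", sum(keep), " of ", nrow(m), " features retained")
  cm[keep, ]
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over features of the
#' ratio of that sample's count to the feature's geometric mean across
#' samples; only features with strictly positive counts in every sample
#' contribute.
#'
#' @param cm `SummarizedExperiment` or counts matrix.
#' @return Named numeric vector of positive per-sample factors.
#' @export
size_factors <- function(cm) {
  m <- if (is.matrix(cm)) cm else assay(cm, "counts")
  logm <- log(m)
  loggeo <- rowMeans(logm)
  use <- is.finite(loggeo)
  if (!any(use)) {
    stop("no feature has positive counts in every sample; ",
         "consider a pseudo-reference fallback")
  }
  sf <- apply(logm[use, , drop = FALSE], 2, function(lc) exp(median(lc - loggeo[use])))
  if (any(!is.finite(sf) | sf <= 0)) stop("non-positive size factor")
  sf
}

# Per-feature dispersion (variance = mu + alpha * mu^2) by method of
# moments on normalised counts within each condition arm, then shrunk 50/50
# toward a 1/mu trend fitted across features.
estimate_dispersions <- function(norm, group) {
  groups <- split(seq_len(ncol(norm)), group)
  per_group <- vapply(groups, function(idx) {
    mu <- rowMeans(norm[, idx, drop = FALSE])
    v <- apply(norm[, idx, drop = FALSE], 1, var)
    a <- (v - mu) / mu^2
    a[!is.finite(a)] <- NA
    a
  }, numeric(nrow(norm)))
  alpha_mom <- rowMeans(per_group, na.rm = TRUE)
  alpha_mom[!is.finite(alpha_mom)] <- NA
  alpha_mom <- pmax(alpha_mom, 1e-8)
  base_mean <- rowMeans(norm)
  fit_ok <- !is.na(alpha_mom) & base_mean > 0
  if (sum(fit_ok) >= 10) {
    tr <- lm(alpha_mom[fit_ok] ~ I(1 / base_mean[fit_ok]))
    trend <- pmax(coef(tr)[1] + coef(tr)[2] / base_mean, 1e-8)
  } else {
    trend <- rep(max(mean(alpha_mom, na.rm = TRUE), 1e-8), length(alpha_mom))
  }
  alpha <- 0.5 * alpha_mom + 0.5 * trend
  alpha[is.na(alpha)] <- trend[is.na(alpha)]
  pmax(alpha, 1e-8)
}

#' Negative-binomial Wald test for a pairwise contrast
#'
#' Fits, per feature, an NB log-linear model with a condition term and
#' (optionally) fixed donor effects on the samples of the two contrast
#' arms, using the library-size offset from median-of-ratios factors, and
#' tests the condition coefficient with a two-sided normal Wald test.
#' `log2fc > 0` means higher in `condition_a`.
#'
#' @param cm `SummarizedExperiment` with donor/condition in its colData.
#' @param condition_a,condition_b the contrast (a vs b).
#' @param adjust_donor include per-donor fixed effects (default TRUE).
#' @param sf optional precomputed size factors for all samples of `cm`.
#' @return data.frame: `feature_id`, `base_mean`, `log2fc`, `p`, `q`,
#'   `is_differential` (all FALSE until [call_differential()]).
#' @export
nb_wald <- function(cm, condition_a, condition_b, adjust_donor = TRUE, sf = NULL) {
  if (condition_a == condition_b) stop("contrast arms must differ")
  cd <- as.data.frame(colData(cm))
  if (!all(c(condition_a, condition_b) %in% cd$condition)) {
    stop("contrast condition absent from sample sheet")
  }
  if (is.null(sf)) sf <- size_factors(cm)
  sel <- cd$condition %in% c(condition_a, condition_b)
  if (sum(cd$condition == condition_a) < 2 || sum(cd$condition == condition_b) < 2) {
    stop("need >= 2 samples per contrast arm")
  }
  m <- assay(cm, "counts")[, sel, drop = FALSE]
  sf <- sf[sel]
  cd <- cd[sel, , drop = FALSE]
  cond <- factor(cd$condition, levels = c(condition_b, condition_a))
  if (adjust_donor && length(unique(cd$donor)) > 1) {
    X <- model.matrix(~ cond + donor, data.frame(cond = cond, donor = factor(cd$donor)))
  } else {
    X <- model.matrix(~ cond, data.frame(cond = cond))
  }
  coef_idx <- 2L  # the condition_a coefficient
  offs <- log(sf)
  norm <- sweep(m, 2, sf, "/")
  alpha <- estimate_dispersions(norm, cond)
  n <- nrow(m)
  logfc <- p <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    y <- m[i, ]
    if (all(y == 0)) next
    fit <- tryCatch(
      suppressWarnings(glm.fit(X, y, family = negative.binomial(1 / alpha[i]),
                               offset = offs)),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$converged) next
    beta <- fit$coefficients[coef_idx]
    if (is.na(beta)) next
    covp <- tryCatch(chol2inv(qr.R(fit$qr)), error = function(e) NULL)
    if (is.null(covp)) next
    piv <- fit$qr$pivot
    cov <- matrix(NA_real_, ncol(X), ncol(X))
    cov[piv, piv] <- covp
    se <- sqrt(cov[coef_idx, coef_idx])
    if (!is.finite(se) || se <= 0) next
    logfc[i] <- beta
    p[i] <- 2 * pnorm(-abs(beta / se))
  }
  data.frame(
    feature_id = rownames(m),
    base_mean = rowMeans(norm),
    log2fc = logfc / log(2),
    p = p,
    q = bh_fdr(p),
    is_differential = FALSE,
    stringsAsFactors = FALSE
  )
}

#' Flag differential features
#'
#' Applies the strict thresholds of the workflow: a feature is differential
#' when `|log2fc| > log2(fc_threshold)` AND `q < fdr` (both strict).
#'
#' @param results data.frame from [nb_wald()].
#' @param fc_threshold fold-change threshold (1.5 for ATAC, 2 for genes and
#'   eRNAs).
#' @param fdr BH FDR threshold (0.05).
#' @return `results` with `is_differential` set (`NA` p gives FALSE).
#' @export
call_differential <- function(results, fc_threshold, fdr = 0.05) {
  flag <- abs(results$log2fc) > log2(fc_threshold) & results$q < fdr
  results$is_differential <- !is.na(flag) & flag
  ern_log("differential: ", sum(results$is_differential), " of ",
          sum(!is.na(results$p)), " tested features (FC>", fc_threshold,
          ", FDR<", fdr, ")")
  results
}
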