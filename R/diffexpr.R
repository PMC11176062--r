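# Precision-weighted linear modelling with empirical-Bayes moderation.

#' Estimate observation-level precision weights
#'
#' Log-CPM values are modelled per gene by ordinary least squares; the
#' square-root residual standard deviations are smoothed against average
#' log2 count by locally weighted regression, and each observation's weight
#' is the predicted standard deviation at its fitted log-count raised to the
#' power -4. Computed by `limma::voom` (the trend is clamped to its
#' endpoints outside the fitted range).
#'
#' @param counts Count matrix or `DGEList` (after filtering).
#' @param design Design matrix from [build_design()].
#' @param norm_factors Optional TMM factors multiplying library sizes.
#' @param span Smoother span (default 0.5).
#' @param lib_size Optional library sizes.
#' @return An `EList` with components `E` (log-CPM), `weights`, `design`.
#' @export
estimate_precision_weights <- function(counts, design, norm_factors = NULL,
                                       span = 0.5, lib_size = NULL) {
  if (methods::is(counts, "DGEList")) {
    if (is.null(lib_size)) lib_size <- counts$samples$lib.size
    if (is.null(norm_factors) &&
        any(counts$samples$norm.factors != 1))
      norm_factors <- counts$samples$norm.factors
    counts <- counts$counts
  }
  if (is.null(lib_size)) lib_size <- colSums(counts)
  if (nrow(design) != ncol(counts))
    stop("design rows must match count columns")
  if (ncol(counts) - qr(design)$rank < 2)
    stop("fewer than 2 residual degrees of freedom")
  eff <- if (is.null(norm_factors)) lib_size else lib_size * norm_factors
  limma::voom(counts, design, lib.size = eff, span = span)
}

#' Weighted least-squares fits per gene
#'
#' @param voom An `EList` from [estimate_precision_weights()].
#' @param design Optional design override (defaults to `voom$design`).
#' @return An `MArrayLM` fit from `limma::lmFit` (coefficients, unscaled
#'   standard deviations, residual variances `sigma^2`, residual df).
#' @export
fit_weighted <- function(voom, design = NULL) {
  if (is.null(design)) design <- voom$design
  limma::lmFit(voom, design)
}

#' Extract per-gene statistics for one coefficient
#'
#' @param fit `MArrayLM` from [fit_weighted()].
#' @param coef Coefficient name or index.
#' @return `data.frame`: gene_id, beta, stdev_unscaled, sigma2, df_residual,
#'   mean_logcpm.
#' @export
gene_fit <- function(fit, coef) {
  data.frame(gene_id = rownames(fit$coefficients),
             beta = fit$coefficients[, coef],
             stdev_unscaled = fit$stdev.unscaled[, coef],
             sigma2 = fit$sigma^2,
             df_residual = fit$df.residual,
             mean_logcpm = fit$Amean,
             stringsAsFactors = FALSE)
}

#' Empirical-Bayes variance moderation
#'
#' Gene-wise residual variances are shrunk toward a global prior estimated
#' by moment matching of the log variances to a scaled-F distribution
#' (`limma::fitFDist`): the posterior variance is
#' `(d0 * s0^2 + d_g * s_g^2) / (d0 + d_g)` and the moderated t-statistic is
#' referred to a t distribution on `d0 + d_g` degrees of freedom.
#'
#' @param fit `MArrayLM` from [fit_weighted()] (>= 10 genes for stable
#'   moment estimation unless `prior_df` is given).
#' @param coef Coefficient to test.
#' @param prior_df Optional fixed prior df: `0` reproduces the ordinary t
#'   test, `Inf` pools all genes to the common prior variance.
#' @return `data.frame` (class `"moderated_result"`): gene_id, log2fc,
#'   percent_change, t, p, q (BH), mean_logcpm, s2_post, df_total; prior
#'   `d0` and `s02` as attributes.
#' @export
ebayes_moderate <- function(fit, coef, prior_df = NULL) {
  gf <- gene_fit(fit, coef)
  ok <- gf$df_residual > 0 & is.finite(gf$sigma2)
  if (is.null(prior_df)) {
    if (sum(ok) < 10)
      stop("moment estimation of the variance prior needs >= 10 genes")
    fd <- limma::fitFDist(gf$sigma2[ok], df1 = gf$df_residual[ok])
    d0 <- fd$df2
    s02 <- fd$scale
  } else {
    d0 <- prior_df
    s02 <- if (is.finite(prior_df) && prior_df > 0)
      limma::fitFDist(gf$sigma2[ok], df1 = gf$df_residual[ok])$scale
    else mean(gf$sigma2[ok])
  }
  res <- moderate_from_stats(gf, d0, s02)
  attr(res, "d0") <- d0
  attr(res, "s02") <- s02
  class(res) <- c("moderated_result", class(res))
  res
}

# shared arithmetic: posterior variances, moderated t, p, q
moderate_from_stats <- function(gf, d0, s02) {
  s2_post <- if (is.infinite(d0)) rep(s02, nrow(gf)) else
    (d0 * s02 + gf$df_residual * gf$sigma2) / (d0 + gf$df_residual)
  df_total <- gf$df_residual + d0
  tt <- gf$beta / (sqrt(s2_post) * gf$stdev_unscaled)
  p <- 2 * pt(-abs(tt), df = df_total)
  data.frame(gene_id = gf$gene_id, log2fc = gf$beta,
             percent_change = percent_change(gf$beta),
             t = tt, p = p, q = bh_adjust(p),
             mean_logcpm = gf$mean_logcpm,
             s2_post = s2_post, df_total = df_total,
             stringsAsFactors = FALSE, row.names = gf$gene_id)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment:
#' `q_(i) = min_{j >= i} m * p_(j) / j`.
#'
#' @param p Numeric vector of p-values in \[0, 1\]; `NaN` is rejected.
#' @return q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(is.nan(p))) stop("NaN p-values")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  p.adjust(p, method = "BH")
}

#' Percent expression change per exposure unit
#'
#' `(2^log2fc - 1) * 100`.
#'
#' @param log2fc Log2 fold-change(s) per one-unit exposure increase.
#' @return Percent change(s).
#' @export
percent_change <- function(log2fc) (2^log2fc - 1) * 100

#' Complete-data differential expression
#'
#' The full pipeline on a fully observed design: subset to the spec's
#' stratum and complete rows, filter by biotype and average log-CPM on the
#' analysis samples, TMM-normalise, estimate precision weights, fit weighted
#' linear models, moderate, and BH-adjust.
#'
#' @param dge `DGEList` with biotype annotation.
#' @param cohort Cohort table (rows with missing exposure or covariates are
#'   dropped — the complete-case rule).
#' @param spec A [design_spec()].
#' @param span Trend smoother span.
#' @param prefiltered Set `TRUE` when `dge` is already biotype/expression
#'   filtered and normalised.
#' @return A `"moderated_result"` table (see [ebayes_moderate()]) with
#'   attributes `n_used`, `n_genes`, `n_sig_05`, `n_sig_10`, `analysis`.
#' @export
run_de <- function(dge, cohort, spec, span = 0.5, prefiltered = FALSE) {
  ids <- complete_rows(cohort, spec)
  cohort <- cohort[ids, , drop = FALSE]
  dge <- dge[, ids]
  if (!prefiltered) {
    pp <- preprocess_counts(dge)
    dge <- pp$dge
  } else if (all(dge$samples$norm.factors == 1)) {
    dge$samples$norm.factors <-
      as.numeric(tmm_factors(dge$counts, lib_size = dge$samples$lib.size))
  }
  design <- build_design(cohort, spec)
  v <- estimate_precision_weights(dge, design, span = span)
  fit <- fit_weighted(v)
  res <- ebayes_moderate(fit, attr(design, "exposure_coef"))
  attr(res, "n_used") <- nrow(design)
  attr(res, "n_genes") <- nrow(res)
  attr(res, "n_sig_05") <- sum(res$q < 0.05)
  attr(res, "n_sig_10") <- sum(res$q < 0.10)
  attr(res, "analysis") <- paste0(spec$exposure,
    if (!spec$mediators) "_no_mediators",
    if (spec$gestational_age) "_plus_ga",
    if (spec$stratum != "all") paste0("_", spec$stratum))
  res
}

#' Write a result table as TSV
#'
#' @param res Result `data.frame` (moderated or pooled).
#' @param path Output file.
#' @param config_hash Optional hash recorded in a header comment.
#' @export
write_result_tsv <- function(res, path, config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config_hash))
    writeLines(paste0("# config_hash: ", config_hash), con)
  for (a in c("analysis", "n_used", "n_genes", "n_sig_05", "n_sig_10")) {
    if (!is.null(attr(res, a)))
      writeLines(paste0("# ", a, ": ", attr(res, a)), con)
  }
  write.table(res, con, sep = "\t", quote = FALSE, row.names = FALSE)
}
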