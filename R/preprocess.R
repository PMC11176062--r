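# Gene filtering, smoothed log-CPM, and TMM normalisation factors.

#' Filter genes by biotype
#'
#' Keeps genes whose annotated biotype is in `allowed`. Genes without an
#' annotation entry are dropped (their number is reported via `message()`).
#'
#' @param dge An [edgeR::DGEList]; gene annotation is taken from
#'   `dge$genes$biotype` unless `annotation` is supplied.
#' @param annotation Optional `data.frame` with columns `gene_id`,
#'   `biotype`.
#' @param allowed Character vector of biotypes to retain. The default is the
#'   standard mRNA-seq set: protein-coding genes, processed pseudogenes and
#'   long non-coding RNAs.
#' @return The filtered `DGEList` (library sizes recomputed).
#' @export
filter_by_biotype <- function(dge, annotation = NULL,
                              allowed = c("protein_coding",
                                          "processed_pseudogene",
                                          "lncRNA")) {
  if (length(allowed) == 0) stop("`allowed` biotype set is empty")
  ids <- rownames(dge$counts)
  if (!is.null(annotation)) {
    bt <- annotation$biotype[match(ids, annotation$gene_id)]
  } else if (!is.null(dge$genes$biotype)) {
    bt <- dge$genes$biotype
  } else stop("no biotype annotation available")
  unannotated <- sum(is.na(bt))
  if (unannotated > 0)
    message(unannotated, " unannotated genes dropped")
  keep <- !is.na(bt) & bt %in% allowed
  if (!any(keep)) stop("no genes left after biotype filtering")
  dge[keep, , keep.lib.sizes = FALSE]
}

#' Smoothed log2 counts per million
#'
#' `log2((count + prior) / (lib_size * factor + 2 * prior) * 1e6)`, the
#' transform used inside the precision-weight estimation, so that filtering
#' and modelling see the same scale.
#'
#' @param counts Count matrix (genes x samples) or a `DGEList`.
#' @param norm_factors Optional per-sample normalisation factors multiplying
#'   the library sizes.
#' @param prior Pseudo-count added to each count (default 0.5; twice this is
#'   added to the library size).
#' @param lib_size Optional library sizes; default column sums (or the
#'   `DGEList` stored sizes).
#' @return Real matrix of the same shape as `counts`.
#' @export
log_cpm <- function(counts, norm_factors = NULL, prior = 0.5,
                    lib_size = NULL) {
  if (methods::is(counts, "DGEList")) {
    if (is.null(lib_size)) lib_size <- counts$samples$lib.size
    counts <- counts$counts
  }
  if (is.null(lib_size)) lib_size <- colSums(counts)
  if (prior <= 0) stop("`prior` must be positive")
  if (any(lib_size <= 0)) stop("zero or negative library size")
  eff <- if (is.null(norm_factors)) lib_size else lib_size * norm_factors
  t(log2(t(counts + prior) / (eff + 2 * prior) * 1e6))
}

#' Filter genes on average log-CPM
#'
#' Retains genes whose arithmetic mean log-CPM across the analysis samples is
#' at or above `threshold` (genes with mean exactly at the threshold are
#' kept; only strictly lower means are removed). Applied separately per
#' analytic sample set by the callers, since different exposures have
#' different samples with observed exposure.
#'
#' @param logcpm Matrix from [log_cpm()].
#' @param threshold Minimum average log-CPM (default 0).
#' @return Logical vector over genes (`TRUE` = retained).
#' @export
filter_low_expression <- function(logcpm, threshold = 0) {
  rowMeans(logcpm) >= threshold
}

#' Trimmed-mean-of-M-values normalisation factors
#'
#' Per-sample scale factors from doubly trimmed, inverse-variance-weighted
#' log-ratios against a reference sample (the sample whose 75th-percentile
#' CPM is closest to the mean of those percentiles). Factors are rescaled to
#' geometric mean one. Computed by `edgeR::calcNormFactors(method = "TMM")`;
#' an independent step-by-step implementation of the estimator backs the
#' unit tests.
#'
#' @param counts Count matrix or `DGEList`.
#' @param trim_M Two-sided trim fraction on log-ratios (default 0.3).
#' @param trim_A Two-sided trim fraction on average log-abundance
#'   (default 0.05).
#' @param lib_size Optional library sizes (default column sums).
#' @return Numeric vector of positive factors, geometric mean 1, with the
#'   reference sample index as attribute `ref`.
#' @export
tmm_factors <- function(counts, trim_M = 0.3, trim_A = 0.05,
                        lib_size = NULL) {
  if (methods::is(counts, "DGEList")) {
    if (is.null(lib_size)) lib_size <- counts$samples$lib.size
    counts <- counts$counts
  }
  if (is.null(lib_size)) lib_size <- colSums(counts)
  if (ncol(counts) < 2) {
    warning("fewer than 2 samples; all normalisation factors set to 1")
    return(structure(rep(1, ncol(counts)), ref = NA_integer_))
  }
  # reference selection ignores all-zero genes so that factors are
  # invariant to padding the matrix with unexpressed genes
  nz <- rowSums(counts) > 0
  f75 <- apply(counts[nz, , drop = FALSE], 2,
               function(x) quantile(x, 0.75)) / lib_size
  ref <- which.min(abs(f75 - mean(f75)))
  f <- edgeR::calcNormFactors(counts, lib.size = lib_size, method = "TMM",
                              refColumn = ref, logratioTrim = trim_M,
                              sumTrim = trim_A)
  structure(f, ref = ref)
}

#' One-step preprocessing
#'
#' Biotype filter, expression filter on smoothed log-CPM, then TMM factors on
#' the retained genes (filtering before normalisation).
#'
#' @inheritParams filter_by_biotype
#' @param threshold Average log-CPM cutoff, see [filter_low_expression()].
#' @return List: `dge` (filtered), `norm_factors`, `filter_report`
#'   (`data.frame`: gene_id, mean_logcpm, retained).
#' @export
preprocess_counts <- function(dge, annotation = NULL,
                              allowed = c("protein_coding",
                                          "processed_pseudogene",
                                          "lncRNA"),
                              threshold = 0) {
  dge <- filter_by_biotype(dge, annotation, allowed)
  lc <- log_cpm(dge)
  keep <- filter_low_expression(lc, threshold)
  report <- data.frame(gene_id = rownames(dge$counts),
                       mean_logcpm = rowMeans(lc), retained = keep,
                       stringsAsFactors = FALSE)
  dge <- dge[keep, , keep.lib.sizes = TRUE]
  nf <- tmm_factors(dge$counts, lib_size = dge$samples$lib.size)
  dge$samples$norm.factors <- as.numeric(nf)
  list(dge = dge, norm_factors = nf, filter_report = report)
}
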