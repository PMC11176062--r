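# ---- frozen generator calibration -------------------------------------------
# Exposure marginals and dependence were calibrated once, numerically, against
# the published cohort descriptives and then frozen:
#   * SLE sum ~ zero-inflated negative binomial truncated to 0..14 with
#     (pi, mu, size) solved so mean = 1.576, SD = 1.861 and P(0) = 0.379
#     (the zero mass implied by the published exposure quadrant),
#   * the three CTE items are correlated Bernoullis driven by one shared
#     standard-normal factor, item loading solved so P(CTE sum = 0) = 0.637,
#   * the SLE latent loads on the same factor with loading solved so the
#     SLE/CTE Spearman correlation is 0.226.
.sle_zero_infl <- 0.1491511
.sle_mu <- 1.854478
.sle_size <- 1.981771
.sle_max <- 14L
.cte_rates <- c(witnessed_violence = 0.263,
                physical_abuse = 0.080,
                sexual_abuse = 0.190)
.cte_item_loading <- 0.7351724
.sle_factor_loading <- 0.358

# CDF of the truncated zero-inflated negative binomial SLE marginal
.sle_cdf <- function() {
  x <- 0:.sle_max
  px <- dnbinom(x, mu = .sle_mu, size = .sle_size)
  px <- px / sum(px)
  px[1] <- .sle_zero_infl + (1 - .sle_zero_infl) * px[1]
  px[-1] <- (1 - .sle_zero_infl) * px[-1]
  cumsum(px)
}

# ---- truncated-normal helper -------------------------------------------------

# Solve for the (mu, sigma) of an underlying normal such that after truncation
# to [lo, hi] the distribution has the requested mean and SD; closed-form
# truncated moments, 2-parameter Nelder-Mead.  Deterministic and fast.
trunc_norm_params <- function(mean, sd, lo, hi) {
  moments <- function(mu, sigma) {
    a <- (lo - mu) / sigma
    b <- (hi - mu) / sigma
    z <- pnorm(b) - pnorm(a)
    m <- mu + sigma * (dnorm(a) - dnorm(b)) / z
    v <- sigma^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / z -
                      ((dnorm(a) - dnorm(b)) / z)^2)
    c(m, sqrt(v))
  }
  obj <- function(p) {
    if (p[2] <= 0) return(1e10)
    mm <- moments(p[1], p[2])
    (mm[1] - mean)^2 + (mm[2] - sd)^2
  }
  o <- optim(c(mean, sd), obj, control = list(reltol = 1e-14, maxit = 2000))
  list(mu = o$par[1], sigma = o$par[2], lo = lo, hi = hi)
}

r_trunc_norm <- function(n, mean, sd, lo, hi) {
  p <- trunc_norm_params(mean, sd, lo, hi)
  plo <- pnorm(lo, p$mu, p$sigma)
  phi <- pnorm(hi, p$mu, p$sigma)
  qnorm(runif(n, plo, phi), p$mu, p$sigma)
}

# lognormal matched to a mean and SD, then truncated to [lo, hi] by inverse CDF
r_trunc_lnorm <- function(n, mean, sd, lo, hi) {
  cv2 <- (sd / mean)^2
  sdlog <- sqrt(log1p(cv2))
  meanlog <- log(mean) - sdlog^2 / 2
  plo <- plnorm(lo, meanlog, sdlog)
  phi <- plnorm(hi, meanlog, sdlog)
  qlnorm(runif(n, plo, phi), meanlog, sdlog)
}

r_cat <- function(n, levels, prob) {
  prob <- prob / sum(prob)
  factor(sample(levels, n, replace = TRUE, prob = prob), levels = levels)
}

#' Default covariate marginal specification
#'
#' Marginal distributions for the simulated cohort covariates, matching the
#' published sample descriptives of a pregnancy cohort of n = 1065 (maternal
#' age, BMI, income, neighborhood deprivation, gravidity as continuous;
#' race, ethnicity, education, household size, labor type, delivery method,
#' study site and sequencing batch as categorical; fetal sex, tobacco and
#' alcohol use as binary). Category probabilities are renormalised to sum to
#' one. Gestational age is included so the sensitivity design variant can be
#' exercised.
#'
#' @return A named list of marginal specifications understood by
#'   [gen_covariates()].
#' @export
cohort_params <- function() {
  list(
    maternal_age = list(type = "truncnorm", mean = 27.884, sd = 5.677,
                        lo = 16, hi = 43),
    deprivation  = list(type = "truncnorm", mean = 0.171, sd = 0.802,
                        lo = -1.482, hi = 2.804),
    gestational_age = list(type = "truncnorm", mean = 38.8, sd = 2.2,
                           lo = 25, hi = 42),
    income = list(type = "trunclnorm", mean = 56277, sd = 43074,
                  lo = 2493, hi = 214975),
    bmi    = list(type = "trunclnorm", mean = 27.7, sd = 7.5,
                  lo = 14, hi = 62),
    gravidity = list(type = "truncpois", lambda = 2.6, lo = 0, hi = 12),
    fetal_sex = list(type = "categorical",
                     levels = c("Male", "Female"), prob = c(0.499, 0.501)),
    tobacco = list(type = "binary", prob = 0.077),
    alcohol = list(type = "binary", prob = 0.094),
    race = list(type = "categorical",
                levels = c("White", "Black", "Multiple", "Asian", "Other",
                           "AIAN"),
                prob = c(0.482, 0.421, 0.057, 0.016, 0.010, 0.002)),
    ethnicity = list(type = "categorical",
                     levels = c("NotHispanic", "Hispanic"),
                     prob = c(0.941, 0.059)),
    education = list(type = "categorical",
                     levels = c("LessThanHS", "HS", "College", "Graduate"),
                     prob = c(0.071, 0.396, 0.360, 0.172)),
    household_size = list(type = "categorical",
                          levels = c("2-3", "4", "5", "6+"),
                          prob = c(0.205, 0.392, 0.236, 0.167)),
    labor_type = list(type = "categorical",
                      levels = c("Spontaneous", "Augmented", "Induced",
                                 "NoLabor"),
                      prob = c(0.230, 0.279, 0.325, 0.166)),
    delivery_method = list(type = "categorical",
                           levels = c("Vaginal", "Csection"),
                           prob = c(0.617, 0.383)),
    site = list(type = "categorical",
                levels = c("SiteA", "SiteB"), prob = c(0.733, 0.267)),
    batch = list(type = "categorical",
                 levels = c("B1", "B2", "B3"), prob = c(1, 1, 1) / 3)
  )
}

#' Generate cohort covariates
#'
#' Draws `n` samples from the marginal specification (exposures are added
#' separately by [gen_exposures()]). Repeated calls with the same `n`,
#' `params` and `seed` are identical.
#'
#' @param n Number of samples (>= 0).
#' @param params Marginal specification, see [cohort_params()].
#' @param seed Integer seed.
#' @return A `data.frame` with a `sample_id` column and one column per
#'   covariate; binary covariates are factors with levels `No`/`Yes`.
#' @export
gen_covariates <- function(n, params = cohort_params(), seed = 1L) {
  if (n < 0) stop("`n` must be non-negative")
  for (nm in names(params)) {
    p <- params[[nm]]
    if (p$type %in% c("categorical")) {
      if (abs(sum(p$prob / sum(p$prob)) - 1) > 1e-9)
        stop("category probabilities for ", nm, " do not normalise")
      if (any(p$prob < 0)) stop("negative category probability for ", nm)
    }
  }
  set.seed(seed)
  cols <- lapply(names(params), function(nm) {
    p <- params[[nm]]
    switch(p$type,
      truncnorm  = r_trunc_norm(n, p$mean, p$sd, p$lo, p$hi),
      trunclnorm = r_trunc_lnorm(n, p$mean, p$sd, p$lo, p$hi),
      truncpois  = {
        fx <- ppois(p$lo:p$hi, p$lambda)
        lo0 <- if (p$lo > 0) ppois(p$lo - 1, p$lambda) else 0
        u <- runif(n, lo0, fx[length(fx)])
        qpois(u, p$lambda)
      },
      binary = factor(ifelse(runif(n) < p$prob, "Yes", "No"),
                      levels = c("No", "Yes")),
      categorical = r_cat(n, p$levels, p$prob),
      stop("unknown marginal type: ", p$type)
    )
  })
  names(cols) <- names(params)
  out <- data.frame(sample_id = sprintf("S%04d", seq_len(n)),
                    cols, stringsAsFactors = FALSE)
  rownames(out) <- out$sample_id
  out
}

#' Append stress exposures to a cohort
#'
#' Adds a prenatal stressful-life-event (SLE) sum on 0..14 and three maternal
#' childhood-trauma (CTE) binary items plus their sum on 0..3. Dependence
#' between the exposures is induced by a one-factor Gaussian copula: the
#' three item latents and the SLE latent all load on a shared standard normal
#' factor. With the frozen default loadings the simulated cohort reproduces
#' the published SLE mean/SD (1.576/1.861), CTE item rates (26.3/8/19%),
#' CTE-free fraction (63.7%) and SLE-CTE Spearman correlation (0.226).
#'
#' @param cohort A covariate table from [gen_covariates()].
#' @param dependence Loading of the SLE latent on the shared factor, in
#'   (-1, 1). The default is the frozen calibrated value; `0` gives
#'   independent exposures.
#' @param seed Integer seed.
#' @return `cohort` with columns `sle_sum`, `cte_witness`, `cte_physical`,
#'   `cte_sexual` (0/1 integers) and `cte_sum` appended.
#' @export
gen_exposures <- function(cohort, dependence = .sle_factor_loading,
                          seed = 1L) {
  if (!is.finite(dependence) || abs(dependence) >= 1)
    stop("`dependence` must lie in (-1, 1)")
  n <- nrow(cohort)
  set.seed(seed)
  f <- rnorm(n)
  a <- .cte_item_loading
  th <- qnorm(1 - .cte_rates)
  items <- vapply(1:3, function(j) {
    as.integer(a * f + sqrt(1 - a^2) * rnorm(n) > th[j])
  }, integer(n))
  b <- dependence
  z_sle <- b * f + sqrt(1 - b^2) * rnorm(n)
  # inverse CDF of the zero-inflated truncated negative binomial
  fx <- .sle_cdf()
  sle <- findInterval(pnorm(z_sle), c(0, fx), left.open = TRUE)
  sle <- pmin(pmax(sle - 1L, 0L), .sle_max)
  cohort$sle_sum <- as.integer(sle)
  cohort$cte_witness <- items[, 1]
  cohort$cte_physical <- items[, 2]
  cohort$cte_sexual <- items[, 3]
  cohort$cte_sum <- as.integer(rowSums(items))
  cohort
}

#' Default per-variable missingness rates
#'
#' Fractions of samples with a masked value for each cohort variable,
#' matching the published Table-1 missing counts.
#' @return Named numeric vector of rates in \[0, 1\].
#' @export
default_missing_rates <- function() {
  c(sle_sum = 0.179, cte = 0.034, maternal_age = 0.019, income = 0.053,
    deprivation = 0.046, household_size = 0.045, bmi = 0.021,
    gravidity = 0.008, labor_type = 0.015, race = 0.012, ethnicity = 0.002,
    education = 0.002, alcohol = 0.008, tobacco = 0.001)
}

#' Mask cohort values
#'
#' Sets cells to `NA` under a missing-completely-at-random (MCAR) or
#' missing-at-random (MAR) mechanism. Under MAR the per-sample missingness
#' odds for every variable follow a logistic model on supplied predictor
#' scores, with the intercept solved per variable so the marginal masked
#' fraction still matches the requested rate. The special rate name `cte`
#' masks the three trauma items and their sum jointly (item-level missingness
#' is not observed separately in the emulated questionnaire).
#'
#' @param cohort Cohort table (exposures may be present; they may be masked
#'   and are then dropped, never imputed, downstream).
#' @param mechanism `"MCAR"` or `"MAR"`.
#' @param rates Named vector of per-variable missingness fractions.
#' @param mar_predictors Numeric matrix/data.frame (n rows) of fully observed
#'   scores driving MAR missingness; required for `"MAR"`.
#' @param mar_coef Coefficients (recycled across predictors) for the logistic
#'   missingness model; default 1 per predictor.
#' @param seed Integer seed.
#' @return The cohort with masked cells set to `NA`.
#' @export
inject_missingness <- function(cohort, mechanism = c("MCAR", "MAR"),
                               rates = default_missing_rates(),
                               mar_predictors = NULL, mar_coef = NULL,
                               seed = 1L) {
  mechanism <- match.arg(mechanism)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  n <- nrow(cohort)
  set.seed(seed)
  lp <- rep(0, n)
  if (mechanism == "MAR") {
    if (is.null(mar_predictors))
      stop("MAR requires `mar_predictors`")
    x <- scale(as.matrix(mar_predictors))
    if (anyNA(x)) stop("MAR predictors must be fully observed")
    if (is.null(mar_coef)) mar_coef <- rep(1, ncol(x))
    lp <- drop(x %*% rep_len(mar_coef, ncol(x)))
  }
  mask_draw <- function(rate) {
    if (rate == 0) return(logical(n))
    if (mechanism == "MCAR") return(runif(n) < rate)
    # solve intercept so mean(plogis(int + lp)) == rate
    int <- uniroot(function(b) mean(plogis(b + lp)) - rate,
                   c(-30, 30))$root
    runif(n) < plogis(int + lp)
  }
  for (nm in names(rates)) {
    cols <- if (nm == "cte") {
      intersect(c("cte_witness", "cte_physical", "cte_sexual", "cte_sum"),
                names(cohort))
    } else intersect(nm, names(cohort))
    if (!length(cols)) next
    m <- mask_draw(rates[[nm]])
    cohort[m, cols] <- NA
  }
  cohort
}

#' Simulate a count matrix with planted exposure effects
#'
#' Negative-binomial counts with a decreasing mean-dispersion trend.
#' Per-gene expected counts are
#' `mu_gs = base_cpm_g / 1e6 * L_s * 2^(beta_sle_g * SLE_s + beta_cte_g * CTE_s)`,
#' with `L_s` lognormal library sizes. Dispersion follows
#' `phi_g = phi0 + phi1 / mu_g` (biological coefficient of variation
#' `sqrt(phi0)` asymptotically). By default three designated well-expressed
#' genes carry SLE effects of +0.07, -0.04 and -0.03 log2 units per event;
#' all other genes are null.
#'
#' @param cohort Cohort table with exposures (masked exposure cells are
#'   tolerated: the *true* latent exposure must then be supplied via
#'   `exposure_values`, otherwise masked samples get effect 0).
#' @param n_genes Number of genes (>= number of effect genes).
#' @param sle_effects Named or unnamed numeric vector of per-event log2
#'   fold-changes planted on designated genes (in order `EFF1..`).
#' @param cte_effects Same for the CTE sum.
#' @param lib_size_mean Mean library size (default 1e6; desk scale).
#' @param lib_size_sd Standard deviation of log library size (default
#'   0.15; `0` gives equal depths).
#' @param phi0,phi1 Dispersion trend parameters.
#' @param dispersion Optional fixed dispersion overriding the trend; `0`
#'   gives the Poisson limit.
#' @param exposure_values Optional list with unmasked numeric vectors
#'   `sle` and `cte` to use as the generating exposures.
#' @param seed Integer seed.
#' @return A list with elements `counts` (an [edgeR::DGEList] whose `genes`
#'   data.frame carries `gene_id` and `biotype`) and `truth` (a
#'   `data.frame`: `gene_id`, `beta_sle`, `beta_cte`, `base_cpm`,
#'   `dispersion`, with the generator parameters as attributes).
#' @export
gen_counts <- function(cohort, n_genes = 2000,
                       sle_effects = c(0.07, -0.04, -0.03),
                       cte_effects = numeric(0),
                       lib_size_mean = 1e6, lib_size_sd = 0.15,
                       phi0 = 0.04, phi1 = 3,
                       dispersion = NULL, exposure_values = NULL,
                       seed = 1L) {
  n_eff <- max(length(sle_effects), length(cte_effects))
  if (n_genes < n_eff) stop("n_genes smaller than number of effect genes")
  if (lib_size_mean <= 0) stop("library size must be positive")
  n <- nrow(cohort)
  set.seed(seed)
  gene_id <- sprintf("G%05d", seq_len(n_genes))
  # baseline abundance: lognormal relative expression, normalised to CPM;
  # designated effect genes are pinned at a well-expressed 50 CPM baseline
  rel <- rlnorm(n_genes, meanlog = 0, sdlog = 2)
  base_cpm <- rel / sum(rel) * 1e6
  if (n_eff > 0) base_cpm[seq_len(n_eff)] <- 50
  beta_sle <- numeric(n_genes)
  beta_cte <- numeric(n_genes)
  if (length(sle_effects)) beta_sle[seq_along(sle_effects)] <- sle_effects
  if (length(cte_effects)) beta_cte[seq_along(cte_effects)] <- cte_effects
  sle <- if (!is.null(exposure_values)) exposure_values$sle else
    cohort$sle_sum
  cte <- if (!is.null(exposure_values)) exposure_values$cte else
    cohort$cte_sum
  if (is.null(sle)) sle <- rep(0, n)
  if (is.null(cte)) cte <- rep(0, n)
  sle[is.na(sle)] <- 0
  cte[is.na(cte)] <- 0
  lib <- if (lib_size_sd > 0)
    rlnorm(n, log(lib_size_mean) - lib_size_sd^2 / 2, lib_size_sd)
  else rep(lib_size_mean, n)
  lfc <- outer(beta_sle, sle) + outer(beta_cte, cte)   # genes x samples
  mu <- (base_cpm / 1e6) * 2^lfc
  mu <- sweep(mu, 2, lib, `*`)
  phi <- if (is.null(dispersion)) phi0 + phi1 / rowMeans(mu) else
    rep_len(dispersion, n_genes)
  counts <- matrix(0L, n_genes, n,
                   dimnames = list(gene_id, cohort$sample_id))
  for (g in seq_len(n_genes)) {
    counts[g, ] <- as.integer(round(
      if (phi[g] <= 0) rpois(n, mu[g, ]) else
        rnbinom(n, mu = mu[g, ], size = 1 / phi[g])))
  }
  biotype <- rep(c("protein_coding", "lncRNA", "processed_pseudogene"),
                 length.out = n_genes)
  if (n_eff > 0) biotype[seq_len(n_eff)] <- "protein_coding"
  genes <- data.frame(gene_id = gene_id, biotype = biotype,
                      row.names = gene_id, stringsAsFactors = FALSE)
  dge <- edgeR::DGEList(counts = counts, genes = genes)
  truth <- data.frame(gene_id = gene_id, beta_sle = beta_sle,
                      beta_cte = beta_cte, base_cpm = base_cpm,
                      dispersion = phi, stringsAsFactors = FALSE)
  attr(truth, "params") <- list(n_genes = n_genes, lib_size_mean =
    lib_size_mean, phi0 = phi0, phi1 = phi1, seed = seed,
    dependence = .sle_factor_loading)
  list(counts = dge, truth = truth)
}

#' Simulate a complete study (covariates, exposures, counts, missingness)
#'
#' Convenience wrapper chaining [gen_covariates()], [gen_exposures()],
#' [gen_counts()] and [inject_missingness()] with sub-seeds derived from
#' `seed`. Counts are generated from the *unmasked* exposures, then
#' missingness is injected into the cohort table only.
#'
#' @param n Samples; `n_genes` genes.
#' @param missing One of `"none"`, `"MCAR"`, `"MAR"`.
#' @param rates Missingness rates (see [inject_missingness()]).
#' @param mar_on_expression For MAR: drive missingness with the expression of
#'   the designated effect genes (log-CPM scores) plus the SLE sum — the
#'   outcome-dependent mechanism multiple imputation is designed for.
#' @param seed Integer seed.
#' @inheritParams gen_counts
#' @return List with `cohort` (masked), `cohort_complete` (unmasked),
#'   `counts` (DGEList) and `truth`.
#' @export
simulate_study <- function(n = 600, n_genes = 2000,
                           sle_effects = c(0.07, -0.04, -0.03),
                           cte_effects = numeric(0),
                           missing = c("none", "MCAR", "MAR"),
                           rates = default_missing_rates(),
                           mar_on_expression = TRUE,
                           lib_size_mean = 1e6, seed = 1L) {
  missing <- match.arg(missing)
  cohort <- gen_covariates(n, seed = seed)
  cohort <- gen_exposures(cohort, seed = seed + 1L)
  sim <- gen_counts(cohort, n_genes = n_genes, sle_effects = sle_effects,
                    cte_effects = cte_effects,
                    lib_size_mean = lib_size_mean, seed = seed + 2L)
  complete <- cohort
  if (missing == "MCAR") {
    cohort <- inject_missingness(cohort, "MCAR", rates, seed = seed + 3L)
  } else if (missing == "MAR") {
    preds <- data.frame(sle = cohort$sle_sum)
    if (mar_on_expression) {
      n_eff <- sum(sim$truth$beta_sle != 0 | sim$truth$beta_cte != 0)
      if (n_eff > 0) {
        lc <- log_cpm(sim$counts$counts[seq_len(n_eff), , drop = FALSE],
                      lib_size = colSums(sim$counts$counts))
        preds <- cbind(preds, t(lc))
      }
    }
    cohort <- inject_missingness(cohort, "MAR", rates,
                                 mar_predictors = preds, seed = seed + 3L)
  }
  list(cohort = cohort, cohort_complete = complete,
       counts = sim$counts, truth = sim$truth)
}
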