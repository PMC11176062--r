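# Model specification and design matrix construction.

.confounders <- c("race", "ethnicity", "income", "household_size",
                  "education", "deprivation")
.precision_vars <- c("fetal_sex", "gravidity", "delivery_method",
                     "labor_type", "site", "maternal_age", "batch")
.mediators <- c("bmi", "tobacco", "alcohol")

#' Specify a differential-expression model
#'
#' Encodes the analysis variants: one exposure (SLE sum or CTE sum) or both
#' plus their interaction; the a-priori confounder and precision-variable
#' sets; whether the potential mediators (BMI, tobacco, alcohol) are
#' adjusted for (on in the primary analysis); whether gestational age is
#' added (sensitivity variant); and an optional fetal-sex stratum.
#'
#' @param exposure `"sle_sum"`, `"cte_sum"` or `"interaction"`.
#' @param mediators Include BMI/tobacco/alcohol (default `TRUE`).
#' @param gestational_age Add gestational age (default `FALSE`).
#' @param stratum `"all"`, `"male"` or `"female"`.
#' @param confounders,precision_vars Covariate name sets (defaults are the
#'   package's a-priori lists).
#' @return An object of class `"design_spec"`.
#' @export
design_spec <- function(exposure = c("sle_sum", "cte_sum", "interaction"),
                        mediators = TRUE, gestational_age = FALSE,
                        stratum = c("all", "male", "female"),
                        confounders = .confounders,
                        precision_vars = .precision_vars) {
  exposure <- match.arg(exposure)
  stratum <- match.arg(stratum)
  exp_cols <- if (exposure == "interaction") c("sle_sum", "cte_sum") else
    exposure
  covars <- c(confounders, precision_vars,
              if (mediators) .mediators,
              if (gestational_age) "gestational_age")
  if (any(exp_cols %in% covars))
    stop("exposure must not appear among covariates")
  if (stratum != "all") covars <- setdiff(covars, "fetal_sex")
  structure(list(exposure = exposure, exposure_cols = exp_cols,
                 covariates = covars, mediators = mediators,
                 gestational_age = gestational_age, stratum = stratum),
            class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  cat("design_spec: exposure =", x$exposure,
      "| mediators =", x$mediators,
      "| gestational age =", x$gestational_age,
      "| stratum =", x$stratum, "\n")
  cat("covariates:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}

# columns of the cohort a spec uses (exposures first)
spec_columns <- function(spec) c(spec$exposure_cols, spec$covariates)

# subset cohort to the spec's stratum
apply_stratum <- function(cohort, spec) {
  if (spec$stratum == "all") return(cohort)
  lvl <- c(male = "Male", female = "Female")[[spec$stratum]]
  out <- cohort[!is.na(cohort$fetal_sex) & cohort$fetal_sex == lvl, ,
                drop = FALSE]
  if (nrow(out) == 0) stop("empty stratum: ", spec$stratum)
  out
}

# relevel every factor so the most frequent level is the reference
relevel_modal <- function(df) {
  for (nm in names(df)) {
    if (is.character(df[[nm]])) df[[nm]] <- factor(df[[nm]])
    if (is.factor(df[[nm]])) {
      df[[nm]] <- droplevels(df[[nm]])
      tab <- table(df[[nm]])
      df[[nm]] <- stats::relevel(df[[nm]], ref = names(which.max(tab)))
    }
  }
  df
}

#' Build a design matrix
#'
#' Intercept + exposure(s) (+ product term for the interaction variant) +
#' covariates, with categorical covariates dummy-coded against their most
#' frequent level and continuous covariates untransformed. The caller must
#' supply rows with no missing values in the used columns (see
#' [complete_rows()]); the matrix must be full column rank, otherwise the
#' aliased columns are reported.
#'
#' @param cohort Cohort rows to use (already stratum-filtered and complete).
#' @param spec A [design_spec()].
#' @return Numeric design matrix (samples x coefficients) with attribute
#'   `exposure_coef` naming the tested coefficient(s).
#' @export
build_design <- function(cohort, spec) {
  cohort <- apply_stratum(cohort, spec)
  use <- spec_columns(spec)
  miss <- setdiff(use, names(cohort))
  if (length(miss))
    stop("cohort lacks columns: ", paste(miss, collapse = ", "))
  d <- cohort[, use, drop = FALSE]
  if (anyNA(d))
    stop("missing values in design columns; impute or subset first")
  d <- relevel_modal(d)
  fml <- if (spec$exposure == "interaction") {
    stats::as.formula(paste("~ sle_sum * cte_sum +",
                            paste(spec$covariates, collapse = " + ")))
  } else {
    stats::as.formula(paste("~", paste(c(spec$exposure_cols,
                                         spec$covariates),
                                       collapse = " + ")))
  }
  x <- model.matrix(fml, data = d)
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    aliased <- colnames(x)[qrx$pivot[(qrx$rank + 1):ncol(x)]]
    stop("design matrix is rank deficient; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  attr(x, "exposure_coef") <- switch(spec$exposure,
    interaction = "sle_sum:cte_sum", spec$exposure)
  x
}

#' Rows usable for a complete-data analysis
#'
#' Samples in the spec's stratum with the exposure observed and, when
#' `covariates = TRUE`, every design covariate observed (the complete-case
#' rule). Samples missing the exposure are always excluded — exposures are
#' never imputed.
#'
#' @param cohort Cohort table with `NA` for missing.
#' @param spec A [design_spec()].
#' @param covariates Also require complete covariates (default `TRUE`).
#' @return Character vector of sample ids.
#' @export
complete_rows <- function(cohort, spec, covariates = TRUE) {
  cohort <- apply_stratum(cohort, spec)
  cols <- if (covariates) spec_columns(spec) else spec$exposure_cols
  keep <- complete.cases(cohort[, cols, drop = FALSE])
  cohort$sample_id[keep]
}
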