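# mivoom

Differential expression of bulk RNA-seq counts against ordinal exposures
when model covariates are partially missing.

## The problem

Cohort transcriptomic studies regress gene expression on an exposure
(here: counts of prenatal stressful life events, SLE 0–14, or maternal
childhood traumatic events, CTE 0–3) adjusted for a dozen or more
covariates — and some covariate values are always missing. Dropping
incomplete samples (complete case) wastes power and is biased whenever
missingness is related to the outcome. Proper multiple imputation must
include the outcome among the predictors of the missing covariates, which
is infeasible with ~14,000 outcome genes in one model.

`mivoom` implements the gene-binned solution: genes are partitioned into
bins; within each bin the covariates are multiply imputed by chained
equations with the bin's log-CPM values (and the exposure) as predictors;
per imputed dataset, precision-weighted linear models are fitted and
variances moderated; per-gene estimates are then pooled with Rubin's rules.

## The model

For gene *g* and sample *s*, log2-CPM `E_gs` is modelled as

    E_gs = x_s' beta_g + e_gs,   Var(e_gs) = sigma_g^2 / w_gs

with observation weights `w_gs` interpolated from the fitted mean–variance
trend (voom). Gene-wise variances are squeezed toward a global prior
estimated by moment matching, `s2_post = (d0*s0^2 + d_g*s_g^2)/(d0 + d_g)`.
Across the `M` imputed datasets of a bin, for the exposure coefficient:

    Qbar = mean(beta_m)          pooled log2 fold-change per exposure unit
    Ubar = mean(var_m)           within-imputation variance
    B    = var(beta_m)           between-imputation variance
    T    = Ubar + (1 + 1/M) B    total variance
    t    = Qbar / sqrt(T)        referred to t on Barnard–Rubin df

Benjamini–Hochberg FDR is applied across all genes, and effects are also
reported as percent change per exposure unit, `(2^log2FC - 1) * 100`.

Around this core: TMM library-size normalisation, biotype and expression
filtering, complete-case and iterative random-forest single-imputation
sensitivity pipelines, a rank-concordance comparison of the three
strategies, an ensemble gene-set enrichment stage (over-representation,
correlation-adjusted competitive, z-score, singular-vector and Welch
location tests, combined by Fisher's method), sex-stratified and
interaction variants, and a negative-binomial cohort simulator calibrated
to published perinatal-stress cohort statistics.

## Worked example

```r
library(mivoom)

# a synthetic cohort: 600 samples, 2000 genes, three genes carry SLE
# effects of +0.07 / -0.04 / -0.03 log2 units per event, covariates
# masked at the published missingness rates
st <- simulate_study(n = 600, n_genes = 2000, missing = "MCAR", seed = 1)

spec <- design_spec("sle_sum")           # primary model, mediators adjusted
mi <- mi_de(st$counts, st$cohort, spec, M = 5, bin_size = 50, seed = 1)

attr(mi, "n_used")                        # 483  (samples with SLE observed)
attr(mi, "n_genes")                       # 1961 (biotype + expression filter)
head(mi[order(mi$p), c("log2fc", "percent_change", "t", "p", "q")], 3)
#>             log2fc percent_change         t            p            q
#> G00001  0.07333369       5.214511  6.501978 1.488799e-10 2.919535e-07
#> G00003 -0.05603082      -3.809309 -4.524552 7.086767e-06 6.948575e-03
#> G01211  0.08095401       5.771724  3.786955 1.653138e-04 1.080601e-01
```

The two leading genes are planted effects: per additional stressful life
event, a 5.2% expression increase (true effect +0.07 log2 units) and a
3.8% decrease (true −0.04), both significant at FDR < 0.05 at this cohort
size; the smallest planted effect (−0.03) needs a larger cohort. The
third row is a null gene, not significant. Sensitivity strategies and
their agreement:

```r
si <- si_de(st$counts, st$cohort, spec, seed = 1)   # random-forest single
cc <- cc_de(st$counts, st$cohort, spec)             # complete case
rank_concordance(mi, si)                  # 0.9976
```

Enrichment and the full orchestrated pipeline:

```r
er <- ensemble_run(mi, random_gene_sets(mi$gene_id, 100, seed = 1))
cfg <- run_config(outdir = "run1", seed = 1)
pipeline_run_all(cfg)                     # simulate, analyze, enrich, report
```

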