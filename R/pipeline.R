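# Orchestration: a YAML-configured, seeded, resumable run of the full
# analysis graph (simulate -> analyze -> enrich -> report) with plain
# TSV/JSON stage outputs carrying the config hash.

#' Build a run configuration
#'
#' @param outdir Output directory.
#' @param seed Integer seed (mandatory).
#' @param n,n_genes Simulated cohort size (desk preset defaults).
#' @param missing Missingness mechanism for the simulation stage.
#' @param exposures Exposures to analyse.
#' @param variants Covariate-set variants to run: `primary` (mediators
#'   adjusted), `no_mediators`, `plus_ga`.
#' @param mi_m,mi_bin_size,mi_max_iter Multiple-imputation settings.
#' @param methods,rule,min_size,max_size Enrichment settings.
#' @param n_sets Synthetic gene-set collection size for `pipeline_enrich`
#'   when no GMT path is given.
#' @param gmt Optional GMT file path.
#' @param scale `"desk"` or `"full"` (full raises n_genes/library size).
#' @return List of class `"run_config"`.
#' @export
run_config <- function(outdir, seed, n = 600, n_genes = 2000,
                       missing = "MCAR",
                       exposures = c("sle_sum", "cte_sum"),
                       variants = "primary",
                       mi_m = 5, mi_bin_size = 50, mi_max_iter = 5,
                       methods = c("ora", "camera", "zscore", "plage",
                                   "gage"),
                       rule = "mean", min_size = 10, max_size = 500,
                       n_sets = 100, gmt = NULL, scale = "desk") {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  if (scale == "full") {
    n_genes <- max(n_genes, 14000)
  }
  cfg <- list(outdir = outdir, seed = as.integer(seed), n = n,
              n_genes = n_genes, missing = missing, exposures = exposures,
              variants = variants, mi_m = mi_m, mi_bin_size = mi_bin_size,
              mi_max_iter = mi_max_iter, methods = methods, rule = rule,
              min_size = min_size, max_size = max_size, n_sets = n_sets,
              gmt = gmt, scale = scale)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with the fields of [run_config()].
#' @return A `"run_config"`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

# hash of the scientific configuration: output location excluded, so the
# same analysis in two directories carries the same hash
config_hash <- function(cfg) {
  core <- unclass(cfg)
  core$outdir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(core), tmp)
  unname(tools::md5sum(tmp))
}

write_config <- function(cfg) {
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(unclass(cfg), file.path(cfg$outdir, "config.yaml"))
}

#' Simulation stage
#'
#' Generates the synthetic study and writes it as a fixture directory under
#' `outdir/fixture`, with a manifest (parameter echo + file checksums).
#'
#' @param cfg A [run_config()].
#' @param force Overwrite an existing non-empty fixture directory.
#' @return The fixture directory, invisibly.
#' @export
pipeline_simulate <- function(cfg, force = FALSE) {
  fdir <- file.path(cfg$outdir, "fixture")
  if (dir.exists(fdir) && length(dir(fdir)) && !force)
    stop("fixture directory exists; use force = TRUE to overwrite")
  write_config(cfg)
  study <- simulate_study(n = cfg$n, n_genes = cfg$n_genes,
                          missing = cfg$missing, seed = cfg$seed)
  write_fixture(fdir, study$cohort, study$counts, study$truth)
  files <- dir(fdir, full.names = TRUE)
  manifest <- list(config = unclass(cfg), config_hash = config_hash(cfg),
                   checksums = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(fdir)
}

#' Verify a fixture manifest
#'
#' @param outdir Run directory containing `manifest.json`.
#' @return `TRUE` if all checksums validate, else an error.
#' @export
check_manifest <- function(outdir) {
  man <- jsonlite::read_json(file.path(outdir, "manifest.json"),
                             simplifyVector = TRUE)
  current <- tools::md5sum(names(man$checksums))
  if (!identical(unname(current), unname(unlist(man$checksums))))
    stop("fixture checksums do not match the manifest")
  TRUE
}

de_variant_spec <- function(exposure, variant, stratum = "all") {
  switch(variant,
    primary = design_spec(exposure, mediators = TRUE, stratum = stratum),
    no_mediators = design_spec(exposure, mediators = FALSE,
                               stratum = stratum),
    plus_ga = design_spec(exposure, mediators = TRUE,
                          gestational_age = TRUE, stratum = stratum),
    stop("unknown variant: ", variant))
}

#' Analysis stage
#'
#' Per exposure: the interaction screen, the primary multiple-imputation
#' analysis, the single-imputation and complete-case sensitivity strategies,
#' the configured covariate-set variants, and the cross-method rank
#' concordances. Each table is written once under `outdir/analysis`; tables
#' already on disk are not recomputed (stage outputs are idempotent), so an
#' interrupted run resumes. When a truth table is present a recovery report
#' (bias, TPR, FDR vs. truth) is emitted.
#'
#' @param cfg A [run_config()].
#' @return List of result tables, invisibly.
#' @export
pipeline_analyze <- function(cfg) {
  fdir <- file.path(cfg$outdir, "fixture")
  adir <- file.path(cfg$outdir, "analysis")
  dir.create(adir, showWarnings = FALSE, recursive = TRUE)
  fx <- read_fixture(fdir)
  hash <- config_hash(cfg)
  out <- list()
  save_tbl <- function(res, name) {
    path <- file.path(adir, paste0(name, ".tsv"))
    if (!file.exists(path)) write_result_tsv(res, path, hash)
    out[[name]] <<- res
    msg <- sprintf(
      "[analyze] %s: n=%s genes=%s FDR<0.05=%s FDR<0.10=%s",
      name, attr(res, "n_used"), attr(res, "n_genes"),
      attr(res, "n_sig_05"), attr(res, "n_sig_10"))
    message(msg)
    res
  }
  for (expo in cfg$exposures) {
    # interaction screen (complete case)
    ispec <- design_spec("interaction")
    save_tbl(run_de(fx$counts, fx$cohort, ispec),
             paste0(expo, "_interaction"))
    for (variant in cfg$variants) {
      spec <- de_variant_spec(expo, variant)
      base <- paste(expo, variant, sep = "_")
      mi <- save_tbl(mi_de(fx$counts, fx$cohort, spec, M = cfg$mi_m,
                           bin_size = cfg$mi_bin_size,
                           max_iter = cfg$mi_max_iter, seed = cfg$seed),
                     paste0(base, "_mi"))
      si <- save_tbl(si_de(fx$counts, fx$cohort, spec, seed = cfg$seed),
                     paste0(base, "_si"))
      cc <- save_tbl(cc_de(fx$counts, fx$cohort, spec),
                     paste0(base, "_cc"))
      conc <- data.frame(
        comparison = c("mi_vs_si", "mi_vs_cc", "si_vs_cc"),
        spearman = c(rank_concordance(mi, si), rank_concordance(mi, cc),
                     rank_concordance(si, cc)))
      write.table(conc, file.path(adir, paste0(base, "_concordance.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      shared <- Reduce(intersect, list(mi$gene_id, si$gene_id, cc$gene_id))
      ranks <- data.frame(
        gene = shared,
        rank_mi = rank(mi$p[match(shared, mi$gene_id)]),
        rank_si = rank(si$p[match(shared, si$gene_id)]),
        rank_cc = rank(cc$p[match(shared, cc$gene_id)]))
      write.table(ranks, file.path(adir, paste0(base, "_ranks.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(fx$truth) && expo == "sle_sum") {
        tr <- fx$truth
        beta <- tr$beta_sle[match(mi$gene_id, tr$gene_id)]
        eff <- beta != 0
        rec <- data.frame(
          strategy = "mi",
          bias = mean(mi$log2fc[eff] - beta[eff]),
          tpr_fdr05 = mean(mi$q[eff] < 0.05),
          fdp_fdr05 = {
            sig <- mi$q < 0.05
            if (any(sig)) mean(!eff[sig]) else 0
          })
        write.table(rec, file.path(adir, paste0(base, "_recovery.tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
  }
  invisible(out)
}

#' Enrichment stage
#'
#' Ensemble enrichment per exposure on the single-imputation results plus
#' the sex-stratified runs, written under `outdir/enrichment` as long-format
#' TSV (set, exposure, stratum, per-method p, combined p, q, mean log2FC).
#' Uses the configured GMT file, or a synthetic collection drawn from the
#' tested genes when none is configured.
#'
#' @param cfg A [run_config()].
#' @return List of enrichment tables, invisibly.
#' @export
pipeline_enrich <- function(cfg) {
  fdir <- file.path(cfg$outdir, "fixture")
  edir <- file.path(cfg$outdir, "enrichment")
  dir.create(edir, showWarnings = FALSE, recursive = TRUE)
  fx <- read_fixture(fdir)
  hash <- config_hash(cfg)
  out <- list()
  long <- list()
  for (expo in cfg$exposures) {
    spec <- design_spec(expo)
    de <- si_de(fx$counts, fx$cohort, spec, seed = cfg$seed)
    collection <- if (!is.null(cfg$gmt)) read_gmt(cfg$gmt) else
      random_gene_sets(de$gene_id, n_sets = cfg$n_sets,
                       seed = cfg$seed)
    er <- ensemble_run(de, collection, methods = cfg$methods,
                       rule = cfg$rule, min_size = cfg$min_size,
                       max_size = cfg$max_size)
    out[[expo]] <- er
    er$exposure <- expo
    er$stratum <- "all"
    long[[paste0(expo, "_all")]] <- er
    strat <- stratified_enrichment(fx$counts, fx$cohort, spec, collection,
                                   methods = cfg$methods, rule = cfg$rule,
                                   min_size = cfg$min_size,
                                   max_size = cfg$max_size)
    for (s in c("male", "female")) {
      tb <- strat[[s]]
      tb$exposure <- expo
      tb$stratum <- s
      long[[paste0(expo, "_", s)]] <- tb
    }
    write.table(strat$concordance,
                file.path(edir, paste0(expo, "_sex_concordance.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  tall <- do.call(rbind, long)
  con <- file(file.path(edir, "enrichment_long.tsv"), "w")
  writeLines(paste0("# config_hash: ", hash), con)
  write.table(tall, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(out)
}

#' Report stage
#'
#' Consolidates completed stage outputs into one markdown summary and a TSV
#' of headline numbers: cohort descriptives with per-variable missing
#' counts, DE hits per analysis, rank concordances, and significant
#' enrichment sets. Regenerable byte-identically from the stage outputs.
#'
#' @param outdir Run directory.
#' @return Path of the markdown report, invisibly.
#' @export
pipeline_report <- function(outdir) {
  cfg <- read_run_config(file.path(outdir, "config.yaml"))
  hash <- config_hash(cfg)
  fx <- read_fixture(file.path(outdir, "fixture"))
  co <- fx$cohort
  num <- vapply(co, is.numeric, TRUE) & names(co) != "sample_id"
  desc <- data.frame(
    variable = names(co)[names(co) != "sample_id"],
    stringsAsFactors = FALSE)
  desc$mean <- vapply(desc$variable, function(v)
    if (num[[v]]) mean(co[[v]], na.rm = TRUE) else NA_real_, 0)
  desc$sd <- vapply(desc$variable, function(v)
    if (num[[v]]) sd(co[[v]], na.rm = TRUE) else NA_real_, 0)
  desc$n_missing <- vapply(desc$variable, function(v)
    sum(is.na(co[[v]])), 0L)
  write.table(desc, file.path(outdir, "report_descriptives.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  lines <- c("# Run report", "",
             paste0("config hash: ", hash), "",
             "## Cohort",
             paste0("samples: ", nrow(co)),
             paste0("genes: ", nrow(fx$counts$counts)), "",
             "## Differential expression")
  adir <- file.path(outdir, "analysis")
  for (f in sort(dir(adir, pattern = "_(mi|si|cc|interaction)\\.tsv$"))) {
    hdr <- grep("^#", readLines(file.path(adir, f), n = 10), value = TRUE)
    lines <- c(lines, paste0("- ", f, ": ",
                             paste(sub("^# ", "", hdr), collapse = "; ")))
  }
  efile <- file.path(outdir, "enrichment", "enrichment_long.tsv")
  if (file.exists(efile)) {
    e <- read.delim(efile, comment.char = "#")
    lines <- c(lines, "", "## Enrichment",
               paste0("significant sets (q < 0.05): ",
                      sum(e$significant)))
  }
  path <- file.path(outdir, "report.md")
  writeLines(lines, path)
  invisible(path)
}

#' Run the full pipeline
#'
#' @param cfg A [run_config()].
#' @param force Passed to [pipeline_simulate()].
#' @return The run directory, invisibly.
#' @export
pipeline_run_all <- function(cfg, force = FALSE) {
  pipeline_simulate(cfg, force = force)
  pipeline_analyze(cfg)
  pipeline_enrich(cfg)
  pipeline_report(cfg$outdir)
  invisible(cfg$outdir)
}
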