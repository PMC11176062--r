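# GMT parsing, the five base set tests, p-value combination, ensemble.

test_that("GMT files parse, deduplicate, and round-trip", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3",
               "setB\tdesc\tg2\tg4\tg4"), path)
  gs <- read_gmt(path)
  expect_named(gs, c("setA", "setB"))
  expect_setequal(gs$setA, c("g1", "g2", "g3"))
  expect_equal(gs$setB, c("g2", "g4"))   # duplicate stored once

  out <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(gs, out)
  gs2 <- read_gmt(out)
  expect_equal(unclass(gs)[], unclass(gs2)[], ignore_attr = TRUE)

  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1", "broken_line"), bad)
  expect_error(read_gmt(bad), "line 2")
})

test_that("over-representation matches exact enumeration", {
  # universe 10, set 5, significant 5, full overlap: p = 1 / C(10,5)
  de <- data.frame(gene_id = paste0("g", 1:10), p = (1:10) / 100)
  p <- ora(de, set = paste0("g", 1:5), top_k = 5)
  expect_equal(p, 1 / choose(10, 5), tolerance = 1e-12)

  # zero overlap: upper tail includes >= 0, so p = 1
  p0 <- ora(de, set = paste0("g", 6:10), top_k = 5)
  expect_equal(p0, enum_ora(10, 5, 5, 0), tolerance = 1e-12)
  expect_equal(p0, 1, tolerance = 1e-12)

  # agreement with enumeration across many configurations, universe <= 15
  set.seed(21)
  for (i in 1:20) {
    N <- sample(8:15, 1)
    K <- sample(2:(N - 2), 1)
    k_sig <- sample(2:(N - 1), 1)
    deu <- data.frame(gene_id = paste0("u", 1:N), p = runif(N))
    st <- sample(deu$gene_id, K)
    sig <- deu$gene_id[order(deu$p)][1:k_sig]
    obs <- length(intersect(sig, st))
    expect_equal(ora(deu, st, top_k = k_sig),
                 enum_ora(N, K, k_sig, obs), tolerance = 1e-12)
  }
})

test_that("the competitive test matches hand VIF arithmetic and its rho = 0 oracle", {
  stats <- setNames(rep(1.3, 20), paste0("g", 1:20))
  r <- camera_test(stats, paste0("g", 1:3))
  expect_equal(r$p, 1)

  # rho = 0 equals the naive pooled two-group comparison
  set.seed(22)
  z <- setNames(rnorm(50), paste0("g", 1:50))
  memb <- paste0("g", 1:8)
  r0 <- camera_test(z, memb, intergene_correlation = 0)
  inset <- names(z) %in% memb
  m <- sum(inset); G <- length(z)
  delta <- mean(z[inset]) - mean(z[!inset])
  sp2 <- (sum((z[inset] - mean(z[inset]))^2) +
            sum((z[!inset] - mean(z[!inset]))^2)) / (G - 2)
  tnaive <- delta / sqrt(sp2 * (1 / m + 1 / (G - m)))
  expect_equal(r0$p, 2 * pt(-abs(tnaive), G - 2), tolerance = 1e-10)

  # fixed toy vector, rho = 0.1: step-by-step VIF computation
  toy <- setNames(c(2.0, 1.5, 1.0, 0.5, 0.0, -0.5, -1.0, -1.5, 0.3, 0.7),
                  paste0("t", 1:10))
  ts <- camera_test(toy, c("t1", "t2", "t3"), intergene_correlation = 0.1)
  mm <- 3; GG <- 10
  dd <- mean(toy[1:3]) - mean(toy[4:10])
  s2 <- (sum((toy[1:3] - mean(toy[1:3]))^2) +
           sum((toy[4:10] - mean(toy[4:10]))^2)) / (GG - 2)
  vif <- 1 + (mm - 1) * 0.1
  tt <- dd / sqrt(s2 * (vif / mm + 1 / (GG - mm)))
  expect_equal(ts$p, 2 * pt(-abs(tt), GG - 2), tolerance = 1e-12)
  expect_equal(ts$direction, sign(dd))

  expect_error(camera_test(z, "g1"), "fewer than 2")
})

test_that("score-based tests reduce correctly and fix the singular-vector sign", {
  st <- small_study()
  spec <- design_spec("sle_sum", mediators = FALSE)
  ids <- complete_rows(st$cohort, spec)
  design <- build_design(st$cohort[ids, ], spec)
  lc <- log_cpm(st$counts[, ids])

  # m = 1: the z-score test equals the single-gene linear-model test
  g1 <- rownames(lc)[10]
  sc <- score_based_tests(lc, design, g1)
  y <- as.numeric(scale(lc[g1, ]))
  fit <- lm(y ~ design - 1)
  p_single <- summary(fit)$coefficients["designsle_sum", 4]
  expect_equal(unname(sc$p_zscore), unname(p_single), tolerance = 1e-8)

  # sign convention: the singular-vector score correlates positively with
  # mean member expression
  memb <- rownames(lc)[1:12]
  sc2 <- score_based_tests(lc, design, memb)
  expect_gt(cor(sc2$score_plage, colMeans(lc[memb, ])), 0)

  # constant rows are dropped with a warning
  lc2 <- rbind(lc, const = rep(1, ncol(lc)))
  expect_warning(score_based_tests(lc2, design, c(memb, "const")),
                 "constant")
})

test_that("the location test matches a textbook Welch computation and detects shifts", {
  set.seed(23)
  z <- setNames(rnorm(100), paste0("g", 1:100))
  memb <- paste0("g", 1:10)
  p <- gage_like(z, memb)
  a <- z[1:10]; b <- z[11:100]
  tw <- (mean(a) - mean(b)) / sqrt(var(a) / 10 + var(b) / 90)
  dfw <- (var(a) / 10 + var(b) / 90)^2 /
    ((var(a) / 10)^2 / 9 + (var(b) / 90)^2 / 89)
  expect_equal(p, 2 * pt(-abs(tw), dfw), tolerance = 1e-12)

  zs <- z
  zs[memb] <- zs[memb] + 3
  expect_lt(gage_like(zs, memb), 1e-6)
  expect_error(gage_like(z, "g1"), "fewer than 2")
})

test_that("p-value combination matches the closed forms", {
  f <- combine_pvalues(c(0.5, 0.5), "fisher")
  x <- -2 * sum(log(c(0.5, 0.5)))
  expect_equal(as.numeric(f), exp(-x / 2) * (1 + x / 2), tolerance = 1e-10)
  expect_equal(round(as.numeric(f), 4), 0.5966)

  expect_equal(as.numeric(combine_pvalues(0.123, "fisher")), 0.123,
               tolerance = 1e-12)
  w <- combine_pvalues(c(0.1, 0.1, 0.1), "wilkinson")
  expect_equal(as.numeric(w), 1 - (1 - 0.1)^3, tolerance = 1e-12)
  expect_equal(attr(w, "k"), 3)

  expect_warning(cz <- combine_pvalues(c(0, 0.5), "fisher"), "clamped")
  expect_lt(as.numeric(cz), 1e-100)
  # NA methods are skipped and k reduced
  k2 <- combine_pvalues(c(0.2, NA, 0.4), "fisher")
  expect_equal(attr(k2, "k"), 2)
  expect_error(combine_pvalues(NA_real_), "no valid")
})

test_that("the ensemble recovers a planted coordinated set and respects size bounds", {
  hits <- 0
  for (s in 1:5) {
    co <- gen_exposures(gen_covariates(150, seed = 500 + s),
                        seed = 500 + s)
    sim <- gen_counts(co, n_genes = 300, sle_effects = rep(0.4, 15),
                      seed = 500 + s)
    de <- run_de(sim$counts, co, design_spec("sle_sum",
                                             mediators = FALSE))
    planted <- intersect(sim$truth$gene_id[sim$truth$beta_sle != 0],
                         de$gene_id)
    gs <- random_gene_sets(de$gene_id, n_sets = 29, size_range = c(10, 30),
                           seed = s)
    gs$PLANTED <- planted
    er <- ensemble_run(de, gs, top_k = 50)
    if (er$set[1] == "PLANTED") hits <- hits + 1
    expect_true(all(er$m >= 10 & er$m <= 500))
    expect_equal(er[er$set == "PLANTED", "direction"], 1)
  }
  expect_gte(hits, 4)
})

test_that("stratified enrichment is modular and flags planted sex-discordant sets", {
  set.seed(31)
  co <- gen_exposures(gen_covariates(260, seed = 31), seed = 31)
  male <- co$fetal_sex == "Male"
  # plant a sex-opposite effect on genes 1..12 by simulating strata apart
  sim_m <- gen_counts(co[male, ], n_genes = 250,
                      sle_effects = rep(0.5, 12), seed = 32)
  sim_f <- gen_counts(co[!male, ], n_genes = 250,
                      sle_effects = rep(-0.5, 12), seed = 33)
  counts <- cbind(sim_m$counts$counts, sim_f$counts$counts)
  counts <- counts[, co$sample_id]
  dge <- edgeR::DGEList(counts = counts, genes = sim_m$counts$genes)
  spec <- design_spec("sle_sum", mediators = FALSE)
  gs <- random_gene_sets(rownames(counts), n_sets = 19,
                         size_range = c(10, 25), seed = 34)
  gs$OPPOSITE <- sprintf("G%05d", 1:12)
  strat <- stratified_enrichment(dge, co, spec, gs, top_k = 50)
  expect_setequal(names(strat), c("male", "female", "concordance"))
  opp <- strat$concordance[strat$concordance$set == "OPPOSITE", ]
  expect_false(opp$concordant)

  # modularity: male results do not depend on female data
  co2 <- co
  f_ids <- co2$sample_id[!male]
  set.seed(99)
  dge2 <- dge
  dge2$counts[, f_ids] <- dge2$counts[, sample(f_ids)]
  strat2 <- stratified_enrichment(dge2, co2, spec, gs, top_k = 50)
  expect_equal(strat$male$combined_p, strat2$male$combined_p,
               tolerance = 1e-12)
})
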