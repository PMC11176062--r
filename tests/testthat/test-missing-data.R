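# Binning, chained-equations MI, Rubin pooling, RF single imputation,
# rank concordance.

test_that("gene binning partitions deterministically with a small last bin", {
  ids <- sprintf("g%03d", 1:100)
  b <- bin_genes(ids, 50, seed = 1)
  expect_length(b, 2)
  expect_equal(lengths(b), c(`1` = 50, `2` = 50))

  b3 <- bin_genes(sprintf("g%03d", 1:101), 50, seed = 1)
  expect_equal(unname(lengths(b3)), c(50, 50, 1))

  expect_identical(bin_genes(ids, 7, seed = 9), bin_genes(ids, 7, seed = 9))
  expect_setequal(unlist(b3), sprintf("g%03d", 1:101))
  expect_error(bin_genes(ids, 0), "bin_size")
})

test_that("imputation preserves observed cells and collapses when nothing is missing", {
  st <- small_study()
  spec <- design_spec("sle_sum")
  co <- st$cohort
  lc <- log_cpm(st$counts)[1:20, ]
  cols <- intersect(spec$covariates, names(co))

  imp0 <- impute_bin(co, lc, M = 3, max_iter = 2, seed = 1,
                     columns = cols, exposure_cols = "sle_sum")
  for (m in 1:3) expect_identical(imp0[[m]], co)

  # with missingness: observed cells bitwise identical, masked cells filled
  com <- inject_missingness(co, "MCAR", seed = 2)
  com <- com[!is.na(com$sle_sum), ]
  lcm <- lc[, com$sample_id]
  imp <- impute_bin(com, lcm, M = 3, max_iter = 2, seed = 3,
                    columns = cols, exposure_cols = "sle_sum")
  for (m in 1:3) {
    cm <- imp[[m]]
    expect_false(anyNA(cm[, cols]))
    for (v in cols) {
      obs <- !is.na(com[[v]])
      expect_identical(cm[[v]][obs], com[[v]][obs])
    }
  }
  # imputations differ where cells were masked (M > 1 distinct draws)
  vmiss <- cols[colSums(is.na(com[cols])) > 5][1]
  expect_false(identical(imp[[1]][[vmiss]], imp[[2]][[vmiss]]))

  expect_error(impute_bin(co, lc, M = 1), "M must be")
  com_bad <- inject_missingness(co, "MCAR", seed = 4)
  expect_error(impute_bin(com_bad, lc, M = 2, exposure_cols = "sle_sum"),
               "masked exposure")
})

test_that("MCAR imputation preserves the mean of a continuous covariate", {
  set.seed(5)
  co <- gen_exposures(gen_covariates(500, seed = 5), seed = 5)
  sim <- gen_counts(co, n_genes = 10, sle_effects = numeric(0), seed = 5)
  lc <- log_cpm(sim$counts)
  com <- inject_missingness(co, "MCAR", rates = c(income = 0.2), seed = 6)
  imp <- impute_bin(com, lc, M = 5, max_iter = 3, seed = 7,
                    columns = c("income", "maternal_age", "bmi"),
                    exposure_cols = "sle_sum")
  obs_mean <- mean(com$income, na.rm = TRUE)
  imp_means <- vapply(imp, function(d)
    mean(d$income[is.na(com$income)]), 0)
  mc_se <- sd(co$income) / sqrt(sum(is.na(com$income)))
  expect_lt(abs(mean(imp_means) - obs_mean), 3 * mc_se)
})

test_that("Rubin pooling matches hand arithmetic and degenerates correctly", {
  # hand oracle: estimates (1,2,3), variances (1,1,1)
  out <- rubin_pool(matrix(c(1, 2, 3), 1), matrix(c(1, 1, 1), 1),
                    df_com = 10)
  expect_equal(out$estimate, 2, tolerance = 1e-12)
  expect_equal(out$b_between, 1, tolerance = 1e-12)
  expect_equal(out$u_bar, 1, tolerance = 1e-12)
  expect_equal(out$t_total, 1 + (4 / 3), tolerance = 1e-12)

  # identical fits: B = 0, T = U, df -> complete-data df, p = single-fit p
  out0 <- rubin_pool(matrix(2, 1, 4), matrix(0.25, 1, 4), df_com = 30)
  expect_equal(out0$b_between, 0)
  expect_equal(out0$t_total, 0.25)
  expect_equal(out0$df, 30)
  expect_equal(out0$p, 2 * pt(-abs(2 / 0.5), 30), tolerance = 1e-12)

  # adjusted df is monotone decreasing in the missing-information fraction
  lam_grid <- c(0.5, 0.2, 0.05, 0.01)
  nu <- vapply(lam_grid, function(l) {
    M <- 5; dfcom <- 50
    nu_obs <- ((dfcom + 1) / (dfcom + 3)) * dfcom * (1 - l)
    nu_old <- (M - 1) / l^2
    1 / (1 / nu_old + 1 / nu_obs)
  }, 0)
  expect_true(all(diff(nu) > 0))    # nu increases as lambda decreases
  expect_lt(max(nu), 50)            # never exceeds complete-data df

  expect_error(rubin_pool(matrix(1, 1, 1), matrix(1, 1, 1), 10), "M >= 2")
})

test_that("pooled variance always dominates the within-imputation variance", {
  set.seed(11)
  est <- matrix(rnorm(50 * 5), 50, 5)
  va <- matrix(rgamma(50 * 5, 3, 3), 50, 5)
  out <- rubin_pool(est, va, df_com = 40)
  expect_true(all(out$t_total >= out$u_bar))
  expect_true(all(out$t_total > out$u_bar | out$b_between == 0))
  expect_true(all(out$df <= 40 + 1e-9))
})

test_that("the MI pipeline reduces to the direct pipeline at zero missingness", {
  st <- small_study()
  spec <- design_spec("sle_sum")
  de <- run_de(st$counts, st$cohort, spec)
  mi <- mi_de(st$counts, st$cohort, spec, M = 3, bin_size = 100,
              max_iter = 2, seed = 1)
  expect_lt(max(abs(mi[de$gene_id, "t"] - de$t)), 1e-8)
  expect_true(all(mi$b_between == 0))
})

test_that("random-forest single imputation is deterministic and recovers structure", {
  st <- small_study()
  expect_identical(single_impute(st$cohort, seed = 1), st$cohort)

  # covariate that is an exact linear function of another is recovered
  set.seed(12)
  co <- gen_exposures(gen_covariates(500, seed = 12), seed = 12)
  co$proxy <- 2 * co$maternal_age + 5
  com <- inject_missingness(co, "MCAR", rates = c(proxy = 0.2), seed = 13)
  filled <- single_impute(com, seed = 14, exposure_cols = "sle_sum",
                          columns = c("proxy", "maternal_age", "bmi"))
  mis <- is.na(com$proxy)
  expect_gt(cor(filled$proxy[mis], co$proxy[mis]), 0.95)
  # observed cells untouched
  expect_identical(filled$proxy[!mis], co$proxy[!mis])
  # determinism
  filled2 <- single_impute(com, seed = 14, exposure_cols = "sle_sum",
                           columns = c("proxy", "maternal_age", "bmi"))
  expect_identical(filled, filled2)
})

test_that("rank concordance is a Spearman correlation on shared genes", {
  a <- data.frame(gene_id = paste0("g", 1:10), p = (1:10) / 100)
  expect_equal(rank_concordance(a, a), 1)
  b <- a
  b$p <- rev(b$p)
  expect_equal(rank_concordance(a, b), -1)
  c2 <- data.frame(gene_id = paste0("x", 1:5), p = runif(5))
  expect_error(rank_concordance(a, c2), "disjoint")
})
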