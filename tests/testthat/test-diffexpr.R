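# Precision weights, weighted fits, moderation, FDR, effect transforms.

test_that("precision weights are flat when variance is flat and track a real trend", {
  # equal-abundance genes: the mean-variance trend is a single point, so
  # weights are near-constant
  set.seed(1)
  n <- 100
  m <- matrix(rnbinom(500 * n, mu = 300, size = 30), 500, n)
  rownames(m) <- sprintf("g%03d", 1:500)
  colnames(m) <- sprintf("s%03d", 1:n)
  design <- cbind(1, rnorm(n))
  v <- estimate_precision_weights(m, design)
  expect_lt(diff(range(v$weights)) / median(v$weights), 0.1)

  # decreasing mean-variance trend: weights grow with abundance
  mu <- rep(2^seq(3, 10, length.out = 200), each = 1)
  m2 <- t(vapply(mu, function(mm) rnbinom(n, mu = mm, size = 1 / 0.3),
                 numeric(n)))
  dimnames(m2) <- list(sprintf("h%03d", 1:200), sprintf("s%03d", 1:n))
  v2 <- estimate_precision_weights(m2, design)
  expect_gt(cor(rowMeans(v2$weights), mu, method = "spearman"), 0.9)

  expect_error(estimate_precision_weights(m[, 1:2], cbind(1, c(0, 1))),
               "residual degrees")
})

test_that("weighted fits match an exact line, a normal-equation oracle, and weight symmetries", {
  # exact line: slope 1, zero residual variance
  e <- matrix(c(1, 2, 3), 1, dimnames = list("g1", c("a", "b", "c")))
  x <- cbind(intercept = 1, slope = c(0, 1, 2))
  el <- new("EList", list(E = e, weights = matrix(1, 1, 3), design = x))
  fit <- fit_weighted(el)
  expect_equal(unname(fit$coefficients[1, "slope"]), 1, tolerance = 1e-12)
  expect_equal(unname(fit$sigma[1]), 0, tolerance = 1e-10)

  # random data + random weights vs brute-force normal equations
  set.seed(4)
  n <- 25
  X <- cbind(1, rnorm(n), rbinom(n, 1, 0.4))
  colnames(X) <- c("i", "x1", "x2")
  y <- matrix(rnorm(3 * n), 3, n, dimnames = list(paste0("g", 1:3), NULL))
  w <- matrix(rgamma(3 * n, 4, 4), 3, n)
  elw <- new("EList", list(E = y, weights = w, design = X))
  fitw <- fit_weighted(elw)
  for (g in 1:3) {
    o <- naive_wls(X, y[g, ], w[g, ])
    expect_equal(unname(fitw$coefficients[g, ]), unname(o$beta),
                 tolerance = 1e-10)
    expect_equal(unname(fitw$sigma[g]^2), o$s2, tolerance = 1e-10)
    expect_equal(unname(fitw$stdev.unscaled[g, ]^2), unname(o$v_unscaled),
                 tolerance = 1e-10)
  }

  # rescaling all weights by c > 0 leaves t-statistics unchanged
  el5 <- new("EList", list(E = y, weights = 5 * w, design = X))
  f5 <- fit_weighted(el5)
  t1 <- fitw$coefficients[, 2] / (fitw$sigma * fitw$stdev.unscaled[, 2])
  t2 <- f5$coefficients[, 2] / (f5$sigma * f5$stdev.unscaled[, 2])
  expect_equal(t1, t2, tolerance = 1e-10)

  # duplicating a sample at half weight reproduces the original fit
  Xd <- rbind(X, X[1, ])
  yd <- cbind(y, y[, 1])
  wd <- cbind(w, w[, 1])
  wd[, 1] <- w[, 1] / 2
  wd[, n + 1] <- w[, 1] / 2
  eld <- new("EList", list(E = yd, weights = wd, design = Xd))
  fd <- fit_weighted(eld)
  expect_equal(fd$coefficients, fitw$coefficients, tolerance = 1e-10)
})

test_that("moderation has the right limits and recovers a known prior", {
  st <- small_study()
  spec <- design_spec("sle_sum")
  ids <- complete_rows(st$cohort, spec)
  pp <- preprocess_counts(st$counts[, ids])
  design <- build_design(st$cohort[ids, ], spec)
  v <- estimate_precision_weights(pp$dge, design)
  fit <- fit_weighted(v)

  # d0 = 0: moderated t equals the ordinary t exactly
  r0 <- ebayes_moderate(fit, "sle_sum", prior_df = 0)
  gf <- gene_fit(fit, "sle_sum")
  t_ord <- gf$beta / (sqrt(gf$sigma2) * gf$stdev_unscaled)
  expect_equal(r0$t, unname(t_ord), tolerance = 1e-12)

  # d0 = Inf: all posterior variances collapse to the common prior
  rI <- ebayes_moderate(fit, "sle_sum", prior_df = Inf)
  expect_equal(unname(rI$s2_post), rep(mean(gf$sigma2), nrow(gf)),
               tolerance = 1e-12)

  # agreement with the reference empirical-Bayes implementation
  eb <- limma::eBayes(fit)
  rr <- ebayes_moderate(fit, "sle_sum")
  expect_equal(rr$t, unname(eb$t[, "sle_sum"]), tolerance = 1e-8)
  expect_equal(rr$p, unname(eb$p.value[, "sle_sum"]), tolerance = 1e-8)

  # moment estimator recovers a known (d0 = 4, s02 = 2) prior
  set.seed(7)
  d <- 20
  sigma2_true <- 2 * 4 / rchisq(20000, 4)
  s2 <- sigma2_true * rchisq(20000, d) / d
  fd <- limma::fitFDist(s2, df1 = d)
  expect_lt(abs(fd$df2 - 4) / 4, 0.1)
  expect_lt(abs(fd$scale - 2) / 2, 0.1)
})

test_that("BH adjustment matches the hand step-up and its order properties", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.1, NaN)), "NaN")
  expect_error(bh_adjust(c(0.1, 1.2)), "outside")

  set.seed(8)
  p <- runif(200)^2
  q <- bh_adjust(p)
  expect_equal(q, naive_bh(p), tolerance = 1e-12)
  expect_true(all(q >= p))
  expect_true(all(which(q < 0.05) %in% which(q < 0.10)))
})

test_that("percent change matches the published effect translations", {
  expect_equal(round(percent_change(0.07), 1), 5.0)
  expect_equal(round(percent_change(-0.04), 1), -2.7)
  expect_equal(round(percent_change(-0.03), 1), -2.1)
  expect_equal(percent_change(0), 0)
  expect_equal(percent_change(1), 100)
})

test_that("the complete-data pipeline is permutation-invariant and powered at large effects", {
  st <- small_study()
  spec <- design_spec("sle_sum")
  de <- run_de(st$counts, st$cohort, spec)

  set.seed(9)
  perm <- sample(ncol(st$counts$counts))
  de_p <- run_de(st$counts[, perm], st$cohort[perm, ], spec)
  expect_equal(de[de$gene_id, "t"], de_p[de$gene_id, "t"],
               tolerance = 1e-10)

  # planted large effects are detected
  co <- gen_exposures(gen_covariates(150, seed = 33), seed = 33)
  sim <- gen_counts(co, n_genes = 300,
                    sle_effects = rep(0.5, 20), seed = 33)
  deP <- run_de(sim$counts, co, design_spec("sle_sum", mediators = FALSE))
  planted <- intersect(sim$truth$gene_id[sim$truth$beta_sle != 0],
                       deP$gene_id)
  expect_gt(mean(deP[planted, "q"] < 0.05), 0.8)
  expect_lte(attr(deP, "n_sig_05"), attr(deP, "n_sig_10"))

  # interaction term null: p-values uniform
  ix <- run_de(st$counts, st$cohort, design_spec("interaction"))
  ks <- suppressWarnings(ks.test(ix$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})
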