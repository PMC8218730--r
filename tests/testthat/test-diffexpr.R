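test_that("gene filter keeps total >= 10 and detected >= 2, boundaries exact", {
  v <- rbind(
    keep_boundary = c(5, 5, rep(0, 14)),   # total 10, detected 2 -> kept
    drop_single   = c(10, rep(0, 15)),     # detected in 1 sample -> removed
    drop_total    = c(4, 5, rep(0, 14)),   # total 9 -> removed
    keep_rich     = rep(3, 16)
  )
  colnames(v) <- paste0("s", 1:16)
  m <- expr_matrix(v, "counts")
  f <- suppressMessages(filter_genes(m))
  expect_equal(gene_ids(f), c("keep_boundary", "keep_rich"))
  expect_error(suppressMessages(filter_genes(subset_expr(m, genes = "drop_total"))),
               "no genes pass")
})

test_that("gene filter is idempotent and equals the rule-check oracle on random input", {
  set.seed(31)
  v <- matrix(rpois(50 * 16, 1.2), 50, 16,
              dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:16)))
  m <- expr_matrix(v, "counts")
  f1 <- suppressMessages(filter_genes(m))
  oracle <- rownames(v)[apply(v, 1, function(y) sum(y) >= 10 && sum(y > 0) >= 2)]
  expect_identical(gene_ids(f1), oracle)
  f2 <- suppressMessages(filter_genes(f1))
  expect_identical(f2$values, f1$values)
})

test_that("size factors: symmetry, scaling, geometric-mean convention", {
  v <- matrix(rep(c(5, 10, 20, 40), 4), 4, 4, byrow = FALSE,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:4)))
  m <- expr_matrix(v, "counts")
  expect_equal(unname(size_factors(m)), rep(1, 4))
  v2 <- v; v2[, 2] <- v2[, 2] * 2
  sf <- size_factors(expr_matrix(v2, "counts"))
  expect_equal(unname(sf[2] / sf[1]), 2)
  set.seed(32)
  vr <- matrix(rpois(80, 30) + 1, 20, 4,
               dimnames = list(paste0("g", 1:20), paste0("s", 1:4)))
  sfr <- size_factors(expr_matrix(vr, "counts"))
  expect_lt(abs(exp(mean(log(sfr))) - 1), 1e-12)
  all_zero <- expr_matrix(matrix(c(0L, 5L, 5L, 0L), 2, 2,
                                 dimnames = list(c("a", "b"), c("s1", "s2"))), "counts")
  expect_error(size_factors(all_zero), "positive counts in all samples")
})

test_that("size factors agree with the DESeq2 median-of-ratios construction", {
  set.seed(33)
  v <- matrix(rnbinom(200 * 8, mu = 50, size = 10), 200, 8,
              dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:8)))
  v[, 3] <- v[, 3] * 3L
  m <- expr_matrix(v, "counts")
  mine <- size_factors(m)
  ref <- suppressMessages(DESeq2::estimateSizeFactorsForMatrix(v))
  # same construction up to the geometric-mean-1 rescaling convention
  expect_equal(unname(mine / mine[1]), unname(ref / ref[1]), tolerance = 1e-10)
})

test_that("NB GLM on a constant gene matches the closed-form intercept fit", {
  y <- rep(7, 16)
  X <- matrix(1, 16, 1, dimnames = list(NULL, "(Intercept)"))
  fit <- fit_nb_glm(y, X, rep(1, 16))
  expect_equal(unname(fit$coefficients), log(7), tolerance = 1e-6)
  # constant data are equidispersed: alpha collapses to the floor
  expect_lt(fit$dispersion, 1e-6)
  expect_equal(fit$loglik, sum(dpois(y, 7, log = TRUE)), tolerance = 1e-4)
  # with size factors the offset shifts the intercept
  sf <- rep(2, 16)
  fit2 <- fit_nb_glm(y, X, sf)
  expect_equal(unname(fit2$coefficients), log(7 / 2), tolerance = 1e-6)
})

test_that("NB GLM agrees with MASS::glm.nb on overdispersed data", {
  set.seed(34)
  meta <- canonical_sample_metadata()
  X <- design_matrices(meta, "C1")$full
  mu <- exp(drop(X %*% c(4, 0.2, -0.1, 0.3, 0.5, -0.8)))
  y <- rnbinom(16, mu = mu, size = 1 / 0.08)
  fit <- fit_nb_glm(y, X, rep(1, 16), cr_adjust = FALSE)  # ML, like glm.nb
  df <- data.frame(y = y, meta)
  ref <- suppressWarnings(MASS::glm.nb(y ~ pool + td + phenotype, data = df))
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-4)
  expect_equal(fit$dispersion, 1 / ref$theta, tolerance = 1e-3)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-6)
})

test_that("rank-deficient designs are rejected", {
  y <- rpois(8, 20)
  X <- cbind(1, rep(c(0, 1), 4), rep(c(0, 1), 4))
  expect_error(fit_nb_glm(y, X, rep(1, 8)), "rank deficient")
})

test_that("Poisson-simulated data drive the dispersion to the floor", {
  # Fisher information at alpha = 0 gives sd(alpha_hat) ~ sqrt(2/(n mu^2)),
  # so estimates concentrate at the 1e-8 floor with a ~0.0035-sd upper half
  set.seed(35)
  X <- matrix(1, 16, 1)
  alpha_hat <- replicate(200, fit_nb_glm(rpois(16, 100), X, rep(1, 16))$dispersion)
  expect_lt(median(alpha_hat), 1e-4)
  expect_gt(mean(alpha_hat < 1e-3), 0.5)
  expect_lt(quantile(alpha_hat, 0.99), 0.02)
})

test_that("LRT: identity case, reparameterization and reordering invariance", {
  set.seed(36)
  meta <- canonical_sample_metadata()
  dm <- design_matrices(meta, "C1")
  y <- rnbinom(16, mu = 60, size = 20)
  sf <- rep(1, 16)
  full <- fit_nb_glm(y, dm$full, sf)
  self <- lrt_test(full, full)
  expect_equal(self$lrt_stat, 0)
  expect_equal(self$p_raw, 1)
  reduced <- fit_nb_glm(y, dm$reduced, sf, dispersion = full$dispersion)
  lr <- lrt_test(full, reduced)
  expect_gte(lr$lrt_stat, 0)
  # different pool reference level -> same statistic
  meta2 <- meta
  meta2$pool <- factor(meta2$pool, levels = c("pool3", "pool1", "pool2", "pool4"))
  dm2 <- design_matrices(meta2, "C1")
  full2 <- fit_nb_glm(y, dm2$full, sf, dispersion = full$dispersion)
  reduced2 <- fit_nb_glm(y, dm2$reduced, sf, dispersion = full$dispersion)
  lr2 <- lrt_test(full2, reduced2)
  full_fix <- fit_nb_glm(y, dm$full, sf, dispersion = full$dispersion)
  lr_fix <- lrt_test(full_fix, reduced)
  expect_equal(lr2$lrt_stat, lr_fix$lrt_stat, tolerance = 1e-6)
  # sample reordering
  perm <- sample(16)
  dmp <- dm; dmp$full <- dm$full[perm, ]; dmp$reduced <- dm$reduced[perm, ]
  fullp <- fit_nb_glm(y[perm], dmp$full, sf, dispersion = full$dispersion)
  redp <- fit_nb_glm(y[perm], dmp$reduced, sf, dispersion = full$dispersion)
  expect_equal(lrt_test(fullp, redp)$lrt_stat, lr_fix$lrt_stat, tolerance = 1e-6)
  # rescaling all size factors by a constant
  fullc <- fit_nb_glm(y, dm$full, sf * 3, dispersion = full$dispersion)
  redc <- fit_nb_glm(y, dm$reduced, sf * 3, dispersion = full$dispersion)
  expect_equal(lrt_test(fullc, redc)$lrt_stat, lr_fix$lrt_stat, tolerance = 1e-6)
})

test_that("Holm adjustment matches the hand-computed and brute-force oracles", {
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(0.3), 0.3)
  set.seed(37)
  for (i in 1:25) {
    m <- sample(1:12, 1)
    p <- round(runif(m), 3)  # rounding makes ties likely
    adj <- holm_adjust(p)
    expect_equal(adj, holm_oracle(p))
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("C1 fold-change sign follows the SSM-positive convention", {
  # spike one gene up in CD11c- (SSM) samples, one up in CD11c+ (MSM)
  cfg <- sim_config(n_genes = 60, seed = 38,
                    phenotype_effect_genes = stats::setNames(c(3, -3), c(1, 2)),
                    td_effect_genes = stats::setNames(numeric(0), integer(0)))
  sim <- generate_counts(cfg)
  f <- suppressMessages(filter_genes(sim$counts))
  fit <- suppressMessages(run_comparison(f, comparison = "C1"))
  res <- fit$results
  g_up_ssm <- sim$truth$genes$gene_id[sim$truth$genes$phenotype_log2fc == 3]
  g_up_msm <- sim$truth$genes$gene_id[sim$truth$genes$phenotype_log2fc == -3]
  expect_gt(res$log2_fc[res$gene_id == g_up_ssm], 1)
  expect_lt(res$log2_fc[res$gene_id == g_up_msm], -1)
  # the spiked genes dominate the ranking
  expect_true(all(c(g_up_ssm, g_up_msm) %in% res$gene_id[1:4]))
})

test_that("C2 recovers a tumor-draining effect with positive sign", {
  cfg <- sim_config(n_genes = 60, seed = 39,
                    phenotype_effect_genes = stats::setNames(numeric(0), integer(0)),
                    td_effect_genes = stats::setNames(3, 1))
  sim <- generate_counts(cfg)
  f <- suppressMessages(filter_genes(sim$counts))
  fit <- suppressMessages(run_comparison(f, comparison = "C2"))
  g <- sim$truth$genes$gene_id[sim$truth$genes$td_log2fc == 3]
  expect_gt(fit$results$log2_fc[fit$results$gene_id == g], 1)
  expect_equal(fit$results$gene_id[1], g)
})

test_that("DEG selection applies strict thresholds and splits by sign", {
  res <- data.frame(
    gene_id = paste0("g", 1:5),
    base_mean = c(150, 150, 100, 150, 150),
    log2_fc = c(1, -1, 1, 2, -2),
    dispersion = 0.05, lrt_stat = 10,
    p_raw = 0.001, p_holm = c(0.005, 0.005, 0.005, 0.01, NA),
    converged = TRUE
  )
  deg <- select_deg(res)
  expect_equal(deg$up$gene_id, "g1")    # g3: base_mean == 100 excluded
  expect_equal(deg$down$gene_id, "g2")  # g4: p_holm == 0.01 excluded; g5: NA
})

test_that("nb_lrt methods expose the fit", {
  cfg <- null_config(n_genes = 45, seed = 40)
  sim <- generate_counts(cfg)
  f <- suppressMessages(filter_genes(sim$counts))
  fit <- suppressMessages(run_comparison(f, comparison = "C1"))
  expect_s3_class(fit, "nb_lrt")
  expect_output(print(fit), "comparison C1")
  s <- summary(fit)
  expect_s3_class(s, "summary.nb_lrt")
  expect_output(print(s), "DEGs")
  cf <- coef(fit)
  expect_named(cf)
  expect_equal(sort(names(cf)), sort(gene_ids(f)))
  expect_equal(as.data.frame(fit), fit$results)
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})
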