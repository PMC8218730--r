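make_probe_fixture <- function(seed = 1, n_genes = 10, n_samples = 4) {
  set.seed(seed)
  k <- sample(1:3, n_genes, replace = TRUE)
  gene <- rep(paste0("g", seq_len(n_genes)), k)
  pid <- sprintf("p%03d", seq_along(gene))
  v <- matrix(rnorm(length(pid) * n_samples, 8, 2), nrow = length(pid),
              dimnames = list(pid, paste0("s", seq_len(n_samples))))
  probe_matrix(v, data.frame(probe_id = pid, gene_id = gene))
}

test_that("probe aggregation averages per gene and matches a group-by oracle", {
  # one probe per gene: identity
  pm1 <- probe_matrix(matrix(c(2, 4), 2, 1, dimnames = list(c("p1", "p2"), "s1")),
                      data.frame(probe_id = c("p1", "p2"), gene_id = c("gA", "gB")))
  agg1 <- aggregate_probes(pm1)
  expect_equal(unname(agg1$values[, 1]), c(2, 4))
  # two probes valued 2 and 4 -> 3
  pm2 <- probe_matrix(matrix(c(2, 4), 2, 1, dimnames = list(c("p1", "p2"), "s1")),
                      data.frame(probe_id = c("p1", "p2"), gene_id = c("gA", "gA")))
  expect_equal(unname(aggregate_probes(pm2)$values[, 1]), 3)
  # random fixture vs brute-force oracle
  pm <- make_probe_fixture(seed = 7)
  agg <- aggregate_probes(pm)
  for (g in gene_ids(agg)) {
    probes_g <- pm$probe_to_gene$probe_id[pm$probe_to_gene$gene_id == g]
    oracle <- colMeans(pm$values[probes_g, , drop = FALSE])
    expect_equal(agg$values[g, ], oracle)
  }
})

test_that("unmapped probes are dropped; fully unmapped input errors", {
  v <- matrix(1:4, 2, 2, dimnames = list(c("p1", "p2"), c("s1", "s2")))
  pm <- probe_matrix(v, data.frame(probe_id = "p1", gene_id = "gA"))
  expect_message(agg <- aggregate_probes(pm), "unmapped")
  expect_equal(nrow(agg$values), 1L)
  pm_none <- probe_matrix(v, data.frame(probe_id = character(), gene_id = character()))
  expect_error(aggregate_probes(pm_none), "unmapped")
})

test_that("log2 CPM transform follows its closed form and is depth-invariant", {
  m <- tiny_counts(matrix(c(7, 0, 0), 3, 1, dimnames = list(c("a", "b", "c"), "s1")))
  lt <- log_transform_counts(m)
  expect_equal(unname(lt$values[, 1]), c(log2(1e6 + 1), 0, 0))
  # doubling all counts in a sample leaves log2 CPM unchanged
  set.seed(2)
  v <- matrix(rpois(40, 20) + 1, 10, 4,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  m1 <- expr_matrix(v, "counts"); m2 <- expr_matrix(v * 2, "counts")
  expect_equal(log_transform_counts(m1)$values, log_transform_counts(m2)$values)
  zero <- expr_matrix(matrix(0, 2, 1, dimnames = list(c("a", "b"), "s1")), "counts")
  expect_error(log_transform_counts(zero), "zero column sum")
})

test_that("platform intersection keeps shared detected genes and is idempotent", {
  va <- matrix(1, 3, 2, dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  vb <- matrix(1, 3, 2, dimnames = list(c("B", "C", "D"), c("t1", "t2")))
  a <- expr_matrix(va, "counts"); b <- expr_matrix(vb, "counts")
  both <- intersect_platform_genes(a, b)
  expect_equal(gene_ids(both$a), c("B", "C"))
  expect_equal(gene_ids(both$b), c("B", "C"))
  again <- intersect_platform_genes(both$a, both$b)
  expect_equal(again$a$values, both$a$values)
  # all-zero counts do not count as detected
  va2 <- va; va2["B", ] <- 0
  both2 <- intersect_platform_genes(expr_matrix(va2, "counts"),
                                    expr_matrix(vb, "log2_intensity"))
  expect_equal(gene_ids(both2$a), "C")
  # all-NA intensities do not count as detected either; here nothing survives
  vb2 <- vb; vb2["C", ] <- NA
  expect_error(intersect_platform_genes(expr_matrix(va2, "counts"),
                                        expr_matrix(vb2, "log2_intensity")),
               "no genes")
})

test_that("standardization hits its postconditions and is idempotent", {
  m <- expr_matrix(matrix(c(1, 2, 3), 3, 1, dimnames = list(letters[1:3], "s1")),
                   "log2_intensity")
  z <- standardize_samples(m)
  expect_equal(unname(z$values[, 1]), c(-1, 0, 1))
  z2 <- standardize_samples(z)
  expect_equal(z2$values, z$values, tolerance = 1e-12)
  set.seed(3)
  r <- expr_matrix(matrix(rnorm(50, 5, 3), 10, 5,
                          dimnames = list(paste0("g", 1:10), paste0("s", 1:5))),
                   "log2_intensity")
  rz <- standardize_samples(r)
  expect_true(all(abs(colMeans(rz$values)) < 1e-9))
  expect_true(all(abs(apply(rz$values, 2, sd) - 1) < 1e-9))
  const <- expr_matrix(matrix(5, 3, 1, dimnames = list(letters[1:3], "flat")),
                       "log2_intensity")
  expect_error(standardize_samples(const), "flat")
})

test_that("platform means equal the row-mean oracle", {
  set.seed(4)
  v <- matrix(rnorm(20), 5, 4, dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  v <- apply(v, 2, function(x) (x - mean(x)) / sd(x))
  m <- expr_matrix(v, "standardized")
  expect_equal(platform_means(m), rowMeans(v))
  single <- expr_matrix(v[, 1, drop = FALSE], "standardized")
  expect_equal(platform_means(single), v[, 1])
})

test_that("cross-platform correlation endpoints and errors", {
  x <- c(1, 2, 3, 5)
  expect_equal(cross_platform_correlation(x, x), 1)
  expect_equal(cross_platform_correlation(x, -x), -1)
  expect_error(cross_platform_correlation(x, rep(1, 4)), "zero variance")
  expect_error(cross_platform_correlation(x, x[1:3]), "length")
})

test_that("harmonization chain is equivariant to gene order and invariant to sample order", {
  cfg <- null_config(n_genes = 80, seed = 21)
  sim <- generate_counts(cfg)
  probes <- generate_microarray(sim$truth, cfg)
  h <- suppressMessages(harmonize_platforms(sim$counts, probes))
  # permute genes and samples of the inputs
  set.seed(9)
  vp <- sim$counts$values[sample(nrow(sim$counts$values)),
                          sample(ncol(sim$counts$values))]
  counts_p <- expr_matrix(vp, "counts")
  counts_p$meta <- sim$counts$meta
  h2 <- suppressMessages(harmonize_platforms(counts_p, probes))
  expect_equal(h2$r, h$r, tolerance = 1e-12)
  m1 <- h$means; m2 <- h2$means[match(m1$gene_id, h2$means$gene_id), ]
  expect_equal(m2$rnaseq, m1$rnaseq, tolerance = 1e-12)
})
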