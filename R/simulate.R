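#' Configuration for the synthetic study generator
#'
#' Describes a synthetic version of the sorting study: a pooled factorial
#' design (`pools` x TD {0, 1} x phenotype {+, -}), negative-binomial counts
#' with gene-specific means and a common dispersion, phenotype / TD effects
#' on chosen genes, and additive lymphocyte contamination modelled as a
#' convex mixture: for gene g and sample s the expected count is
#' `mu_gs = L_s * pi_gp * [(1 - f_s) * m_g * 2^effects + f_s * l_g]`,
#' where `m_g` is the macrophage-compartment mean, `l_g` the lymphocyte
#' compartment mean (high for B/T markers, zero for macrophage markers,
#' equal to `m_g` for housekeeping and background genes), `f_s` the
#' per-sample contamination fraction, `pi_gp` a small gene-by-pool
#' log-normal perturbation shared within a pool, and `L_s` a log-uniform
#' library-size factor.
#'
#' The first genes of every simulated matrix are the canonical marker panels
#' (see [marker_panels()]); the remaining `background` genes carry the
#' phenotype / TD effects. Effects are expressed on the log2 scale with the
#' reporting convention of the differential-expression stage: a positive
#' phenotype effect means higher in CD11c- (SSM) samples, a positive TD
#' effect means higher in tumor-draining samples.
#'
#' @param n_genes Total number of genes, including the 37 marker genes.
#' @param pools Number of biological-replicate pools (default 4; the
#'   canonical design has 4 pools x 4 sorted fractions = 16 samples).
#' @param baseline_log2_mean_range Range of the gene-wise baseline mean on
#'   the log2 scale (means drawn log-uniformly).
#' @param dispersion_alpha NB dispersion: variance = mu + alpha * mu^2.
#'   Scalar or per-gene vector.
#' @param phenotype_effect_genes Named numeric vector: log2 effect per
#'   background gene index (indices into the non-marker genes), positive =
#'   up in SSM. `NULL` gives the default of 100 genes at +/- 2.
#' @param td_effect_genes Same, for the tumor-draining effect; default 30
#'   genes at +/- 1.
#' @param contamination_fractions Per-sample lymphocyte fraction `f` in
#'   [0, 1); scalar recycled or vector of length `4 * pools`. Default 0.02
#'   (a well-sorted preparation).
#' @param library_size_range Range of the log-uniform library-size factor.
#' @param pool_sd_log2 SD (log2 scale) of the shared within-pool gene
#'   perturbation.
#' @param lymph_log2_mean Log2 lymphocyte-compartment mean of B/T marker
#'   genes.
#' @param marker_log2_mean Log2 macrophage-compartment mean of macrophage
#'   and housekeeping marker genes.
#' @param probes_per_gene Possible probe counts per gene for the microarray
#'   twin (sampled uniformly).
#' @param probe_offset_sd SD of the per-probe additive offset (log2 scale).
#' @param noise_sd_array SD of per-cell Gaussian measurement noise on the
#'   microarray twin (log2 scale).
#' @param n_array_samples,array_contamination Sample count and per-sample
#'   contamination fractions of the microarray twin dataset (default: 8
#'   samples at f = 0.25, emulating a legacy sort with heavier lymphocyte
#'   carry-over).
#' @param seed Integer seed; all draws are consumed in a fixed order, so
#'   output is bit-reproducible.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_genes = 2000L,
                       pools = 4L,
                       baseline_log2_mean_range = c(1, 10),
                       dispersion_alpha = 0.05,
                       phenotype_effect_genes = NULL,
                       td_effect_genes = NULL,
                       contamination_fractions = 0.02,
                       library_size_range = c(0.5, 2),
                       pool_sd_log2 = 0.1,
                       lymph_log2_mean = 9,
                       marker_log2_mean = 8,
                       probes_per_gene = 1:4,
                       probe_offset_sd = 0.3,
                       noise_sd_array = 0.25,
                       n_array_samples = 8L,
                       array_contamination = 0.25,
                       seed = 1L) {
  n_markers <- length(unlist(marker_panels()))
  if (n_genes <= n_markers) stop("n_genes must exceed the ", n_markers,
                                 " marker genes", call. = FALSE)
  n_background <- n_genes - n_markers
  if (is.null(phenotype_effect_genes)) {
    k <- min(100L, n_background %/% 4L)
    phenotype_effect_genes <- stats::setNames(rep(c(2, -2), length.out = k), seq_len(k))
  }
  if (is.null(td_effect_genes)) {
    k <- min(30L, n_background %/% 8L)
    td_effect_genes <- stats::setNames(rep(c(1, -1), length.out = k),
                                       n_background %/% 2L + seq_len(k))
  }
  n_samples <- 4L * pools
  f <- rep_len(contamination_fractions, n_samples)
  f_arr <- rep_len(array_contamination, n_array_samples)
  cfg <- list(n_genes = as.integer(n_genes), pools = as.integer(pools),
              baseline_log2_mean_range = baseline_log2_mean_range,
              dispersion_alpha = dispersion_alpha,
              phenotype_effect_genes = phenotype_effect_genes,
              td_effect_genes = td_effect_genes,
              contamination_fractions = f,
              library_size_range = library_size_range,
              pool_sd_log2 = pool_sd_log2,
              lymph_log2_mean = lymph_log2_mean,
              marker_log2_mean = marker_log2_mean,
              probes_per_gene = probes_per_gene,
              probe_offset_sd = probe_offset_sd,
              noise_sd_array = noise_sd_array,
              n_array_samples = as.integer(n_array_samples),
              array_contamination = f_arr,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (any(contamination_fractions < 0) || any(contamination_fractions >= 1) ||
        any(array_contamination < 0) || any(array_contamination >= 1)) {
      stop("contamination fractions must lie in [0, 1)", call. = FALSE)
    }
    if (any(dispersion_alpha <= 0)) stop("dispersions must be > 0", call. = FALSE)
    if (any(library_size_range <= 0) || diff(library_size_range) < 0) {
      stop("library_size_range must be positive and increasing", call. = FALSE)
    }
    if (diff(baseline_log2_mean_range) < 0) {
      stop("baseline_log2_mean_range must be increasing", call. = FALSE)
    }
    n_bg <- n_genes - length(unlist(marker_panels()))
    idx <- c(as.integer(names(phenotype_effect_genes)),
             as.integer(names(td_effect_genes)))
    if (length(idx) && (anyNA(idx) || any(idx < 1L) || any(idx > n_bg))) {
      stop("effect gene indices must index the background genes (1..", n_bg, ")",
           call. = FALSE)
    }
  })
  invisible(cfg)
}

# run code with a locally-seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# gene-level ground truth shared by both platform generators
sim_gene_truth <- function(cfg) {
  panels <- marker_panels()
  marker_ids <- unlist(panels, use.names = FALSE)
  lineage <- rep(names(panels), vapply(panels, length, integer(1)))
  n_bg <- cfg$n_genes - length(marker_ids)
  bg_ids <- sprintf("gene%05d", seq_len(n_bg))
  gene_id <- c(marker_ids, bg_ids)
  lineage <- c(lineage, rep("background", n_bg))

  rng <- cfg$baseline_log2_mean_range
  base_log2 <- stats::runif(cfg$n_genes, rng[1], rng[2])
  m <- 2^base_log2
  l <- m  # housekeeping and background: identical in both compartments
  is_bt <- lineage %in% c("bcell", "tcell")
  is_mac <- lineage == "macrophage"
  is_hk <- lineage == "housekeeping"
  m[is_bt] <- 1                               # near-absent in macrophages
  l[is_bt] <- 2^cfg$lymph_log2_mean           # high in lymphocytes
  m[is_mac] <- 2^cfg$marker_log2_mean
  l[is_mac] <- 0                              # absent in lymphocytes
  m[is_hk] <- 2^cfg$marker_log2_mean
  l[is_hk] <- m[is_hk]

  pheno_fc <- td_fc <- rep(0, cfg$n_genes)
  bg_offset <- length(marker_ids)
  if (length(cfg$phenotype_effect_genes)) {
    pheno_fc[bg_offset + as.integer(names(cfg$phenotype_effect_genes))] <-
      cfg$phenotype_effect_genes
  }
  if (length(cfg$td_effect_genes)) {
    td_fc[bg_offset + as.integer(names(cfg$td_effect_genes))] <- cfg$td_effect_genes
  }
  alpha <- rep_len(cfg$dispersion_alpha, cfg$n_genes)
  data.frame(gene_id = gene_id, lineage = lineage,
             macro_mean = m, lymph_mean = l,
             phenotype_log2fc = pheno_fc, td_log2fc = td_fc,
             dispersion_alpha = alpha, stringsAsFactors = FALSE)
}

# expected counts mu_gs for a set of samples given gene truth;
# pool_mult: genes x pools matrix or NULL
sim_expected_mu <- function(genes, meta, f, lib, pool_mult = NULL) {
  # phenotype effect convention: positive = up in SSM (CD11c-)
  eff <- outer(genes$phenotype_log2fc, as.numeric(meta$phenotype == "-")) +
    outer(genes$td_log2fc, as.numeric(meta$td == 1L))
  macro <- genes$macro_mean * 2^eff
  mixed <- sweep(macro, 2L, 1 - f, "*") + outer(genes$lymph_mean, f)
  if (!is.null(pool_mult)) {
    mixed <- mixed * pool_mult[, as.integer(factor(meta$pool)), drop = FALSE]
  }
  mu <- sweep(mixed, 2L, lib, "*")
  dimnames(mu) <- list(genes$gene_id, meta$sample_id)
  mu
}

#' Generate a synthetic RNA-seq count dataset
#'
#' Draws a 4-pools x TD x phenotype count matrix from the mixture model
#' described in [sim_config()], together with the ground truth used to make
#' it. All randomness comes from `config$seed`; the caller's RNG state is
#' left untouched.
#'
#' @param config A [sim_config()].
#' @return List with `counts` (an `expr_matrix` of kind `counts` carrying
#'   the sample metadata) and `truth`, itself a list: `genes` (per-gene
#'   lineage label, compartment means, true log2 effects, dispersion),
#'   `samples` (per-sample contamination fraction and library size) and `mu`
#'   (the genes x samples expected-count matrix, useful for expectation-level
#'   checks).
#' @export
generate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    meta <- canonical_sample_metadata(pools = config$pools)
    genes <- sim_gene_truth(config)
    lib <- exp(stats::runif(nrow(meta), log(config$library_size_range[1]),
                            log(config$library_size_range[2])))
    pool_mult <- matrix(2^stats::rnorm(config$n_genes * config$pools,
                                       sd = config$pool_sd_log2),
                        nrow = config$n_genes)
    f <- config$contamination_fractions
    mu <- sim_expected_mu(genes, meta, f, lib, pool_mult)
    if (any(mu > 2^31)) stop("expected counts overflow guard: mu > 2^31",
                             call. = FALSE)
    counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                    size = 1 / rep(genes$dispersion_alpha, ncol(mu))),
                     nrow = nrow(mu), dimnames = dimnames(mu))
    storage.mode(counts) <- "double"
    samples <- data.frame(meta, contamination = f, library_size = lib,
                          stringsAsFactors = FALSE)
    cm <- expr_matrix(counts, "counts")
    cm$meta <- meta
    list(counts = cm, truth = list(genes = genes, samples = samples, mu = mu))
  })
}

#' Generate a microarray-like twin dataset
#'
#' Builds probe-level log2 intensities from the same gene-level ground truth
#' as [generate_counts()]. By default it simulates its own sample set (a
#' legacy-style dataset with `config$n_array_samples` samples, half CD11c-
#' and half CD11c+, at the heavier `config$array_contamination` fractions):
#' each array sample is an NB realization of its expected mixture
#' expression (biological replicates exist on both platforms), a gene's
#' per-sample log2 abundance is the log2 CPM of that realization, each gene
#' gets `k` probes (`k` drawn uniformly from `config$probes_per_gene`) whose
#' affinity offsets (`N(0, probe_offset_sd)`) are centered within the gene
#' (the gene-level abundance is defined as its probe average), and every
#' probe cell adds Gaussian measurement noise (`N(0, noise_sd_array)`).
#'
#' Passing `gene_values` (an `expr_matrix` of kind `log2_intensity`, e.g. the
#' log2 CPM of a realized count matrix) instead probe-ifies exactly those
#' values — the paired-platform mode used to check that harmonization
#' recovers platform agreement when no array noise is added.
#'
#' @param truth Ground truth from [generate_counts()].
#' @param config The same [sim_config()].
#' @param gene_values Optional `expr_matrix` of gene-level log2 values to
#'   probe-ify directly (paired-platform mode).
#' @return A `probe_matrix` (log2 intensities plus probe-to-gene map).
#' @export
generate_microarray <- function(truth, config, gene_values = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 1L, {
    if (is.null(gene_values)) {
      genes <- truth$genes
      n_arr <- config$n_array_samples
      meta <- data.frame(
        sample_id = sprintf("array%02d_%s", seq_len(n_arr),
                            rep_len(c("cd11cneg", "cd11cpos"), n_arr)),
        pool = "arraypool", td = 0L,
        phenotype = factor(rep_len(c("-", "+"), n_arr), levels = c("-", "+")),
        platform = "microarray", stringsAsFactors = FALSE)
      mu <- sim_expected_mu(genes, meta, config$array_contamination,
                            rep(1, n_arr), pool_mult = NULL)
      # biological replicate variability: the array measures NB-realized
      # samples, just like the sequencing arm
      y <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                 size = 1 / rep(genes$dispersion_alpha, ncol(mu))),
                  nrow = nrow(mu), dimnames = dimnames(mu))
      gv <- log2(sweep(y, 2L, pmax(colSums(y), 1), "/") * 1e6 + 1)
    } else {
      stopifnot(inherits(gene_values, "expr_matrix"))
      gv <- gene_values$values
    }
    k <- sample(rep_len(config$probes_per_gene, max(2L, length(config$probes_per_gene))),
                nrow(gv), replace = TRUE)
    gene_of_probe <- rep(rownames(gv), k)
    probe_id <- sprintf("probe%06d", seq_along(gene_of_probe))
    # probe affinity offsets, centered within each gene: the gene-level
    # abundance is defined as the average over its probes
    offsets <- stats::rnorm(length(probe_id), sd = config$probe_offset_sd)
    offsets <- offsets - stats::ave(offsets, gene_of_probe)
    vals <- gv[gene_of_probe, , drop = FALSE] + offsets +
      matrix(stats::rnorm(length(probe_id) * ncol(gv), sd = config$noise_sd_array),
             nrow = length(probe_id))
    rownames(vals) <- probe_id
    probe_matrix(vals, data.frame(probe_id = probe_id, gene_id = gene_of_probe,
                                  stringsAsFactors = FALSE))
  })
}
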