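#' Filter weakly measured genes
#'
#' Removes genes with a cumulative read count smaller than 10 and genes
#' detected (count > 0) in fewer than 2 samples; both rules must hold to
#' keep a gene. Gene order is preserved and the removed count is logged.
#'
#' @param counts An `expr_matrix` of kind `counts`.
#' @param total_count_min Minimum cumulative count (default 10; `>=`).
#' @param min_detected_samples Minimum number of samples with a positive
#'   count (default 2; `>=`).
#' @return The filtered `expr_matrix`.
#' @export
filter_genes <- function(counts, total_count_min = 10, min_detected_samples = 2L) {
  stopifnot(inherits(counts, "expr_matrix"))
  if (counts$value_kind != "counts") stop("input must hold raw counts", call. = FALSE)
  v <- counts$values
  keep <- rowSums(v) >= total_count_min & rowSums(v > 0) >= min_detected_samples
  if (!any(keep)) stop("no genes pass the count filter", call. = FALSE)
  log_stage("filter", "kept %d of %d genes (removed %d)",
            sum(keep), nrow(v), sum(!keep))
  out <- subset_expr(counts, genes = rownames(v)[keep])
  out
}

#' Median-of-ratios size factors
#'
#' Per-sample scaling factors in the median-of-ratios construction: the
#' reference level of each gene is its geometric mean across samples, and a
#' sample's factor is the median over reference genes (genes with positive
#' counts in every sample) of count / reference. Factors are rescaled to
#' have geometric mean 1.
#'
#' @param counts An `expr_matrix` of kind `counts`.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  stopifnot(inherits(counts, "expr_matrix"))
  if (counts$value_kind != "counts") stop("input must hold raw counts", call. = FALSE)
  v <- counts$values
  ref <- rowSums(v > 0) == ncol(v)
  if (!any(ref)) stop("no gene has positive counts in all samples", call. = FALSE)
  log_geo <- rowMeans(log(v[ref, , drop = FALSE]))
  ratios <- log(v[ref, , drop = FALSE]) - log_geo
  sf <- exp(apply(ratios, 2L, stats::median))
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(v))
}

#' Design matrices for the two model comparisons
#'
#' Both comparisons share the full model
#' `log mu = b0 + pool + td + phenotype` (treatment coding; references:
#' first pool level, TD = 0, phenotype `-`). The reduced model drops the
#' factor under test: phenotype for `C1` (consistent SSM-vs-MSM expression
#' differences adjusting for TD and pool), TD for `C2` (tumor-draining
#' association adjusting for pool and phenotype). The degrees-of-freedom
#' difference is 1 in both.
#'
#' @param meta Sample metadata (see [read_sample_metadata()]).
#' @param comparison `"C1"` or `"C2"`.
#' @return List with `full`, `reduced` (numeric design matrices), `tested`
#'   (name of the tested coefficient) and `df` (= 1).
#' @export
design_matrices <- function(meta, comparison = c("C1", "C2")) {
  comparison <- match.arg(comparison)
  meta$pool <- factor(meta$pool)
  meta$phenotype <- factor(meta$phenotype, levels = c("-", "+"))
  full <- stats::model.matrix(~ pool + td + phenotype, data = meta)
  reduced <- if (comparison == "C1") {
    stats::model.matrix(~ pool + td, data = meta)
  } else {
    stats::model.matrix(~ pool + phenotype, data = meta)
  }
  if (qr(full)$rank < ncol(full)) stop("full design is rank deficient", call. = FALSE)
  list(full = full, reduced = reduced,
       tested = if (comparison == "C1") "phenotype+" else "td", df = 1L)
}

#' Per-gene differential expression by NB likelihood-ratio test
#'
#' The fitting function of the package. For every gene: fit the full NB GLM
#' (estimating the dispersion under the full model), re-fit the reduced
#' model at the same dispersion, form the likelihood-ratio statistic and its
#' chi-square (df = 1) p-value, then Holm-adjust across all tested genes.
#'
#' Fold changes follow the reporting convention of the study: under `C1` a
#' positive `log2_fc` means higher in CD11c- (SSM) samples; under `C2`
#' positive means higher in tumor-draining samples.
#'
#' @param counts Filtered `expr_matrix` of kind `counts` (see
#'   [filter_genes()]).
#' @param meta Sample metadata; defaults to the metadata attached to
#'   `counts`.
#' @param comparison `"C1"` (phenotype) or `"C2"` (tumor-draining status).
#' @param sf Size factors; computed with [size_factors()] when `NULL`.
#' @param cr_adjust Passed to [fit_nb_glm()].
#' @return An object of class `"nb_lrt"`: list with `results` (a
#'   `data.frame` sorted by `p_holm` then decreasing `|log2_fc|`, columns
#'   `gene_id`, `base_mean`, `log2_fc`, `dispersion`, `lrt_stat`, `p_raw`,
#'   `p_holm`, `converged`), `comparison`, `tested`, `size_factors`,
#'   `design` and the `call`. Non-converged genes keep their fit summaries
#'   but are excluded from testing (`p_raw`/`p_holm` are `NA`).
#' @seealso [select_deg()], [summary.nb_lrt()], [plot.nb_lrt()]
#' @export
run_comparison <- function(counts, meta = counts$meta,
                           comparison = c("C1", "C2"), sf = NULL,
                           cr_adjust = TRUE) {
  stopifnot(inherits(counts, "expr_matrix"))
  comparison <- match.arg(comparison)
  if (is.null(meta)) stop("sample metadata required", call. = FALSE)
  meta <- align_metadata(counts, validate_sample_metadata(meta))
  dm <- design_matrices(meta, comparison)
  if (is.null(sf)) sf <- size_factors(counts)
  sf <- sf[sample_ids(counts)]
  v <- counts$values
  norm <- sweep(v, 2L, sf, "/")
  base_mean <- rowMeans(norm)
  sign_flip <- if (comparison == "C1") -1 else 1

  n_genes <- nrow(v)
  res <- data.frame(gene_id = rownames(v), base_mean = base_mean,
                    log2_fc = NA_real_, dispersion = NA_real_,
                    lrt_stat = NA_real_, p_raw = NA_real_, p_holm = NA_real_,
                    converged = FALSE, row.names = NULL,
                    stringsAsFactors = FALSE)
  for (g in seq_len(n_genes)) {
    y <- v[g, ]
    full <- fit_nb_glm(y, dm$full, sf, cr_adjust = cr_adjust)
    reduced <- fit_nb_glm(y, dm$reduced, sf, dispersion = full$dispersion)
    res$log2_fc[g] <- sign_flip * full$coefficients[[dm$tested]] / log(2)
    res$dispersion[g] <- full$dispersion
    res$converged[g] <- full$converged && reduced$converged
    if (res$converged[g]) {
      lr <- lrt_test(full, reduced, df = dm$df)
      res$lrt_stat[g] <- lr$lrt_stat
      res$p_raw[g] <- lr$p_raw
    }
  }
  n_fail <- sum(!res$converged)
  if (n_fail > 0L) log_stage("de", "%d gene(s) failed to converge and were not tested",
                             n_fail)
  res$p_holm <- holm_adjust(res$p_raw)
  ord <- order(res$p_holm, -abs(res$log2_fc), res$gene_id)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  structure(list(results = res, comparison = comparison, tested = dm$tested,
                 size_factors = sf, design = dm, n_samples = ncol(v),
                 call = match.call()),
            class = "nb_lrt")
}

#' Select differentially expressed genes
#'
#' Strict thresholds on the Holm-adjusted p-value and the base mean
#' (average of size-factor-normalized counts): a gene is a DEG when
#' `p_holm < padj_max` and `base_mean > base_mean_min`. Results are
#' partitioned by fold-change sign.
#'
#' @param results An `nb_lrt` fit or its `results` data.frame.
#' @param padj_max Adjusted-p threshold (default 0.01, strict `<`).
#' @param base_mean_min Base-mean threshold (default 100 reads, strict `>`).
#' @return List with data.frames `up` (`log2_fc > 0`) and `down`
#'   (`log2_fc < 0`).
#' @export
select_deg <- function(results, padj_max = 0.01, base_mean_min = 100) {
  df <- if (inherits(results, "nb_lrt")) results$results else results
  keep <- !is.na(df$p_holm) & df$p_holm < padj_max & df$base_mean > base_mean_min
  deg <- df[keep, , drop = FALSE]
  list(up = deg[deg$log2_fc > 0, , drop = FALSE],
       down = deg[deg$log2_fc < 0, , drop = FALSE])
}
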