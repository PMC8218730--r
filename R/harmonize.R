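#' Probe-level intensity matrix
#'
#' Microarrays measure each gene with several probes distributed along its
#' mRNA; this container holds the probes x samples log2 intensities together
#' with the probe-to-gene annotation.
#'
#' @param values Numeric matrix (probes x samples) of log2 intensities, with
#'   unique probe identifiers as rownames and sample identifiers as colnames.
#' @param probe_to_gene `data.frame` with columns `probe_id` and `gene_id`;
#'   probes absent from the map are treated as unmapped.
#' @return An object of class `"probe_matrix"`.
#' @export
probe_matrix <- function(values, probe_to_gene) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    stop("unique probe identifiers (rownames) are required", call. = FALSE)
  }
  if (is.null(colnames(values)) || anyDuplicated(colnames(values))) {
    stop("unique sample identifiers (colnames) are required", call. = FALSE)
  }
  if (!is.data.frame(probe_to_gene) ||
      !all(c("probe_id", "gene_id") %in% names(probe_to_gene))) {
    stop("`probe_to_gene` must have columns probe_id and gene_id", call. = FALSE)
  }
  probe_to_gene$probe_id <- as.character(probe_to_gene$probe_id)
  probe_to_gene$gene_id <- as.character(probe_to_gene$gene_id)
  if (anyDuplicated(probe_to_gene$probe_id)) {
    stop("probe_to_gene maps some probe more than once", call. = FALSE)
  }
  structure(list(values = values, probe_to_gene = probe_to_gene),
            class = "probe_matrix")
}

#' @export
print.probe_matrix <- function(x, ...) {
  n_mapped <- sum(rownames(x$values) %in% x$probe_to_gene$probe_id)
  cat(sprintf("probe_matrix: %d probes (%d mapped) x %d samples, %d genes\n",
              nrow(x$values), n_mapped, ncol(x$values),
              length(unique(x$probe_to_gene$gene_id))))
  invisible(x)
}

#' Read / write a probe matrix
#'
#' The probe matrix uses the same TSV dialect as [read_expression_matrix()]
#' (first column `probe_id`); the map file has columns `probe_id`, `gene_id`.
#'
#' @param path,map_path Paths to the intensity TSV and the probe-to-gene TSV.
#' @return A `probe_matrix`.
#' @export
read_probe_matrix <- function(path, map_path) {
  m <- read_expression_matrix(path, value_kind = "log2_intensity")
  map <- utils::read.delim(map_path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", fileEncoding = "UTF-8")
  probe_matrix(m$values, map)
}

#' @rdname read_probe_matrix
#' @param x A `probe_matrix`.
#' @export
write_probe_matrix <- function(x, path, map_path) {
  v <- x$values
  body <- matrix(sprintf("%.17g", v), nrow = nrow(v))
  body[is.na(v)] <- "NA"
  writeLines(c(paste(c("probe_id", colnames(v)), collapse = "\t"),
               paste(rownames(v), apply(body, 1L, paste, collapse = "\t"), sep = "\t")),
             path, useBytes = TRUE)
  utils::write.table(x$probe_to_gene, map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Aggregate probes to gene level
#'
#' Groups probes by gene identifier and averages their values per sample
#' (arithmetic mean on the log2 scale), giving one row per mapped gene.
#' Unmapped probes are dropped with a logged count.
#'
#' @param probes A `probe_matrix`.
#' @return An `expr_matrix` of kind `log2_intensity`, genes in first-seen
#'   probe order.
#' @export
aggregate_probes <- function(probes) {
  stopifnot(inherits(probes, "probe_matrix"))
  v <- probes$values
  gene <- probes$probe_to_gene$gene_id[match(rownames(v), probes$probe_to_gene$probe_id)]
  unmapped <- is.na(gene)
  if (all(unmapped)) stop("all probes are unmapped", call. = FALSE)
  if (any(unmapped)) log_stage("aggregate_probes", "dropping %d unmapped probe(s)",
                               sum(unmapped))
  v <- v[!unmapped, , drop = FALSE]
  gene <- gene[!unmapped]
  gl <- factor(gene, levels = unique(gene))
  out <- apply(v, 2L, function(col) tapply(col, gl, mean, na.rm = TRUE))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1L, dimnames = list(levels(gl), colnames(v)))
  out[is.nan(out)] <- NA_real_
  expr_matrix(out, "log2_intensity")
}

#' Log2 counts-per-million transform
#'
#' Converts raw counts to `log2(1e6 * count / column_sum + 1)` (log2 CPM with
#' a pseudocount of 1). The per-sample scaling removes sequencing-depth
#' differences before standardization; the pseudocount maps zero counts to
#' exactly zero.
#'
#' @param counts An `expr_matrix` of kind `counts`.
#' @return An `expr_matrix` of kind `log2_intensity`.
#' @export
log_transform_counts <- function(counts) {
  stopifnot(inherits(counts, "expr_matrix"))
  if (counts$value_kind != "counts") stop("input must hold raw counts", call. = FALSE)
  cs <- colSums(counts$values)
  if (any(cs == 0)) {
    stop("zero column sum for sample(s): ",
         paste(colnames(counts$values)[cs == 0], collapse = ", "), call. = FALSE)
  }
  v <- log2(sweep(counts$values, 2L, cs, "/") * 1e6 + 1)
  out <- expr_matrix(v, "log2_intensity")
  out$meta <- counts$meta
  out
}

# genes considered detected: any count > 0 for count matrices,
# any non-missing value for intensity matrices
detected_genes <- function(m) {
  if (m$value_kind == "counts") {
    rownames(m$values)[rowSums(m$values > 0) >= 1L]
  } else {
    rownames(m$values)[rowSums(!is.na(m$values)) >= 1L]
  }
}

#' Restrict two platforms to their shared detected genes
#'
#' Cross-platform comparison only makes sense on genes measured on both
#' platforms, so genes detected on a single platform are filtered out.
#' Detection means at least one sample with a positive count (RNA-seq) or a
#' non-missing intensity (microarray).
#'
#' @param a,b `expr_matrix` objects indexed by gene.
#' @return A list with elements `a` and `b`, both restricted to the common
#'   genes in the same order (order of appearance in `a`).
#' @export
intersect_platform_genes <- function(a, b) {
  stopifnot(inherits(a, "expr_matrix"), inherits(b, "expr_matrix"))
  shared <- intersect(intersect(gene_ids(a), detected_genes(a)),
                      intersect(gene_ids(b), detected_genes(b)))
  if (length(shared) == 0L) stop("no genes detected on both platforms", call. = FALSE)
  log_stage("intersect", "%d genes detected on both platforms (from %d and %d)",
            length(shared), nrow(a$values), nrow(b$values))
  list(a = subset_expr(a, genes = shared), b = subset_expr(b, genes = shared))
}

#' Standardize each sample column
#'
#' Per sample: subtract the column mean and divide by the column standard
#' deviation (n - 1 denominator). Missing cells are ignored in the moments
#' and stay missing in the output.
#'
#' @param m An `expr_matrix`.
#' @return An `expr_matrix` of kind `standardized`.
#' @export
standardize_samples <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  v <- m$values
  mu <- colMeans(v, na.rm = TRUE)
  sdv <- apply(v, 2L, stats::sd, na.rm = TRUE)
  if (any(is.na(sdv)) || any(sdv == 0)) {
    bad <- colnames(v)[is.na(sdv) | sdv == 0]
    stop("constant column(s), cannot standardize: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  z <- sweep(sweep(v, 2L, mu, "-"), 2L, sdv, "/")
  out <- expr_matrix(z, "standardized")
  out$meta <- m$meta
  out
}

#' Platform-wise gene means
#'
#' Gene-specific expression level of a platform: the average of that
#' platform's (standardized) data points for each gene.
#'
#' @param m An `expr_matrix`, normally of kind `standardized`.
#' @return Named numeric vector, one mean per gene.
#' @export
platform_means <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  rowMeans(m$values, na.rm = TRUE)
}

#' Pearson correlation between platform mean vectors
#'
#' @param mean_a,mean_b Numeric vectors of per-gene platform means, in
#'   matched gene order, length >= 3.
#' @return Pearson product-moment correlation coefficient.
#' @export
cross_platform_correlation <- function(mean_a, mean_b) {
  if (length(mean_a) != length(mean_b)) stop("vectors differ in length", call. = FALSE)
  keep <- !is.na(mean_a) & !is.na(mean_b)
  a <- mean_a[keep]; b <- mean_b[keep]
  if (length(a) < 3L) stop("need at least 3 paired values", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero variance in a platform mean vector", call. = FALSE)
  }
  stats::cor(a, b)
}

#' Full cross-platform harmonization chain
#'
#' Convenience wrapper running the comparison workflow: log2 CPM transform of
#' the RNA-seq counts, probe aggregation of the microarray, platform gene
#' intersection, per-sample standardization, platform-wise averaging, and the
#' comparability Pearson correlation.
#'
#' @param counts RNA-seq `expr_matrix` of kind `counts`.
#' @param probes Microarray `probe_matrix`.
#' @param normalization `"log2cpm1"` (default) or `"log2count1"`
#'   (`log2(count + 1)` without depth scaling).
#' @return List with the two standardized matrices (`rnaseq`, `microarray`),
#'   the per-gene platform means, the shared gene set, and `r`, the Pearson
#'   correlation between the platform means.
#' @export
harmonize_platforms <- function(counts, probes, normalization = c("log2cpm1", "log2count1")) {
  normalization <- match.arg(normalization)
  rna <- if (normalization == "log2cpm1") {
    log_transform_counts(counts)
  } else {
    out <- expr_matrix(log2(counts$values + 1), "log2_intensity")
    out$meta <- counts$meta
    out
  }
  arr <- aggregate_probes(probes)
  both <- intersect_platform_genes(rna, arr)
  rna_z <- standardize_samples(both$a)
  arr_z <- standardize_samples(both$b)
  mean_rna <- platform_means(rna_z)
  mean_arr <- platform_means(arr_z)
  r <- cross_platform_correlation(mean_rna, mean_arr)
  log_stage("harmonize", "%d shared genes, cross-platform Pearson r = %.4f",
            length(mean_rna), r)
  list(rnaseq = rna_z, microarray = arr_z,
       means = data.frame(gene_id = names(mean_rna), rnaseq = unname(mean_rna),
                          microarray = unname(mean_arr), stringsAsFactors = FALSE),
       genes = names(mean_rna), r = r, normalization = normalization)
}
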