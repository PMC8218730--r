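#' Expression matrix container
#'
#' Lightweight container for a genes x samples expression matrix together
#' with the kind of values it holds and (optionally) per-sample metadata.
#' Three value kinds are supported: `"counts"` (non-negative integers, e.g.
#' RNA-seq read counts), `"log2_intensity"` (log2-scale expression, e.g.
#' microarray intensities or log2 CPM), and `"standardized"` (per-sample
#' z-scores; every column has mean 0 and unit standard deviation).
#'
#' @param values Numeric matrix with unique gene identifiers as rownames and
#'   unique sample identifiers as colnames.
#' @param value_kind One of `"counts"`, `"log2_intensity"`, `"standardized"`.
#' @param meta Optional sample metadata `data.frame` (see
#'   [read_sample_metadata()]); its `sample_id` column must match the matrix
#'   columns one-to-one.
#' @return An object of class `"expr_matrix"`: a list with elements `values`,
#'   `value_kind` and `meta`.
#' @examples
#' m <- matrix(0:5, nrow = 3, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' expr_matrix(m, "counts")
#' @export
expr_matrix <- function(values, value_kind = c("counts", "log2_intensity", "standardized"),
                        meta = NULL) {
  value_kind <- match.arg(value_kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  x <- structure(list(values = values, value_kind = value_kind, meta = meta),
                 class = "expr_matrix")
  validate_expr_matrix(x)
  x
}

#' Validate an expression matrix
#'
#' Checks the invariants of the container: unique gene/sample identifiers
#' matching the matrix dimensions; counts are non-negative integers with no
#' missing cells; standardized columns have mean 0 and standard deviation 1
#' within `1e-9`; metadata (when present) covers exactly the matrix samples.
#'
#' @param x An `expr_matrix`.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_expr_matrix <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  v <- x$values
  gid <- rownames(v)
  sid <- colnames(v)
  if (is.null(gid) || anyNA(gid) || any(gid == "")) {
    stop("gene identifiers (rownames) are required", call. = FALSE)
  }
  if (is.null(sid) || anyNA(sid) || any(sid == "")) {
    stop("sample identifiers (colnames) are required", call. = FALSE)
  }
  if (anyDuplicated(gid)) {
    stop("duplicate gene identifiers: ",
         paste(unique(gid[duplicated(gid)]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(sid)) {
    stop("duplicate sample identifiers: ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "), call. = FALSE)
  }
  if (x$value_kind == "counts") {
    if (anyNA(v)) stop("missing values are not permitted in counts", call. = FALSE)
    if (any(v < 0)) stop("negative values are not permitted in counts", call. = FALSE)
    if (any(v != round(v))) stop("counts must be integers", call. = FALSE)
  }
  if (x$value_kind == "standardized") {
    mu <- colMeans(v, na.rm = TRUE)
    sdv <- apply(v, 2, stats::sd, na.rm = TRUE)
    if (any(abs(mu) > 1e-9) || any(abs(sdv - 1) > 1e-9)) {
      stop("standardized columns must have mean 0 and sd 1 (tolerance 1e-9)",
           call. = FALSE)
    }
  }
  if (!is.null(x$meta)) {
    if (!is.data.frame(x$meta) || is.null(x$meta$sample_id)) {
      stop("`meta` must be a data.frame with a sample_id column", call. = FALSE)
    }
    if (!setequal(x$meta$sample_id, sid) || nrow(x$meta) != length(sid)) {
      stop("metadata samples do not match matrix samples", call. = FALSE)
    }
  }
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix [%s]: %d genes x %d samples\n",
              x$value_kind, nrow(x$values), ncol(x$values)))
  if (!is.null(x$meta)) cat("with sample metadata:",
                            paste(setdiff(names(x$meta), "sample_id"), collapse = ", "), "\n")
  n <- min(5L, nrow(x$values))
  k <- min(5L, ncol(x$values))
  print(x$values[seq_len(n), seq_len(k), drop = FALSE])
  if (nrow(x$values) > n || ncol(x$values) > k) cat("...\n")
  invisible(x)
}

#' Gene and sample identifiers of an expression matrix
#' @param x An `expr_matrix` or `probe_matrix`.
#' @return Character vector of identifiers.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Subset an expression matrix by gene and/or sample identifiers
#'
#' @param x An `expr_matrix`.
#' @param genes,samples Character vectors of identifiers to keep (in the
#'   given order); `NULL` keeps everything.
#' @return An `expr_matrix` of the same kind.
#' @export
subset_expr <- function(x, genes = NULL, samples = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  v <- x$values
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(v))
    if (length(missing)) stop("unknown genes: ", paste(missing, collapse = ", "),
                              call. = FALSE)
    v <- v[genes, , drop = FALSE]
  }
  meta <- x$meta
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(v))
    if (length(missing)) stop("unknown samples: ", paste(missing, collapse = ", "),
                              call. = FALSE)
    v <- v[, samples, drop = FALSE]
    if (!is.null(meta)) meta <- meta[match(samples, meta$sample_id), , drop = FALSE]
  }
  out <- structure(list(values = v, value_kind = x$value_kind, meta = meta),
                   class = "expr_matrix")
  # subsetting a standardized matrix by genes breaks the column moments,
  # so revalidate only for kinds whose invariants survive subsetting
  if (x$value_kind != "standardized" || is.null(genes)) validate_expr_matrix(out)
  out
}
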