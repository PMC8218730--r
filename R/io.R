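#' Read an expression matrix from a tab-separated file
#'
#' Expects a TSV with gene identifiers in the first column and sample
#' identifiers in the header; the body must be numeric. The dialect is
#' tab-separated UTF-8 with `.` as decimal separator and no quoting, the
#' format of typical GEO supplementary count/intensity matrices.
#'
#' @param path Path to the TSV file.
#' @param value_kind Declared kind of the values (see [expr_matrix()]).
#' @return An `expr_matrix`.
#' @seealso [write_expression_matrix()]
#' @export
read_expression_matrix <- function(path, value_kind = c("counts", "log2_intensity", "standardized")) {
  value_kind <- match.arg(value_kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = NA, fileEncoding = "UTF-8")
  if (ncol(df) < 2L) stop("expected a gene-id column plus at least one sample column",
                          call. = FALSE)
  gid <- as.character(df[[1L]])
  body <- df[, -1L, drop = FALSE]
  non_numeric <- !vapply(body, is.numeric, logical(1))
  if (any(non_numeric)) {
    stop("non-numeric cells in sample column(s): ",
         paste(names(body)[non_numeric], collapse = ", "), call. = FALSE)
  }
  v <- as.matrix(body)
  storage.mode(v) <- "double"
  rownames(v) <- gid
  expr_matrix(v, value_kind)
}

#' Write an expression matrix to a tab-separated file
#'
#' Values are formatted with `%.17g` so that doubles survive a
#' write/read round trip bit-for-bit.
#'
#' @param x An `expr_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  validate_expr_matrix(x)
  v <- x$values
  body <- matrix(sprintf("%.17g", v), nrow = nrow(v))
  body[is.na(v)] <- "NA"
  lines <- c(
    paste(c("gene_id", colnames(v)), collapse = "\t"),
    paste(rownames(v), apply(body, 1L, paste, collapse = "\t"), sep = "\t")
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read sorted-sample metadata
#'
#' Reads the per-sample factor table of the sorting design: `sample_id`,
#' `pool` (biological replicate; lymph nodes pooled from 2 mice), `td`
#' (1 = tumor-draining lymph node, 0 = non-draining), `phenotype` (`+` =
#' CD11c+ medullary sinus macrophage, `-` = CD11c- sub-capsular sinus
#' macrophage) and `platform` (`rnaseq` or `microarray`).
#'
#' @param path Path to a TSV file with the columns above.
#' @return A validated `data.frame` with `pool` and `phenotype` as factors
#'   and `td` integer in `{0, 1}`.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", fileEncoding = "UTF-8")
  if (nrow(df) == 0L) stop("metadata file has no rows: ", path, call. = FALSE)
  validate_sample_metadata(df)
}

#' Validate a sample metadata table
#'
#' @param df A data.frame with columns `sample_id`, `pool`, `td`,
#'   `phenotype`, `platform`.
#' @return The coerced, validated data.frame.
#' @export
validate_sample_metadata <- function(df) {
  required <- c("sample_id", "pool", "td", "phenotype", "platform")
  missing <- setdiff(required, names(df))
  if (length(missing)) stop("missing metadata column(s): ",
                            paste(missing, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  td <- suppressWarnings(as.integer(as.character(df$td)))
  if (anyNA(td) || !all(td %in% c(0L, 1L))) {
    stop("td must be 0 (non-draining) or 1 (tumor-draining)", call. = FALSE)
  }
  ph <- as.character(df$phenotype)
  if (!all(ph %in% c("+", "-"))) {
    stop("phenotype must be '+' (CD11c+, MSM) or '-' (CD11c-, SSM)", call. = FALSE)
  }
  plat <- as.character(df$platform)
  if (!all(plat %in% c("rnaseq", "microarray"))) {
    stop("platform must be 'rnaseq' or 'microarray'", call. = FALSE)
  }
  out <- data.frame(
    sample_id = as.character(df$sample_id),
    pool = factor(as.character(df$pool)),
    td = td,
    phenotype = factor(ph, levels = c("-", "+")),
    platform = plat,
    stringsAsFactors = FALSE
  )
  out
}

#' Write sample metadata
#' @param meta Metadata data.frame (see [read_sample_metadata()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Canonical 16-sample sorting design
#'
#' The study design: 4 pools (each pooling lymph nodes from 2 mice), and for
#' each pool the four sorted fractions CD11c+/- from tumor-draining and
#' non-draining lymph nodes, i.e. 4 pools x TD {0, 1} x phenotype {+, -}
#' = 16 RNA-seq samples.
#'
#' @param pools Number of pools (default 4).
#' @param platform Platform label stamped on every sample.
#' @return A metadata data.frame with `4 * pools` rows.
#' @export
canonical_sample_metadata <- function(pools = 4L, platform = "rnaseq") {
  grid <- expand.grid(phenotype = c("-", "+"), td = c(0L, 1L),
                      pool = paste0("pool", seq_len(pools)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$sample_id <- sprintf("%s_td%d_%s", grid$pool, grid$td,
                            ifelse(grid$phenotype == "+", "cd11cpos", "cd11cneg"))
  grid$platform <- platform
  validate_sample_metadata(grid[, c("sample_id", "pool", "td", "phenotype", "platform")])
}

#' Check that a matrix and a metadata table describe the same samples
#'
#' @param x An `expr_matrix`.
#' @param meta A metadata data.frame.
#' @return The metadata reordered to the matrix column order.
#' @export
align_metadata <- function(x, meta) {
  sid <- sample_ids(x)
  if (!setequal(meta$sample_id, sid) || nrow(meta) != length(sid)) {
    stop("matrix and metadata sample sets differ", call. = FALSE)
  }
  meta[match(sid, meta$sample_id), , drop = FALSE]
}

# stage-tagged progress line on stderr
log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}
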