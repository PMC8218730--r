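#' Immune lineage marker panels
#'
#' The four marker shortlists used for contamination QC of sorted macrophage
#' preparations, derived from ImmPort lineage gene lists: B-cell and T-cell
#' panels flag lymphocyte carry-over (membrane blebs shed by fragile
#' macrophages stick to lymphocytes, creating mixed-marker sorted events),
#' the macrophage panel confirms the sorted lineage, and the housekeeping
#' panel is the low-variability reference used as the denominator of
#' contamination ratios. Gene symbols are mouse and are matched verbatim
#' (case-sensitive).
#'
#' @return Named list of character vectors: `bcell`, `tcell`,
#'   `housekeeping`, `macrophage`.
#' @export
marker_panels <- function() {
  list(
    bcell = c("Blnk", "Btk", "Cd19", "Cd79a", "Cd79b", "Cr2", "Fcgr2b",
              "Ighg3", "Ighm"),
    tcell = c("Cd247", "Cd28", "Cd3d", "Cd3e", "Cd3g", "Cd4", "Cd40lg",
              "Cd8a", "Cd8b1", "Icos", "Zap70"),
    housekeeping = c("Rpl37a", "B2m", "Hmbs", "Stx5a", "Psmb2", "Hnrnpab",
                     "Actb", "Qars"),
    macrophage = c("Csf1r", "Cd45", "Siglec1", "Cd48", "Lyz2", "Fos",
                   "Nr4a1", "H2-k1", "Ly6e")
  )
}

#' Lineage signature score per sample
#'
#' The signature value of a sample is the sum of the (standardized)
#' expression values of the panel's marker genes. Standardized values can be
#' negative, which would make downstream ratios ill-defined, so
#' `shift = "minzero"` (the default) first subtracts the global minimum of
#' the matrix so every value is non-negative; the shift preserves the
#' ordering of samples within a panel. Markers absent from the matrix are
#' skipped with a warning (cross-platform intersection can drop markers);
#' `n_markers_found` records how many were used.
#'
#' @param m An `expr_matrix`, normally of kind `standardized`.
#' @param panel Character vector of marker gene identifiers, or the name of
#'   a canonical panel (see [marker_panels()]).
#' @param shift `"minzero"` or `"none"`.
#' @param shift_value Optional explicit shift to subtract instead of the
#'   matrix minimum — use this to score two harmonized datasets on a common
#'   scale (pass the minimum over both matrices).
#' @return `data.frame` with columns `sample_id`, `panel`,
#'   `signature_value`, `n_markers_found`.
#' @export
score_signature <- function(m, panel, shift = c("minzero", "none"),
                            shift_value = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  shift <- match.arg(shift)
  panel_name <- "custom"
  if (is.character(panel) && length(panel) == 1L && panel %in% names(marker_panels())) {
    panel_name <- panel
    panel <- marker_panels()[[panel]]
  } else if (!is.null(names(panel)) || is.list(panel)) {
    panel <- as.character(unlist(panel))
  }
  found <- intersect(panel, gene_ids(m))
  if (length(found) == 0L) {
    stop("no panel gene present in the matrix", call. = FALSE)
  }
  if (length(found) < length(panel)) {
    warning(sprintf("panel '%s': %d of %d markers absent from matrix (%s)",
                    panel_name, length(panel) - length(found), length(panel),
                    paste(setdiff(panel, found), collapse = ", ")),
            call. = FALSE)
  }
  v <- m$values
  s <- if (shift == "minzero") {
    if (is.null(shift_value)) shift_value <- min(v, na.rm = TRUE)
    v[found, , drop = FALSE] - shift_value
  } else {
    v[found, , drop = FALSE]
  }
  data.frame(sample_id = colnames(v), panel = panel_name,
             signature_value = colSums(s, na.rm = TRUE),
             n_markers_found = length(found),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Contamination ratio of a lineage signature to the housekeeping signature
#'
#' The housekeeping signature has low variability across samples and serves
#' as the reference level; the ratio lineage / housekeeping quantifies that
#' lineage's contribution per sample.
#'
#' @param lineage,housekeeping `data.frame`s from [score_signature()] over
#'   the same samples.
#' @return `data.frame` with columns `sample_id`, `panel`, `ratio`.
#' @export
contamination_ratio <- function(lineage, housekeeping) {
  hk <- housekeeping$signature_value[match(lineage$sample_id, housekeeping$sample_id)]
  if (anyNA(hk)) stop("housekeeping scores missing for some samples", call. = FALSE)
  if (any(hk <= 0)) {
    stop("non-positive housekeeping signature; score with shift = \"minzero\" ",
         "so signature values are non-negative", call. = FALSE)
  }
  data.frame(sample_id = lineage$sample_id, panel = lineage$panel,
             ratio = lineage$signature_value / hk,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare contamination ratios between two datasets
#'
#' For each lineage panel, compares the per-sample housekeeping-referenced
#' ratios of two datasets with the two-sided Mann-Whitney test and reports
#' group medians alongside the U statistic and p-value.
#'
#' @param ratios_a,ratios_b `data.frame`s with columns `panel` and `ratio`
#'   (one row per sample and panel), e.g. built with [contamination_ratio()].
#' @param panels Panels to compare; default: all panels present in both.
#' @param mode Mann-Whitney mode, see [mann_whitney()].
#' @return An object of class `"contamination_report"`: a `data.frame` with
#'   one row per panel (`panel`, `n_a`, `n_b`, `median_a`, `median_b`, `U`,
#'   `p`, `method`).
#' @export
compare_contamination <- function(ratios_a, ratios_b, panels = NULL,
                                  mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (is.null(panels)) panels <- intersect(unique(ratios_a$panel), unique(ratios_b$panel))
  if (length(panels) == 0L) stop("no shared panels to compare", call. = FALSE)
  rows <- lapply(panels, function(p) {
    a <- ratios_a$ratio[ratios_a$panel == p]
    b <- ratios_b$ratio[ratios_b$panel == p]
    mw <- mann_whitney(a, b, mode = mode)
    data.frame(panel = p, n_a = length(a), n_b = length(b),
               median_a = stats::median(a), median_b = stats::median(b),
               U = mw$U, p = mw$p, method = mw$method,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("contamination_report", class(out))
  out
}

#' @export
print.contamination_report <- function(x, ...) {
  cat("Contamination ratio comparison (Mann-Whitney, two-sided)\n")
  df <- as.data.frame(unclass(x), stringsAsFactors = FALSE)
  df$p <- signif(df$p, 4)
  df$median_a <- signif(df$median_a, 4)
  df$median_b <- signif(df$median_b, 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Signature-based contamination report for two harmonized datasets
#'
#' End-to-end QC: scores every lineage panel on both standardized matrices
#' using a common `minzero` shift (the global minimum over both matrices, so
#' the two datasets share one scale), forms housekeeping-referenced ratios,
#' and compares the datasets per panel with the Mann-Whitney test.
#'
#' @param std_a,std_b Standardized `expr_matrix` objects on a shared gene set
#'   (see [harmonize_platforms()]).
#' @param panels Named list of marker panels; default [marker_panels()].
#' @param mode Mann-Whitney mode.
#' @return List with per-sample `signatures`, per-sample `ratios` (both with
#'   a `dataset` column), the `comparison` report and the `shift` used.
#' @export
contamination_report <- function(std_a, std_b, panels = marker_panels(),
                                 mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (!"housekeeping" %in% names(panels)) {
    stop("panels must include a 'housekeeping' reference panel", call. = FALSE)
  }
  shift_value <- min(min(std_a$values, na.rm = TRUE), min(std_b$values, na.rm = TRUE))
  score_all <- function(m, dataset) {
    sc <- lapply(names(panels), function(nm) {
      s <- score_signature(m, panels[[nm]], shift = "minzero", shift_value = shift_value)
      s$panel <- nm
      s
    })
    sc <- do.call(rbind, sc)
    sc$dataset <- dataset
    sc
  }
  sig <- rbind(score_all(std_a, "a"), score_all(std_b, "b"))
  ratio_for <- function(ds) {
    s <- sig[sig$dataset == ds, , drop = FALSE]
    hk <- s[s$panel == "housekeeping", , drop = FALSE]
    rr <- lapply(setdiff(names(panels), "housekeeping"), function(nm) {
      contamination_ratio(s[s$panel == nm, , drop = FALSE], hk)
    })
    out <- do.call(rbind, rr)
    out$dataset <- ds
    out
  }
  ratios <- rbind(ratio_for("a"), ratio_for("b"))
  cmp <- compare_contamination(ratios[ratios$dataset == "a", ],
                               ratios[ratios$dataset == "b", ], mode = mode)
  list(signatures = sig, ratios = ratios, comparison = cmp, shift = shift_value)
}
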