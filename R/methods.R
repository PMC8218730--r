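#' @export
print.nb_lrt <- function(x, n = 6L, ...) {
  df <- x$results
  cat(sprintf("NB GLM likelihood-ratio test, comparison %s (tested: %s)\n",
              x$comparison, x$tested))
  cat(sprintf("%d genes x %d samples; %d gene(s) failed to converge\n",
              nrow(df), x$n_samples, sum(!df$converged)))
  top <- utils::head(df, n)
  top$base_mean <- signif(top$base_mean, 4)
  top$log2_fc <- signif(top$log2_fc, 3)
  top$dispersion <- signif(top$dispersion, 3)
  top$lrt_stat <- signif(top$lrt_stat, 4)
  top$p_raw <- signif(top$p_raw, 3)
  top$p_holm <- signif(top$p_holm, 3)
  print(top, row.names = FALSE)
  if (nrow(df) > n) cat("...", nrow(df) - n, "more genes\n")
  invisible(x)
}

#' Summarize a differential-expression fit
#'
#' @param object An `nb_lrt` fit.
#' @param padj_max,base_mean_min DEG thresholds (see [select_deg()]).
#' @param ... Unused.
#' @return An object of class `"summary.nb_lrt"` with DEG counts and
#'   dispersion quantiles.
#' @export
summary.nb_lrt <- function(object, padj_max = 0.01, base_mean_min = 100, ...) {
  deg <- select_deg(object, padj_max = padj_max, base_mean_min = base_mean_min)
  out <- list(
    comparison = object$comparison,
    n_genes = nrow(object$results),
    n_converged = sum(object$results$converged),
    n_up = nrow(deg$up), n_down = nrow(deg$down),
    padj_max = padj_max, base_mean_min = base_mean_min,
    dispersion_quartiles = stats::quantile(object$results$dispersion,
                                           c(0.25, 0.5, 0.75), na.rm = TRUE),
    size_factor_range = range(object$size_factors)
  )
  class(out) <- "summary.nb_lrt"
  out
}

#' @export
print.summary.nb_lrt <- function(x, ...) {
  cat(sprintf("Comparison %s: %d genes tested (%d converged)\n",
              x$comparison, x$n_genes, x$n_converged))
  cat(sprintf("DEGs at p_holm < %g and base_mean > %g: %d up, %d down\n",
              x$padj_max, x$base_mean_min, x$n_up, x$n_down))
  cat(sprintf("Dispersion quartiles: %.3g / %.3g / %.3g\n",
              x$dispersion_quartiles[1], x$dispersion_quartiles[2],
              x$dispersion_quartiles[3]))
  cat(sprintf("Size factors in [%.3g, %.3g]\n",
              x$size_factor_range[1], x$size_factor_range[2]))
  invisible(x)
}

#' @export
coef.nb_lrt <- function(object, ...) {
  stats::setNames(object$results$log2_fc, object$results$gene_id)
}

#' @export
as.data.frame.nb_lrt <- function(x, ...) x$results

#' MA plot of a differential-expression fit
#'
#' Base-graphics MA plot: log10 base mean against log2 fold change, with
#' genes passing the DEG thresholds highlighted.
#'
#' @param x An `nb_lrt` fit.
#' @param padj_max,base_mean_min DEG thresholds.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.nb_lrt <- function(x, padj_max = 0.01, base_mean_min = 100, ...) {
  df <- x$results
  sig <- !is.na(df$p_holm) & df$p_holm < padj_max & df$base_mean > base_mean_min
  graphics::plot(log10(df$base_mean + 1), df$log2_fc,
                 pch = 16, cex = 0.4, col = ifelse(sig, "firebrick", "grey60"),
                 xlab = "log10(base mean + 1)", ylab = "log2 fold change",
                 main = sprintf("Comparison %s", x$comparison), ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
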