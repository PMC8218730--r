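#' Default run configuration
#'
#' Thresholds default to the analysis' canonical values: count filter
#' (cumulative count >= 10, detected in >= 2 samples), DEG selection
#' (Holm-adjusted p < 0.01, base mean > 100 reads), log2 CPM normalization
#' before cross-platform standardization, `minzero` signature shift and
#' `auto` Mann-Whitney mode.
#'
#' @param ... Overrides of the default fields.
#' @return Named list of class `"run_config"`.
#' @export
run_config <- function(...) {
  cfg <- list(
    counts = NULL,            # path to counts TSV; NULL -> simulate
    metadata = NULL,
    probes = NULL,            # path to probe TSV (+ probe_map) for harmonization
    probe_map = NULL,
    total_count_min = 10,
    min_detected_samples = 2L,
    padj_max = 0.01,
    base_mean_min = 100,
    normalization = "log2cpm1",
    signature_shift = "minzero",
    mwu_mode = "auto",
    seed = 1L,
    sim = list()              # overrides forwarded to sim_config()
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  cfg[names(dots)] <- dots
  class(cfg) <- "run_config"
  cfg
}

#' Read a YAML run configuration
#'
#' @param path Path to a YAML file whose keys are [run_config()] fields.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages on disk: (optionally) simulate inputs, filter the
#' count matrix, run both differential-expression comparisons, harmonize the
#' two platforms, and score lymphocyte contamination. Every stage logs its
#' record counts; a machine-readable manifest (stage, outputs, record
#' counts, parameters) and the resolved configuration are written next to
#' the outputs, and every output is a TSV or JSON file, so a rerun with the
#' same config and seed reproduces the bundle byte for byte.
#'
#' @param config A [run_config()] (or path to a YAML file).
#' @param out_dir Output directory, created if needed.
#' @return The manifest, invisibly (a list; also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  manifest <- list()
  note <- function(stage, outputs, counts, params = NULL) {
    manifest[[length(manifest) + 1L]] <<- list(
      stage = stage, outputs = outputs, counts = counts, params = params)
  }

  # -- inputs: load or simulate ------------------------------------------
  probes <- NULL
  if (is.null(config$counts)) {
    scfg <- do.call(sim_config, c(config$sim, list(seed = config$seed)))
    sim <- generate_counts(scfg)
    probes <- generate_microarray(sim$truth, scfg)
    counts <- sim$counts
    meta <- counts$meta
    write_expression_matrix(counts, p("counts.tsv"))
    write_sample_metadata(meta, p("metadata.tsv"))
    write_probe_matrix(probes, p("probes.tsv"), p("probe_map.tsv"))
    utils::write.table(sim$truth$genes, p("truth_genes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(sim$truth$samples, p("truth_samples.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    log_stage("simulate", "%d genes x %d samples (+ %d probes)",
              nrow(counts$values), ncol(counts$values), nrow(probes$values))
    note("simulate",
         c("counts.tsv", "metadata.tsv", "probes.tsv", "probe_map.tsv",
           "truth_genes.tsv", "truth_samples.tsv"),
         list(genes = nrow(counts$values), samples = ncol(counts$values),
              probes = nrow(probes$values)),
         list(seed = config$seed))
  } else {
    counts <- read_expression_matrix(config$counts, "counts")
    meta <- read_sample_metadata(config$metadata)
    counts$meta <- align_metadata(counts, meta)
    if (!is.null(config$probes)) {
      probes <- read_probe_matrix(config$probes, config$probe_map)
    }
    note("load", character(),
         list(genes = nrow(counts$values), samples = ncol(counts$values)))
  }

  # -- filter -------------------------------------------------------------
  filtered <- filter_genes(counts, total_count_min = config$total_count_min,
                           min_detected_samples = config$min_detected_samples)
  write_expression_matrix(filtered, p("filtered_counts.tsv"))
  note("filter", "filtered_counts.tsv",
       list(genes_in = nrow(counts$values), genes_out = nrow(filtered$values)),
       list(total_count_min = config$total_count_min,
            min_detected_samples = config$min_detected_samples))

  # -- differential expression -------------------------------------------
  sf <- size_factors(filtered)
  de_counts <- list()
  for (cmp in c("C1", "C2")) {
    fit <- run_comparison(filtered, comparison = cmp, sf = sf)
    out_main <- sprintf("results_%s.tsv", cmp)
    utils::write.table(format_results(fit$results), p(out_main), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    deg <- select_deg(fit, padj_max = config$padj_max,
                      base_mean_min = config$base_mean_min)
    utils::write.table(format_results(deg$up), p(sprintf("deg_up_%s.tsv", cmp)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(format_results(deg$down), p(sprintf("deg_down_%s.tsv", cmp)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_stage("de", "%s: %d genes tested, %d up / %d down DEGs",
              cmp, nrow(fit$results), nrow(deg$up), nrow(deg$down))
    de_counts[[cmp]] <- list(genes_in = nrow(filtered$values),
                             genes_tested = sum(fit$results$converged),
                             deg_up = nrow(deg$up), deg_down = nrow(deg$down))
    note(paste0("de_", cmp),
         c(out_main, sprintf("deg_up_%s.tsv", cmp), sprintf("deg_down_%s.tsv", cmp)),
         de_counts[[cmp]],
         list(padj_max = config$padj_max, base_mean_min = config$base_mean_min))
  }

  # -- harmonize + contamination -----------------------------------------
  if (!is.null(probes)) {
    harm <- harmonize_platforms(filtered, probes,
                                normalization = config$normalization)
    utils::write.table(harm$means, p("platform_means.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(n_shared_genes = length(harm$genes),
                              pearson_r = harm$r,
                              normalization = harm$normalization),
                         p("harmonize.json"), auto_unbox = TRUE, digits = NA)
    note("harmonize", c("platform_means.tsv", "harmonize.json"),
         list(genes_in = nrow(filtered$values), genes_out = length(harm$genes)),
         list(normalization = config$normalization))

    rep <- contamination_report(harm$rnaseq, harm$microarray,
                                mode = config$mwu_mode)
    utils::write.table(rep$signatures, p("signatures.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(shift = rep$shift,
                              shift_mode = config$signature_shift,
                              comparison = as.data.frame(unclass(rep$comparison))),
                         p("contamination.json"), auto_unbox = TRUE, digits = NA)
    log_stage("contamination", "%d panels compared", nrow(rep$comparison))
    note("contamination", c("signatures.tsv", "contamination.json"),
         list(genes_in = length(harm$genes), panels = nrow(rep$comparison)),
         list(shift = config$signature_shift, mwu_mode = config$mwu_mode))
  }

  yaml::write_yaml(unclass(config), p("config_resolved.yaml"))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}

# fixed-format numeric columns so pipeline TSV outputs are byte-stable
format_results <- function(df) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  df
}
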