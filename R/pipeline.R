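# End-to-end orchestration: filter -> three contrasts -> classification ->
# epsilon calibration -> per-category enrichment.

#' @keywords internal
check_design <- function(sheet) {
  required <- data.frame(
    stimulation = c("NS", "IFNB_TNF", "IFNB_TNF", "IFNB_TNF"),
    silencing = c("CTRL", "CTRL", "STAT2", "IRF9"),
    stringsAsFactors = FALSE
  )
  n_rep <- mapply(function(st, si) {
    sum(sheet$stimulation == st & sheet$silencing == si)
  }, required$stimulation, required$silencing)
  absent <- n_rep < 2L
  if (any(absent)) {
    stop("design is missing group(s) (need >= 2 replicates each): ",
         paste(sprintf("(%s, %s)", required$stimulation[absent],
                       required$silencing[absent]), collapse = ", "))
  }
  invisible(sheet)
}

#' @keywords internal
empty_result_table <- function() {
  data.frame(gene_id = character(0), base_mean = numeric(0),
             log2fc = numeric(0), p = numeric(0), q = numeric(0),
             status = factor(character(0), levels = c("UP", "DOWN", "NS")),
             stringsAsFactors = FALSE)
}

#' Run the full dual-knockdown classification pipeline
#'
#' Executes, in order: the counts-per-million expression filter; the three
#' canonical contrasts (stimulated vs unstimulated control; each stimulated
#' knockdown vs stimulated control) with one shared set of median-of-ratios
#' size factors; differential-expression calling; classification of every
#' induced gene into the nine regulation categories; calibration of the
#' epsilon-centering so hierarchical clustering of knockdown fold-change
#' profiles matches the categories; and, when a module collection is given,
#' per-category hypergeometric enrichment. The run is fully deterministic.
#'
#' When `out_dir` is given, every intermediate is written as TSV
#' (`kept_genes.tsv`, `size_factors.tsv`, `de_<contrast>.tsv`,
#' `categories.tsv`, `category_counts.tsv`, `epsilon_grid.tsv`,
#' `heatmap.tsv`, `enrichment.tsv`). Progress is logged to standard error.
#'
#' @param counts Integer count matrix (genes x samples).
#' @param sheet Sample sheet covering the four canonical groups.
#' @param modules Optional [module_collection()] for enrichment.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for the TSV artifacts.
#' @return A list of class `crosstalk_result` with elements `config`,
#'   `kept`, `size_factors`, `results` (list of the three contrast tables),
#'   `classification`, `profiles`, `epsilon_fit`, `enrichment`.
#' @export
run_pipeline <- function(counts, sheet, modules = NULL,
                         config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_counts(counts)
  sheet <- validate_sample_sheet(sheet)
  check_design(sheet)
  missing <- setdiff(sheet$sample_id, colnames(counts))
  if (length(missing) > 0L) {
    stop("samples in sheet but not in counts: ",
         paste(missing, collapse = ", "))
  }
  counts <- counts[, sheet$sample_id, drop = FALSE]

  ct_log("expression filter: >= ", config$min_cpm, " CPM in >= ",
         config$min_samples, " samples")
  filt <- cpm_filter(counts, config$min_cpm, config$min_samples)
  ct_log(sum(filt$kept), " of ", nrow(counts), " genes pass the filter")

  contrasts <- canonical_contrasts()
  if (nrow(filt$counts) == 0L) {
    results <- lapply(contrasts, function(x) empty_result_table())
    size_factors <- stats::setNames(rep(NA_real_, ncol(counts)),
                                    colnames(counts))
    classification <- classify_genes(results$stim, results$stat2,
                                     results$irf9)
    res <- structure(list(config = config, kept = filt$kept,
                          size_factors = size_factors, results = results,
                          classification = classification,
                          profiles = NULL, epsilon_fit = NULL,
                          enrichment = NULL),
                     class = "crosstalk_result")
    if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
    return(res)
  }

  size_factors <- estimate_size_factors(filt$counts)
  ct_log("size factors: ",
         paste(sprintf("%.3f", size_factors), collapse = " "))

  results <- lapply(contrasts, function(ctr) {
    test_contrast(filt$counts, sheet, ctr, size_factors, config)
  })
  n_deg <- vapply(results, function(r) sum(r$status != "NS"), integer(1))
  ct_log("DEGs per contrast: ",
         paste(names(results), n_deg, sep = "=", collapse = ", "))

  classification <- classify_genes(results$stim, results$stat2,
                                   results$irf9)
  ct_log(nrow(classification$assignments),
         " induced genes classified into categories")

  profiles <- NULL
  epsilon_fit <- NULL
  if (nrow(classification$assignments) > 0L) {
    profiles <- fc_profiles(classification, results$stat2, results$irf9)
    epsilon_fit <- calibrate_epsilon(profiles, config$epsilon_grid,
                                     config$linkage)
    ct_log("epsilon calibration: epsilon = ", epsilon_fit$epsilon,
           ", ARI = ", format(epsilon_fit$agreement, digits = 4))
  }

  enrichment <- NULL
  if (!is.null(modules) && nrow(classification$assignments) > 0L) {
    universe <- rownames(filt$counts)
    enrichment <- per_category_enrichment(classification, modules, universe,
                                          fdr = config$fdr,
                                          config$min_module_size)
    ct_log(sum(enrichment$significant), " significant category-module pairs")
  }

  res <- structure(list(config = config, kept = filt$kept,
                        size_factors = size_factors, results = results,
                        classification = classification,
                        profiles = profiles, epsilon_fit = epsilon_fit,
                        enrichment = enrichment),
                   class = "crosstalk_result")
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

#' Write every pipeline intermediate as TSV
#'
#' @param res A `crosstalk_result` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_pipeline_outputs <- function(res, out_dir) {
  stopifnot(inherits(res, "crosstalk_result"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv_file(data.frame(gene_id = names(res$kept), kept = res$kept,
                            stringsAsFactors = FALSE),
                 file.path(out_dir, "kept_genes.tsv"))
  write_tsv_file(data.frame(sample_id = names(res$size_factors),
                            size_factor = res$size_factors,
                            stringsAsFactors = FALSE),
                 file.path(out_dir, "size_factors.tsv"))
  for (nm in names(res$results)) {
    write_tsv_file(res$results[[nm]],
                   file.path(out_dir, paste0("de_", nm, ".tsv")))
  }
  write_tsv_file(res$classification$assignments,
                 file.path(out_dir, "categories.tsv"))
  write_tsv_file(data.frame(category = names(res$classification$counts),
                            n_genes = res$classification$counts,
                            stringsAsFactors = FALSE),
                 file.path(out_dir, "category_counts.tsv"))
  if (!is.null(res$epsilon_fit)) {
    write_tsv_file(res$epsilon_fit$grid,
                   file.path(out_dir, "epsilon_grid.tsv"))
    heatmap_export(res$epsilon_fit, file.path(out_dir, "heatmap.tsv"))
  }
  if (!is.null(res$enrichment)) {
    write_tsv_file(res$enrichment, file.path(out_dir, "enrichment.tsv"))
  }
  invisible(out_dir)
}

#' @export
print.crosstalk_result <- function(x, ...) {
  cat("crosstalk_result\n")
  cat(sprintf("  genes passing filter: %d\n", sum(x$kept)))
  for (nm in names(x$results)) {
    r <- x$results[[nm]]
    cat(sprintf("  %s: %d UP, %d DOWN of %d tested\n", nm,
                sum(r$status == "UP"), sum(r$status == "DOWN"), nrow(r)))
  }
  cat("  category counts: ",
      paste(names(x$classification$counts), x$classification$counts,
            sep = "=", collapse = " "), "\n")
  if (!is.null(x$epsilon_fit)) {
    cat(sprintf("  epsilon = %g (ARI %s)\n", x$epsilon_fit$epsilon,
                format(x$epsilon_fit$agreement, digits = 4)))
  }
  invisible(x)
}
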