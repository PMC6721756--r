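#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline in one validated object.
#' Defaults follow the standard bulk RNA-seq conventions used throughout the
#' package: a differentially expressed gene must clear fold change > 1.5,
#' p < 0.05 and Benjamini-Hochberg FDR < 0.05, over genes passing a
#' counts-per-million expression filter of >= 1 CPM in >= 3 samples.
#'
#' @param fc Fold-change threshold (ratio scale, > 1); genes must exceed
#'   `log2(fc)` in absolute log2 fold change.
#' @param p Per-gene p-value threshold, in (0, 1).
#' @param fdr Benjamini-Hochberg adjusted p (q) threshold, in (0, 1).
#' @param min_cpm Minimum counts-per-million for the expression filter.
#' @param min_samples Minimum number of samples reaching `min_cpm`.
#' @param pseudo_count Pseudo-count added to normalised group means before
#'   the log2 ratio, guarding against zero-count groups.
#' @param epsilon_grid Numeric `c(lo, hi, step)` search grid for the epsilon
#'   centering calibration.
#' @param linkage Hierarchical clustering linkage method (see
#'   [stats::hclust()]).
#' @param min_module_size Modules with fewer genes than this inside the
#'   universe are skipped during enrichment.
#' @param seed Optional integer seed echoed into simulation helpers.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(fc = 1.5, p = 0.05, fdr = 0.05,
                            min_cpm = 1, min_samples = 3,
                            pseudo_count = 0.5,
                            epsilon_grid = c(-5, 5, 0.05),
                            linkage = "average",
                            min_module_size = 3,
                            seed = NULL) {
  stopifnot(is.numeric(fc), length(fc) == 1L, fc > 1)
  stopifnot(is.numeric(p), length(p) == 1L, p > 0, p < 1)
  stopifnot(is.numeric(fdr), length(fdr) == 1L, fdr > 0, fdr < 1)
  stopifnot(is.numeric(min_cpm), length(min_cpm) == 1L, min_cpm > 0)
  stopifnot(is.numeric(min_samples), length(min_samples) == 1L,
            min_samples >= 0, min_samples == round(min_samples))
  stopifnot(is.numeric(pseudo_count), length(pseudo_count) == 1L,
            pseudo_count > 0)
  stopifnot(is.numeric(epsilon_grid), length(epsilon_grid) == 3L,
            epsilon_grid[3L] > 0, epsilon_grid[1L] <= epsilon_grid[2L])
  stopifnot(is.character(linkage), length(linkage) == 1L)
  stopifnot(is.numeric(min_module_size), length(min_module_size) == 1L,
            min_module_size >= 1)
  structure(list(fc = fc, p = p, fdr = fdr,
                 min_cpm = min_cpm, min_samples = as.integer(min_samples),
                 pseudo_count = pseudo_count,
                 epsilon_grid = epsilon_grid,
                 linkage = linkage,
                 min_module_size = as.integer(min_module_size),
                 seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys absent from the file keep their [pipeline_config()] defaults;
#' unknown keys raise an error rather than being silently dropped.
#'
#' @param path Path to a YAML file.
#' @param ... Overrides applied on top of the file values (e.g. from
#'   command-line flags).
#' @return A `pipeline_config`.
#' @export
read_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(vals$epsilon_grid)) {
    vals$epsilon_grid <- as.numeric(unlist(vals$epsilon_grid))
  }
  do.call(pipeline_config, vals)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config:\n")
  cat(sprintf("  DEG thresholds: FC > %.3g, p < %.3g, FDR < %.3g\n",
              x$fc, x$p, x$fdr))
  cat(sprintf("  CPM filter: >= %.3g CPM in >= %d samples\n",
              x$min_cpm, x$min_samples))
  cat(sprintf("  epsilon grid: [%g, %g] step %g; linkage: %s\n",
              x$epsilon_grid[1L], x$epsilon_grid[2L], x$epsilon_grid[3L],
              x$linkage))
  invisible(x)
}
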