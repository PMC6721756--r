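# Expression filtering, normalisation and the negative-binomial Wald test.

#' Counts-per-million expression filter
#'
#' Keeps genes with CPM >= `min_cpm` in at least `min_samples` samples.
#' CPM is computed against the library sizes (column sums) of the
#' *unfiltered* matrix, so the filter itself cannot shift the scale it is
#' judged on.
#'
#' @param counts Integer count matrix (genes x samples).
#' @param min_cpm CPM threshold (inclusive).
#' @param min_samples Number of samples required to reach the threshold;
#'   `0` keeps every gene.
#' @return A list with `counts` (the filtered matrix) and `kept` (logical
#'   vector over the input genes).
#' @export
cpm_filter <- function(counts, min_cpm = 1, min_samples = 3) {
  validate_counts(counts)
  stopifnot(min_cpm > 0, min_samples >= 0, min_samples <= ncol(counts))
  lib <- colSums(counts)
  if (any(lib == 0)) stop("every sample must have a positive library size")
  cpm <- sweep(counts, 2L, lib, "/") * 1e6
  kept <- rowSums(cpm >= min_cpm) >= min_samples
  list(counts = counts[kept, , drop = FALSE],
       kept = stats::setNames(kept, rownames(counts)))
}

#' Median-of-ratios size factors
#'
#' Per sample, the median over genes (restricted to genes positive in every
#' sample) of the ratio count / geometric row mean, rescaled so the factors
#' have geometric mean 1. When no gene is positive in all samples the
#' factors fall back to relative library sizes, with a warning.
#'
#' @param counts Integer count matrix.
#' @return Named positive numeric vector, one factor per sample.
#' @export
estimate_size_factors <- function(counts) {
  validate_counts(counts)
  if (ncol(counts) == 1L) {
    return(stats::setNames(1, colnames(counts)))
  }
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos)) {
    warning("no gene has positive counts in every sample; ",
            "falling back to library-size factors")
    lib <- colSums(counts)
    sf <- lib / exp(mean(log(lib)))
    return(stats::setNames(sf, colnames(counts)))
  }
  x <- counts[all_pos, , drop = FALSE]
  log_geo <- rowMeans(log(x))
  sf <- apply(x, 2L, function(col) exp(stats::median(log(col) - log_geo)))
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

#' Contrast specification
#'
#' @param test_stimulation,test_silencing Group tested.
#' @param ref_stimulation,ref_silencing Reference group.
#' @return A list of class `contrast_spec`.
#' @export
contrast_spec <- function(test_stimulation, test_silencing,
                          ref_stimulation, ref_silencing) {
  test <- c(stimulation = test_stimulation, silencing = test_silencing)
  ref <- c(stimulation = ref_stimulation, silencing = ref_silencing)
  stopifnot(test["stimulation"] %in% .stimulation_levels,
            ref["stimulation"] %in% .stimulation_levels,
            test["silencing"] %in% .silencing_levels,
            ref["silencing"] %in% .silencing_levels)
  if (identical(unname(test), unname(ref))) {
    stop("test and reference groups must differ")
  }
  structure(list(test = test, ref = ref), class = "contrast_spec")
}

# The three contrasts of the canonical design.
#' @keywords internal
canonical_contrasts <- function() {
  list(
    stim = contrast_spec("IFNB_TNF", "CTRL", "NS", "CTRL"),
    stat2 = contrast_spec("IFNB_TNF", "STAT2", "IFNB_TNF", "CTRL"),
    irf9 = contrast_spec("IFNB_TNF", "IRF9", "IFNB_TNF", "CTRL")
  )
}

#' @keywords internal
group_samples <- function(sheet, group) {
  sheet$sample_id[sheet$stimulation == group[["stimulation"]] &
                    sheet$silencing == group[["silencing"]]]
}

#' Negative-binomial Wald test for one two-group contrast
#'
#' For each gene, counts are scaled by the size factors, the two group means
#' are compared on the log2 scale (after adding `pseudo_count`), and a Wald
#' statistic log2FC / SE is formed with the SE propagated from the NB
#' variance of each group mean (variance = mu + alpha mu^2).
#'
#' The dispersion alpha is estimated by method of moments on the normalised
#' counts, pooled within groups, in one of two modes. `"common"` (the
#' default model of the package) assumes one dispersion shared by all genes
#' and pools the moment equations across the whole matrix; the resulting
#' estimate is stable enough that the Wald statistic is referred to the
#' normal distribution. `"genewise"` estimates alpha per gene from the two
#' groups alone; with the few replicates typical of this design that
#' estimate is noisy, so the statistic is referred to a Student t
#' distribution on the residual degrees of freedom (n_test + n_ref - 2) to
#' keep the null calibrated (at the cost of a floor on attainable
#' p-values). Either way alpha is floored at 1e-8 and capped at 10.
#'
#' @param counts Count matrix (ideally already CPM-filtered).
#' @param sheet Sample sheet covering both groups.
#' @param contrast A [contrast_spec()].
#' @param size_factors Optional named size factors; estimated with
#'   [estimate_size_factors()] from `counts` when omitted.
#' @param pseudo_count Pseudo-count added to normalised group means.
#' @param dispersion `"common"` or `"genewise"` (see Details).
#' @return A data.frame with columns `gene_id`, `base_mean` (mean normalised
#'   count over both groups), `log2fc`, `p`; the dispersion estimate(s) are
#'   attached as attribute `"alpha"`.
#' @export
nb_contrast_test <- function(counts, sheet, contrast, size_factors = NULL,
                             pseudo_count = 0.5,
                             dispersion = c("common", "genewise")) {
  dispersion <- match.arg(dispersion)
  validate_counts(counts)
  sheet <- validate_sample_sheet(sheet)
  stopifnot(inherits(contrast, "contrast_spec"))
  ids_t <- group_samples(sheet, contrast$test)
  ids_r <- group_samples(sheet, contrast$ref)
  if (length(ids_t) < 2L || length(ids_r) < 2L) {
    stop("both contrast groups need at least 2 replicates")
  }
  missing <- setdiff(c(ids_t, ids_r), colnames(counts))
  if (length(missing) > 0L) {
    stop("samples absent from count matrix: ", paste(missing, collapse = ", "))
  }
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  norm <- sweep(counts[, c(ids_t, ids_r), drop = FALSE], 2L,
                size_factors[c(ids_t, ids_r)], "/")
  xt <- norm[, ids_t, drop = FALSE]
  xr <- norm[, ids_r, drop = FALSE]
  nt <- length(ids_t)
  nr <- length(ids_r)
  mt <- rowMeans(xt)
  mr <- rowMeans(xr)
  vt <- rowSums((xt - mt)^2) / (nt - 1L)
  vr <- rowSums((xr - mr)^2) / (nr - 1L)
  # method-of-moments dispersion: var = mu + alpha mu^2 within each group
  if (dispersion == "common") {
    num <- sum((nt - 1L) * (vt - mt) + (nr - 1L) * (vr - mr))
    den <- sum((nt - 1L) * mt^2 + (nr - 1L) * mr^2)
    alpha <- if (den > 0 && is.finite(num / den)) num / den else 0
  } else {
    alpha <- ((nt - 1L) * (vt - mt) + (nr - 1L) * (vr - mr)) /
      ((nt - 1L) * mt^2 + (nr - 1L) * mr^2)
    alpha[!is.finite(alpha)] <- 0
  }
  alpha <- pmin(pmax(alpha, 1e-8), 10)
  c0 <- pseudo_count
  log2fc <- log2((mt + c0) / (mr + c0))
  var_mt <- (mt + alpha * mt^2) / nt
  var_mr <- (mr + alpha * mr^2) / nr
  se2 <- (var_mt / (mt + c0)^2 + var_mr / (mr + c0)^2) / log(2)^2
  z <- ifelse(se2 > 0, log2fc / sqrt(se2), 0)
  p <- if (dispersion == "common") {
    2 * stats::pnorm(-abs(z))
  } else {
    2 * stats::pt(-abs(z), df = nt + nr - 2L)
  }
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  out <- data.frame(gene_id = rownames(counts),
                    base_mean = (nt * mt + nr * mr) / (nt + nr),
                    log2fc = log2fc, p = p,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `q_i = min_{j: p_(j) >= p_(i)} m p_(j) / j`,
#' capped at 1 (as implemented by [stats::p.adjust()] with method `"BH"`).
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return Numeric vector of q-values, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) stop("pvalues must be nonempty")
  if (anyNA(pvalues) || any(pvalues <= 0) || any(pvalues > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Call differential-expression status
#'
#' Applies the three calling thresholds with strict inequalities: a gene is
#' `UP` iff `log2fc > log2(fc)`, `p < p_thr` and `q < fdr`; `DOWN` with the
#' mirrored fold-change condition; `NS` otherwise.
#'
#' @param results Data.frame from [nb_contrast_test()] with a `q` column
#'   already added over the contrast's full tested family (see
#'   [bh_adjust()]).
#' @param fc,p,fdr Thresholds (see [pipeline_config()]).
#' @return The input with a `status` factor column (`UP`/`DOWN`/`NS`).
#' @export
apply_status <- function(results, fc = 1.5, p = 0.05, fdr = 0.05) {
  stopifnot(is.data.frame(results),
            all(c("log2fc", "p", "q") %in% names(results)))
  lfc_thr <- log2(fc)
  sig <- results$p < p & results$q < fdr
  status <- rep("NS", nrow(results))
  status[sig & results$log2fc > lfc_thr] <- "UP"
  status[sig & results$log2fc < -lfc_thr] <- "DOWN"
  results$status <- factor(status, levels = c("UP", "DOWN", "NS"))
  results
}

#' Run one contrast end to end
#'
#' [nb_contrast_test()] followed by [bh_adjust()] over the contrast's tested
#' genes and [apply_status()].
#'
#' @inheritParams nb_contrast_test
#' @param config A [pipeline_config()].
#' @return A complete `GeneTestResult` data.frame
#'   (`gene_id`, `base_mean`, `log2fc`, `p`, `q`, `status`).
#' @export
test_contrast <- function(counts, sheet, contrast, size_factors = NULL,
                          config = pipeline_config()) {
  res <- nb_contrast_test(counts, sheet, contrast, size_factors,
                          pseudo_count = config$pseudo_count)
  res$q <- bh_adjust(res$p)
  apply_status(res, fc = config$fc, p = config$p, fdr = config$fdr)
}

#' Relative quantification by the delta-delta-Ct method
#'
#' Fold change between condition and control, each normalised to a
#' reference transcript:
#' `fold = 2^-((Ct_target,cond - Ct_ref,cond) - (Ct_target,ctrl - Ct_ref,ctrl))`.
#'
#' @param ct_target_cond,ct_ref_cond Target and reference Ct in the
#'   condition of interest.
#' @param ct_target_ctrl,ct_ref_ctrl Target and reference Ct in the control
#'   condition.
#' @return Fold change(s), vectorised over the inputs.
#' @export
ddct_fold <- function(ct_target_cond, ct_ref_cond,
                      ct_target_ctrl, ct_ref_ctrl) {
  cts <- cbind(ct_target_cond, ct_ref_cond, ct_target_ctrl, ct_ref_ctrl)
  if (anyNA(cts) || any(!is.finite(cts))) stop("Ct values must be finite")
  ddct <- (ct_target_cond - ct_ref_cond) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}

#' Concordance between two fold-change measurements
#'
#' Pearson correlation and least-squares slope of `log2(fc_b)` on
#' `log2(fc_a)`, as used to check sequencing-derived fold changes against an
#' orthogonal qPCR quantification.
#'
#' @param fc_a,fc_b Paired positive fold changes (length >= 3).
#' @return A list with `correlation` and `slope`.
#' @export
fc_concordance <- function(fc_a, fc_b) {
  stopifnot(length(fc_a) == length(fc_b), length(fc_a) >= 3L)
  if (any(fc_a <= 0) || any(fc_b <= 0)) {
    stop("fold changes must be positive")
  }
  la <- log2(fc_a)
  lb <- log2(fc_b)
  fit <- stats::lm.fit(cbind(1, la), lb)
  list(correlation = stats::cor(la, lb),
       slope = unname(fit$coefficients[2L]))
}
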