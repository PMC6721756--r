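# Synthetic negative-binomial count data with planted regulation categories.
#
# Counts are NB(mu, alpha) with var = mu + alpha * mu^2. Per-gene expected
# count is base_mean x library size factor x 2^(log2 effects active in the
# sample's group): the stimulation effect in every stimulated group, plus the
# matching knockdown effect in the stimulated siSTAT2 / siIRF9 groups. The
# unstimulated group sees base_mean alone.

# Sign conventions of the nine regulation categories, expressed as the
# direction of the expression change upon silencing each factor
# (-1 = transcript drops when the factor is silenced, i.e. positive
# regulation; +1 = transcript rises, i.e. negative regulation).
.category_signs <- data.frame(
  category = c("A", "B", "C", "D", "E", "F", "G", "H", "I"),
  stat2 = c(-1,  1,  0, -1,  1,  0,  0, -1,  1),
  irf9  = c(-1,  1,  0,  0,  0, -1,  1,  1, -1),
  stringsAsFactors = FALSE
)

.truth_categories <- c(.category_signs$category, "DOWNREG", "NONDEG")

#' Simulation specification
#'
#' Defines the synthetic experiment: how many genes carry each regulation
#' category, the effect-size range, the negative-binomial parameters, and
#' the library-size imbalance. Defaults emulate a stimulated dual-knockdown
#' RNA-seq design at desk scale: 3 replicates per group, a minority of genes
#' induced by stimulation, one shared dispersion, and non-trivial library
#' size variation.
#'
#' @param n_genes Total number of genes.
#' @param category_counts Named integer vector over
#'   `c("A".."I", "DOWNREG")`; unlisted genes are unregulated (`NONDEG`).
#'   The default plants every category that the classification stage must
#'   recover, with the knockdown-independent class (C) the largest, a small
#'   D class, and the opposite-effect classes essentially absent.
#' @param effect_lfc Length-2 range; planted effect magnitudes are drawn
#'   uniformly from it (absolute log2 fold change). Must exceed
#'   `log2(1.5)` so planted effects sit beyond the calling threshold.
#' @param base_mean_meanlog,base_mean_sdlog Log-normal parameters of the
#'   per-gene baseline expected count.
#' @param dispersion Shared NB dispersion alpha (variance = mu + alpha mu^2).
#' @param lib_size_range Length-2 positive range; per-sample size factors
#'   are drawn log-uniformly from it.
#' @param replicates Replicates per experimental group.
#' @param seed Integer seed governing every draw of the fixture.
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_genes = 2000,
                            category_counts = c(A = 40, B = 12, C = 80,
                                                D = 12, E = 8, F = 15,
                                                G = 12, I = 1,
                                                DOWNREG = 30),
                            effect_lfc = c(1, 3),
                            base_mean_meanlog = log(100),
                            base_mean_sdlog = 1,
                            dispersion = 0.05,
                            lib_size_range = c(0.5, 2),
                            replicates = 3,
                            seed = 1L) {
  stopifnot(is.numeric(n_genes), n_genes >= 1)
  category_counts <- category_counts[category_counts > 0]
  bad <- setdiff(names(category_counts), setdiff(.truth_categories, "NONDEG"))
  if (length(bad) > 0L) {
    stop("unknown categories in category_counts: ", paste(bad, collapse = ", "))
  }
  if (sum(category_counts) > n_genes) {
    stop("category_counts sum exceeds n_genes")
  }
  stopifnot(length(effect_lfc) == 2L, all(effect_lfc >= log2(1.5)),
            effect_lfc[1L] <= effect_lfc[2L])
  stopifnot(dispersion > 0, replicates >= 1,
            length(lib_size_range) == 2L, all(lib_size_range > 0))
  structure(list(n_genes = as.integer(n_genes),
                 category_counts = category_counts,
                 effect_lfc = effect_lfc,
                 base_mean_meanlog = base_mean_meanlog,
                 base_mean_sdlog = base_mean_sdlog,
                 dispersion = dispersion,
                 lib_size_range = lib_size_range,
                 replicates = as.integer(replicates),
                 seed = seed),
            class = "simulation_spec")
}

#' Canonical four-group sample sheet
#'
#' Builds the design of the dual-knockdown experiment: unstimulated control,
#' stimulated control, and the two stimulated knockdown groups, each with
#' `replicates` replicates.
#'
#' @param replicates Replicates per group.
#' @return A sample sheet data.frame.
#' @export
make_design_sheet <- function(replicates = 3) {
  groups <- data.frame(
    stimulation = c("NS", "IFNB_TNF", "IFNB_TNF", "IFNB_TNF"),
    silencing = c("CTRL", "CTRL", "STAT2", "IRF9"),
    stringsAsFactors = FALSE
  )
  sheet <- groups[rep(seq_len(nrow(groups)), each = replicates), ]
  sheet$replicate <- rep(seq_len(replicates), times = nrow(groups))
  sheet$sample_id <- sprintf("%s_si%s_r%d", sheet$stimulation,
                             sheet$silencing, sheet$replicate)
  rownames(sheet) <- NULL
  validate_sample_sheet(sheet)
}

#' Simulate the per-gene ground truth
#'
#' Assigns each gene a regulation category and draws its true effect sizes
#' with the signs the category dictates: e.g. a category A gene is induced
#' by stimulation and drops under both knockdowns, while a category C gene
#' is induced but untouched by either knockdown.
#'
#' @param spec A [simulation_spec()].
#' @return A data.frame (`truth_table`) with columns `gene_id`, `category`,
#'   `true_log2fc_stim`, `true_log2fc_stat2`, `true_log2fc_irf9`,
#'   `base_mean`, `dispersion`.
#' @export
simulate_truth <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_seed(spec$seed, {
    n <- spec$n_genes
    cats <- rep("NONDEG", n)
    idx <- 1L
    for (cat in names(spec$category_counts)) {
      k <- spec$category_counts[[cat]]
      cats[idx:(idx + k - 1L)] <- cat
      idx <- idx + k
    }
    draw_mag <- function(m) stats::runif(m, spec$effect_lfc[1L],
                                         spec$effect_lfc[2L])
    stim <- numeric(n)
    s2 <- numeric(n)
    i9 <- numeric(n)
    up <- cats %in% .category_signs$category
    stim[up] <- draw_mag(sum(up))
    stim[cats == "DOWNREG"] <- -draw_mag(sum(cats == "DOWNREG"))
    sign_row <- match(cats, .category_signs$category)
    has_s2 <- !is.na(sign_row) & .category_signs$stat2[sign_row] != 0
    has_i9 <- !is.na(sign_row) & .category_signs$irf9[sign_row] != 0
    s2[has_s2] <- .category_signs$stat2[sign_row[has_s2]] *
      draw_mag(sum(has_s2))
    i9[has_i9] <- .category_signs$irf9[sign_row[has_i9]] *
      draw_mag(sum(has_i9))
    base_mean <- stats::rlnorm(n, spec$base_mean_meanlog,
                               spec$base_mean_sdlog)
    data.frame(
      gene_id = sprintf("gene%05d", seq_len(n)),
      category = cats,
      true_log2fc_stim = stim,
      true_log2fc_stat2 = s2,
      true_log2fc_irf9 = i9,
      base_mean = base_mean,
      dispersion = spec$dispersion,
      stringsAsFactors = FALSE
    )
  })
}

# Expected count for every gene x sample combination under the design.
#' @keywords internal
expected_means <- function(truth, sheet, size_factors) {
  mu <- outer(truth$base_mean, size_factors)
  stim <- sheet$stimulation == "IFNB_TNF"
  mu[, stim] <- mu[, stim] * 2^truth$true_log2fc_stim
  s2 <- stim & sheet$silencing == "STAT2"
  mu[, s2] <- mu[, s2] * 2^truth$true_log2fc_stat2
  i9 <- stim & sheet$silencing == "IRF9"
  mu[, i9] <- mu[, i9] * 2^truth$true_log2fc_irf9
  dimnames(mu) <- list(truth$gene_id, sheet$sample_id)
  mu
}

#' Simulate a count matrix from a truth table
#'
#' Draws NB counts with per-gene dispersion around the design means implied
#' by the truth table, the sample sheet and log-uniform library size
#' factors.
#'
#' @param truth Truth table from [simulate_truth()].
#' @param sheet Sample sheet (see [make_design_sheet()]).
#' @param spec The [simulation_spec()] (library size range and seed).
#' @return An integer count matrix, genes x samples, with a
#'   `"size_factors"` attribute holding the planted factors.
#' @export
simulate_counts <- function(truth, sheet, spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  sheet <- validate_sample_sheet(sheet)
  with_seed(spec$seed + 1L, {
    ns <- nrow(sheet)
    lo <- log(spec$lib_size_range[1L])
    hi <- log(spec$lib_size_range[2L])
    size_factors <- exp(stats::runif(ns, lo, hi))
    mu <- expected_means(truth, sheet, size_factors)
    counts <- matrix(
      stats::rnbinom(length(mu), mu = mu, size = 1 / truth$dispersion),
      nrow = nrow(mu), dimnames = dimnames(mu)
    )
    storage.mode(counts) <- "integer"
    attr(counts, "size_factors") <- stats::setNames(size_factors,
                                                    sheet$sample_id)
    counts
  })
}

#' Plant enriched gene-set modules
#'
#' Builds a module collection in which `n_enriched` modules draw at least
#' `frac_planted` of their members from category-A genes (so the enrichment
#' stage has known positives) and the remaining modules are uniform draws
#' from all genes (known nulls).
#'
#' @param truth Truth table from [simulate_truth()].
#' @param n_modules Total number of modules.
#' @param module_size Genes per module.
#' @param n_enriched Number of category-A-loaded modules.
#' @param frac_planted Fraction of an enriched module drawn from category A.
#' @param seed Integer seed.
#' @return A [module_collection()]; planted module ids start with `"ENR"`.
#' @export
plant_modules <- function(truth, n_modules = 50, module_size = 20,
                          n_enriched = 5, frac_planted = 0.8, seed = 1L) {
  stopifnot(module_size >= 1, module_size <= nrow(truth),
            n_enriched <= n_modules, frac_planted >= 0, frac_planted <= 1)
  pool_a <- truth$gene_id[truth$category == "A"]
  k_planted <- ceiling(frac_planted * module_size)
  if (n_enriched > 0L && k_planted > length(pool_a)) {
    stop(sprintf(
      "planted modules need %d category-A genes but only %d are available",
      k_planted, length(pool_a)))
  }
  with_seed(seed, {
    genes <- vector("list", n_modules)
    titles <- character(n_modules)
    ids <- character(n_modules)
    for (m in seq_len(n_modules)) {
      if (m <= n_enriched) {
        core <- sample(pool_a, k_planted)
        rest <- sample(setdiff(truth$gene_id, core),
                       module_size - k_planted)
        genes[[m]] <- c(core, rest)
        ids[m] <- sprintf("ENR%02d", m)
        titles[m] <- sprintf("planted enriched module %d", m)
      } else {
        genes[[m]] <- sample(truth$gene_id, module_size)
        ids[m] <- sprintf("RND%02d", m - n_enriched)
        titles[m] <- sprintf("random module %d", m - n_enriched)
      }
    }
    names(genes) <- ids
    module_collection(genes, titles)
  })
}

#' Simulate a complete experiment bundle
#'
#' Convenience wrapper producing everything one pipeline run needs: design
#' sheet, truth table, count matrix and (optionally) planted modules. When
#' `out_dir` is given, each piece is also written in its on-disk format
#' (`counts.tsv`, `samples.tsv`, `truth.tsv`, `modules.gmt`).
#'
#' @param spec A [simulation_spec()].
#' @param modules Logical; also plant a module collection?
#' @param out_dir Optional output directory.
#' @return A list with `counts`, `sheet`, `truth`, `modules` (or NULL) and
#'   `spec`.
#' @export
simulate_experiment <- function(spec = simulation_spec(), modules = TRUE,
                                out_dir = NULL) {
  sheet <- make_design_sheet(spec$replicates)
  truth <- simulate_truth(spec)
  counts <- simulate_counts(truth, sheet, spec)
  mods <- if (modules) plant_modules(truth, seed = spec$seed + 2L) else NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_counts(counts, file.path(out_dir, "counts.tsv"))
    write_sample_sheet(sheet, file.path(out_dir, "samples.tsv"))
    write_tsv_file(truth, file.path(out_dir, "truth.tsv"))
    if (!is.null(mods)) write_gmt(mods, file.path(out_dir, "modules.gmt"))
  }
  list(counts = counts, sheet = sheet, truth = truth, modules = mods,
       spec = spec)
}
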