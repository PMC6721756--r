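# Shared fixtures, all built in code at test time.

# minimal two-group sheet (3 + 3) for single-contrast tests
two_group_sheet <- function(n = 3) {
  data.frame(
    sample_id = sprintf("s%d", seq_len(2 * n)),
    stimulation = rep(c("IFNB_TNF", "NS"), each = n),
    silencing = "CTRL",
    replicate = rep(seq_len(n), 2),
    stringsAsFactors = FALSE
  )
}

unit_size_factors <- function(ids) stats::setNames(rep(1, length(ids)), ids)

# hand-built GeneTestResult table
toy_results <- function(gene_id, log2fc, p, q = NULL,
                        status = NULL) {
  df <- data.frame(gene_id = gene_id, base_mean = 100,
                   log2fc = log2fc, p = p, stringsAsFactors = FALSE)
  df$q <- if (is.null(q)) bh_adjust(df$p) else q
  if (is.null(status)) {
    apply_status(df)
  } else {
    df$status <- factor(status, levels = c("UP", "DOWN", "NS"))
    df
  }
}

# profiles with well-separated category centroids (gap >> within-SD)
separable_profiles <- function(n_per = 12, sd = 0.1, seed = 5) {
  centers <- rbind(A = c(-3, -3), B = c(3, 3), C = c(0, 0),
                   F = c(0, -3), G = c(0, 3))
  withr::with_seed(seed, {
    rows <- do.call(rbind, lapply(rownames(centers), function(cc) {
      data.frame(
        gene_id = sprintf("%s_%02d", cc, seq_len(n_per)),
        fc_stat2 = stats::rnorm(n_per, centers[cc, 1], sd),
        fc_irf9 = stats::rnorm(n_per, centers[cc, 2], sd),
        category = cc, stringsAsFactors = FALSE
      )
    }))
    rows
  })
}

# small complete synthetic bundle, cached across tests in one session
small_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- simulation_spec(
        n_genes = 600,
        category_counts = c(A = 20, B = 8, C = 40, D = 6, E = 5, F = 8,
                            G = 6, DOWNREG = 10),
        effect_lfc = c(2, 2), seed = 101
      )
      cache <<- simulate_experiment(spec)
    }
    cache
  }
})
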