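test_that("truth table plants the requested category counts with the right signs", {
  spec <- simulation_spec(
    n_genes = 1000,
    category_counts = c(A = 50, C = 100, F = 30),
    seed = 3
  )
  truth <- simulate_truth(spec)
  expect_identical(nrow(truth), 1000L)
  tab <- table(truth$category)
  expect_identical(unname(c(tab[c("A", "C", "F", "NONDEG")])),
                   c(50L, 100L, 30L, 820L))
  a <- truth[truth$category == "A", ]
  expect_true(all(a$true_log2fc_stim > 0))
  expect_true(all(a$true_log2fc_stat2 < 0))
  expect_true(all(a$true_log2fc_irf9 < 0))
  cc <- truth[truth$category == "C", ]
  expect_true(all(cc$true_log2fc_stat2 == 0 & cc$true_log2fc_irf9 == 0))
  expect_true(all(cc$true_log2fc_stim > 0))
  f <- truth[truth$category == "F", ]
  expect_true(all(f$true_log2fc_stat2 == 0 & f$true_log2fc_irf9 < 0))
})

test_that("all-null specification yields zero effects everywhere", {
  spec <- simulation_spec(n_genes = 50, category_counts = c(), seed = 1)
  truth <- simulate_truth(spec)
  expect_true(all(truth$category == "NONDEG"))
  expect_true(all(truth$true_log2fc_stim == 0))
  expect_true(all(truth$true_log2fc_stat2 == 0))
  expect_true(all(truth$true_log2fc_irf9 == 0))
})

test_that("every category's effect signs follow the classification convention", {
  spec <- simulation_spec(
    n_genes = 90,
    category_counts = c(A = 10, B = 10, C = 10, D = 10, E = 10,
                        F = 10, G = 10, H = 10, I = 10),
    seed = 7
  )
  truth <- simulate_truth(spec)
  signs <- list(A = c(-1, -1), B = c(1, 1), C = c(0, 0), D = c(-1, 0),
                E = c(1, 0), F = c(0, -1), G = c(0, 1), H = c(-1, 1),
                I = c(1, -1))
  for (cat in names(signs)) {
    sub <- truth[truth$category == cat, ]
    expect_true(all(sign(sub$true_log2fc_stat2) == signs[[cat]][1]),
                label = paste("stat2 sign, category", cat))
    expect_true(all(sign(sub$true_log2fc_irf9) == signs[[cat]][2]),
                label = paste("irf9 sign, category", cat))
    expect_true(all(sub$true_log2fc_stim >= log2(1.5)))
  }
  # magnitudes respect the requested range
  nz <- truth$true_log2fc_stat2[truth$true_log2fc_stat2 != 0]
  expect_true(all(abs(nz) >= spec$effect_lfc[1] &
                    abs(nz) <= spec$effect_lfc[2]))
})

test_that("simulated counts are reproducible under the seed", {
  spec <- simulation_spec(n_genes = 100, seed = 11,
                          category_counts = c(A = 5, C = 10))
  sheet <- make_design_sheet(3)
  t1 <- simulate_truth(spec)
  c1 <- simulate_counts(t1, sheet, spec)
  c2 <- simulate_counts(simulate_truth(spec), sheet, spec)
  expect_identical(c1, c2)
  spec2 <- simulation_spec(n_genes = 100, seed = 12,
                           category_counts = c(A = 5, C = 10))
  c3 <- simulate_counts(simulate_truth(spec2), sheet, spec2)
  expect_false(identical(c1[, 1], c3[, 1]))
})

test_that("counts approach the Poisson limit as dispersion vanishes", {
  n <- 1e4
  sheet <- data.frame(sample_id = sprintf("s%05d", seq_len(n)),
                      stimulation = "NS", silencing = "CTRL",
                      replicate = seq_len(n), stringsAsFactors = FALSE)
  spec <- simulation_spec(n_genes = 1, category_counts = c(),
                          base_mean_meanlog = log(100), base_mean_sdlog = 0,
                          dispersion = 1e-8, lib_size_range = c(1, 1),
                          seed = 13)
  x <- as.numeric(simulate_counts(simulate_truth(spec), sheet, spec))
  expect_gt(var(x) / mean(x), 0.9)
  expect_lt(var(x) / mean(x), 1.1)
})

test_that("group means recover the design expectation within Monte-Carlo error", {
  n <- 200
  sheet <- data.frame(sample_id = sprintf("s%03d", seq_len(n)),
                      stimulation = "IFNB_TNF", silencing = "STAT2",
                      replicate = seq_len(n), stringsAsFactors = FALSE)
  spec <- simulation_spec(n_genes = 1, category_counts = c(A = 1),
                          effect_lfc = c(2, 2),
                          base_mean_meanlog = log(100), base_mean_sdlog = 0,
                          dispersion = 0.05, lib_size_range = c(1, 1),
                          seed = 17)
  truth <- simulate_truth(spec)
  # stimulated knockdown group: stimulation and STAT2 effects both apply
  mu <- truth$base_mean * 2^(truth$true_log2fc_stim +
                               truth$true_log2fc_stat2)
  x <- as.numeric(simulate_counts(truth, sheet, spec))
  se <- sqrt((mu + spec$dispersion * mu^2) / n)
  expect_lt(abs(mean(x) - mu), 3 * se)
})

test_that("generated counts obey the NB mean-variance relation", {
  spec <- simulation_spec(n_genes = 2000, category_counts = c(),
                          dispersion = 0.05, lib_size_range = c(1, 1),
                          replicates = 3, seed = 19)
  counts <- simulate_counts(simulate_truth(spec), make_design_sheet(3), spec)
  m <- rowMeans(counts)
  v <- apply(counts, 1, var)
  # weighted regression of (var - mean) on mean^2 through the origin;
  # inverse-variance weights keep a handful of high-mean genes from
  # dominating the fit
  a0 <- sum(v - m) / sum(m^2)
  w <- 1 / (1 / m + a0)^2
  slope <- sum(w * (v - m) / m^2) / sum(w)
  expect_lt(abs(slope - 0.05) / 0.05, 0.2)
})

test_that("planted modules draw from category A and validate the pool", {
  spec <- simulation_spec(n_genes = 300,
                          category_counts = c(A = 30, C = 50), seed = 23)
  truth <- simulate_truth(spec)
  mods <- plant_modules(truth, n_modules = 10, module_size = 20,
                        n_enriched = 3, seed = 5)
  expect_identical(length(mods), 10L)
  pool_a <- truth$gene_id[truth$category == "A"]
  for (id in sprintf("ENR%02d", 1:3)) {
    expect_gte(length(intersect(mods$genes[[id]], pool_a)) / 20, 0.8)
  }
  expect_error(
    plant_modules(truth, n_modules = 2, module_size = 50, n_enriched = 1),
    "category-A"
  )
  # degenerate but valid: singleton modules, none enriched
  singletons <- plant_modules(truth, n_modules = 4, module_size = 1,
                              n_enriched = 0, seed = 6)
  expect_true(all(lengths(singletons$genes) == 1L))
  expect_true(all(grepl("^RND", names(singletons$genes))))
})

test_that("genes with larger true effects get stochastically larger estimates", {
  spec <- simulation_spec(
    n_genes = 600,
    category_counts = c(C = 200), effect_lfc = c(log2(1.5), 3),
    lib_size_range = c(1, 1), seed = 29
  )
  truth <- simulate_truth(spec)
  sheet <- make_design_sheet(3)
  counts <- simulate_counts(truth, sheet, spec)
  res <- nb_contrast_test(counts, sheet,
                          contrast_spec("IFNB_TNF", "CTRL", "NS", "CTRL"))
  est <- abs(res$log2fc[match(truth$gene_id, res$gene_id)])
  expect_gt(cor(abs(truth$true_log2fc_stim), est, method = "spearman"), 0.5)
  # mean |estimate| ordered by true magnitude tertile
  grp <- cut(abs(truth$true_log2fc_stim), c(-Inf, 0.001, 1.5, Inf))
  means <- tapply(est, grp, mean)
  expect_true(all(diff(means) > 0))
})
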