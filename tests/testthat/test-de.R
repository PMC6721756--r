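test_that("CPM filter keeps genes by the inclusive threshold rule", {
  # library sizes of exactly 1e6 so counts equal CPM
  filler <- c(1e6 - 1, 1e6 - 1, 1e6 - 1, 1e6)
  counts <- rbind(boundary = c(1, 1, 1, 0),
                  zero = c(0, 0, 0, 0),
                  filler = filler)
  colnames(counts) <- sprintf("s%d", 1:4)
  storage.mode(counts) <- "integer"

  filt <- cpm_filter(counts, min_cpm = 1, min_samples = 3)
  expect_true(filt$kept[["boundary"]])   # >= is inclusive at the boundary
  expect_false(filt$kept[["zero"]])
  expect_true(filt$kept[["filler"]])

  # min_samples = 0 is the identity filter
  all_kept <- cpm_filter(counts, min_cpm = 1, min_samples = 0)
  expect_true(all(all_kept$kept))
  expect_identical(all_kept$counts, counts)
})

test_that("median-of-ratios size factors match closed forms", {
  m <- matrix(rpois(40, 50) + 1L, 10, 4,
              dimnames = list(sprintf("g%d", 1:10), sprintf("s%d", 1:4)))
  same <- m[, c(1, 1, 1)]
  colnames(same) <- sprintf("s%d", 1:3)
  expect_equal(unname(estimate_size_factors(same)), rep(1, 3))

  two <- cbind(A = m[, 1], B = 2L * m[, 1])
  expect_equal(unname(estimate_size_factors(two)),
               c(2^(-1 / 2), 2^(1 / 2)))

  one <- m[, 1, drop = FALSE]
  expect_identical(unname(estimate_size_factors(one)), 1)

  # no gene positive everywhere -> library-size fallback with warning
  disjoint <- rbind(g1 = c(5L, 0L), g2 = c(0L, 10L))
  colnames(disjoint) <- c("a", "b")
  expect_warning(sf <- estimate_size_factors(disjoint), "library-size")
  expect_equal(unname(sf), c(5, 10) / sqrt(50))
})

test_that("identical groups give zero fold change and p = 1", {
  sheet <- two_group_sheet(3)
  x <- matrix(rep(c(3L, 10L, 0L), each = 6), 3, 6, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), sheet$sample_id))
  res <- nb_contrast_test(x, sheet,
                          contrast_spec("IFNB_TNF", "CTRL", "NS", "CTRL"),
                          size_factors = unit_size_factors(sheet$sample_id))
  expect_equal(res$log2fc, rep(0, 3))
  expect_equal(res$p, rep(1, 3))
})

test_that("log2FC estimates are invariant to compensated library rescaling", {
  bundle <- small_bundle()
  sheet <- bundle$sheet
  counts <- bundle$counts
  sf <- attr(counts, "size_factors")
  ctr <- contrast_spec("IFNB_TNF", "STAT2", "IFNB_TNF", "CTRL")
  r1 <- nb_contrast_test(counts, sheet, ctr, size_factors = sf)
  k <- 3
  counts2 <- counts
  counts2[, 1] <- counts2[, 1] * k
  sf2 <- sf
  sf2[1] <- sf2[1] * k
  r2 <- nb_contrast_test(counts2, sheet, ctr, size_factors = sf2)
  expect_equal(r2$log2fc, r1$log2fc, tolerance = 1e-6)
})

test_that("both dispersion modes agree in rank with an exact permutation oracle", {
  set.seed(9)
  ng <- 200
  mu <- sample(c(20, 100), ng, replace = TRUE)
  counts <- matrix(rnbinom(ng * 6, mu = rep(mu, 6), size = 20), ng,
                   dimnames = list(sprintf("g%03d", 1:ng),
                                   sprintf("s%d", 1:6)))
  sheet <- two_group_sheet(3)
  ctr <- contrast_spec("IFNB_TNF", "CTRL", "NS", "CTRL")
  sf <- unit_size_factors(sheet$sample_id)
  p_gene <- nb_contrast_test(counts, sheet, ctr, size_factors = sf,
                             dispersion = "genewise")$p
  p_comm <- nb_contrast_test(counts, sheet, ctr, size_factors = sf)$p
  # exact permutation p over all C(6,3) = 20 relabelings of each gene
  perms <- combn(6, 3)
  p_perm <- apply(counts, 1, function(x) {
    obs <- abs(log2((mean(x[1:3]) + 0.5) / (mean(x[4:6]) + 0.5)))
    st <- apply(perms, 2, function(ix) {
      abs(log2((mean(x[ix]) + 0.5) / (mean(x[-ix]) + 0.5)))
    })
    mean(st >= obs - 1e-12)
  })
  expect_gt(cor(p_gene, p_perm, method = "spearman"), 0.9)
  expect_gt(cor(p_comm, p_perm, method = "spearman"), 0.8)
})

test_that("detection power rises with the true effect size", {
  sheet <- two_group_sheet(3)
  ctr <- contrast_spec("IFNB_TNF", "CTRL", "NS", "CTRL")
  sf <- unit_size_factors(sheet$sample_id)
  rate <- sapply(c(0.5, 1, 2), function(lfc) {
    set.seed(31)
    ng <- 300
    counts <- cbind(
      matrix(rnbinom(ng * 3, mu = 100 * 2^lfc, size = 20), ng),
      matrix(rnbinom(ng * 3, mu = 100, size = 20), ng)
    )
    dimnames(counts) <- list(sprintf("g%03d", 1:ng), sheet$sample_id)
    mean(nb_contrast_test(counts, sheet, ctr, size_factors = sf)$p < 0.05)
  })
  expect_true(all(diff(rate) > 0))
  expect_gt(rate[3], 0.95)
})

test_that("status calls apply the strict three-threshold rule", {
  res <- toy_results(
    gene_id = sprintf("g%d", 1:6),
    log2fc = c(2, log2(1.5), -2, 0.9, 2, -0.1),
    p = c(1e-6, 1e-6, 1e-6, 0.2, 1e-6, 0.5),
    q = c(1e-4, 1e-4, 1e-4, 0.5, 0.2, 0.9),
    status = rep("NS", 6)
  )
  res$status <- NULL
  out <- apply_status(res)
  expect_identical(as.character(out$status),
                   c("UP",   # clear pass
                     "NS",   # log2fc == log2(1.5): strict >
                     "DOWN", # mirrored rule
                     "NS",   # fails p
                     "NS",   # fails fdr
                     "NS"))  # fails everything
})

test_that("BH adjustment matches the step-up definition and its invariants", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(numeric(0)), "nonempty")
  set.seed(41)
  for (i in 1:20) {
    p <- runif(50)
    q <- bh_adjust(p)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(q <= 1))
    expect_true(all(diff(q[order(p)]) >= -1e-15))  # monotone in p
  }
})

test_that("delta-delta-Ct folds follow the closed form", {
  expect_equal(ddct_fold(20, 15, 20, 15), 1)        # ddCt = 0
  expect_equal(ddct_fold(17, 15, 20, 15), 8)        # 3-cycle drop -> 2^3
  # invariance to a global Ct shift
  expect_equal(ddct_fold(17 + 4, 15 + 4, 20 + 4, 15 + 4), 8)
  expect_equal(ddct_fold(c(20, 17), c(15, 15), c(20, 20), c(15, 15)),
               c(1, 8))
  expect_error(ddct_fold(Inf, 15, 20, 15), "finite")
})

test_that("fold-change concordance reports correlation and log-scale slope", {
  fc <- c(1.5, 2, 4, 8, 0.5)
  out <- fc_concordance(fc, fc)
  expect_equal(out$correlation, 1)
  expect_equal(out$slope, 1)
  out2 <- fc_concordance(fc, fc^2)  # squaring doubles the log2 slope
  expect_equal(out2$slope, 2)
  expect_error(fc_concordance(fc, -fc), "positive")
  expect_error(fc_concordance(1:2, 1:2), "length")
  # 13 paired measurements with moderate noise stay strongly concordant
  withr::with_seed(43, {
    la <- runif(13, -2, 4)
    lb <- la + rnorm(13, sd = 0.3)
    out3 <- fc_concordance(2^la, 2^lb)
  })
  expect_gt(out3$correlation, 0.9)
})
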