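test_that("histogram-rule bin counts follow the drop-factor convention", {
  expect_identical(bin_count(1024), 11L)          # log2 exact: 10 + 1
  expect_identical(bin_count(3000), 13L)          # ceil(log2(3000) + 1)
  expect_identical(bin_count(1024, k = 0.3), 4L)  # ceil(11 * 0.3)
  expect_identical(bin_count(1000, "rice"), 20L)  # ceil(2 * 10)
  expect_identical(bin_count(100, "sqrt"), 10L)
  expect_identical(bin_count(1), 1L)              # tiny-path floor relaxed
  expect_identical(bin_count(3, k = 0.3), 1L)     # ceil(3 * 0.3) = 1, N < 4
  expect_identical(bin_count(4, k = 0.3), 2L)     # floored at 2 from N >= 4
  expect_error(bin_count(100, k = 0.2), "0.3")
  expect_error(bin_count(100, "median"), "arg")
  expect_error(bin_count(100, "scott"), "pseudotime")
  x <- c(rep(0, 50), rexp(50))
  expect_gte(bin_count(100, "doane", x = x), 2L)
  expect_gte(bin_count(100, "freedman_diaconis", x = x), 2L)
})

test_that("bin assignment uses left-closed intervals, closed last bin", {
  expect_identical(assign_bins(c(0, 2.5, 5, 7.5, 10), 5), 1:5)
  # t exactly on an internal boundary goes right (left-closed)
  expect_identical(assign_bins(c(0, 2, 4), 2)[2], 2L)
  expect_identical(assign_bins(rep(3.7, 6), 4), rep(1L, 6))
  expect_error(assign_bins(c(0, 1), 0), "n_bins")
})

test_that("bin indices are non-decreasing in pseudotime", {
  set.seed(31)
  for (i in 1:20) {
    pt <- rgamma(200, sample(1:4, 1), 1)
    idx <- assign_bins(pt, sample(2:15, 1))
    expect_true(all(diff(idx[order(pt)]) >= 0))
  }
})

test_that("oversized bins split into near-equal sub-bins by rank", {
  ce <- ce_with_bin_sizes(c(10, 10, 100))
  bm <- bin_pseudotime(ce, n_bins = 3, split_bin = FALSE)
  expect_identical(bm$paths$A$size, c(10L, 10L, 100L))
  # mu = 40, sigma = sqrt(1800), mu + sigma ~ 82.4 -> 100 splits into 2 x 50
  eq <- equalize_bins(bm, split_large = TRUE)
  expect_identical(eq$paths$A$size, c(10L, 10L, 50L, 50L))
  expect_identical(eq$paths$A$bin, 1:4)
  # sizes all equal: sigma = 0, nothing to do
  ce2 <- ce_with_bin_sizes(c(10, 10, 10))
  bm2 <- bin_pseudotime(ce2, n_bins = 3, split_bin = FALSE)
  expect_identical(equalize_bins(bm2, split_large = TRUE)$paths$A$size,
                   c(10L, 10L, 10L))
})

test_that("pruning removes bins under mu - sigma and drops their cells", {
  ce <- ce_with_bin_sizes(c(1, 50, 50))
  bm <- bin_pseudotime(ce, n_bins = 3, split_bin = FALSE)
  # mu ~ 33.7, sigma ~ 23.1 -> the 1-cell bin is below mu - sigma ~ 10.6
  eq <- equalize_bins(bm, split_large = FALSE, prune_small = TRUE)
  expect_identical(eq$paths$A$size, c(50L, 50L))
  expect_identical(eq$n_dropped, 1L)
  expect_identical(sum(is.na(eq$cells$bin)), 1L)
})

test_that("equalization is a no-op with both flags off and idempotent", {
  ce <- ce_with_bin_sizes(c(10, 10, 100))
  bm <- bin_pseudotime(ce, n_bins = 3, split_bin = FALSE)
  expect_identical(equalize_bins(bm, FALSE, FALSE)$paths$A$size,
                   bm$paths$A$size)
  eq1 <- equalize_bins(bm, split_large = TRUE, prune_small = TRUE)
  eq2 <- equalize_bins(eq1, split_large = TRUE, prune_small = TRUE)
  expect_identical(eq2$paths$A$size, eq1$paths$A$size)
})

test_that("drop_tails truncates to the shortest path's bin range", {
  ce <- ce_two_paths(n_per_path = 60)
  bm <- bin_pseudotime(ce, n_bins = c(A = 6, B = 3), split_bin = FALSE)
  expect_identical(max(bm$paths$A$bin), 6L)
  expect_identical(max(bm$paths$B$bin), 3L)
  td <- drop_tails(bm)
  expect_identical(max(td$paths$A$bin), 3L)
  expect_identical(max(td$paths$B$bin), 3L)
  # equal bin counts: unchanged
  bm2 <- bin_pseudotime(ce, n_bins = 4, split_bin = FALSE)
  expect_identical(drop_tails(bm2)$paths$A$size, bm2$paths$A$size)
  # single path: warning, no-op
  ce1 <- ce_with_bin_sizes(c(10, 10))
  bm1 <- bin_pseudotime(ce1, n_bins = 2, split_bin = FALSE)
  expect_warning(drop_tails(bm1), "2 paths")
})

test_that("aggregation sums member cells and separates paths", {
  counts <- matrix(c(1, 2, 3, 4), 2, 2)  # cells: [1,2] and [3,4]
  ce <- cell_experiment(counts, c(0.1, 0.2), c("A", "A"))
  bm <- bin_pseudotime(ce, n_bins = 1, split_bin = FALSE)
  be <- aggregate_bins(ce, bm)
  expect_equal(unname(SummarizedExperiment::assay(be, "pseudobulk")[, 1]),
               c(4, 6))
  # same pseudotime, different paths -> distinct bins
  ce2 <- cell_experiment(counts, c(0.5, 0.5), c("A", "B"))
  bm2 <- bin_pseudotime(ce2, split_bin = FALSE)
  be2 <- aggregate_bins(ce2, bm2)
  expect_identical(ncol(be2), 2L)
  expect_identical(SummarizedExperiment::colData(be2)$path, c("A", "B"))
})

test_that("aggregation conserves total counts over retained cells", {
  ce <- ce_two_paths(n_per_path = 80, n_genes = 10, seed = 9)
  bm <- bin_pseudotime(ce)
  be <- aggregate_bins(ce, bm)
  expect_equal(sum(SummarizedExperiment::assay(be, "pseudobulk")),
               sum(SummarizedExperiment::assay(ce, "counts")))
})

test_that("size factors are totals over their geometric mean", {
  pb <- matrix(c(50, 50, 100, 100), 2, 2)
  be <- binned_from_matrix(pb, c("A", "A"), c(1, 2))
  sf <- size_factors(be)
  expect_equal(sf$size_factor, c(100 / sqrt(2e4), 200 / sqrt(2e4)),
               tolerance = 1e-12)
  expect_equal(mean(sf$offset), 0)
  # equal totals -> unit factors
  pb2 <- matrix(c(5, 5, 5, 5), 2, 2)
  expect_equal(size_factors(binned_from_matrix(pb2, c("A", "A"),
                                               c(1, 2)))$size_factor,
               c(1, 1))
})

test_that("a zero-total bin errors and points to pruning", {
  pb <- matrix(c(0, 0, 25, 25), 2, 2)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(pseudobulk = pb),
    colData = S4Vectors::DataFrame(path = c("A", "A"), bin_index = c(1, 2),
                                   bin_size = c(1L, 1L),
                                   bin_total = colSums(pb)))
  expect_error(size_factors(se), "prune")
})
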