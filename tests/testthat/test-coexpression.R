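test_that("pearson_r matches direct evaluation and enforces preconditions", {
  expect_equal(pearson_r(c(1, 2, 3, 4), c(2, 4, 6, 8)), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(pearson_r(1:3, 1:4), "length mismatch")
  expect_error(pearson_r(1:2, 2:1), "at least 3")
  expect_error(pearson_r(c(1, 1, 1), 1:3, xname = "geneX"), "geneX")
})

test_that("affine invariance with positive slope, sign flip with negative", {
  set.seed(41)
  x <- rnorm(12); y <- rnorm(12)
  r <- pearson_r(x, y)
  expect_equal(pearson_r(3 * x + 7, y), r)
  expect_equal(pearson_r(x, 0.5 * y - 2), r)
  expect_equal(pearson_r(-2 * x + 1, y), -r)
})

ranked_fixture <- function() {
  samples <- paste(rep(c("flower", "leaf", "stem", "root"), each = 3), 1:3,
                   sep = "_")
  tiss <- setNames(rep(c("flower", "leaf", "stem", "root"), each = 3),
                   samples)
  metab <- matrix(c(1, 1.2, 0.9, 2, 2.1, 1.9, 3, 3.2, 2.8, 30, 31, 29),
                  1, 12, dimnames = list("hb", samples))
  expr <- rbind(
    prop = 2 * metab[1, ] + 1,                 # proportional to metabolite
    leafy = rep(c(1, 10, 1, 1), each = 3) + (1:12) / 100,  # leaf-maximal
    noise = c(5, 2, 8, 1, 9, 3, 7, 4, 6, 2, 8, 5))
  colnames(expr) <- samples
  list(expr = expr, metab = metab, tiss = tiss)
}

test_that("rank_candidates flags strong/edge pairs and tissue co-maxima", {
  fx <- ranked_fixture()
  res <- rank_candidates(fx$expr, fx$metab, fx$tiss)
  expect_identical(nrow(res), 3L)
  expect_true(!is.unsorted(rev(res$r)))
  prop <- res[res$gene == "prop", ]
  expect_equal(prop$r, 1)
  expect_true(prop$strong && prop$edge)
  expect_true(prop$root_coexpressed)
  # leaf-maximal gene never counts as root-coexpressed, whatever its r
  leafy <- res[res$gene == "leafy", ]
  expect_identical(leafy$gene_max_tissue, "leaf")
  expect_false(leafy$root_coexpressed)
  # strong implies edge at the default thresholds
  expect_true(all(!res$strong | res$edge))
})

test_that("sample mismatches and zero variance are rejected by name", {
  fx <- ranked_fixture()
  bad <- fx$metab; colnames(bad)[1] <- "extra_9"
  expect_error(rank_candidates(fx$expr, bad, fx$tiss), "extra_9")
  flat <- fx$expr; flat["noise", ] <- 5
  expect_error(rank_candidates(flat, fx$metab, fx$tiss), "noise")
})

test_that("tissue-mean correlation mode collapses replicates first", {
  fx <- ranked_fixture()
  res <- rank_candidates(fx$expr, fx$metab, fx$tiss, level = "tissue_mean")
  expect_identical(unique(res$n), 4L)
  expect_equal(res$r[res$gene == "prop"], 1)
})

test_that("network export writes strictly thresholded, sorted edges", {
  fx <- ranked_fixture()
  res <- rank_candidates(fx$expr, fx$metab, fx$tiss)
  f <- withr::local_tempfile(fileext = ".tsv")
  edges <- export_network(res, f, threshold = 0.50)
  expect_true(all(edges$r > 0.50))
  back <- utils::read.delim(f)
  expect_identical(nrow(back), nrow(edges))
  # a threshold of 1.0 can never be exceeded
  none <- export_network(res, f, threshold = 1.0)
  expect_identical(nrow(none), 0L)
  expect_identical(readLines(f)[1], "gene\tmetabolite\tr")
})
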