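test_that("TPM matches the closed form and columns sum to one million", {
  expect_equal(unname(computeTpm(cbind(s = 5), 100)[1, 1]), 1e6)
  tpm <- computeTpm(cbind(s = c(10, 10)), c(100, 200))
  expect_equal(unname(tpm[, 1]), c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)
  ## property: random count matrices
  set.seed(21)
  for (i in 1:20) {
    n <- sample(2:40, 1)
    counts <- matrix(rpois(n * 4, 30), n, 4,
                     dimnames = list(NULL, c("2nd", "4th", "female",
                                             "male")))
    tpm <- computeTpm(counts, sample(200:2000, n, TRUE))
    expect_equal(unname(colSums(tpm)), rep(1e6, 4), tolerance = 1e-3)
  }
  ## all-zero sample stays all-zero
  z <- computeTpm(cbind(s = c(0, 0)), c(100, 200))
  expect_true(all(z == 0))
  expect_error(computeTpm(cbind(s = -1), 100), "nonnegative")
})

test_that("pooling sums counts then renormalises, not averaging TPM", {
  ## identical member samples: pooled TPM equals member TPM
  counts <- matrix(c(10, 20, 10, 20, 5, 8, 5, 8), 2, 4,
                   dimnames = list(c("t1", "t2"),
                                   c("2nd", "4th", "female", "male")))
  cm <- countMatrix(counts, c(100, 100))
  pooled <- poolGroups(cm)
  memberTpm <- computeTpm(cm)
  expect_equal(pooled$tpm[, "nymphs"], memberTpm[, "2nd"])
  expect_equal(unname(colSums(pooled$tpm)), rep(1e6, 2), tolerance = 1e-3)
  ## disjoint expression halves the pool
  c2 <- countMatrix(matrix(c(10, 0, 0, 10, 1, 1, 1, 1), 2, 4,
                           dimnames = dimnames(counts)), c(100, 100))
  expect_equal(unname(poolGroups(c2)$tpm[, "nymphs"]), c(5e5, 5e5))
  ## counterexample: with unequal depths, pooled TPM != mean of member TPM
  c3 <- countMatrix(matrix(c(90, 10, 1000, 9000, 1, 1, 1, 1), 2, 4,
                           dimnames = dimnames(counts)), c(100, 100))
  p3 <- poolGroups(c3)$tpm[, "nymphs"]
  avg3 <- rowMeans(computeTpm(c3)[, c("2nd", "4th")])
  expect_gt(max(abs(p3 - avg3)), 1e4)
  expect_error(poolGroups(cm, list(g = "nope")), "unknown sample")
})

test_that("log2 fold-change reproduces printed ratios and sentinel states", {
  expect_equal(round(log2FoldChange(253.24, 7.24), 4), 5.1284)
  expect_identical(formatLog2fc(log2FoldChange(0, 0)), "undefined")
  expect_identical(formatLog2fc(log2FoldChange(1, 0)), "+inf")
  expect_identical(formatLog2fc(log2FoldChange(0, 1)), "-inf")
  expect_error(log2FoldChange(-1, 2), "nonnegative")
  ## antisymmetry on random positive pairs
  set.seed(31)
  a <- runif(500, 0.01, 1e4); b <- runif(500, 0.01, 1e4)
  expect_equal(log2FoldChange(a, b), -log2FoldChange(b, a))
})

test_that("contrast ranking floors, ranks by |log2FC| and ignores order", {
  t3 <- read.delim(hbugExtdata("stage_contrast_tpm.tsv"))
  blk <- t3[t3$contrast == "2nd:4th", ]
  ranked <- rankContrast(blk$gene, blk$tpm_num, blk$tpm_den,
                         contrastConfig("4th:2nd", topK = 5))
  expect_equal(round(max(ranked$log2fc[ranked$direction == "up"]), 4),
               5.1284)
  expect_equal(round(min(ranked$log2fc[ranked$direction == "down"]), 4),
               -5.3563)
  ## row order invariance
  perm <- sample(nrow(blk))
  r2 <- rankContrast(blk$gene[perm], blk$tpm_num[perm], blk$tpm_den[perm],
                     contrastConfig("4th:2nd", topK = 5))
  expect_identical(ranked, r2)
  ## everything below the floor: empty under filter_min_both
  r3 <- rankContrast(c("a", "b"), c(4, 1), c(1, 4), contrastConfig())
  expect_identical(nrow(r3), 0L)
  ## clamp mode instead floors the values
  r4 <- rankContrast(c("a"), 40, 1, contrastConfig(floorMode = "clamp"))
  expect_equal(r4$log2fc, log2(40 / 5))
  expect_error(rankContrast("a", 1, 1, contrastConfig(topK = 0)), "topK")
})

test_that("sex-pattern classifier reproduces the survey's category calls", {
  ## 0.03 vs 18.87: female-specific, |log2(m:f)| = 9.2969
  expect_identical(classifySexPattern(0.03, 18.87), "female_specific")
  expect_equal(round(abs(log2FoldChange(0.03, 18.87)), 4), 9.2969)
  ## both >= 5 TPM with >= 2-fold differential: male-dominant expressed
  expect_identical(classifySexPattern(38.09, 6.24),
                   "male_dominant_expressed")
  expect_identical(classifySexPattern(6.24, 38.09),
                   "female_dominant_expressed")
  ## male side of the specific rule
  expect_identical(classifySexPattern(9.95, 0.01), "male_dominant")
  ## below both rules
  expect_identical(classifySexPattern(4.9, 4.9), "none")
  expect_identical(classifySexPattern(5.5, 5.6), "none")
})

test_that("count containers validate sample labels and lengths", {
  m <- matrix(1:8, 2, 4,
              dimnames = list(c("t1", "t2"), c("2nd", "4th", "female",
                                               "male")))
  expect_s4_class(countMatrix(m, c(100, 200)), "SummarizedExperiment")
  expect_error(countMatrix(m[, 1:3], c(100, 200)), "columns")
  expect_error(countMatrix(m, c(100, 0)), "positive")
  expect_error(countMatrix(-m, c(100, 200)), "nonnegative")
})
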