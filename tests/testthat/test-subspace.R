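test_that("pearsonCorrelation matches hand-computed values and flags degenerates", {
  expect_equal(pearsonCorrelation(c(1, 5, 2), c(1, 5, 2)), 1)
  expect_equal(pearsonCorrelation(c(1, 5, 2), -c(1, 5, 2)), -1)
  # (1,2,3) vs (1,2,4): 3 / sqrt(2 * 42/9)
  expect_equal(pearsonCorrelation(c(1, 2, 3), c(1, 2, 4)),
               3 / sqrt(2 * 42 / 9), tolerance = 1e-12)
  expect_equal(pearsonCorrelation(c(1, 2, 3), c(1, 2, 4)), 0.9819805,
               tolerance = 1e-6)
  expect_error(pearsonCorrelation(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearsonCorrelation(1, 2), "two samples")
})

test_that("snrScore matches hand-computed values and is affine-invariant", {
  expect_equal(snrScore(c(1, 3, 0, 0), c(1, 1, -1, -1)), 2, tolerance = 1e-9)
  expect_equal(snrScore(c(2, 4, 1, 3), c(1, 1, -1, -1)), 0.5, tolerance = 1e-9)
  expect_equal(snrScore(c(5, 5, 5, 5), c(1, 1, -1, -1)), 0)
  expect_error(snrScore(c(1, 2), c(1, 1)), "both classes")

  set.seed(4)
  for (i in 1:20) {
    v <- rnorm(14)
    y <- rep(c(1, -1), 7)
    a <- runif(1, 0.1, 10); b <- rnorm(1)
    expect_equal(snrScore(a * v + b, y), snrScore(v, y), tolerance = 1e-9)
  }
})

test_that("clusterGenes recovers planted duplicate groups and handles bounds", {
  set.seed(9)
  base1 <- rnorm(20); base2 <- rnorm(20)
  v <- rbind(base1, base1 + rnorm(20, 0, 0.05), base1 + rnorm(20, 0, 0.05),
             base2, base2 + rnorm(20, 0, 0.05), base2 + rnorm(20, 0, 0.05))
  cl <- clusterGenes(v, 2)
  expect_equal(length(unique(cl)), 2L)
  expect_equal(length(unique(cl[1:3])), 1L)
  expect_equal(length(unique(cl[4:6])), 1L)
  expect_false(cl[1] == cl[4])

  expect_equal(clusterGenes(v, nrow(v)), 1:6)
  expect_equal(unique(clusterGenes(v, 1)), 1L)
  expect_error(clusterGenes(v, 7), "exceeds")
  vconst <- rbind(v, rep(1, 20))
  expect_error(clusterGenes(vconst, 2), "constant")
})

test_that("buildFeatureSpace keeps one top-SNR gene per cluster", {
  set.seed(10)
  ds <- makeRecoveryFixture(1)
  std <- exprsMatrix(ds)
  yBin <- ifelse(classCodes(ds) <= 5, 1, -1)
  sp <- buildFeatureSpace(std, yBin, K = 10)
  expect_s4_class(sp, "FeatureSpace")
  expect_length(geneIndices(sp), 10)
  cl <- clusterAssignment(sp)[geneIndices(sp)]
  expect_false(anyDuplicated(cl) > 0)
  # each selected gene attains its cluster's max SNR
  snrAll <- apply(std, 1, snrScore, binaryLabels = yBin)
  for (k in seq_along(geneIndices(sp))) {
    members <- which(clusterAssignment(sp) == cl[k])
    expect_equal(snrScores(sp)[k], max(snrAll[members]), tolerance = 1e-12)
  }
  # never two genes from the same planted redundancy group
  truth <- geneTruth(ds)
  picks <- truth[geneIndices(sp), ]
  grp <- ifelse(is.na(picks$parent), picks$gene_id, picks$parent)
  expect_false(anyDuplicated(grp[picks$role != "noise"]) > 0)
})

test_that("buildFeatureSpace edge cases: K = nGenes, ties, constants", {
  set.seed(11)
  v <- matrix(rnorm(8 * 12), 8, 12)
  y <- rep(c(1, -1), each = 6)
  sp <- buildFeatureSpace(v, y, K = 8)
  expect_setequal(geneIndices(sp), 1:8)

  # two identical genes share a cluster; the lower index is selected
  vdup <- rbind(v[1, ], v[1, ], matrix(rnorm(4 * 12), 4, 12))
  spd <- buildFeatureSpace(vdup, y, K = 5)
  expect_true(1L %in% geneIndices(spd))
  expect_false(2L %in% geneIndices(spd))

  vconst <- rbind(v, rep(3, 12))
  spc <- buildFeatureSpace(vconst, y, K = 8)  # constant dropped, 8 usable
  expect_false(9L %in% geneIndices(spc))
  expect_error(buildFeatureSpace(vconst, y, K = 9), "non-constant")
})

test_that("subspace sampling respects D, membership and determinism", {
  set.seed(12)
  v <- matrix(rnorm(30 * 20), 30, 20)
  y <- rep(c(1, -1), each = 10)
  sp <- buildFeatureSpace(v, y, K = 12)
  sub <- sampleFeatureSubspace(sp, 5)
  expect_length(geneIndices(sub), 5)
  expect_true(all(geneIndices(sub) %in% geneIndices(sp)))
  full <- sampleFeatureSubspace(sp, 12)
  expect_setequal(geneIndices(full), geneIndices(sp))
  expect_error(sampleFeatureSubspace(sp, 13), "exceeds")
  expect_error(sampleFeatureSubspace(sp, 0), "at least 1")

  set.seed(99); a <- geneIndices(sampleFeatureSubspace(sp, 6))
  set.seed(99); b <- geneIndices(sampleFeatureSubspace(sp, 6))
  expect_identical(a, b)
})

test_that("coselection rate and theoretical diversity agree with theory", {
  expect_equal(theoreticalDiversity(100, 20), 0.8)
  expect_equal(theoreticalDiversity(100, 100), 0)
  expect_equal(theoreticalDiversity(100, 0), 1)
  expect_error(theoreticalDiversity(10, 11), "D <= K")

  # mean pairwise overlap fraction of independent D-subsets of K
  # genes is D/K (hypergeometric expectation D^2/K over D)
  sp <- methods::new("FeatureSpace", geneIndices = 1:50, K = 50L,
                     clusterAssignment = 1:50, snrScores = rep(1, 50))
  set.seed(13)
  overlaps <- replicate(400, {
    a <- geneIndices(sampleFeatureSubspace(sp, 10))
    b <- geneIndices(sampleFeatureSubspace(sp, 10))
    length(intersect(a, b)) / 10
  })
  se <- sd(overlaps) / sqrt(length(overlaps))
  expect_lt(abs(mean(overlaps) - 10 / 50), 3 * se)
})
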