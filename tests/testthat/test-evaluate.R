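test_that("stratified folds track class proportions within one sample", {
  set.seed(1)
  labels <- rep(1:3, c(45, 30, 15))
  fold <- stratifiedFolds(labels, 3)
  expect_equal(attr(fold, "nFolds"), 3L)
  for (f in 1:3) {
    tab <- table(factor(labels[fold == f], levels = 1:3))
    expect_equal(unname(as.integer(tab)), c(15L, 10L, 5L))
  }
  # uneven classes stay within +/- 1
  labels2 <- rep(1:2, c(10, 7))
  fold2 <- stratifiedFolds(labels2, 3)
  for (f in 1:3)
    expect_lte(abs(sum(labels2[fold2 == f] == 2) - 7 / 3), 1)
})

test_that("folds degrade with a warning when a class is tiny", {
  labels <- rep(1:2, c(20, 2))
  expect_warning(fold <- stratifiedFolds(labels, 3), "reducing folds")
  expect_equal(attr(fold, "nFolds"), 2L)
  expect_error(suppressWarnings(stratifiedFolds(rep(1:2, c(5, 1)), 3)),
               "too small")
})

test_that("grid search returns the stated default grid and sane winners", {
  # default grids: C in 2^-2..2^15 (18), sigma in 2^-6..2^5 (12)
  expect_length(eval(formals(gridSearchBranch)$cGrid), 18)
  expect_length(eval(formals(gridSearchBranch)$sigmaGrid), 12)

  set.seed(2)
  x <- rbind(matrix(rnorm(20 * 2, mean = 0), 20, 2),
             matrix(rnorm(20 * 2, mean = 4), 20, 2))
  y <- rep(c(1, -1), each = 20)
  one <- gridSearchBranch(x, y, cGrid = 2, sigmaGrid = 1)
  expect_equal(one$cost, 2)
  expect_equal(one$sigma, 1)

  best <- gridSearchBranch(x, y, cGrid = c(1, 8), sigmaGrid = c(0.5, 2, 8))
  expect_equal(best$gMean, 1)  # separable toy data
  expect_true(best$cost %in% c(1, 8) && best$sigma %in% c(0.5, 2, 8))
})

test_that("repeated stratified CV is deterministic and averages correctly", {
  ds <- makeToyDataset(nPerClass = c(15, 9, 6), nGenes = 24, seed = 3)
  a <- repeatedStratifiedCV(ds, nFolds = 3, nRepeats = 2, seed = 7,
                            K = 12, D = 4, L = 3, correction = "thr")
  b <- repeatedStratifiedCV(ds, nFolds = 3, nRepeats = 2, seed = 7,
                            K = 12, D = 4, L = 3, correction = "thr")
  expect_identical(a$perRepeat, b$perRepeat)
  expect_equal(a$summary$mean[a$summary$metric == "gMean"],
               mean(a$perRepeat$gMean), tolerance = 1e-12)
  expect_equal(a$summary$mean[a$summary$metric == "acc"],
               mean(a$perRepeat$acc), tolerance = 1e-12)
  expect_length(a$reports, 2)
  expect_length(a$avgPerClassAccuracy, 3)
})

test_that("feature spaces depend only on training samples (no leakage)", {
  ds <- makeToyDataset(nPerClass = c(15, 9, 6), nGenes = 24, seed = 4)
  lab <- classCodes(ds)
  set.seed(5)
  fold <- stratifiedFolds(lab, 3)
  tr <- fold != 1
  model <- trainEnsemble(ds[, tr], K = 10, D = 4, L = 2,
                         correction = "none", seed = 6)
  # recompute spaces from the training subset alone, standardized with
  # the model's stored constants: identical gene selections
  std <- (exprsMatrix(ds[, tr]) - model@center) / model@scale
  for (i in 1:3) {
    yBin <- ifelse(lab[tr] == i, 1, -1)
    sp <- buildFeatureSpace(std, yBin, K = 10)
    expect_identical(geneIndices(sp), geneIndices(model@branches[[i]]$space))
  }
})

test_that("the D sweep emits one row per dimension with sane values", {
  ds <- makeToyDataset(nPerClass = c(15, 9, 6), nGenes = 24, seed = 8)
  tab <- sweepSubspaceDimension(ds, dValues = c(3, 6, 12), K = 12,
                                nFolds = 3, nRepeats = 1, seed = 9,
                                L = 3, correction = "thr")
  expect_equal(nrow(tab), 3)
  expect_equal(tab$D, c(3, 6, 12))
  expect_true(all(tab$gMean >= 0 & tab$gMean <= 1))
  expect_true(all(tab$acc >= 0 & tab$acc <= 1))
  expect_error(sweepSubspaceDimension(ds, dValues = c(3, 20), K = 12),
               "<= K")
})
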