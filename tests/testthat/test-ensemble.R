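test_that("trained ensembles have the configured structure", {
  ds <- makeToyDataset(nPerClass = c(12, 8, 6), nGenes = 30, seed = 2)
  m <- trainEnsemble(ds, K = 20, D = 5, L = 4, correction = "thr", seed = 3)
  expect_s4_class(m, "EnsembleModel")
  expect_equal(nClasses(m), 3L)
  expect_equal(m@L, 4L)
  for (i in 1:3) {
    br <- m@branches[[i]]
    expect_length(br$classifiers, 4)
    for (cl in br$classifiers)
      expect_true(all(geneIndices(cl@subspace) %in% geneIndices(br$space)))
  }
})

test_that("identical seeds give identical models and predictions", {
  ds <- makeToyDataset(seed = 4)
  test <- makeToyDataset(seed = 5)
  m1 <- trainEnsemble(ds, K = 15, D = 5, L = 3, correction = "rus", seed = 42)
  m2 <- trainEnsemble(ds, K = 15, D = 5, L = 3, correction = "rus", seed = 42)
  expect_identical(predict(m1, test, type = "code"),
                   predict(m2, test, type = "code"))
  expect_identical(counterVotes(m1, test), counterVotes(m2, test))
})

test_that("counters are proportions quantized to 1/L", {
  ds <- makeToyDataset(seed = 6)
  L <- 7
  m <- trainEnsemble(ds, K = 15, D = 4, L = L, correction = "none", seed = 1)
  cnt <- counterVotes(m, ds)
  expect_true(all(cnt >= 0 & cnt <= 1))
  expect_equal(cnt * L, round(cnt * L), tolerance = 1e-9)
  expect_equal(colnames(cnt), labelMap(ds))
})

test_that("threshold correction stores the branch theta, RUS balances subsets", {
  ds <- makeToyDataset(nPerClass = c(20, 10, 5), nGenes = 24, seed = 7)
  thr <- trainEnsemble(ds, K = 12, D = 4, L = 2, correction = "thr", seed = 2)
  # branch 3: 5 positives vs 30 negatives
  expect_equal(thr@branches[[3]]$classifiers[[1]]@theta,
               (5 - 30) / (5 + 30 + 2), tolerance = 1e-12)
  expect_equal(thr@branches[[1]]$classifiers[[1]]@theta,
               (20 - 15) / (20 + 15 + 2), tolerance = 1e-12)

  rus <- trainEnsemble(ds, K = 12, D = 4, L = 2, correction = "rus", seed = 2)
  # RUS base learners are fitted on 2 * minority samples
  fit <- rus@branches[[3]]$classifiers[[1]]@fit
  expect_equal(sum(fit$nSV), fit$tot.nSV)
  expect_lte(fit$tot.nSV, 10)
  expect_equal(rus@branches[[3]]$classifiers[[1]]@theta, 0)
})

test_that("predictions are invariant to permuting gene order", {
  ds <- makeToyDataset(seed = 8)
  m <- trainEnsemble(ds, K = 15, D = 5, L = 3, correction = "thr", seed = 9)
  v <- exprsMatrix(ds)
  perm <- sample(nrow(v))
  shuffled <- v[perm, ]
  expect_identical(predict(m, shuffled, type = "code"),
                   predict(m, v, type = "code"))
  # missing genes are refused
  expect_error(predict(m, v[-1, , drop = FALSE]), "missing genes")
})

test_that("argmax decoding follows counters with the documented tie-break", {
  ds <- makeToyDataset(seed = 10)
  m <- trainEnsemble(ds, K = 15, D = 5, L = 5, correction = "none", seed = 11)
  cnt <- counterVotes(m, ds)
  pred <- predict(m, ds, type = "code")
  for (s in seq_len(ncol(ds))) {
    best <- which(cnt[s, ] == max(cnt[s, ]))
    expect_true(pred[s] %in% best)
  }
  # class labels come back in the original naming
  cls <- predict(m, ds)
  expect_s3_class(cls, "factor")
  expect_equal(levels(cls), labelMap(ds))
})

test_that("strong separable signal yields near-perfect held-out G-mean", {
  # signal must be dense in the feature space for the premise to hold:
  # clustering keeps one representative per informative group, so use a
  # small gene pool (9 informative, 3 noise) and K = 6, D = 4
  train <- makeToyDataset(nPerClass = c(20, 12, 8), nGenes = 12,
                          effect = 4, seed = 12)
  test <- makeToyDataset(nPerClass = c(20, 12, 8), nGenes = 12,
                         effect = 4, seed = 13)
  m <- trainEnsemble(train, K = 6, D = 4, L = 21, correction = "thr",
                     seed = 14)
  r <- multiclassMetrics(classCodes(test), predict(m, test, type = "code"))
  expect_gt(metricValues(r)[["gMean"]], 0.9)
})

test_that("degenerate parameters reduce to a single OAA SVM", {
  train <- makeToyDataset(nPerClass = c(14, 10, 7), nGenes = 24,
                          effect = 2, seed = 15)
  test <- makeToyDataset(nPerClass = c(14, 10, 7), nGenes = 24,
                         effect = 2, seed = 16)
  K <- 10
  m <- trainEnsemble(train, K = K, D = K, L = 1, correction = "none",
                     cost = 4, sigma = 2, seed = 17)
  ensPred <- predict(m, test, type = "code")

  # direct OAA SVM on the same feature spaces, standardization and
  # hyperparameters, decoded by the maximum raw decision value
  vtr <- (exprsMatrix(train) - m@center) / m@scale
  vte <- (exprsMatrix(test) - m@center) / m@scale
  lab <- classCodes(train)
  dec <- sapply(1:3, function(i) {
    gi <- geneIndices(m@branches[[i]]$space)
    yf <- factor(ifelse(lab == i, "pos", "neg"), levels = c("pos", "neg"))
    xtr <- t(vtr[gi, , drop = FALSE]); dimnames(xtr) <- NULL
    fit <- e1071::svm(xtr, yf, kernel = "radial", gamma = 1 / (2 * 2^2),
                      cost = 4, scale = FALSE)
    xte <- t(vte[gi, , drop = FALSE]); dimnames(xte) <- NULL
    dv <- as.numeric(attr(predict(fit, xte, decision.values = TRUE),
                          "decision.values"))
    if (fit$levels[fit$labels[1]] != "pos") dv <- -dv
    dv
  })
  direct <- apply(dec, 1, which.max)
  expect_equal(ensPred, direct, ignore_attr = TRUE)
})

test_that("binary problems decode like majority voting between branches", {
  train <- makeToyDataset(nPerClass = c(16, 10), nGenes = 20, seed = 18)
  test <- makeToyDataset(nPerClass = c(16, 10), nGenes = 20, seed = 19)
  m <- trainEnsemble(train, K = 12, D = 4, L = 9, correction = "rus",
                     seed = 20)
  cnt <- counterVotes(m, test)
  pred <- predict(m, test, type = "code")
  votes1 <- round(cnt[, 1] * m@L); votes2 <- round(cnt[, 2] * m@L)
  clear <- votes1 != votes2
  expect_true(any(clear))
  expect_equal(pred[clear], ifelse(votes1[clear] > votes2[clear], 1L, 2L),
               ignore_attr = TRUE)
})

test_that("single named sample vectors are accepted", {
  ds <- makeToyDataset(seed = 21)
  m <- trainEnsemble(ds, K = 10, D = 3, L = 3, correction = "none", seed = 22)
  v <- exprsMatrix(ds)[, 4]
  p1 <- predict(m, v, type = "code")
  pAll <- predict(m, ds, type = "code")
  expect_equal(p1, pAll[4], ignore_attr = TRUE)
})
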