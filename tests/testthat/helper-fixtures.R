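# Shared fixtures and independent oracles.

# Small labelled dataset with a strong class signal, built directly
# (not via the generator) so io/ensemble tests do not depend on it.
makeToyDataset <- function(nPerClass = c(12, 8, 6), nGenes = 30,
                           effect = 2, seed = 1) {
  set.seed(seed)
  C <- length(nPerClass)
  n <- sum(nPerClass)
  labels <- rep(seq_len(C), nPerClass)
  values <- matrix(rnorm(nGenes * n), nGenes, n)
  # first C*3 genes informative: gene block c shifts in class c
  for (cls in seq_len(C)) {
    rows <- (cls - 1) * 3 + 1:3
    values[rows, labels == cls] <- values[rows, labels == cls] + effect
  }
  dimnames(values) <- list(sprintf("g%02d", seq_len(nGenes)),
                           sprintf("s%02d", seq_len(n)))
  ExpressionDataset(values, labels = paste0("cl", labels))
}

# Brute-force confusion-matrix metrics: explicit loops over the C x C
# table and direct transcription of the metric definitions. Kept free
# of any package code so it can serve as an independent oracle.
bruteForceReport <- function(yTrue, yPred, C) {
  conf <- matrix(0, C, C)
  for (i in seq_along(yTrue))
    conf[yTrue[i], yPred[i]] <- conf[yTrue[i], yPred[i]] + 1
  acc_i <- prec_i <- f_i <- P_i <- numeric(C)
  for (cl in seq_len(C)) {
    tp <- conf[cl, cl]
    fn <- sum(conf[cl, ]) - tp
    fp <- sum(conf[, cl]) - tp
    acc_i[cl] <- tp / (tp + fn)
    prec_i[cl] <- if (tp + fp > 0) tp / (tp + fp) else 0
    f_i[cl] <- if (prec_i[cl] + acc_i[cl] > 0)
      2 * prec_i[cl] * acc_i[cl] / (prec_i[cl] + acc_i[cl]) else 0
    P_i[cl] <- (tp + fn) / length(yTrue)
  }
  list(acc_i = acc_i, prec_i = prec_i, f_i = f_i, P_i = P_i,
       acc = sum(acc_i * P_i), fScore = mean(f_i),
       gMean = prod(acc_i)^(1 / C))
}

# Random labelled prediction pair with every class present in truth.
randomPredictionPair <- function(C, n) {
  yTrue <- c(seq_len(C), sample(seq_len(C), n - C, replace = TRUE))
  yPred <- sample(seq_len(C), n, replace = TRUE)
  list(yTrue = yTrue, yPred = yPred)
}

# Planted-cluster recovery fixture: one informative parent per class
# (10 classes of 6 samples), 4 redundant copies each, 50 noise genes.
# Group patterns are mutually near-orthogonal so the 10 planted
# clusters are recoverable by correlation clustering.
makeRecoveryFixture <- function(seed) {
  simulateExpressionDataset(syntheticConfig(
    classSizes = rep(6, 10), nInformativePerClass = 1,
    nRedundantCopies = 4, nNoiseGenes = 50, effectSize = 6,
    seed = seed))
}

# The imbalanced 5-class study dataset: n = 200, imbalance ratio 15,
# 2000 genes (5 x 80 distinct informative + 1600 noise), effect 1.
makeStudyDataset <- function(seed) {
  simulateExpressionDataset(syntheticConfig(
    classSizes = c(135, 20, 19, 17, 9), nInformativePerClass = 80,
    nRedundantCopies = 0, nNoiseGenes = 1600, effectSize = 1,
    seed = seed))
}

# Stratified train/test split: about 1/3 of every class held out.
stratifiedHoldout <- function(labels) {
  test <- unlist(lapply(split(seq_along(labels), labels),
                        function(ix) sample(ix, max(1, round(length(ix) / 3)))))
  list(train = setdiff(seq_along(labels), test), test = sort(test))
}
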