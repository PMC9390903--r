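blob_dataset <- function(n = 100, p = 4, sep = 8, seed = 1) {
  set.seed(seed)
  y <- rep(c(0, 1), length.out = n)
  x <- matrix(rnorm(n * p), n, p)
  x[, 1:2] <- x[, 1:2] + sep * y
  clinical_dataset(x, rep("continuous", p), y)
}

test_that("stratified folds keep both classes and depend only on seed", {
  y <- c(rep(0, 30), rep(1, 70))
  f1 <- stratified_folds(y, 10, seed = 5)
  f2 <- stratified_folds(y, 10, seed = 5)
  expect_identical(f1, f2)
  for (f in 1:10) {
    expect_setequal(unique(y[f1 == f]), c(0, 1))
    expect_equal(sum(f1 == f), 10)
  }
  expect_false(identical(f1, stratified_folds(y, 10, seed = 6)))
})

test_that("fitness is 1 on separable blobs and chance on permuted labels", {
  d <- blob_dataset()
  expect_equal(cv_fitness(c(1, 1, 0, 0), d, folds = 5, seed = 2), 1)
  set.seed(31)
  for (s in 1:3) {
    dn <- blob_dataset(n = 200, sep = 0, seed = 40 + s)
    expect_lt(abs(cv_fitness(rep(1, 4), dn, folds = 10, seed = s) - 0.5), 0.1)
  }
})

test_that("fitness ignores column order within the masked set", {
  d <- blob_dataset(n = 80, p = 5, sep = 1, seed = 3)
  perm <- c(3, 1, 5, 2, 4)
  dp <- clinical_dataset(d$values[, perm], d$kinds[perm], d$labels,
                         colnames(d$values)[perm])
  mask <- c(1, 1, 0, 1, 0)                      # selects columns 1, 2, 4
  maskp <- colnames(d$values)[as.logical(mask)] # same set under permutation
  expect_equal(cv_fitness(mask, d, folds = 5, seed = 7),
               cv_fitness(colnames(dp$values) %in% maskp, dp,
                          folds = 5, seed = 7))
})

test_that("empty masks and single-class data are rejected", {
  d <- blob_dataset()
  expect_error(cv_fitness(rep(0, 4), d), "empty")
  dbad <- d; dbad$labels <- rep(1L, nrow(d$values))
  expect_error(cv_fitness(rep(1, 4), dbad), "both classes")
})

test_that("confusion metrics follow the textbook formulas", {
  m <- confusion_metrics(9, 1, 1, 9)
  expect_equal(c(m$acc, m$rec, m$pre, m$f1), rep(0.9, 4))
  m <- confusion_metrics(8, 2, 4, 6)
  expect_equal(m$acc, 0.7)
  expect_equal(m$rec, 0.8)
  expect_equal(m$pre, 2 / 3, tolerance = 1e-12)
  expect_equal(m$f1, 8 / 11, tolerance = 1e-12)
  m <- confusion_metrics(0, 0, 0, 10)
  expect_equal(m$rec, 0)
  expect_true("rec" %in% m$undefined)
  expect_error(confusion_metrics(-1, 0, 0, 1), "non-negative")

  set.seed(14)
  for (i in 1:25) {
    cts <- sample(0:30, 4, replace = TRUE)
    if (sum(cts) == 0) cts[1] <- 1
    m <- confusion_metrics(cts[1], cts[2], cts[3], cts[4])
    expect_equal(m$acc, (cts[1] + cts[4]) / sum(cts))
    if (cts[1] + cts[2] > 0) expect_equal(m$rec, cts[1] / (cts[1] + cts[2]))
    if (cts[1] + cts[3] > 0) expect_equal(m$pre, cts[1] / (cts[1] + cts[3]))
    if (m$pre + m$rec > 0)
      expect_equal(m$f1, 2 * m$pre * m$rec / (m$pre + m$rec))
  }
})

test_that("AUROC equals the rank statistic and matches pROC", {
  expect_equal(score_curves(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))$auroc, 1)
  expect_equal(score_curves(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0))$auroc, 0)
  set.seed(15)
  for (i in 1:10) {
    n <- 40
    y <- rbinom(n, 1, 0.5); if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    s <- rnorm(n)                                   # continuous: tie-free
    cv <- score_curves(s, y)
    expect_equal(cv$auroc, auroc_rank(s, y), tolerance = 1e-10)
    expect_gte(cv$auprc, 0); expect_lte(cv$auprc, 1)
  }
  skip_if_not_installed("pROC")
  set.seed(16)
  y <- rbinom(100, 1, 0.4); s <- rnorm(100) + y
  expect_equal(score_curves(s, y)$auroc,
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-10)
  expect_error(score_curves(s, rep(1, 100)), "both classes")
})

test_that("cross-validated evaluation reports coherent counts and curves", {
  d <- blob_dataset(n = 120, sep = 1.5, seed = 22)
  rep1 <- evaluate_subset(c(1, 1, 0, 0), d, folds = 6, seed = 4)
  expect_s3_class(rep1, "evaluation_report")
  expect_equal(rep1$tp + rep1$fn, sum(d$labels == 1))
  expect_equal(rep1$tn + rep1$fp, sum(d$labels == 0))
  expect_equal(rep1$acc, (rep1$tp + rep1$tn) / nrow(d$values))
  expect_gte(rep1$auroc, 0.8)       # strong planted signal
  expect_identical(rep1, evaluate_subset(c(1, 1, 0, 0), d, folds = 6, seed = 4))
})

test_that("importance scores normalise to one and rank ever-present winners
           first", {
  set.seed(33)
  n <- 80
  y <- rep(c(0, 1), each = n / 2)
  x <- cbind(matrix(rnorm(2 * n) + 3 * y, n, 2), matrix(rnorm(4 * n), n, 4))
  d <- clinical_dataset(x, rep("continuous", 6), y,
                        paste0("v", 1:6))
  rk <- importance_ranking(d, n_repeats = 3, seed = 2,
                           flip = 3, n_bees = 4, max_iteration = 2,
                           local_iteration = 3, fitness_folds = 4)
  expect_equal(sum(rk$score), 1, tolerance = 1e-12)
  expect_true(rk$feature[1] %in% c("v1", "v2"))
  expect_true(all(diff(rk$score) <= 0))
})
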