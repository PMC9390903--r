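make_ds <- function(values, kinds = rep("continuous", ncol(values)),
                    labels = rep_len(c(0, 1), nrow(values))) {
  clinical_dataset(values, kinds, labels)
}

test_that("sparse-column dropping uses a strictly-greater-than rule", {
  x <- cbind(a = c(rep(NA, 4), 5:10), b = c(rep(NA, 3), 4:10), c = 1:10)
  d <- make_ds(x)
  res <- drop_sparse_columns(d, 0.30)
  expect_equal(res$dropped, "a")                     # 40% missing: dropped
  expect_equal(colnames(res$dataset$values), c("b", "c"))  # exactly 30%: kept
  expect_error(drop_sparse_columns(d, 0), "fraction")
  allna <- make_ds(matrix(NA_real_, 4, 2))
  expect_error(drop_sparse_columns(allna, 0.3), "every column")
})

test_that("continuous fill matches the reciprocal-distance weighted average", {
  # target row missing col 1; neighbours at shared-feature distances 1 and 3
  # with values 10 and 20: fill = (1*10 + (1/3)*20) / (1 + 1/3) = 12.5
  x <- rbind(c(NA, 0), c(10, 1), c(20, 3))
  d <- make_ds(x, labels = c(0, 1, 0))
  filled <- knn_impute(d, k = 5)
  expect_equal(unname(filled$values[1, 1]), 12.5)
  expect_equal(unname(filled$values[-1, ]), x[-1, ])  # observed cells untouched
})

test_that("unanimous neighbours and modal voting behave as defined", {
  x <- rbind(c(NA, 0), c(7, 1), c(7, 2), c(7, 3))
  expect_equal(unname(knn_impute(make_ds(x), k = 3)$values[1, 1]), 7)

  xd <- rbind(c(NA, 0), c(1, 1), c(1, 2), c(2, 3))
  dd <- make_ds(xd, kinds = c("discrete", "continuous"))
  expect_equal(unname(knn_impute(dd, k = 3)$values[1, 1]), 1)  # mode of {1,1,2}

  # tie {1, 2}: closer neighbour's category wins
  xt <- rbind(c(NA, 0), c(2, 1), c(1, 2))
  dt <- make_ds(xt, kinds = c("discrete", "continuous"), labels = c(0, 1, 0))
  expect_equal(unname(knn_impute(dt, k = 2)$values[1, 1]), 2)
})

test_that("fills are convex combinations and imputation is idempotent", {
  set.seed(7)
  for (rep in 1:10) {
    tb <- random_mixed_table(8, 5)
    d <- clinical_dataset(tb$values, tb$kinds, rbinom(8, 1, 0.5))
    filled <- knn_impute(d, k = 3)
    expect_false(anyNA(filled$values))
    cont <- which(tb$kinds == "continuous")
    for (j in cont) {
      miss <- which(is.na(tb$values[, j]))
      obs <- tb$values[!is.na(tb$values[, j]), j]
      for (a in miss) {
        expect_gte(filled$values[a, j], min(obs))
        expect_lte(filled$values[a, j], max(obs))
      }
    }
    expect_equal(knn_impute(filled, k = 3)$values, filled$values)
  }
})

test_that("imputation fails loudly when a cell has no possible neighbour", {
  x <- rbind(c(NA, 1), c(NA, 2), c(NA, 3))
  expect_error(knn_impute(make_ds(x), k = 2), "row 1, column")
})

test_that("z-scoring uses the population standard deviation", {
  d <- make_ds(cbind(a = c(1, 2, 3)), labels = c(0, 1, 0))
  z <- zscore_normalize(d)
  expect_equal(unname(z$dataset$values[, "a"]), c(-1, 0, 1) * sqrt(3 / 2),
               tolerance = 1e-12)
  expect_equal(unname(z$center["a"]), 2)
  expect_equal(unname(z$scale["a"]), sqrt(2 / 3), tolerance = 1e-12)
})

test_that("constant columns warn and pass through centred", {
  d <- make_ds(cbind(a = c(5, 5, 5)), labels = c(0, 1, 0))
  expect_warning(z <- zscore_normalize(d), "constant")
  expect_equal(unname(z$dataset$values[, "a"]), c(0, 0, 0))
})

test_that("normalisation centres continuous columns and skips discrete ones", {
  set.seed(11)
  x <- cbind(matrix(rnorm(60, 5, 3), 20, 3), rbinom(20, 1, 0.5))
  d <- make_ds(x, kinds = c(rep("continuous", 3), "discrete"))
  z <- zscore_normalize(d)
  for (j in 1:3) {
    expect_lt(abs(mean(z$dataset$values[, j])), 1e-12)
    expect_equal(sqrt(mean(z$dataset$values[, j]^2)), 1, tolerance = 1e-12)
  }
  expect_equal(z$dataset$values[, 4], x[, 4], ignore_attr = TRUE)
  # stored transform reproduces the normalised values on the same rows
  back <- sweep(sweep(x, 2, z$center), 2, z$scale, "/")
  expect_equal(unname(back), unname(z$dataset$values), tolerance = 1e-12)
})

test_that("imputation agrees with brute-force evaluation on small tables", {
  set.seed(99)
  for (rep in 1:10) {
    tb <- random_mixed_table(sample(4:8, 1), sample(3:6, 1))
    d <- clinical_dataset(tb$values, tb$kinds, rbinom(nrow(tb$values), 1, 0.5))
    k <- sample(2:4, 1)
    expect_equal(knn_impute(d, k)$values,
                 brute_impute(tb$values, tb$kinds, k),
                 ignore_attr = TRUE, tolerance = 1e-10)
  }
})
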