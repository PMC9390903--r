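#' Drop columns with too many missing values
#'
#' Removes every feature whose missing proportion is strictly greater than
#' `fraction` (default 0.30, i.e. a column missing in more than 30% of the
#' samples is excluded). Surviving columns keep their order.
#'
#' @param dataset a [clinical_dataset()].
#' @param fraction maximum tolerated missing proportion, in (0, 1].
#' @return list with `dataset` (columns retained) and `dropped`
#'   (character vector of removed column names).
#' @export
drop_sparse_columns <- function(dataset, fraction = 0.3) {
  stopifnot(inherits(dataset, "clinical_dataset"))
  if (!(fraction > 0 && fraction <= 1))
    stop("`fraction` must be in (0, 1]")
  miss <- colMeans(is.na(dataset$values))
  keep <- miss <= fraction          # strictly-greater-than rule: > fraction drops
  if (!any(keep))
    stop("drop_sparse_columns: every column exceeds the missing threshold")
  list(dataset = subset_columns(dataset, which(keep)),
       dropped = colnames(dataset$values)[!keep])
}

#' Hybrid k-nearest-neighbour imputation
#'
#' Fills each missing cell from the k most similar samples that observe the
#' target column. Similarity is the reciprocal of the Euclidean distance
#' computed over the features observed in both rows (discrete features
#' contribute a 0/1 mismatch). A missing continuous value is replaced by the
#' weight-averaged neighbour values; a missing discrete value by the
#' neighbours' modal category. All fills are computed from the original
#' observed values and written at once, so the result does not depend on row
#' order and the operation is idempotent.
#'
#' Mode ties are resolved in favour of the candidate category with the
#' smallest summed neighbour distance to the target row, then by category
#' order. A zero distance (an identical neighbour) is floored at 1e-12
#' before taking the reciprocal.
#'
#' @param dataset a [clinical_dataset()].
#' @param k number of neighbours (default 5).
#' @return the imputed [clinical_dataset()] with no missing entries.
#' @export
knn_impute <- function(dataset, k = 5) {
  stopifnot(inherits(dataset, "clinical_dataset"))
  if (k < 1) stop("`k` must be >= 1")
  x <- dataset$values
  if (!anyNA(x)) return(dataset)
  n <- nrow(x)
  discrete <- dataset$kinds == "discrete"
  out <- x

  rows_missing <- which(rowSums(is.na(x)) > 0)
  for (a in rows_missing) {
    d <- row_distances(x, a, discrete)
    for (i in which(is.na(x[a, ]))) {
      cand <- which(!is.na(x[, i]) & is.finite(d) & seq_len(n) != a)
      if (!length(cand))
        stop(sprintf("knn_impute: no candidate neighbour for (row %d, column %s)",
                     a, colnames(x)[i]))
      nb <- cand[order(d[cand], cand)][seq_len(min(k, length(cand)))]
      dnb <- pmax(d[nb], 1e-12)
      if (discrete[i]) {
        out[a, i] <- neighbour_mode(x[nb, i], dnb)
      } else {
        w <- 1 / dnb
        out[a, i] <- sum(w * x[nb, i]) / sum(w)
      }
    }
  }
  clinical_dataset(out, dataset$kinds, dataset$labels, colnames(x))
}

# Euclidean distance from row a to every row, over columns observed in both
# rows; discrete columns contribute 0/1 mismatch. Inf when nothing is shared.
row_distances <- function(x, a, discrete) {
  obs_a <- !is.na(x[a, ])
  diffs <- sweep(x[, obs_a, drop = FALSE], 2, x[a, obs_a], "-")
  if (any(discrete[obs_a])) {
    dd <- diffs[, discrete[obs_a], drop = FALSE]
    diffs[, discrete[obs_a]] <- (dd != 0) * 1
  }
  sq <- diffs^2
  shared <- rowSums(!is.na(sq))
  d <- sqrt(rowSums(sq, na.rm = TRUE))
  d[shared == 0] <- Inf
  d
}

# modal category; ties -> smallest summed distance, then category order
neighbour_mode <- function(vals, dists) {
  tab <- tapply(rep(1, length(vals)), vals, sum)
  cats <- as.numeric(names(tab))
  top <- cats[tab == max(tab)]
  if (length(top) > 1) {
    dsum <- vapply(top, function(v) sum(dists[vals == v]), 0)
    top <- top[dsum == min(dsum)]
  }
  min(top)
}

#' z-score normalisation of continuous features
#'
#' Centres each continuous column and divides by its population (divide-by-n)
#' standard deviation. Discrete columns are left untouched. A constant column
#' gets scale 1 (with a warning) instead of a division by zero. The returned
#' centre/scale vectors allow applying the identical transform to new rows.
#'
#' @param dataset a complete (no missing entries) [clinical_dataset()].
#' @return list with `dataset` (normalised), `center` and `scale`
#'   (named numeric vectors; 0/1 for discrete columns).
#' @export
zscore_normalize <- function(dataset) {
  stopifnot(inherits(dataset, "clinical_dataset"))
  if (anyNA(dataset$values))
    stop("zscore_normalize: dataset still contains missing values; impute first")
  x <- dataset$values
  n <- nrow(x)
  center <- stats::setNames(rep(0, ncol(x)), colnames(x))
  scale <- stats::setNames(rep(1, ncol(x)), colnames(x))
  cont <- which(dataset$kinds == "continuous")
  for (j in cont) {
    mu <- mean(x[, j])
    sdev <- sqrt(sum((x[, j] - mu)^2) / n)
    if (sdev == 0) {
      warning("constant column '", colnames(x)[j], "': scale set to 1")
      sdev <- 1
    }
    center[j] <- mu
    scale[j] <- sdev
    x[, j] <- (x[, j] - mu) / sdev
  }
  list(dataset = clinical_dataset(x, dataset$kinds, dataset$labels, colnames(x)),
       center = center, scale = scale)
}
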