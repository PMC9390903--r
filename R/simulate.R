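#' Simulate a clinical-like mixed-type dataset with planted signal
#'
#' Generates a samples x features table shaped like a neonatal clinical
#' cohort: a mix of continuous measurements and binary flags, class imbalance
#' near 2:1, missing entries completely at random, and a small set of planted
#' informative features. Informative continuous columns are Gaussian with a
#' class mean shift of `effect_size` standard deviations; informative binary
#' columns shift their log-odds by `effect_size`. Each informative column has
#' one redundant partner correlated at `redundancy_rho` (noisy copy for
#' continuous, random flips for binary), so tests can distinguish relevance
#' from redundancy. All remaining columns are independent of the label.
#'
#' The defaults mirror the cohort shape the package targets: 447 samples,
#' 119 variables, positive fraction 296/447, half discrete.
#'
#' @param n_samples,n_features table dimensions.
#' @param n_informative number of planted informative features
#'   (each also gets one redundant partner when `redundancy_rho > 0`).
#' @param effect_size standardised mean shift (continuous) or log-odds shift
#'   (binary) between classes.
#' @param discrete_fraction fraction of binary columns, in \[0, 1\].
#' @param positive_fraction expected fraction of positive labels, in (0, 1).
#' @param missing_rate per-cell missingness probability, in \[0, 0.5).
#' @param redundancy_rho informative/partner correlation, in \[0, 1).
#' @param seed integer seed; the draw is fully determined by it and the
#'   caller's RNG stream is untouched.
#' @return list with `dataset` (a [clinical_dataset()]), `informative`
#'   (planted column indices) and `redundant` (their partners' indices,
#'   or integer(0)).
#' @export
simulate_clinical <- function(n_samples = 447, n_features = 119,
                              n_informative = 10, effect_size = 1,
                              discrete_fraction = 0.5,
                              positive_fraction = 296 / 447,
                              missing_rate = 0.1, redundancy_rho = 0.5,
                              seed = 1) {
  stopifnot(n_samples >= 4, n_features >= 1,
            n_informative >= 0, n_informative <= n_features,
            effect_size >= 0,
            discrete_fraction >= 0, discrete_fraction <= 1,
            positive_fraction > 0, positive_fraction < 1,
            missing_rate >= 0, missing_rate < 0.5,
            redundancy_rho >= 0, redundancy_rho < 1)
  n_redundant <- if (redundancy_rho > 0) n_informative else 0L
  if (n_informative + n_redundant > n_features)
    stop("n_features too small for the informative columns and their partners")
  with_local_seed(seed, {
    y <- stats::rbinom(n_samples, 1, positive_fraction)
    # both classes are required downstream
    if (sum(y) == 0) y[1] <- 1L
    if (sum(y) == n_samples) y[1] <- 0L

    kinds <- rep("continuous", n_features)
    kinds[sample.int(n_features, round(discrete_fraction * n_features))] <-
      "discrete"
    slots <- sample.int(n_features, n_informative + n_redundant)
    informative <- slots[seq_len(n_informative)]
    redundant <- slots[n_informative + seq_len(n_redundant)]

    x <- matrix(NA_real_, n_samples, n_features)
    for (j in seq_len(n_features)) {
      if (j %in% c(informative, redundant)) next
      x[, j] <- if (kinds[j] == "discrete")
        stats::rbinom(n_samples, 1, stats::runif(1, 0.2, 0.8))
      else stats::rnorm(n_samples)
    }
    base_p <- 0.35   # baseline prevalence of an informative binary flag
    for (idx in seq_len(n_informative)) {
      j <- informative[idx]
      if (kinds[j] == "discrete") {
        p <- stats::plogis(stats::qlogis(base_p) + effect_size * y)
        x[, j] <- stats::rbinom(n_samples, 1, p)
      } else {
        x[, j] <- stats::rnorm(n_samples) + effect_size * y
      }
      if (n_redundant) {
        jp <- redundant[idx]
        kinds[jp] <- kinds[j]   # partner shares its source's kind
        if (kinds[j] == "discrete") {
          flip <- stats::rbinom(n_samples, 1, (1 - redundancy_rho) / 2)
          x[, jp] <- ifelse(flip == 1, 1 - x[, j], x[, j])
        } else {
          z <- (x[, j] - mean(x[, j])) / stats::sd(x[, j])
          x[, jp] <- redundancy_rho * z +
            sqrt(1 - redundancy_rho^2) * stats::rnorm(n_samples)
        }
      }
    }
    if (missing_rate > 0) {
      holes <- matrix(stats::runif(n_samples * n_features) < missing_rate,
                      n_samples, n_features)
      # keep at least 2 observed values per column
      for (j in which(colSums(!holes) < 2))
        holes[sample(which(holes[, j]), 2 - sum(!holes[, j])), j] <- FALSE
      x[holes] <- NA_real_
    }
    ds <- clinical_dataset(x, kinds, y,
                           sprintf("f%03d", seq_len(n_features)))
    ord <- order(informative)   # keep informative/redundant pairing aligned
    list(dataset = ds, informative = informative[ord],
         redundant = if (n_redundant) redundant[ord] else integer(0))
  })
}

#' Fixed 20-bit reference solution
#'
#' A stable alternating 0/1 mask of length 20 for exercising the canonical
#' worked example of the two flip strategies (n = 20, flip = 5).
#'
#' @return integer 0/1 mask of length 20.
#' @export
example_reference <- function() rep(c(1L, 0L), 10)
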