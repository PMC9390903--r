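#' Closed-form ridge regression
#'
#' Solves the L2-penalised least-squares problem
#' \deqn{J(\beta) = \sum_i (y_i - \beta^T x_i)^2 + \lambda \|\beta\|_2^2,
#'   \quad \lambda > 0,}
#' whose minimiser satisfies the normal equations
#' \eqn{(X^TX + \lambda I)\beta = X^Ty}. The system is solved by a Cholesky
#' factorisation (the penalised Gram matrix is positive definite), not by an
#' explicit inverse.
#'
#' By default the design and response are used as given; with `center = TRUE`
#' both are mean-centred first and an intercept is recovered, which is the
#' form used by the screening stage (binary labels encoded 0/1 are the
#' regression target).
#'
#' @param x numeric design matrix, samples x features.
#' @param y numeric response vector.
#' @param lambda positive regularisation strength.
#' @param center centre `x` and `y` before solving?
#' @return object of class `ridge_model`: list with `beta` (named coefficient
#'   vector), `lambda`, `intercept`, `center` (logical).
#' @examples
#' ridge_fit(diag(2), c(1, 2), lambda = 1)$beta  # (I + I)^-1 y = (0.5, 1)
#' @export
ridge_fit <- function(x, y, lambda, center = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) < 1 || ncol(x) < 1) stop("x must have at least one row and column")
  if (length(y) != nrow(x)) stop("dimension mismatch between x and y")
  if (!(lambda > 0)) stop("lambda must be > 0")
  xm <- rep(0, ncol(x)); ym <- 0
  if (center) {
    xm <- colMeans(x); ym <- mean(y)
    x <- sweep(x, 2, xm); y <- y - ym
  }
  g <- crossprod(x) + diag(lambda, ncol(x))
  beta <- drop(chol2inv(chol(g)) %*% crossprod(x, y))
  names(beta) <- colnames(x)
  structure(list(beta = beta, lambda = lambda,
                 intercept = ym - sum(xm * beta), center = center),
            class = "ridge_model")
}

#' @export
print.ridge_model <- function(x, ...) {
  cat(sprintf("ridge_model: %d coefficients, lambda = %.4g\n",
              length(x$beta), x$lambda))
  invisible(x)
}

#' Choose the ridge penalty by cross-validation
#'
#' Evaluates each candidate penalty by k-fold cross-validated held-out squared
#' error of the centred ridge fit and returns the grid value with the smallest
#' mean error (ties go to the smallest penalty). The fold assignment is drawn
#' from `seed` and does not perturb the caller's random number stream.
#'
#' @param x design matrix; @param y response.
#' @param grid candidate penalties (positive). The default is 50 log-spaced
#'   values spanning 1e-2 to 1e4.
#' @param folds number of folds (>= 2).
#' @param seed integer seed for the fold assignment.
#' @return the selected penalty (scalar).
#' @export
ridge_cv_lambda <- function(x, y, grid = default_lambda_grid(),
                            folds = 10, seed = 1) {
  x <- as.matrix(x)
  if (!length(grid) || any(grid <= 0)) stop("grid must be non-empty and positive")
  if (folds < 2) stop("folds must be >= 2")
  n <- nrow(x)
  if (n < folds) stop("fewer samples than folds")
  fold_id <- with_local_seed(seed, sample(rep_len(seq_len(folds), n)))
  grid <- sort(grid)
  err <- vapply(grid, function(lam) {
    mean(vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      fit <- ridge_fit(x[tr, , drop = FALSE], y[tr], lam, center = TRUE)
      pred <- drop(x[!tr, , drop = FALSE] %*% fit$beta) + fit$intercept
      mean((y[!tr] - pred)^2)
    }, 0))
  }, 0)
  grid[which.min(err)]   # ties: which.min takes the first = smallest lambda
}

#' @rdname ridge_cv_lambda
#' @export
default_lambda_grid <- function() exp(seq(log(1e-2), log(1e4), length.out = 50))

#' Screen features by ridge coefficient magnitude
#'
#' Keeps feature j iff `|beta_j| > epsilon`. Penalised coefficients are
#' essentially never exactly zero, so irrelevant features are removed with a
#' small relative threshold; the default is `1e-6 * max|beta|`.
#'
#' @param model a fitted [ridge_fit()] model.
#' @param epsilon non-negative threshold; `NULL` for the relative default.
#' @return logical mask over the model's features (TRUE = keep).
#' @export
ridge_screen <- function(model, epsilon = NULL) {
  stopifnot(inherits(model, "ridge_model"))
  if (is.null(epsilon)) epsilon <- 1e-6 * max(abs(model$beta))
  if (epsilon < 0) stop("epsilon must be >= 0")
  mask <- abs(model$beta) > epsilon
  if (!any(mask))
    stop("ridge_screen: all coefficients below epsilon; use a smaller epsilon")
  mask
}
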