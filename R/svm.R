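#' Linear support vector machine (hinge loss, L2 penalty)
#'
#' Fits the soft-margin linear SVM
#' \deqn{\min_w \tfrac12\|w\|^2 + C\sum_i \max(0, 1 - y_i w^Tx_i)}
#' by dual coordinate descent with projected-gradient updates — the standard
#' algorithm for linear-kernel SVMs when many small fits are needed, as in a
#' wrapper feature-selection loop. The intercept is a unit-augmented,
#' penalised bias term. Fits are deterministic (a private generator drives
#' the coordinate ordering) and do not touch the R RNG stream.
#'
#' @param x numeric matrix, samples x features.
#' @param y 0/1 labels (1 = positive class).
#' @param C error penalty (default 1, the method's reference setting).
#' @param eps stopping tolerance on the maximal projected gradient
#'   (default 0.1, the customary dual tolerance).
#' @param max_epochs hard cap on passes over the data.
#' @return object of class `linear_svm`: list with `w` (feature weights),
#'   `b` (intercept) and `C`.
#' @seealso [predict.linear_svm()]
#' @export
svm_linear_fit <- function(x, y, C = 1, eps = 0.1, max_epochs = 1000) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("svm_linear_fit: x contains missing values")
  if (!all(y %in% c(0, 1))) stop("y must be 0/1")
  if (length(unique(y)) < 2) stop("both classes must be present")
  ypm <- ifelse(y == 1, 1L, -1L)
  w <- .dcd_svm_fit(x, as.integer(ypm), C, eps, as.integer(max_epochs))
  p <- ncol(x)
  structure(list(w = stats::setNames(w[seq_len(p)], colnames(x)),
                 b = w[p + 1], C = C),
            class = "linear_svm")
}

#' Predict from a fitted linear SVM
#'
#' @param object a [svm_linear_fit()] model.
#' @param newdata numeric matrix with the training columns.
#' @param type `"class"` for 0/1 labels, `"decision"` for the signed distance
#'   `w.x + b` (positive = positive class).
#' @param ... unused.
#' @export
predict.linear_svm <- function(object, newdata,
                               type = c("class", "decision"), ...) {
  type <- match.arg(type)
  d <- drop(as.matrix(newdata) %*% object$w) + object$b
  if (type == "decision") d else as.integer(d > 0)
}

#' @export
print.linear_svm <- function(x, ...) {
  cat(sprintf("linear_svm: %d features, C = %g, |w| = %.4f\n",
              length(x$w), x$C, sqrt(sum(x$w^2))))
  invisible(x)
}
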