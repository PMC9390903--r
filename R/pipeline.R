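#' Ridge-screened Q-learning bee swarm feature selection
#'
#' Fits the full selection cascade on a clinical dataset: (1) drop features
#' missing in more than `missing_drop_fraction` of samples, (2) hybrid
#' k-nearest-neighbour imputation, (3) z-score normalisation of continuous
#' features, (4) closed-form ridge regression on the 0/1 labels with a
#' cross-validated penalty, screening out near-zero-coefficient features,
#' (5) Q-learning bee swarm search over subsets of the surviving features,
#' scored by stratified cross-validated linear-SVM accuracy, and (6) a final
#' cross-validated evaluation of the winning subset (confusion metrics,
#' ROC/PRC) under a fold seed distinct from the one the search optimised.
#'
#' One master seed deterministically spawns the per-stage seeds (ridge CV
#' folds, fitness folds, search randomness, final evaluation folds), so
#' identical inputs give identical results.
#'
#' @param dataset a [clinical_dataset()].
#' @param missing_drop_fraction missing-proportion threshold of stage 1.
#' @param knn_k neighbours used by [knn_impute()].
#' @param lambda ridge penalty; `NULL` (default) selects it from
#'   `lambda_grid` by [ridge_cv_lambda()].
#' @param lambda_grid candidate penalties for the ridge CV.
#' @param ridge_epsilon screening threshold; `NULL` for the relative default
#'   `1e-6 * max|beta|`.
#' @param flip,n_bees,max_iteration,local_iteration,gamma,init_fraction
#'   search hyper-parameters, see [search_config()]; defaults are the
#'   reference settings of the method.
#' @param fitness_folds,svm_C folds and SVM error penalty of the wrapper
#'   fitness (defaults 10 and 1).
#' @param seed master seed.
#' @param final_evaluation run stage 6? (Set `FALSE` to fit the selector
#'   only, e.g. inside [importance_ranking()].)
#' @return object of class `rqbso`; see Details. Use [print()], [summary()],
#'   [plot()], [coef()] and [predict()] on it.
#' @details The returned object contains `selected` (original column names of
#' the chosen subset), `mask` (0/1 over the screened features),
#' `search_fitness` (best cross-validated accuracy found), `history`
#' (per-iteration best-so-far fitness), `report` (the stage-6
#' [evaluate_subset()] result, or `NULL`), `ridge` (the screening fit with
#' `lambda` and `epsilon`), `dropped`, `screened` (surviving names),
#' `center`/`scale` (the z-score transform), `model` (a linear SVM refitted
#' on all samples with the selected features, used by [predict.rqbso()]),
#' `seeds` and the matched `call`.
#' @examples
#' sim <- simulate_clinical(n_samples = 120, n_features = 12,
#'                          n_informative = 3, effect_size = 2,
#'                          missing_rate = 0.05, seed = 7)
#' fit <- rqbso(sim$dataset, max_iteration = 2, local_iteration = 3,
#'              n_bees = 4, flip = 3, seed = 1)
#' print(fit)
#' @export
rqbso <- function(dataset,
                  missing_drop_fraction = 0.3,
                  knn_k = 5,
                  lambda = NULL,
                  lambda_grid = default_lambda_grid(),
                  ridge_epsilon = NULL,
                  flip = 5, n_bees = 10, max_iteration = 10,
                  local_iteration = 10, gamma = 0.1, init_fraction = 0.2,
                  fitness_folds = 10, svm_C = 1,
                  seed = 1, final_evaluation = TRUE) {
  stopifnot(inherits(dataset, "clinical_dataset"))
  if (length(unique(dataset$labels)) < 2)
    stop("rqbso: both classes must be present")
  cl <- match.call()
  seeds <- derive_seeds(seed, 4)
  names(seeds) <- c("ridge_cv", "fitness_folds", "search", "evaluation")

  # stage 1-3: drop sparse, impute, normalise
  stage1 <- drop_sparse_columns(dataset, missing_drop_fraction)
  imputed <- knn_impute(stage1$dataset, k = knn_k)
  norm <- zscore_normalize(imputed)
  work <- norm$dataset
  y <- work$labels

  # stage 4: ridge screening
  if (is.null(lambda))
    lambda <- ridge_cv_lambda(work$values, y, grid = lambda_grid,
                              folds = min(fitness_folds, nrow(work$values)),
                              seed = seeds[["ridge_cv"]])
  rmod <- ridge_fit(work$values, y, lambda, center = TRUE)
  keep <- tryCatch(ridge_screen(rmod, ridge_epsilon),
                   error = function(e)
                     stop("rqbso: ridge screening stage removed all columns (",
                          conditionMessage(e), ")"))
  screened <- subset_columns(work, which(keep))

  # stage 5: QBSO wrapper search on the screened columns
  fold_id <- stratified_folds(y, fitness_folds, seeds[["fitness_folds"]])
  fitness_fn <- function(mask)
    cv_fitness(mask, screened, C = svm_C, fold_id = fold_id)
  cfg <- search_config(flip = min(flip, ncol(screened$values)),
                       n_bees = n_bees, max_iteration = max_iteration,
                       local_iteration = local_iteration, gamma = gamma,
                       init_fraction = init_fraction,
                       seed = seeds[["search"]])
  search <- qbso_select(fitness_fn, ncol(screened$values), cfg)
  selected <- colnames(screened$values)[search$solution == 1]

  # stage 6: final evaluation under a fresh fold seed
  report <- NULL
  if (final_evaluation)
    report <- evaluate_subset(search$solution, screened, folds = fitness_folds,
                              C = svm_C, seed = seeds[["evaluation"]])

  model <- svm_linear_fit(screened$values[, selected, drop = FALSE], y,
                          C = svm_C)
  structure(list(selected = selected, mask = search$solution,
                 search_fitness = search$fitness, history = search$history,
                 report = report, ridge = rmod,
                 ridge_epsilon = if (is.null(ridge_epsilon))
                   1e-6 * max(abs(rmod$beta)) else ridge_epsilon,
                 dropped = stage1$dropped,
                 screened = colnames(screened$values),
                 kinds = work$kinds,
                 center = norm$center, scale = norm$scale,
                 model = model, svm_C = svm_C,
                 fitness_folds = fitness_folds,
                 config = cfg, seeds = seeds, call = cl),
            class = "rqbso")
}

#' @export
print.rqbso <- function(x, ...) {
  cat("Ridge-screened Q-learning bee swarm feature selection\n\n")
  cat(sprintf("  %d feature(s) selected of %d screened (%d dropped as sparse)\n",
              length(x$selected), length(x$screened), length(x$dropped)))
  cat(sprintf("  best cross-validated accuracy: %.4f\n", x$search_fitness))
  if (!is.null(x$report))
    cat(sprintf("  held-out evaluation: acc %.4f, f1 %.4f, auroc %.4f\n",
                x$report$acc, x$report$f1, x$report$auroc))
  cat("\nSelected features:\n ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.rqbso <- function(object, ...) {
  structure(list(fit = object), class = "summary.rqbso")
}

#' @export
print.summary.rqbso <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("\nRidge screening: lambda = %.4g, epsilon = %.3g, kept %d/%d\n",
              f$ridge$lambda, f$ridge_epsilon, length(f$screened),
              length(f$ridge$beta)))
  cat("Search trajectory (best-so-far fitness):\n")
  print(f$history, row.names = FALSE)
  if (!is.null(f$report)) {
    cat("\nFinal evaluation:\n")
    print(f$report)
  }
  invisible(x)
}

#' Ridge screening coefficients of a fitted selection
#'
#' @param object an [rqbso()] fit.
#' @param ... unused.
#' @return named vector of the stage-4 ridge coefficients (all features that
#'   entered the screen).
#' @export
coef.rqbso <- function(object, ...) object$ridge$beta

#' Best-so-far fitness trajectory of the search
#'
#' @param x an [rqbso()] fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.rqbso <- function(x, ...) {
  h <- x$history
  graphics::plot(h$iteration, h$best_fitness, type = "s", lwd = 2,
                 xlab = "iteration", ylab = "best cross-validated accuracy",
                 main = "QBSO search trajectory", ...)
  graphics::points(h$iteration, h$best_fitness, pch = 19)
  invisible(x)
}

#' Predict with the selected-feature linear SVM
#'
#' Applies the training z-score transform to `newdata`, restricts to the
#' selected features, and predicts with the SVM refitted on the full training
#' data. `newdata` must contain the selected columns and have no missing
#' values in them.
#'
#' @param object an [rqbso()] fit.
#' @param newdata matrix or data.frame with (at least) the selected columns,
#'   on the original measurement scale.
#' @param type `"class"` for 0/1 labels, `"decision"` for signed distances to
#'   the separating hyperplane (larger = more positive-class).
#' @param ... unused.
#' @export
predict.rqbso <- function(object, newdata,
                          type = c("class", "decision"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(as.data.frame(newdata)[, object$selected, drop = FALSE])
  if (anyNA(newdata))
    stop("newdata contains missing values in selected columns; impute first")
  newdata <- sweep(sweep(newdata, 2, object$center[object$selected]), 2,
                   object$scale[object$selected], "/")
  predict(object$model, newdata, type = type)
}
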