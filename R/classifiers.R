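# The common train/predict contract: feature matrices are features x samples,
# labels are GP/PP, a trained model predicts on exactly the training features
# in the same order.

#' Train a diagonal linear discriminant analysis model
#'
#' DLDA assumes independent Gaussian features with a shared (pooled)
#' per-feature variance and equal class priors. Training stores per-class
#' feature means and the pooled within-class variances; zero variances are
#' floored to `1e-8 * max(variance)` (or 1e-8 when all are zero) with a
#' warning so constant features cannot produce infinite scores.
#'
#' @param X Numeric features x samples matrix.
#' @param y GP/PP labels, one per column of `X`.
#' @return An object of class `dlda_model` with elements `means` (features x
#'   2), `var` (pooled variances) and `feature_ids`.
#' @export
train_dlda <- function(X, y) {
  y <- as_prognosis(y)
  if (ncol(X) != length(y)) abort("labels must match samples")
  if (any(table(y) < 2L)) abort("need at least 2 samples per class")
  lv <- prognosis_levels()
  means <- vapply(lv, function(cl) rowMeans(X[, y == cl, drop = FALSE]),
                  numeric(nrow(X)))
  if (nrow(X) == 1L) means <- matrix(means, nrow = 1L,
                                     dimnames = list(rownames(X), lv))
  ss <- rowSums((X[, y == lv[1L], drop = FALSE] - means[, 1L])^2) +
        rowSums((X[, y == lv[2L], drop = FALSE] - means[, 2L])^2)
  v <- ss / (ncol(X) - 2L)
  if (any(v <= 0)) {
    floor_v <- if (max(v) > 0) 1e-8 * max(v) else 1e-8
    warning(sum(v <= 0), " zero-variance feature(s) floored", call. = FALSE)
    v[v <= 0] <- floor_v
  }
  structure(list(means = means, var = v, feature_ids = rownames(X)),
            class = "dlda_model")
}

#' Predict prognosis classes with a DLDA model
#'
#' A sample is assigned to the class minimising the diagonal Gaussian
#' distance `sum_g (x_g - mean_kg)^2 / var_g`; exact ties go to GP.
#'
#' @param model A `dlda_model`.
#' @param X Numeric features x samples matrix; rownames must equal the
#'   training `feature_ids` in the same order.
#' @return Factor of predicted labels (levels GP, PP), named by sample.
#' @export
predict_dlda <- function(model, X) {
  if (!identical(rownames(X), model$feature_ids)) {
    abort("feature mismatch: predict needs the training features in order")
  }
  score <- function(k) colSums((X - model$means[, k])^2 / model$var)
  d_gp <- score("GP"); d_pp <- score("PP")
  pred <- ifelse(d_pp < d_gp, "PP", "GP")   # tie -> GP
  stats::setNames(factor(pred, levels = prognosis_levels()), colnames(X))
}

#' Build a classifier adapter
#'
#' Returns a specification conforming to the shared contract: call
#' [train_classifier()] with a features x samples matrix and GP/PP labels,
#' then [predict()][predict.progsig_classifier] on new samples carrying the
#' same features. `dlda` is the in-package diagonal discriminant;
#' `rf` is a bagged CART decision forest ([forest_train()]) and `svm` a
#' linear maximum-margin classifier ([svm_train()]), both implemented in
#' this package (see the methods vignette for why stock wrappers are not
#' used) with the conventional defaults: 500 trees / linear kernel, cost 1.
#'
#' @param kind One of `"dlda"`, `"rf"`, `"svm"`.
#' @param params Named list of hyperparameters passed through to the
#'   underlying trainer (e.g. `ntree`, `mtry` for rf; `cost` for svm).
#' @param seed Optional integer; fixes the RNG for stochastic learners so a
#'   given seed yields identical predictions.
#' @return An object of class `classifier_spec`.
#' @export
classifier_adapter <- function(kind, params = list(), seed = NULL) {
  if (!(length(kind) == 1L && kind %in% c("dlda", "rf", "svm"))) {
    abort("unknown classifier kind '", paste(kind, collapse = ","),
          "'; must be one of dlda, rf, svm")
  }
  structure(list(kind = kind, params = params, seed = seed),
            class = "classifier_spec")
}

#' Train a classifier under the common contract
#'
#' @param spec A [classifier_adapter()] specification.
#' @param X Numeric features x samples matrix.
#' @param y GP/PP labels per sample.
#' @return An object of class `progsig_classifier`.
#' @export
train_classifier <- function(spec, X, y) {
  stopifnot(inherits(spec, "classifier_spec"))
  y <- as_prognosis(y)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  fit <- switch(spec$kind,
    dlda = train_dlda(X, y),
    rf = do.call(forest_train, c(list(X = X, y = y), spec$params)),
    svm = do.call(svm_train, c(list(X = X, y = y), spec$params)))
  structure(list(kind = spec$kind, fit = fit, feature_ids = rownames(X)),
            class = "progsig_classifier")
}

#' Predict with a trained classifier
#' @param object A `progsig_classifier`.
#' @param X Numeric features x samples matrix with the training features in
#'   the training order.
#' @param ... Unused.
#' @return Factor of GP/PP predictions, named by sample.
#' @export
predict.progsig_classifier <- function(object, X, ...) {
  if (!identical(rownames(X), object$feature_ids)) {
    abort("feature mismatch: predict needs the training features in order")
  }
  switch(object$kind,
    dlda = predict_dlda(object$fit, X),
    rf = forest_predict(object$fit, X),
    svm = svm_predict(object$fit, X))
}
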