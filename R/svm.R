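# A linear maximum-margin classifier: L2-regularised squared-hinge SVM
# solved in the primal by BFGS. Deterministic (no RNG), standardises
# features internally for conditioning. Exists because no SVM package is
# available in the supported dependency set; at the problem sizes targeted
# here the primal solve is exact enough for the linear kernel, cost-1
# defaults the comparison uses.

#' Train a linear support vector machine
#'
#' Minimises `0.5 * ||w||^2 + cost * sum_i max(0, 1 - y_i f(x_i))^2` with
#' `f(x) = w'x + b` over standardised features (squared hinge keeps the
#' objective differentiable; its minimiser is a maximum-margin separator on
#' separable data as cost grows).
#'
#' @param X Numeric features x samples matrix.
#' @param y GP/PP labels per sample (GP is coded -1, PP +1).
#' @param cost Penalty on margin violations (default 1, the usual default).
#' @param maxit BFGS iteration cap.
#' @return An object of class `svm_model`.
#' @export
svm_train <- function(X, y, cost = 1, maxit = 500L) {
  y <- as_prognosis(y)
  if (ncol(X) != length(y)) abort("labels must match samples")
  xs <- t(X)
  center <- colMeans(xs)
  scale_ <- apply(xs, 2L, stats::sd)
  scale_[scale_ < 1e-12] <- 1
  xs <- sweep(sweep(xs, 2L, center), 2L, scale_, "/")
  yy <- ifelse(y == "PP", 1, -1)
  p <- ncol(xs)
  obj <- function(par) {
    w <- par[seq_len(p)]; b <- par[p + 1L]
    m <- 1 - yy * (xs %*% w + b)
    m[m < 0] <- 0
    0.5 * sum(w^2) + cost * sum(m^2)
  }
  grad <- function(par) {
    w <- par[seq_len(p)]; b <- par[p + 1L]
    m <- as.vector(1 - yy * (xs %*% w + b))
    act <- m > 0
    gw <- w - 2 * cost * as.vector(t(xs[act, , drop = FALSE]) %*% (yy[act] * m[act]))
    gb <- -2 * cost * sum(yy[act] * m[act])
    c(gw, gb)
  }
  fit <- stats::optim(numeric(p + 1L), obj, grad, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-12))
  structure(list(w = fit$par[seq_len(p)], b = fit$par[p + 1L],
                 center = center, scale = scale_,
                 feature_ids = rownames(X)),
            class = "svm_model")
}

#' Predict with a linear SVM
#'
#' Decision value `>= 0` predicts PP, otherwise GP (the boundary itself goes
#' to GP, matching the package-wide tie rule).
#'
#' @param model An `svm_model`.
#' @param X Numeric features x samples matrix (training features, same
#'   order).
#' @return Factor of GP/PP predictions, named by sample.
#' @export
svm_predict <- function(model, X) {
  if (!identical(rownames(X), model$feature_ids)) {
    abort("feature mismatch: predict needs the training features in order")
  }
  xs <- sweep(sweep(t(X), 2L, model$center), 2L, model$scale, "/")
  f <- as.vector(xs %*% model$w + model$b)
  pred <- ifelse(f > 0, "PP", "GP")
  stats::setNames(factor(pred, levels = prognosis_levels()), colnames(X))
}
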