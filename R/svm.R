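# Soft-margin RBF-kernel SVM trained by sequential minimal optimization
# (simplified SMO). Written in-package because no SVM library is available
# in the target environment; adequate for the small feature sets produced
# by CSP (tens of features, ~100 trials).

rbf_kernel <- function(X, Y, gamma) {
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  exp(-gamma * pmax(d2, 0))
}

#' Median-heuristic RBF kernel width
#'
#' `gamma = 1 / (2 * median(||x_i - x_j||^2))` over distinct training
#' pairs; a parameter-free default width.
#' @param X feature matrix (rows = samples).
#' @return gamma (scalar).
#' @export
median_heuristic_gamma <- function(X) {
  d2 <- as.numeric(stats::dist(X))^2
  m <- stats::median(d2[d2 > 0])
  if (!is.finite(m) || m <= 0) return(1)
  1 / (2 * m)
}

# Binary SMO (compiled); y in {-1, +1}. Working pairs are drawn from R's
# RNG under a fixed seed, so training is reproducible.
svm_train_binary <- function(X, y, C = 1, gamma = NULL, tol = 1e-4,
                             max_passes = 10L, max_iter = 5000L,
                             seed = 1L) {
  stopifnot(all(y %in% c(-1, 1)))
  if (is.null(gamma)) gamma <- median_heuristic_gamma(X)
  K <- rbf_kernel(X, X, gamma)
  fit <- with_seed(seed, smo_train(K, as.numeric(y), C, tol,
                                   as.integer(max_passes),
                                   as.integer(max_iter)))
  alpha <- fit$alpha
  sv <- which(alpha > 1e-8)
  list(X = X[sv, , drop = FALSE], coef = alpha[sv] * y[sv], b = fit$b,
       gamma = gamma)
}

svm_decision <- function(model, X) {
  as.numeric(rbf_kernel(X, model$X, model$gamma) %*% model$coef + model$b)
}

#' Multiclass RBF-SVM via one-versus-rest
#'
#' Trains one binary soft-margin RBF SVM per class against the rest
#' (simplified SMO, C = 1 by default, median-heuristic kernel width shared
#' across subproblems); prediction is the class with the largest decision
#' value. Two classes collapse to a single binary machine.
#'
#' @param X training feature matrix (rows = samples).
#' @param y factor or character labels.
#' @param C soft-margin cost.
#' @param gamma RBF width; `NULL` for the median heuristic on `X`.
#' @param seed RNG seed for the SMO working-pair selection.
#' @return an object of class `ovr_svm`.
#' @export
svm_fit <- function(X, y, C = 1, gamma = NULL, seed = 1L) {
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) < 2L) stopf("need at least two classes")
  if (is.null(gamma)) gamma <- median_heuristic_gamma(X)
  if (length(classes) == 2L) {
    m <- svm_train_binary(X, ifelse(y == classes[2L], 1, -1), C, gamma,
                          seed = seed)
    return(structure(list(classes = classes, binary = m), class = "ovr_svm"))
  }
  machines <- lapply(seq_along(classes), function(k)
    svm_train_binary(X, ifelse(y == classes[k], 1, -1), C, gamma,
                     seed = derive_seed(seed, classes[k])))
  structure(list(classes = classes, machines = machines), class = "ovr_svm")
}

#' @param object an `ovr_svm` model.
#' @param newdata feature matrix to classify.
#' @param ... unused.
#' @rdname svm_fit
#' @export
predict.ovr_svm <- function(object, newdata, ...) {
  if (!is.null(object$binary)) {
    d <- svm_decision(object$binary, newdata)
    return(object$classes[ifelse(d > 0, 2L, 1L)])
  }
  D <- vapply(object$machines, function(m) svm_decision(m, newdata),
              numeric(nrow(newdata)))
  if (!is.matrix(D)) D <- matrix(D, nrow = 1L)
  object$classes[max.col(D, ties.method = "first")]
}
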