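#' Fit a linear SVM (one-vs-one for multiclass)
#'
#' Thin wrapper around the libsvm solver (via e1071) that fits a
#' C-classification linear SVM and exposes the quantities the ranking
#' criterion needs: per-class-pair dual coefficients, support vectors and
#' the primal weight vector w = sum_i alpha_i y_i x_i. Multiclass problems
#' are fitted as all k(k-1)/2 one-vs-one binary problems so each pair has a
#' well-defined weight vector. No internal feature rescaling is applied:
#' data are expected to be z-scored upstream (see [zscore_normalize()]).
#'
#' @param x Numeric matrix, samples x features (typically one bag restricted
#'   to the surviving features).
#' @param y Labels; at least two classes present.
#' @param cost Soft-margin cost C (default 1).
#' @param tolerance Solver termination tolerance (libsvm default 1e-3).
#'
#' @return Object of class `linear_svm`: list with `levels`, `cost`,
#'   `feature_ids` and `pairs`, one entry per one-vs-one class pair holding
#'   `classes` (positive, negative), signed weight vector `w`, offset
#'   `rho` (decision value is `x %*% w - rho`, positive for the first
#'   class), dual coefficients `coefs` (alpha_i y_i) and the original row
#'   indices of the support vectors.
#' @export
fit_linear_svm <- function(x, y, cost = 1, tolerance = 1e-3) {
  if (is.data.frame(x)) x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) stop("single-class input: an SVM needs two classes in the bag")
  if (any(!is.finite(x))) stop("non-finite values in x")
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  lv <- levels(y)
  combos <- utils::combn(lv, 2L, simplify = FALSE)
  pairs <- lapply(combos, function(cl) {
    rows <- which(y %in% cl)
    ysub <- factor(as.character(y[rows]), levels = cl)
    fit <- e1071::svm(x[rows, , drop = FALSE], ysub, type = "C-classification",
                      kernel = "linear", cost = cost, scale = FALSE,
                      tolerance = tolerance)
    w <- drop(t(fit$coefs) %*% fit$SV)
    coefs <- drop(fit$coefs)
    rho <- fit$rho
    # libsvm orients the decision value toward the first label it saw;
    # normalize so positive always means `cl[1]`
    if (fit$levels[fit$labels[1L]] != cl[1L]) {
      w <- -w; rho <- -rho; coefs <- -coefs
    }
    names(w) <- colnames(x)
    list(classes = cl, w = w, rho = rho, coefs = coefs,
         sv_index = rows[fit$index])
  })
  structure(list(levels = lv, cost = cost, feature_ids = colnames(x),
                 pairs = pairs),
            class = "linear_svm")
}

#' @export
print.linear_svm <- function(x, ...) {
  cat("Linear SVM (", length(x$levels), " classes, ", length(x$pairs),
      " one-vs-one pair(s), C = ", x$cost, ", ",
      length(x$feature_ids), " features)\n", sep = "")
  invisible(x)
}

#' Primal weight vector of a binary linear SVM
#'
#' @param object A binary [fit_linear_svm()] solution.
#' @return Named numeric vector, the hyperplane normal
#'   w = sum alpha_i y_i x_i, oriented so positive decision values favour
#'   the first factor level.
#' @export
weight_vector <- function(object) {
  stopifnot(inherits(object, "linear_svm"))
  if (length(object$pairs) != 1L)
    stop("weight_vector() is defined for binary solutions only; ",
         "use ranking_criterion() for multiclass")
  object$pairs[[1L]]$w
}

#' Per-feature ranking criterion c_j = w_j^2
#'
#' Squared components of the SVM weight vector; for multiclass, the sum of
#' squared weights over all one-vs-one pairs. Invariant to swapping class
#' labels (since (-w)^2 = w^2).
#'
#' @param object A [fit_linear_svm()] solution.
#' @return Named nonnegative numeric vector, one entry per feature.
#' @export
ranking_criterion <- function(object) {
  stopifnot(inherits(object, "linear_svm"))
  crit <- Reduce(`+`, lapply(object$pairs, function(p) p$w^2))
  names(crit) <- object$feature_ids
  crit
}

#' Per-class decision scores
#'
#' For each one-vs-one pair, the signed decision value `x %*% w - rho` is
#' added to the pair's positive class and subtracted from its negative
#' class. For binary problems the positive-class column is the usual SVM
#' decision value; for multiclass these summed votes serve as per-class
#' scores for one-vs-rest AUC.
#'
#' @param object A [fit_linear_svm()] solution.
#' @param newx Matrix of samples to score (same features, same order).
#' @return Numeric matrix samples x classes.
#' @export
decision_scores <- function(object, newx) {
  stopifnot(inherits(object, "linear_svm"))
  if (is.data.frame(newx)) newx <- as.matrix(newx)
  if (is.null(dim(newx))) newx <- matrix(newx, nrow = 1L)
  if (ncol(newx) != length(object$feature_ids))
    stop("newx has ", ncol(newx), " features; model expects ", length(object$feature_ids))
  scores <- matrix(0, nrow(newx), length(object$levels),
                   dimnames = list(rownames(newx), object$levels))
  for (p in object$pairs) {
    f <- drop(newx %*% p$w) - p$rho
    scores[, p$classes[1L]] <- scores[, p$classes[1L]] + f
    scores[, p$classes[2L]] <- scores[, p$classes[2L]] - f
  }
  scores
}

#' @export
predict.linear_svm <- function(object, newdata, ...) {
  s <- decision_scores(object, newdata)
  factor(object$levels[max.col(s, ties.method = "first")], levels = object$levels)
}
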