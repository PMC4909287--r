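#' Binary ROC AUC (Mann-Whitney formulation)
#'
#' Probability that a randomly chosen positive sample receives a higher
#' score than a randomly chosen negative one, with ties counted 1/2.
#' Computed from midranks, which is exactly the pair-counting definition.
#'
#' @param scores Real decision values, higher = more positive.
#' @param labels Binary labels; both classes must be present.
#' @param positive Which label value is the positive class (default: the
#'   last factor level of `labels`).
#' @return AUC in `[0, 1]`.
#' @export
auc_binary <- function(scores, labels, positive = NULL) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L)
    stop("auc_binary needs exactly two classes present, got ", nlevels(labels))
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  if (is.null(positive)) positive <- levels(labels)[2L]
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores)  # midranks handle ties as 1/2 wins
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Macro-averaged one-vs-rest multiclass AUC
#'
#' @param scores Matrix samples x classes of per-class decision scores,
#'   with class names as column names.
#' @param labels Per-sample labels. Classes with a score column but no
#'   sample in `labels` are skipped with a warning.
#' @return Mean of the per-class one-vs-rest binary AUCs.
#' @export
auc_multiclass <- function(scores, labels) {
  labels <- as.factor(labels)
  if (is.null(colnames(scores))) stop("scores must have class names as column names")
  present <- intersect(colnames(scores), levels(droplevels(labels)))
  absent <- setdiff(colnames(scores), present)
  if (length(absent))
    warning("class(es) absent from labels skipped: ", paste(absent, collapse = ", "))
  if (length(present) < 2L) stop("need at least two classes present")
  mean(vapply(present, function(cl) {
    auc_binary(scores[, cl], factor(labels == cl, levels = c(FALSE, TRUE)),
               positive = "TRUE")
  }, numeric(1)))
}

# score one sample set with a fitted SVM; binary -> positive-class decision
# values, multiclass -> per-class score matrix
score_samples <- function(fit, newx) {
  s <- decision_scores(fit, newx)
  if (length(fit$levels) == 2L) s[, fit$levels[2L]] else s
}

eval_auc <- function(scores, labels) {
  if (is.matrix(scores) && ncol(scores) > 2L) auc_multiclass(scores, labels)
  else auc_binary(scores, labels)
}

#' Leave-one-out AUC curve over candidate feature counts
#'
#' For each candidate count `k`, restricts the data to the top `k` features
#' of a ranking, and for every sample fits a linear SVM on the remaining
#' n - 1 samples and records the held-out sample's decision value. The AUC
#' over these n held-out scores measures how well the top-k subset
#' generalizes; the chosen count is the smallest `k` attaining the maximum
#' AUC (parsimony).
#'
#' @param x Training samples x features matrix or [expression_dataset()].
#' @param y Labels (ignored for `expr_dataset`).
#' @param ranking An [esvm_rfe()] fit, or a character vector of feature IDs
#'   ranked best-first.
#' @param ks Increasing candidate feature counts.
#' @param cost SVM cost C.
#'
#' @return Object of class `auc_curve`: list with `ks`, `auc` and
#'   `chosen_k`.
#' @export
loo_select_k <- function(x, y = NULL, ranking, ks, cost = 1) {
  d <- resolve_xy(x, y)
  rk <- if (inherits(ranking, "esvm_rfe")) ranking$ranking else as.character(ranking)
  ks <- sort(unique(as.integer(ks)))
  if (max(ks) > length(rk) || max(ks) > ncol(d$x)) stop("ks exceed the available feature count")
  n <- nrow(d$x)
  multi <- nlevels(d$y) > 2L
  auc <- vapply(ks, function(k) {
    feats <- rk[seq_len(k)]
    xs <- d$x[, feats, drop = FALSE]
    if (multi) {
      sc <- matrix(NA_real_, n, nlevels(d$y), dimnames = list(NULL, levels(d$y)))
    } else sc <- numeric(n)
    for (i in seq_len(n)) {
      if (nlevels(droplevels(d$y[-i])) < 2L)
        stop("leave-one-out fold with a single class; dataset too small/degenerate")
      fit <- fit_linear_svm(xs[-i, , drop = FALSE], d$y[-i], cost = cost)
      s <- score_samples(fit, xs[i, , drop = FALSE])
      if (multi) {
        sc[i, colnames(s)] <- s
      } else sc[i] <- s
    }
    eval_auc(sc, d$y)
  }, numeric(1))
  chosen <- ks[min(which(auc == max(auc)))]
  structure(list(ks = ks, auc = auc, chosen_k = chosen), class = "auc_curve")
}

#' @export
print.auc_curve <- function(x, ...) {
  cat("LOO AUC curve over", length(x$ks), "feature counts\n")
  cat("  max AUC", sprintf("%.4f", max(x$auc)), "first attained at k =", x$chosen_k, "\n")
  invisible(x)
}

#' @export
plot.auc_curve <- function(x, ...) {
  plot(x$ks, x$auc, type = "b", xlab = "number of top-ranked features",
       ylab = "leave-one-out AUC", ...)
  abline(v = x$chosen_k, lty = 2)
  invisible(x)
}

#' Bootstrap test-set AUC distribution
#'
#' Draws `B` uniform with-replacement resamples of the training set (each of
#' full training size), fits a linear SVM on each resample restricted to the
#' selected features, scores the fixed held-out test set and records the
#' AUC. Resamples that contain a single class are redrawn (at most 10
#' attempts each).
#'
#' @param train,test [expression_dataset()]s (or matrices, with
#'   `train_y`/`test_y`).
#' @param features Selected feature IDs, present in both datasets.
#' @param B Number of bootstrap resamples (default 100).
#' @param cost SVM cost C.
#' @param seed Optional integer seed.
#' @param resample Set `FALSE` to make every "resample" the identity
#'   (degenerate debug protocol: all B AUCs equal the plain train -> test
#'   AUC).
#' @param train_y,test_y Labels when matrices are supplied.
#'
#' @return Object of class `boot_auc`: list with `auc` (length B),
#'   `summary` (six-number summary, see [summarize_auc()]), `B`, `k`
#'   (number of features) and `redraws` (single-class resamples redrawn).
#' @export
bootstrap_test_auc <- function(train, test, features, B = 100, cost = 1,
                               seed = NULL, resample = TRUE,
                               train_y = NULL, test_y = NULL) {
  tr <- resolve_xy(train, train_y)
  te <- resolve_xy(test, test_y)
  B <- as.integer(B)
  stopifnot(B >= 1L)
  miss <- setdiff(features, intersect(colnames(tr$x), colnames(te$x)))
  if (length(miss)) stop("features absent from train or test: ",
                         paste(head(miss, 5L), collapse = ", "))
  xtr <- tr$x[, features, drop = FALSE]
  xte <- te$x[, features, drop = FALSE]
  n <- nrow(xtr)
  redraws <- 0L
  aucs <- with_seed(seed, vapply(seq_len(B), function(b) {
    idx <- if (resample) sample.int(n, n, replace = TRUE) else seq_len(n)
    tries <- 0L
    while (nlevels(droplevels(tr$y[idx])) < 2L) {
      tries <- tries + 1L
      if (tries > 10L) stop("bootstrap resample single-class 10 times in a row")
      idx <- sample.int(n, n, replace = TRUE)
    }
    redraws <<- redraws + tries
    fit <- fit_linear_svm(xtr[idx, , drop = FALSE], tr$y[idx], cost = cost)
    eval_auc(score_samples(fit, xte), te$y)
  }, numeric(1)))
  structure(list(auc = aucs, summary = summarize_auc(aucs), B = B,
                 k = length(features), redraws = redraws),
            class = "boot_auc")
}

#' Six-number summary of an AUC distribution
#'
#' Min, first quartile, median, mean, third quartile and max, with
#' quartiles under R's default linear-interpolation convention
#' (`quantile(type = 7)`).
#'
#' @param aucs Numeric vector.
#' @return Named numeric vector `min, q1, median, mean, q3, max`.
#' @export
summarize_auc <- function(aucs) {
  q <- quantile(aucs, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(min = min(aucs), q1 = q[1], median = q[2], mean = mean(aucs),
    q3 = q[3], max = max(aucs))
}

#' @export
print.boot_auc <- function(x, ...) {
  cat("Bootstrap test AUC over", x$B, "resamples (", x$k, "features )\n")
  print(round(x$summary, 4))
  if (x$redraws > 0L) cat("  (", x$redraws, "single-class resamples redrawn )\n")
  invisible(x)
}

#' Paired t-test on two AUC distributions
#'
#' Two-sided paired t-test on per-bootstrap AUC differences, e.g. the same
#' B resamples evaluated with two different feature selectors. If the
#' differences are an exact non-zero constant the statistic is reported as
#' +/-Inf with p = 0; identical vectors are a degenerate input and error.
#'
#' @param a,b Equal-length paired AUC vectors (length >= 2).
#' @return List with `t`, `p`, `df` and `mean_diff` (mean of `a - b`).
#' @export
paired_auc_ttest <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  if (length(a) < 2L) stop("need at least two pairs")
  d <- a - b
  if (all(d == 0)) stop("identical AUC vectors: paired t-test undefined (zero variance, zero effect)")
  if (sd(d) <= 1e-12 * abs(mean(d))) {  # exact constant shift up to rounding
    return(list(t = sign(mean(d)) * Inf, p = 0, df = length(d) - 1L,
                mean_diff = mean(d)))
  }
  tt <- t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_diff = unname(tt$estimate))
}
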