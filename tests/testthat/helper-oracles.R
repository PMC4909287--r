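# Independent oracles used to cross-check the implementation.
# Everything here is written from the definitions, not from the package's
# internal code paths.

# AUC by explicit pair counting: wins + half-ties over all pos/neg pairs.
auc_pair_oracle <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  wins <- 0
  for (s in pos) for (t in neg) wins <- wins + (s > t) + 0.5 * (s == t)
  wins / (length(pos) * length(neg))
}

# Brute-force classic SVM-RFE: refit a single SVM on the full data at every
# step and drop the feature with the smallest squared weight. Calls e1071
# directly; shares no code with the package's engine loop.
svmrfe_elimination_oracle <- function(x, y, cost = 1) {
  surv <- seq_len(ncol(x))
  elim_order <- integer(0)
  while (length(surv) > 1L) {
    fit <- e1071::svm(x[, surv, drop = FALSE], y, type = "C-classification",
                      kernel = "linear", cost = cost, scale = FALSE)
    w <- drop(t(fit$coefs) %*% fit$SV)
    worst <- which.min(w^2)
    elim_order <- c(elim_order, surv[worst])
    surv <- surv[-worst]
  }
  list(eliminated = elim_order, survivor = surv)
}

# Exact soft-margin SVM dual solve, independent of libsvm: kernlab's
# interior-point QP solver plus one exact active-set KKT refinement.
# Returns the primal weight vector, or NULL when the interior-point solve
# does not converge (rare; callers skip those instances).
svm_dual_qp_oracle <- function(X, yy, C) {
  n <- nrow(X)
  H <- (yy %o% yy) * (X %*% t(X))
  a <- NULL
  for (ridge in c(1e-8, 1e-6, 1e-4)) {
    sol <- try(kernlab::ipop(c = matrix(-rep(1, n)), H = H + diag(n) * ridge,
                             A = matrix(yy, 1), b = 0, r = 0,
                             l = matrix(rep(0, n)), u = matrix(rep(C, n)),
                             sigf = 9, maxiter = 300), silent = TRUE)
    if (!inherits(sol, "try-error") && kernlab::how(sol) == "converged") {
      a <- kernlab::primal(sol)
      break
    }
  }
  if (is.null(a)) return(NULL)
  eps <- 1e-5 * C
  free <- which(a > eps & a < C - eps)
  atC <- which(a >= C - eps)
  a2 <- numeric(n)
  a2[atC] <- C
  if (length(free)) {
    A <- rbind(cbind(H[free, free, drop = FALSE], yy[free]), c(yy[free], 0))
    rhs <- c(1 - if (length(atC)) H[free, atC, drop = FALSE] %*% rep(C, length(atC))
                 else rep(0, length(free)),
             -sum(yy[atC]) * C)
    cand <- (MASS::ginv(A) %*% rhs)[seq_along(free)]
    if (all(cand > -1e-8 & cand < C + 1e-8)) a2[free] <- cand else a2 <- a
  } else {
    a2 <- a
  }
  drop(t(a2 * yy) %*% X)
}

# Small labelled matrix with planted separation, for split/evaluation tests.
toy_dataset <- function(n_a = 10, n_b = 10, p = 6, effect = 0, seed = 1) {
  set.seed(seed)
  y <- factor(rep(c("A", "B"), c(n_a, n_b)))
  x <- matrix(rnorm((n_a + n_b) * p), n_a + n_b, p,
              dimnames = list(paste0("S", seq_len(n_a + n_b)),
                              paste0("F", seq_len(p))))
  if (effect > 0) x[, 1] <- x[, 1] + ifelse(y == "A", -effect / 2, effect / 2)
  expression_dataset(x, y)
}
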