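test_that("binary AUC matches hand-worked cases", {
  expect_equal(auc_binary(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1.0)
  expect_equal(auc_binary(rep(0.5, 6), c(1, 1, 1, 0, 0, 0)), 0.5)  # all ties
  # 3 of the 4 pos/neg pairs won, 1 lost
  expect_equal(auc_binary(c(0.9, 0.3, 0.6, 0.2), c(1, 1, 0, 0)), 0.75)
  expect_error(auc_binary(c(1, 2), c(1, 1)), "two classes")
})

test_that("binary AUC equals the pair-counting oracle on random instances", {
  set.seed(99)
  for (r in 1:200) {
    n <- sample(4:30, 1)
    labels <- factor(sample(c("neg", "pos"), n, replace = TRUE))
    if (nlevels(droplevels(labels)) < 2) next
    # duplicate some scores to exercise tie handling
    scores <- sample(round(rnorm(n), 1), n, replace = TRUE)
    expect_equal(auc_binary(scores, labels, positive = "pos"),
                 auc_pair_oracle(scores, labels, positive = "pos"),
                 tolerance = 1e-12)
  }
})

test_that("negating tie-free scores reflects the AUC around one half", {
  set.seed(77)
  for (r in 1:20) {
    n <- 20
    labels <- factor(rep(c("a", "b"), 10))
    scores <- rnorm(n)  # continuous, ties have probability zero
    expect_equal(auc_binary(-scores, labels), 1 - auc_binary(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("multiclass AUC macro-averages one-vs-rest", {
  y <- factor(rep(c("A", "B", "C"), each = 4))
  # perfect separation
  s <- matrix(0, 12, 3, dimnames = list(NULL, c("A", "B", "C")))
  s[cbind(seq_len(12), as.integer(y))] <- 1
  expect_equal(auc_multiclass(s, y), 1.0)
  # A perfectly scored, B and C at exact chance (constant scores)
  s2 <- cbind(A = ifelse(y == "A", 1, 0), B = 0, C = 0)
  expect_equal(auc_multiclass(s2, y), (1 + 0.5 + 0.5) / 3)
  # class with scores but no samples is skipped with a warning
  y2 <- factor(rep(c("A", "B"), 6), levels = c("A", "B", "C"))
  expect_warning(a <- auc_multiclass(s[, c("A", "B", "C")], y2), "skipped")
})

test_that("label-independent multiclass scores sit near chance", {
  set.seed(55)
  y <- factor(sample(c("A", "B", "C"), 300, replace = TRUE))
  s <- matrix(rnorm(900), 300, 3, dimnames = list(NULL, c("A", "B", "C")))
  expect_lt(abs(auc_multiclass(s, y) - 0.5), 0.1)
})

test_that("LOO curve finds a planted separating feature and prefers the smallest k", {
  set.seed(3)
  y <- factor(rep(c("A", "B"), each = 6))
  x <- matrix(rnorm(12 * 5), 12, 5, dimnames = list(NULL, paste0("F", 1:5)))
  x[, 2] <- ifelse(y == "A", -2, 2) + rnorm(12, sd = 0.05)
  ranking <- c("F2", "F1", "F3", "F4", "F5")
  cv <- loo_select_k(x, y, ranking = ranking, ks = c(1, 2, 5))
  expect_equal(cv$auc, rep(1.0, 3))  # the separator is in every prefix
  expect_equal(cv$chosen_k, 1L)
  # all-features single-point curve
  cv2 <- loo_select_k(x, y, ranking = ranking, ks = 5)
  expect_equal(cv2$chosen_k, 5L)
  expect_length(cv2$auc, 1L)
})

test_that("LOO on pure noise stays below perfect separation", {
  ds <- toy_dataset(n_a = 10, n_b = 10, p = 8, effect = 0, seed = 12)
  cv <- loo_select_k(ds, ranking = colnames(ds$x), ks = c(2, 8))
  expect_lt(max(cv$auc), 1.0)
})

test_that("bootstrap evaluation returns B AUCs whose summary recomputes", {
  tr <- toy_dataset(n_a = 12, n_b = 12, p = 6, effect = 8, seed = 30)
  te <- toy_dataset(n_a = 6, n_b = 6, p = 6, effect = 8, seed = 31)
  rep100 <- bootstrap_test_auc(tr, te, features = "F1", B = 100, seed = 8)
  expect_length(rep100$auc, 100L)
  qs <- quantile(rep100$auc, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  expect_equal(unname(rep100$summary),
               c(min(rep100$auc), qs[1], qs[2], mean(rep100$auc), qs[3], max(rep100$auc)))
  expect_true(all(rep100$auc >= 0 & rep100$auc <= 1))
  # clean separation: every bootstrap model scores the test set perfectly
  expect_equal(unname(rep100$summary), rep(1, 6))
  # determinism under seed
  rep2 <- bootstrap_test_auc(tr, te, features = "F1", B = 100, seed = 8)
  expect_identical(rep100$auc, rep2$auc)
})

test_that("identity resample with B = 1 equals the plain train -> test AUC", {
  tr <- toy_dataset(n_a = 10, n_b = 10, p = 5, effect = 1, seed = 40)
  te <- toy_dataset(n_a = 5, n_b = 5, p = 5, effect = 1, seed = 41)
  rep1 <- bootstrap_test_auc(tr, te, features = colnames(tr$x), B = 1,
                             resample = FALSE)
  fit <- fit_linear_svm(tr$x, tr$y)
  plain <- auc_binary(decision_scores(fit, te$x)[, levels(te$y)[2]], te$y)
  expect_equal(rep1$auc, plain)
})

test_that("six-number summary and paired t-test match closed forms", {
  expect_equal(unname(summarize_auc(c(0.5, 1.0))),
               c(0.5, 0.625, 0.75, 0.75, 0.875, 1.0))
  # textbook paired sample against t = mean(d) / (sd(d)/sqrt(n))
  a <- c(0.88, 0.91, 0.79, 0.95, 0.85)
  b <- c(0.81, 0.89, 0.80, 0.90, 0.78)
  d <- a - b
  tt <- paired_auc_ttest(a, b)
  expect_equal(tt$t, mean(d) / (sd(d) / sqrt(length(d))), tolerance = 1e-12)
  expect_equal(tt$df, length(d) - 1L)
  expect_equal(tt$p, 2 * pt(-abs(tt$t), df = 4), tolerance = 1e-12)
  # exact constant shift: zero variance of differences, p reported as 0
  v <- runif(100)
  shift <- paired_auc_ttest(v + 0.1, v)
  expect_lt(shift$p, 1e-6)
  expect_error(paired_auc_ttest(v, v), "identical")
})
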