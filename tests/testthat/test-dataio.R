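test_that("expression tables read in either orientation, with labels in-table or separate", {
  tmp <- withr::local_tempdir()
  # samples in rows, label column
  f1 <- file.path(tmp, "wide.csv")
  writeLines(c("sample,P1,P2,class",
               "s1,1.5,2.0,A",
               "s2,0.5,1.0,B",
               "s3,-1.0,0.0,A"), f1)
  ds <- read_expression(f1)
  expect_equal(colnames(ds$x), c("P1", "P2"))
  expect_equal(dim(ds$x), c(3L, 2L))
  expect_equal(as.character(ds$y), c("A", "B", "A"))

  # same data transposed, labels from a separate file
  f2 <- file.path(tmp, "tall.csv")
  writeLines(c("probe,s1,s2,s3",
               "P1,1.5,0.5,-1.0",
               "P2,2.0,1.0,0.0"), f2)
  lf <- file.path(tmp, "labels.csv")
  writeLines(c("sample_id,label", "s1,A", "s2,B", "s3,A"), lf)
  ds2 <- read_expression(f2, orientation = "features", label_file = lf)
  expect_identical(ds2$x, ds$x)
  expect_identical(ds2$y, ds$y)
})

test_that("loader rejects non-numeric cells, missing labels and duplicate IDs", {
  tmp <- withr::local_tempdir()
  f <- file.path(tmp, "bad.csv")
  writeLines(c("sample,P1,class", "s1,oops,A", "s2,1.0,B"), f)
  expect_error(read_expression(f), "non-numeric")
  f2 <- file.path(tmp, "nolab.csv")
  writeLines(c("sample,P1,P2", "s1,1,2", "s2,3,4"), f2)
  expect_error(read_expression(f2), "no labels")
  expect_error(expression_dataset(matrix(1:4, 2, 2,
                                         dimnames = list(c("a", "a"), c("x", "y"))),
                                  c("A", "B")),
               "duplicate sample")
  # missing values rejected by default, imputable on request
  f3 <- file.path(tmp, "na.csv")
  writeLines(c("sample,P1,P2,class", "s1,1,2,A", "s2,NA,4,B", "s3,3,6,A"), f3)
  expect_error(read_expression(f3), "missing expression")
  ds <- read_expression(f3, impute = TRUE)
  expect_equal(ds$x["s2", "P1"], 2)  # mean of 1, 3
})

test_that("z-score normalization centers and scales with sample sd, handles refs and degenerate columns", {
  x <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  expect_warning(z <- zscore_normalize(x), "zero-variance")
  expect_equal(unname(z[, "a"]), c(-1, 0, 1))   # sample sd of 1,2,3 is 1
  expect_equal(unname(z[, "b"]), c(0, 0, 0))
  st <- attr(z, "scaling")
  expect_equal(unname(st$center), c(2, 5))
  # reference stats applied verbatim (training stats onto test data)
  z2 <- zscore_normalize(matrix(4, 1, 2), stats = list(center = c(2, 0), scale = c(1, 2)))
  expect_equal(as.vector(z2), c(2, 2))
  expect_error(zscore_normalize(x, stats = list(center = 1, scale = 1)), "length")
})

test_that("z-scored columns have mean 0 and sd 1 on random matrices", {
  for (s in 1:20) {
    set.seed(s)
    x <- matrix(rnorm(15 * 8, mean = runif(1, -5, 5), sd = runif(1, 0.1, 4)), 15, 8)
    z <- zscore_normalize(x)
    expect_lt(max(abs(colMeans(z))), 1e-9)
    expect_lt(max(abs(apply(z, 2, sd) - 1)), 1e-9)
  }
})

test_that("stratified split preserves class proportions and is deterministic", {
  ds <- toy_dataset(n_a = 4, n_b = 4)
  sp <- stratified_split(ds, 0.25, seed = 7)
  expect_equal(as.integer(table(sp$test$y)), c(1L, 1L))
  sp2 <- stratified_split(ds, 0.25, seed = 7)
  expect_identical(sp$assignment, sp2$assignment)
  # disjoint and exhaustive
  expect_length(intersect(rownames(sp$train$x), rownames(sp$test$x)), 0)
  expect_setequal(c(rownames(sp$train$x), rownames(sp$test$x)), rownames(ds$x))
  # singleton class refuses to split
  one <- expression_dataset(matrix(rnorm(6), 3, 2), c("A", "A", "B"))
  expect_error(stratified_split(one, 0.25), "B")
})

test_that("stratified split stays within one sample of exact per-class proportionality", {
  set.seed(42)
  for (r in 1:15) {
    counts <- sample(3:20, sample(2:4, 1))
    names(counts) <- paste0("C", seq_along(counts))
    frac <- runif(1, 0.15, 0.5)
    ds <- expression_dataset(matrix(rnorm(sum(counts) * 3), sum(counts), 3),
                             rep(names(counts), counts))
    sp <- stratified_split(ds, frac, seed = r)
    expect_equal(nrow(sp$test$x), round(sum(counts) * frac))
    got <- table(factor(sp$test$y, levels = names(counts)))
    expect_true(all(abs(as.numeric(got) - counts * frac) <= 1))
  }
})

test_that("ranking and selected-data files round-trip", {
  tmp <- withr::local_tempdir()
  ds <- toy_dataset(p = 4, effect = 6, seed = 3)
  fit <- svm_rfe(ds, n_features = 1, step = 1)
  f <- file.path(tmp, "ranking.tsv")
  df <- write_ranking(fit, f)
  back <- read.table(f, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(nrow(back), 4L)
  expect_equal(back$rank, 1:4)
  expect_equal(back$feature_id, fit$ranking)
  expect_true(is.na(back$iteration_eliminated[1]))  # rank 1 = final survivor

  sel <- file.path(tmp, "selected.csv")
  write_selected(ds, top_features(fit, 2), sel)
  back2 <- read.table(sel, header = TRUE, sep = ",", check.names = FALSE)
  expect_equal(back2$sample_id, rownames(ds$x))
  expect_equal(as.matrix(back2[, top_features(fit, 2)]),
               ds$x[, top_features(fit, 2)], ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(write_selected(ds, character(0), sel), "empty")
})

test_that("write -> read -> write reproduces the matrix and IDs exactly", {
  tmp <- withr::local_tempdir()
  ds <- toy_dataset(n_a = 5, n_b = 5, p = 7, seed = 11)
  f <- file.path(tmp, "all.csv")
  write_selected(ds, colnames(ds$x), f)
  back <- read_expression(f, label_column = "class")
  # sample_id column becomes rownames on re-read
  expect_equal(back$x, ds$x, tolerance = 1e-12)
  expect_identical(rownames(back$x), rownames(ds$x))
  expect_identical(back$y, ds$y)
})
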