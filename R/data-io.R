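#' Expression dataset container
#'
#' Bundles a samples x features numeric matrix with per-sample class labels.
#' All supervised functions in the package accept either an `expr_dataset`
#' or a plain matrix plus a label vector.
#'
#' @param x Numeric matrix, samples in rows, features in columns. Row names
#'   are sample IDs and column names feature IDs; defaults are generated
#'   when absent.
#' @param y Per-sample class labels (factor or coercible); length `nrow(x)`.
#' @param informative Optional character vector of feature IDs known to
#'   carry class signal (used by the synthetic generator).
#'
#' @return An object of class `expr_dataset`: a list with elements `x`
#'   (matrix), `y` (factor) and optionally `informative`.
#' @export
expression_dataset <- function(x, y, informative = NULL) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) stop("`x` must be a numeric matrix")
  if (anyNA(x) || any(!is.finite(x))) stop("expression matrix contains missing or non-finite values")
  if (length(y) != nrow(x)) stop("labels: expected one per sample (", nrow(x), "), got ", length(y))
  if (is.null(rownames(x))) rownames(x) <- paste0("S", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x))) stop("duplicate sample IDs")
  if (anyDuplicated(colnames(x))) stop("duplicate feature IDs")
  y <- droplevels(as.factor(y))
  names(y) <- NULL
  if (anyNA(y)) stop("missing class label for sample(s): ",
                     paste(rownames(x)[is.na(y)], collapse = ", "))
  structure(list(x = x, y = y, informative = informative), class = "expr_dataset")
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat("Expression dataset:", nrow(x$x), "samples x", ncol(x$x), "features\n")
  cat("Classes:", paste(sprintf("%s (%d)", levels(x$y), tabulate(x$y)), collapse = ", "), "\n")
  if (!is.null(x$informative))
    cat("Planted informative features:", length(x$informative), "\n")
  invisible(x)
}

#' @export
dim.expr_dataset <- function(x) dim(x$x)

#' Read an expression table with class labels
#'
#' Reads a delimited (CSV/TSV) expression table into an [expression_dataset()].
#' The table may hold samples in rows (default) or features in rows; the
#' returned dataset is always samples x features. Labels come either from a
#' column of the table or from a separate two-column (sample_id, label) file.
#'
#' @param path Path to the expression table.
#' @param orientation `"samples"` if samples are in rows (the default
#'   layout: header = feature IDs, first column = sample IDs) or
#'   `"features"` for the transposed layout.
#' @param label_column Name of the label column inside the table
#'   (default `"class"`); ignored when `label_file` is given.
#' @param label_file Optional path to a separate label file with columns
#'   sample_id, label (header required).
#' @param sep Field separator; `NULL` (default) sniffs `\t` vs `,` from the
#'   first line.
#' @param impute `FALSE` (default) rejects missing expression values;
#'   `TRUE` replaces them by the per-feature mean.
#'
#' @return An [expression_dataset()].
#' @export
read_expression <- function(path, orientation = c("samples", "features"),
                            label_column = "class", label_file = NULL,
                            sep = NULL, impute = FALSE) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  }
  tab <- read.table(path, header = TRUE, sep = sep, row.names = 1L,
                    check.names = FALSE, stringsAsFactors = FALSE)
  labels <- NULL
  if (is.null(label_file) && orientation == "samples" && label_column %in% colnames(tab)) {
    labels <- setNames(as.character(tab[[label_column]]), rownames(tab))
    tab <- tab[, setdiff(colnames(tab), label_column), drop = FALSE]
  }
  if (orientation == "features" && label_column %in% rownames(tab)) {
    labels <- setNames(as.character(unlist(tab[label_column, ])), colnames(tab))
    tab <- tab[setdiff(rownames(tab), label_column), , drop = FALSE]
  }
  bad <- which(!vapply(tab, is.numeric, logical(1)))
  if (length(bad)) {
    cell <- which(is.na(suppressWarnings(as.numeric(tab[[bad[1]]]))))[1]
    stop("non-numeric expression value at row ", rownames(tab)[cell],
         ", column ", colnames(tab)[bad[1]])
  }
  x <- as.matrix(tab)
  if (orientation == "features") x <- t(x)
  if (anyNA(x)) {
    if (!impute) {
      idx <- which(is.na(x), arr.ind = TRUE)[1, ]
      stop("missing expression value at sample ", rownames(x)[idx[1]],
           ", feature ", colnames(x)[idx[2]], " (set impute = TRUE to mean-impute)")
    }
    for (j in which(colSums(is.na(x)) > 0)) {
      mu <- mean(x[, j], na.rm = TRUE)
      x[is.na(x[, j]), j] <- if (is.finite(mu)) mu else 0
    }
  }
  if (!is.null(label_file)) {
    lf <- read.table(label_file, header = TRUE, sep = sep, stringsAsFactors = FALSE)
    if (ncol(lf) < 2L) stop("label file needs columns sample_id, label")
    labels <- setNames(as.character(lf[[2L]]), as.character(lf[[1L]]))
  }
  if (is.null(labels)) stop("no labels: column '", label_column,
                            "' not found and no label_file given")
  if (!all(rownames(x) %in% names(labels)))
    stop("missing labels for sample(s): ",
         paste(head(setdiff(rownames(x), names(labels)), 5L), collapse = ", "))
  expression_dataset(x, labels[rownames(x)])
}

#' Z-score normalize expression features
#'
#' Centers and scales each feature (column) to mean 0, sd 1 using the sample
#' standard deviation (n - 1 denominator). When reference statistics are
#' supplied -- typically those computed on training data -- they are applied
#' instead, so held-out data can be normalized without information leakage.
#' Zero-variance features become all-zero columns (with a warning) so that
#' feature indices stay stable for ranking.
#'
#' @param x Numeric matrix (samples x features) or [expression_dataset()].
#' @param stats Optional list with numeric vectors `center` and `scale`
#'   (per-feature mean and sd), as returned by a previous call.
#'
#' @return Object of the same type as `x`, with attribute `"scaling"`
#'   holding the list(center, scale) actually used.
#' @export
zscore_normalize <- function(x, stats = NULL) {
  ds <- if (inherits(x, "expr_dataset")) x else NULL
  m <- if (is.null(ds)) x else ds$x
  if (is.data.frame(m)) m <- as.matrix(m)
  if (is.null(stats)) {
    center <- colMeans(m)
    scale <- apply(m, 2L, sd)
  } else {
    if (length(stats$center) != ncol(m) || length(stats$scale) != ncol(m))
      stop("reference stats length does not match feature count")
    center <- stats$center
    scale <- stats$scale
  }
  zero <- !is.finite(scale) | scale == 0
  if (any(zero) && is.null(stats))
    warning(sum(zero), " zero-variance feature(s) set to all-zero columns")
  scale_eff <- ifelse(zero, 1, scale)
  out <- sweep(sweep(m, 2L, center, "-"), 2L, scale_eff, "/")
  out[, zero] <- 0
  used <- list(center = center, scale = scale)
  if (is.null(ds)) {
    attr(out, "scaling") <- used
    return(out)
  }
  ds$x <- out
  attr(ds, "scaling") <- used
  ds
}

#' Stratified train/test split
#'
#' Splits a dataset into train and test sets preserving class proportions.
#' Per-class test counts are the largest-remainder rounding of
#' `class_size * test_fraction`, constrained so the total equals
#' `round(n * test_fraction)`; each class therefore deviates from exact
#' proportionality by at most one sample.
#'
#' @param x Samples x features matrix or [expression_dataset()].
#' @param test_fraction Fraction of samples held out, in (0, 1).
#'   Default 0.25 (a stratified quarter).
#' @param seed Optional integer seed; the split is deterministic given it.
#' @param y Labels, required when `x` is a plain matrix.
#'
#' @return List with elements `train` and `test` (both
#'   [expression_dataset()]s) and `assignment`, a factor
#'   (`"train"`/`"test"`) named by sample ID.
#' @export
stratified_split <- function(x, test_fraction = 0.25, seed = NULL, y = NULL) {
  d <- resolve_xy(x, y)
  if (!(test_fraction > 0 && test_fraction < 1)) stop("test_fraction must be in (0, 1)")
  counts <- table(d$y)
  if (any(counts < 2L))
    stop("class(es) with a single sample cannot be split: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  n <- nrow(d$x)
  total_test <- round(n * test_fraction)
  raw <- as.numeric(counts) * test_fraction
  base <- floor(raw)
  rem <- raw - base
  left <- total_test - sum(base)
  if (left > 0) {
    give <- order(-rem, names(counts))[seq_len(left)]
    base[give] <- base[give] + 1L
  } else if (left < 0) {
    take <- order(rem, names(counts))[seq_len(-left)]
    base[take] <- base[take] - 1L
  }
  test_counts <- setNames(as.integer(base), names(counts))
  test_idx <- with_seed(seed, {
    unlist(lapply(names(counts), function(cl) {
      rows <- which(d$y == cl)
      sample(rows, test_counts[[cl]])
    }), use.names = FALSE)
  })
  assignment <- factor(ifelse(seq_len(n) %in% test_idx, "test", "train"),
                       levels = c("train", "test"))
  names(assignment) <- rownames(d$x)
  tr <- sort(setdiff(seq_len(n), test_idx))
  te <- sort(test_idx)
  list(train = expression_dataset(d$x[tr, , drop = FALSE], d$y[tr]),
       test = expression_dataset(d$x[te, , drop = FALSE], d$y[te]),
       assignment = assignment)
}

#' Write a feature ranking to TSV
#'
#' @param object An [esvm_rfe()] fit (ranking trace).
#' @param path Output file.
#'
#' @return Invisibly, the data frame written: columns `rank`, `feature_id`,
#'   `iteration_eliminated` (NA for final survivors) and
#'   `aggregated_weight_at_elimination` (for survivors, the final ensemble
#'   totals).
#' @export
write_ranking <- function(object, path) {
  stopifnot(inherits(object, "esvm_rfe"))
  df <- ranking_table(object)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' @rdname write_ranking
#' @export
ranking_table <- function(object) {
  stopifnot(inherits(object, "esvm_rfe"))
  elim_iter <- setNames(rep(NA_integer_, length(object$feature_ids)), object$feature_ids)
  elim_wt <- setNames(rep(NA_real_, length(object$feature_ids)), object$feature_ids)
  for (i in seq_along(object$iterations)) {
    it <- object$iterations[[i]]
    elim_iter[it$eliminated] <- i
    elim_wt[it$eliminated] <- it$totals[it$eliminated]
  }
  last <- object$iterations[[length(object$iterations)]]
  elim_wt[object$final_survivors] <- last$totals[object$final_survivors]
  data.frame(rank = seq_along(object$ranking),
             feature_id = object$ranking,
             iteration_eliminated = unname(elim_iter[object$ranking]),
             aggregated_weight_at_elimination = unname(elim_wt[object$ranking]),
             stringsAsFactors = FALSE)
}

#' Write selected features of a dataset to CSV
#'
#' @param x [expression_dataset()] (or matrix with `y` labels).
#' @param features Character vector of feature IDs to keep; must be
#'   non-empty and present in the data.
#' @param path Output CSV; columns are sample_id, class, then the selected
#'   features in the given order. Sample order is preserved.
#' @param y Labels when `x` is a matrix.
#'
#' @return Invisibly, the data frame written.
#' @export
write_selected <- function(x, features, path, y = NULL) {
  d <- resolve_xy(x, y)
  if (length(features) == 0L) stop("empty feature subset")
  miss <- setdiff(features, colnames(d$x))
  if (length(miss)) stop("features not in dataset: ", paste(head(miss, 5L), collapse = ", "))
  df <- data.frame(sample_id = rownames(d$x), class = as.character(d$y),
                   d$x[, features, drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(df)
}
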