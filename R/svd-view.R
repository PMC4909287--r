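#' SVD projection of selected features
#'
#' Column-centers the data restricted to the selected features, computes a
#' thin singular value decomposition and returns the top-k sample scores
#' (U_k Sigma_k), giving a PCA-style low-dimensional view of how well the
#' selected features separate the classes. The stored center and right
#' singular vectors let held-out samples be projected onto the same axes
#' via [predict.svd_projection()].
#'
#' The sign of each right singular vector is fixed so its largest-magnitude
#' entry is positive, making the view reproducible across platforms.
#'
#' @param x Samples x features matrix or [expression_dataset()].
#' @param features Feature IDs to project (default: all).
#' @param k Number of dimensions, `k <= min(n_samples, n_features)`
#'   (default 2).
#' @param y Labels for plotting (ignored for `expr_dataset`; optional).
#'
#' @return Object of class `svd_projection`: `coords` (samples x k),
#'   `d` (top-k singular values), `rotation` (features x k orthonormal
#'   basis), `center` (per-feature means), `features`, and `labels` when
#'   available.
#' @export
svd_project <- function(x, features = NULL, k = 2, y = NULL) {
  labs <- NULL
  if (inherits(x, "expr_dataset")) {
    labs <- x$y
    m <- x$x
  } else {
    m <- if (is.data.frame(x)) as.matrix(x) else x
    if (!is.null(y)) labs <- as.factor(y)
  }
  if (is.null(colnames(m))) colnames(m) <- paste0("V", seq_len(ncol(m)))
  if (is.null(features)) features <- colnames(m)
  miss <- setdiff(features, colnames(m))
  if (length(miss)) stop("features not in data: ", paste(head(miss, 5L), collapse = ", "))
  m <- m[, features, drop = FALSE]
  k <- as.integer(k)
  if (k > min(dim(m))) stop("k = ", k, " exceeds min(samples, features) = ", min(dim(m)))
  center <- colMeans(m)
  mc <- sweep(m, 2L, center)
  sv <- svd(mc, nu = k, nv = k)
  flip <- vapply(seq_len(k), function(j) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  v <- sweep(sv$v, 2L, flip, "*")
  u <- sweep(sv$u, 2L, flip, "*")
  coords <- u %*% diag(sv$d[seq_len(k)], k, k)
  dimnames(coords) <- list(rownames(m), paste0("SV", seq_len(k)))
  dimnames(v) <- list(features, paste0("SV", seq_len(k)))
  structure(list(coords = coords, d = sv$d[seq_len(k)], rotation = v,
                 center = center, features = features, labels = labs),
            class = "svd_projection")
}

#' Project new samples onto an existing SVD basis
#'
#' @param object An [svd_project()] result.
#' @param newdata Samples x features matrix or [expression_dataset()]
#'   containing at least the projection's features. Training samples passed
#'   back in reproduce their training coordinates.
#' @param ... Unused.
#' @return Samples x k coordinate matrix.
#' @export
predict.svd_projection <- function(object, newdata, ...) {
  m <- if (inherits(newdata, "expr_dataset")) newdata$x
       else if (is.data.frame(newdata)) as.matrix(newdata) else newdata
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L, dimnames = list(NULL, names(m)))
  miss <- setdiff(object$features, colnames(m))
  if (length(miss)) stop("new data lacks feature(s): ",
                         paste(head(miss, 10L), collapse = ", "))
  mc <- sweep(m[, object$features, drop = FALSE], 2L, object$center)
  out <- mc %*% object$rotation
  rownames(out) <- rownames(m)
  out
}

#' @export
print.svd_projection <- function(x, ...) {
  cat("SVD projection:", nrow(x$coords), "samples x", ncol(x$coords),
      "components over", length(x$features), "features\n")
  cat("  singular values:", paste(sprintf("%.3f", x$d), collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn svd_project Scatter plot of the first two projected
#'   dimensions, colored by class when labels are available.
#' @param col Colors per class level (recycled).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.svd_projection <- function(x, col = c("red", "black", "blue", "darkgreen",
                                           "orange", "purple", "cyan", "brown"),
                                ...) {
  if (ncol(x$coords) < 2L) stop("need at least two projected dimensions to plot")
  cls <- if (!is.null(x$labels)) as.integer(x$labels) else 1L
  plot(x$coords[, 1L], x$coords[, 2L], col = col[cls],
       xlab = "SV1", ylab = "SV2", pch = 19, ...)
  if (!is.null(x$labels))
    legend("topright", legend = levels(x$labels),
           col = col[seq_len(nlevels(x$labels))], pch = 19, bty = "n")
  invisible(x)
}

#' Write projected coordinates to TSV
#'
#' @param object An [svd_project()] result or a coordinate matrix from
#'   [predict.svd_projection()].
#' @param path Output file; columns sample_id, SV1..SVk (and class when
#'   labels are available).
#' @return Invisibly, `path`.
#' @export
write_coords <- function(object, path) {
  if (inherits(object, "svd_projection")) {
    df <- data.frame(sample_id = rownames(object$coords), object$coords,
                     check.names = FALSE)
    if (!is.null(object$labels)) df$class <- as.character(object$labels)
  } else {
    df <- data.frame(sample_id = rownames(object), object, check.names = FALSE)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
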