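#' Number of features surviving one elimination step
#'
#' The schedule removes `floor(m * elim_frac)` of the `m` current features,
#' but always at least one (so the loop cannot stall when `m * elim_frac`
#' rounds to zero) and never so many that fewer than `d` would remain (the
#' final step is clipped so the run terminates at exactly `d`).
#'
#' @param m Current number of surviving features (`m > d`).
#' @param elim_frac Fraction eliminated per step, in (0, 1).
#' @param d Target number of features.
#' @return Integer in `[d, m - 1]`.
#' @export
survivors_count <- function(m, elim_frac, d) {
  stopifnot(m > d, elim_frac > 0, elim_frac < 1, d >= 1)
  max(as.integer(d), m - max(1L, as.integer(floor(m * elim_frac))))
}

#' Ensemble SVM recursive feature elimination
#'
#' Backward feature elimination in which every elimination step is decided
#' by an ensemble of linear SVMs rather than a single model. Per step:
#' `bags` class-balanced bootstrap bags are drawn from the training data,
#' one linear SVM is fitted per bag on the surviving features, each model's
#' per-feature criterion c_j = w_j^2 is computed, the criteria are summed
#' across the ensemble, and the lowest-scoring fraction `elim_frac` of
#' features is discarded. The loop repeats until exactly `n_features`
#' survive. Balanced bags (default: minority-class size drawn from every
#' class, with replacement) make the ranking robust to class imbalance.
#'
#' With `bags = 1` and `resample = FALSE` the procedure reduces to classic
#' single-model SVM-RFE (see [svm_rfe()]).
#'
#' @param x Samples x features matrix or [expression_dataset()]. Features
#'   are assumed z-scored (see [zscore_normalize()]); no rescaling happens
#'   internally.
#' @param y Labels (ignored when `x` is an `expr_dataset`).
#' @param n_features Target number of surviving features `d` (default 1,
#'   which yields a complete ranking of all features).
#' @param bags Ensemble size `b`: SVMs trained per elimination step
#'   (default 40).
#' @param elim_frac Fraction `E` of surviving features eliminated per step
#'   (default 0.10). Ignored when `elim_step` is given.
#' @param elim_step Optional fixed number of features to eliminate per step
#'   (classic SVM-RFE uses 1).
#' @param bag_spec Named integer vector class -> per-bag draw count, or
#'   `NULL` for the balanced default ([balanced_bag_spec()]).
#' @param cost SVM cost C (default 1).
#' @param resample If `FALSE`, every bag is the full training set taken
#'   exactly once (no bootstrap); used for the classic SVM-RFE baseline.
#' @param seed Optional integer seed; one RNG stream drives all bags of all
#'   iterations, so a single seed reproduces the whole run.
#' @param max_redraw Bags that happen to contain a single class (possible
#'   only with a user-supplied `bag_spec`) are redrawn up to this many
#'   times before erroring.
#'
#' @return Object of class `esvm_rfe` (the full elimination trace):
#'   \describe{
#'     \item{feature_ids}{all input features}
#'     \item{iterations}{per step: `m`, `survive`, surviving feature IDs
#'       before elimination, aggregated ensemble totals (named), and the
#'       IDs eliminated that step (ordered by descending total)}
#'     \item{final_survivors}{the `n_features` retained features, in
#'       original column order}
#'     \item{ranking}{total order over all features, best first: final
#'       survivors by final ensemble totals, then eliminated features in
#'       reverse order of elimination (within a step, by that step's
#'       totals)}
#'   }
#' @seealso [svm_rfe()], [top_features()], [write_ranking()]
#' @export
esvm_rfe <- function(x, y = NULL, n_features = 1, bags = 40, elim_frac = 0.10,
                     elim_step = NULL, bag_spec = NULL, cost = 1,
                     resample = TRUE, seed = NULL, max_redraw = 10) {
  d <- resolve_xy(x, y)
  p <- ncol(d$x)
  n_features <- as.integer(n_features)
  bags <- as.integer(bags)
  stopifnot(bags >= 1L, n_features >= 1L)
  if (n_features >= p) stop("n_features must be smaller than the feature count (", p, ")")
  if (is.null(elim_step)) stopifnot(elim_frac > 0, elim_frac < 1)
  if (min(table(d$y)) < 1L || nlevels(d$y) < 2L) stop("need >= 2 non-empty classes")
  spec <- if (is.null(bag_spec)) balanced_bag_spec(d$y) else {
    storage.mode(bag_spec) <- "integer"
    bag_spec
  }
  ids <- colnames(d$x)

  with_seed(seed, {
    surv <- seq_len(p)
    iterations <- list()
    while (length(surv) > n_features) {
      m <- length(surv)
      survive <- if (is.null(elim_step)) survivors_count(m, elim_frac, n_features)
                 else max(n_features, m - as.integer(elim_step))
      crit <- matrix(0, m, bags)
      for (i in seq_len(bags)) {
        if (resample) {
          bag <- draw_bag(d$y, spec)
          tries <- 0L
          while (nlevels(droplevels(d$y[bag])) < 2L) {
            tries <- tries + 1L
            if (tries > max_redraw)
              stop("drew a single-class bag ", max_redraw, " times in a row; ",
                   "check the bag spec")
            bag <- draw_bag(d$y, spec)
          }
        } else {
          bag <- seq_len(nrow(d$x))
        }
        fit <- fit_linear_svm(d$x[bag, surv, drop = FALSE], d$y[bag], cost = cost)
        crit[, i] <- ranking_criterion(fit)
      }
      totals <- rowSums(crit)
      names(totals) <- ids[surv]
      ord <- order(-totals, seq_len(m))  # stable: total desc, feature index asc
      keep <- ord[seq_len(survive)]
      elim <- ord[(survive + 1L):m]
      iterations[[length(iterations) + 1L]] <-
        list(m = m, survive = survive, survivors = ids[surv],
             totals = totals, eliminated = ids[surv][elim])
      surv <- surv[sort(keep)]
    }
    last <- iterations[[length(iterations)]]
    fin <- ids[surv]
    fin_ranked <- fin[order(-last$totals[fin], match(fin, ids))]
    ranking <- c(fin_ranked,
                 unlist(lapply(rev(iterations), `[[`, "eliminated"), use.names = FALSE))
    structure(list(feature_ids = ids, n_features = n_features, bags = bags,
                   elim_frac = if (is.null(elim_step)) elim_frac else NA_real_,
                   elim_step = elim_step, bag_spec = spec, cost = cost,
                   resample = resample, seed = seed,
                   iterations = iterations, final_survivors = fin,
                   ranking = ranking, call = match.call()),
              class = "esvm_rfe")
  })
}

#' Classic single-model SVM-RFE
#'
#' The degenerate configuration of [esvm_rfe()]: one SVM per step, trained
#' on the full training set (no resampling), eliminating `step` features
#' (or a fraction, if `step < 1`) per iteration.
#'
#' @inheritParams esvm_rfe
#' @param step Features eliminated per iteration: an integer >= 1, or a
#'   fraction in (0, 1).
#' @return An `esvm_rfe` trace (see [esvm_rfe()]).
#' @export
svm_rfe <- function(x, y = NULL, n_features = 1, step = 1, cost = 1, seed = NULL) {
  if (step >= 1) {
    esvm_rfe(x, y, n_features = n_features, bags = 1L, elim_step = as.integer(step),
             cost = cost, resample = FALSE, seed = seed)
  } else {
    esvm_rfe(x, y, n_features = n_features, bags = 1L, elim_frac = step,
             cost = cost, resample = FALSE, seed = seed)
  }
}

#' Top-ranked features from an elimination trace
#'
#' @param object An [esvm_rfe()] fit.
#' @param k How many features (1 <= k <= total).
#' @return Character vector of the `k` best feature IDs, best first.
#' @export
top_features <- function(object, k) {
  stopifnot(inherits(object, "esvm_rfe"))
  k <- as.integer(k)
  if (k < 1L || k > length(object$ranking))
    stop("k must be between 1 and ", length(object$ranking))
  object$ranking[seq_len(k)]
}

#' @export
print.esvm_rfe <- function(x, ...) {
  kind <- if (x$bags == 1L && !x$resample) "SVM-RFE (single model)" else "Ensemble SVM-RFE"
  cat(kind, "\n")
  cat("  features: ", length(x$feature_ids), " -> ", x$n_features,
      " over ", length(x$iterations), " iterations\n", sep = "")
  if (x$bags > 1L || x$resample)
    cat("  ensemble: ", x$bags, " bags/step, bag spec {",
        paste(sprintf("%s: %d", names(x$bag_spec), x$bag_spec), collapse = ", "),
        "}\n", sep = "")
  cat("  elimination: ",
      if (!is.null(x$elim_step)) paste(x$elim_step, "feature(s)/step")
      else paste0(100 * x$elim_frac, "%/step"),
      ", cost C = ", x$cost, "\n", sep = "")
  cat("  final survivors:", paste(head(x$final_survivors, 10L), collapse = ", "),
      if (length(x$final_survivors) > 10L) "..." else "", "\n")
  invisible(x)
}

#' @export
summary.esvm_rfe <- function(object, ...) {
  it <- object$iterations
  df <- data.frame(iteration = seq_along(it),
                   features_in = vapply(it, `[[`, integer(1), "m"),
                   survivors = vapply(it, `[[`, integer(1), "survive"),
                   eliminated = vapply(it, function(i) length(i$eliminated), integer(1)))
  structure(list(schedule = df, ranking_head = head(object$ranking, 20L),
                 object = object), class = "summary.esvm_rfe")
}

#' @export
print.summary.esvm_rfe <- function(x, ...) {
  print(x$object)
  cat("\nElimination schedule:\n")
  print(x$schedule, row.names = FALSE)
  cat("\nTop of ranking:", paste(x$ranking_head, collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn esvm_rfe Bar plot of final aggregated ensemble weights for
#'   the top `k` ranked features.
#' @param k Number of top features to display (default 20).
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.esvm_rfe <- function(x, k = 20, ...) {
  last <- x$iterations[[length(x$iterations)]]
  feats <- head(x$ranking, min(k, length(last$survivors)))
  feats <- feats[feats %in% names(last$totals)]
  barplot(last$totals[feats], las = 2,
          ylab = "aggregated ensemble weight",
          main = "Final-iteration feature weights", ...)
  invisible(x)
}

#' Serialize an elimination trace to JSON
#'
#' Writes iterations (feature counts, totals, eliminated IDs), the final
#' survivors and the full ranking for audit. Deterministic for a given
#' trace.
#'
#' @param object An [esvm_rfe()] fit.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_trace_json <- function(object, path) {
  stopifnot(inherits(object, "esvm_rfe"))
  out <- list(
    n_features = object$n_features, bags = object$bags,
    elim_frac = object$elim_frac, elim_step = object$elim_step,
    cost = object$cost, resample = object$resample,
    bag_spec = as.list(object$bag_spec), seed = object$seed,
    iterations = lapply(object$iterations, function(it)
      list(m = it$m, survive = it$survive,
           totals = as.list(it$totals), eliminated = it$eliminated)),
    final_survivors = object$final_survivors,
    ranking = object$ranking)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
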