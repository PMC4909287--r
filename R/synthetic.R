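#' Generate a microarray-like dataset with planted informative features
#'
#' Emulates the shape of small-cohort expression studies: far fewer samples
#' than features, optional class imbalance, and a small set of
#' class-informative features on an i.i.d. Gaussian noise background.
#' Background features are Normal(0, noise_sd^2) regardless of class;
#' informative features receive class-dependent mean shifts -- +/- effect/2
#' for two classes, and equally spaced class means spanning `effect` for
#' more. The defaults mirror a 60-patient relapse cohort with a 21:39 class
#' imbalance measured over a couple of thousand probes.
#'
#' @param n_per_class Named integer vector class -> sample count
#'   (default `c(Relapse = 21, NonRelapse = 39)`).
#' @param p Total number of features (default 2000).
#' @param informative Number of class-informative features (default 30,
#'   must be `<= p`). The first `informative` feature IDs carry signal; the
#'   returned dataset records them.
#' @param effect Between-class mean separation, in units of `noise_sd`
#'   (default 1).
#' @param noise_sd Background standard deviation (default 1).
#' @param seed Optional integer seed; the dataset is byte-identical given
#'   it.
#'
#' @return An [expression_dataset()] whose `informative` element holds the
#'   planted feature IDs.
#' @export
make_synthetic <- function(n_per_class = c(Relapse = 21, NonRelapse = 39),
                           p = 2000, informative = 30, effect = 1,
                           noise_sd = 1, seed = NULL) {
  stopifnot(all(n_per_class >= 1), p >= 1, effect >= 0, noise_sd > 0)
  if (informative > p) stop("informative (", informative, ") exceeds p (", p, ")")
  if (is.null(names(n_per_class)))
    names(n_per_class) <- paste0("C", seq_along(n_per_class))
  n <- sum(n_per_class)
  classes <- names(n_per_class)
  y <- factor(rep(classes, times = n_per_class), levels = classes)
  shifts <- if (length(classes) == 2L) c(-effect / 2, effect / 2)
            else seq(-effect / 2, effect / 2, length.out = length(classes))
  with_seed(seed, {
    x <- matrix(rnorm(n * p, sd = noise_sd), n, p)
    if (informative > 0L)
      x[, seq_len(informative)] <- x[, seq_len(informative)] +
        shifts[as.integer(y)]
    dimnames(x) <- list(sprintf("S%03d", seq_len(n)),
                        sprintf("F%05d", seq_len(p)))
    expression_dataset(x, y,
                       informative = if (informative > 0L) colnames(x)[seq_len(informative)])
  })
}

#' Recall of planted features in the top of a ranking
#'
#' @param ranking An [esvm_rfe()] fit or a best-first character vector of
#'   feature IDs.
#' @param truth Non-empty character vector of ground-truth informative
#'   feature IDs.
#' @param k Depth of the ranking to inspect.
#' @return `|top-k intersect truth| / |truth|`, in `[0, 1]`.
#' @export
recovery_score <- function(ranking, truth, k) {
  rk <- if (inherits(ranking, "esvm_rfe")) ranking$ranking else as.character(ranking)
  if (length(truth) == 0L) stop("truth set is empty")
  length(intersect(rk[seq_len(min(k, length(rk)))], truth)) / length(truth)
}
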