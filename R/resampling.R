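#' Balanced bag specification
#'
#' Number of samples to bootstrap from each class when building one
#' ensemble bag. The default rule draws the minority-class size from every
#' class, so each bag is exactly class-balanced regardless of how
#' imbalanced the training data are.
#'
#' @param y Training labels (factor or coercible); at least two classes,
#'   each non-empty.
#'
#' @return Named integer vector: class -> per-bag draw count.
#' @export
balanced_bag_spec <- function(y) {
  y <- droplevels(as.factor(y))
  counts <- table(y)
  if (length(counts) < 2L) stop("need at least two classes")
  if (any(counts == 0L)) stop("empty class: ", paste(names(counts)[counts == 0L], collapse = ", "))
  setNames(rep(as.integer(min(counts)), length(counts)), names(counts))
}

#' Draw one bootstrap bag
#'
#' Stratified bootstrap: for each class, draws the specified number of row
#' indices uniformly with replacement from that class's rows. Expression
#' rows and labels are taken from the same indices (a single paired draw),
#' so per-class counts in the bag match the spec exactly.
#'
#' @param y Training labels.
#' @param spec Named integer vector class -> count, e.g. from
#'   [balanced_bag_spec()]. Every class named must be present in `y` and
#'   every count must be >= 1.
#'
#' @return Integer vector of row indices into the training data (length
#'   `sum(spec)`, repeats allowed). Consumes the current RNG stream.
#' @export
draw_bag <- function(y, spec) {
  y <- as.factor(y)
  if (is.null(names(spec)) || any(!nzchar(names(spec))))
    stop("bag spec must be a named vector (class -> count)")
  miss <- setdiff(names(spec), levels(y)[tabulate(y, nbins = nlevels(y)) > 0])
  if (length(miss)) stop("bag spec names class(es) absent from labels: ",
                         paste(miss, collapse = ", "))
  if (any(spec < 1L)) stop("every bag spec count must be >= 1")
  unlist(lapply(names(spec), function(cl) {
    rows <- which(y == cl)
    rows[sample.int(length(rows), spec[[cl]], replace = TRUE)]
  }), use.names = FALSE)
}
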