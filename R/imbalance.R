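# Class-imbalance treatment: random oversampling to equal class counts and
# inverse-count class weights. Applied to training rows only; the pipeline
# never resamples validation or test folds.

#' Random oversampling to equal class counts
#'
#' Minority classes are resampled with replacement (seeded) until every class
#' count equals the majority count. All original rows are retained in their
#' original order; duplicated rows are appended. Already-balanced input is
#' returned unchanged.
#'
#' @param X Numeric matrix of rows to resample (beats x features), or a
#'   [feature_matrix].
#' @param y Class labels (ignored when `X` is a [feature_matrix]).
#' @param seed Integer seed.
#' @return List: `X`, `y` (resampled), `report` (a `balance_report` with
#'   `counts_before`, `counts_after`, `class_weights`, `seed`, and the
#'   resampled row `indices`).
#' @export
random_oversample <- function(X, y = NULL, seed = 1L) {
  fm <- inherits(X, "feature_matrix")
  if (fm) { y <- X$labels; vals <- X$values } else vals <- as.matrix(X)
  y <- as.character(y)
  counts <- table(y)
  if (length(counts) < 2L) stop("need at least two classes")
  if (any(counts == 0L)) stop("every class needs at least one sample")
  target <- max(counts)
  extra <- with_seed(seed, {
    unlist(lapply(names(counts), function(cl) {
      need <- target - counts[[cl]]
      if (need == 0L) return(integer(0))
      sample(which(y == cl), need, replace = TRUE)
    }))
  })
  idx <- c(seq_along(y), extra)
  y2 <- y[idx]
  X2 <- vals[idx, , drop = FALSE]
  counts_after <- table(y2)
  report <- structure(list(counts_before = c(counts),
                           counts_after = c(counts_after),
                           class_weights = 1 / c(counts_after),
                           seed = as.integer(seed), indices = idx),
                      class = "balance_report")
  if (fm) X2 <- feature_matrix(X2, X$names, y2, scaling = X$scaling)
  list(X = X2, y = y2, report = report)
}

#' Inverse-count class weights
#'
#' `weight[c] = 1 / count[c]` per class; computed after resampling when used
#' together with [random_oversample] (where counts are equal and the weights
#' uniform — the literal post-resampling order), or on the raw labels when
#' weighting is used instead of resampling.
#'
#' @param y Class labels (non-empty, every class count >= 1).
#' @return Named numeric vector of per-class weights.
#' @export
class_weights <- function(y) {
  if (!length(y)) stop("empty label vector")
  counts <- table(as.character(y))
  1 / c(counts)
}

#' @export
print.balance_report <- function(x, ...) {
  cat("<balance_report>\n  before:", paste(names(x$counts_before),
      x$counts_before, sep = "=", collapse = " "), "\n  after: ",
      paste(names(x$counts_after), x$counts_after, sep = "=", collapse = " "), "\n")
  invisible(x)
}
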