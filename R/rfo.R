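# Red-fox optimization: a population of candidate solutions (foxes) moves
# toward the best-so-far by a step drawn from its distance to the best. Used
# both as a wrapper feature selector (soft masks in [0,1]^d, binarized for
# fitness) and as a plain continuous minimizer.

#' Distances from each fox to the best fox
#'
#' Euclidean norm of each row of `positions` minus `best`.
#'
#' @param pop List with `positions` (P x d matrix) and `best` (d-vector).
#' @return Non-negative numeric vector of length P.
#' @export
distance_to_best <- function(pop) {
  P <- nrow(pop$positions)
  sqrt(rowSums((pop$positions - matrix(pop$best, P, ncol(pop$positions),
                                       byrow = TRUE))^2))
}

#' Global migration move toward the best fox
#'
#' Each fox moves every coordinate toward the corresponding coordinate of the
#' best by a step `beta` drawn uniformly from `(0, distance_to_best]`
#' (seeded): `x <- x + beta * sign(best - x)`, then clipped to the bounds.
#' Coordinates already equal to the best are unchanged (`sign(0) = 0`); the
#' best fox itself therefore never moves.
#'
#' @param pop List with `positions`, `best`, and optionally `lower`/`upper`
#'   bounds (defaults 0 and 1).
#' @param beta Optional fixed step (vector of length P or scalar); by default
#'   drawn from the population RNG stream.
#' @return The population with updated `positions`.
#' @export
global_move <- function(pop, beta = NULL) {
  P <- nrow(pop$positions); d <- ncol(pop$positions)
  lo <- pop$lower %||% 0; hi <- pop$upper %||% 1
  dist <- distance_to_best(pop)
  if (is.null(beta)) beta <- stats::runif(P) * dist
  B <- matrix(pop$best, P, d, byrow = TRUE)
  pos <- pop$positions + beta * sign(B - pop$positions)
  pop$positions <- pmin(pmax(pos, lo), hi)
  pop
}

# mask from a soft position vector; all-false -> force the largest coordinate
binarize_mask <- function(x, threshold = 0.5) {
  m <- x >= threshold
  if (!any(m)) m[which.max(x)] <- TRUE
  m
}

# stratified k-fold assignment (per class round-robin after a seeded shuffle)
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  })
  fold
}

# nearest-centroid classifier: cheap surrogate for wrapper fitness
nearest_centroid_predict <- function(Xtr, ytr, Xte) {
  classes <- sort(unique(ytr))
  cen <- do.call(rbind, lapply(classes, function(cl)
    colMeans(Xtr[ytr == cl, , drop = FALSE])))
  d2 <- outer(rowSums(Xte^2), rep(1, length(classes))) -
    2 * Xte %*% t(cen) + outer(rep(1, nrow(Xte)), rowSums(cen^2))
  classes[max.col(-d2, ties.method = "first")]
}

#' Fitness of a feature mask
#'
#' Stratified k-fold cross-validated accuracy of a nearest-centroid
#' classifier on the masked features, minus a sparsity penalty
#' `lambda * n_selected / d`. An empty mask scores 0.
#'
#' @param mask Logical d-vector.
#' @param X Feature matrix (numeric matrix or [feature_matrix]).
#' @param y Class labels.
#' @param lambda Sparsity penalty weight (default 0.01).
#' @param k Folds (default 3).
#' @param seed Seed for the fold assignment.
#' @return Scalar fitness.
#' @export
mask_fitness <- function(mask, X, y, lambda = 0.01, k = 3, seed = 1L) {
  if (inherits(X, "feature_matrix")) { y <- X$labels; X <- X$values }
  if (length(unique(y)) < 2L) stop("fitness needs at least two classes")
  if (!any(mask)) return(0)
  Xm <- X[, mask, drop = FALSE]
  fold <- stratified_folds(y, k, seed)
  acc <- vapply(seq_len(k), function(f) {
    te <- fold == f
    if (!any(te) || length(unique(y[!te])) < 2L) return(NA_real_)
    mean(nearest_centroid_predict(Xm[!te, , drop = FALSE], y[!te],
                                  Xm[te, , drop = FALSE]) == y[te])
  }, numeric(1))
  mean(acc, na.rm = TRUE) - lambda * sum(mask) / length(mask)
}

#' Red-fox wrapper feature selection
#'
#' Soft masks in `[0, 1]^d` are scored by [mask_fitness] of their
#' binarization (`position >= binarize_threshold`). Each iteration performs
#' the global migration of [global_move], re-evaluates, replaces the worst
#' `reinit_fraction` of foxes with fresh uniform positions (the "migrating
#' individuals"), and updates the best-so-far. Deterministic for a fixed
#' seed; the fitness history is the non-decreasing best-so-far curve.
#'
#' @param X Feature matrix or [feature_matrix] (then `y` is taken from it).
#' @param y Class labels (two or more classes).
#' @param foxes Population size P (>= 2).
#' @param iterations Number of iterations (>= 1).
#' @param lambda Sparsity penalty, see [mask_fitness].
#' @param binarize_threshold Soft-mask cut point (default 0.5).
#' @param reinit_fraction Fraction of worst foxes replaced per iteration.
#' @param seed Integer seed.
#' @return A list of class `selection_result`: `mask`, `selected_names`,
#'   `fitness_history`, `best_fitness`, `params`.
#' @export
rfo_select <- function(X, y = NULL, foxes = 20, iterations = 50,
                       lambda = 0.01, binarize_threshold = 0.5,
                       reinit_fraction = 0.1, seed = 1L) {
  nm <- NULL
  if (inherits(X, "feature_matrix")) { y <- X$labels; nm <- X$names; X <- X$values }
  if (is.null(nm)) nm <- colnames(X) %||% sprintf("f%02d", seq_len(ncol(X)))
  d <- ncol(X)
  if (d < 2L) stop("need at least two features")
  if (length(unique(y)) < 2L) stop("need at least two classes")
  if (iterations < 1L) stop("iterations must be >= 1")
  if (foxes < 2L) stop("need at least two foxes")
  fit_of <- function(pos) mask_fitness(binarize_mask(pos, binarize_threshold),
                                       X, y, lambda = lambda, seed = seed)
  res <- with_seed(seed, {
    positions <- matrix(stats::runif(foxes * d), foxes, d)
    fitness <- apply(positions, 1, fit_of)
    bi <- which.max(fitness)
    best <- positions[bi, ]; best_fit <- fitness[bi]
    history <- numeric(iterations)
    pop <- list(positions = positions, best = best, lower = 0, upper = 1)
    n_re <- floor(reinit_fraction * foxes)
    for (it in seq_len(iterations)) {
      pop <- global_move(pop)
      fitness <- apply(pop$positions, 1, fit_of)
      if (n_re > 0L) {
        w <- order(fitness)[seq_len(n_re)]
        pop$positions[w, ] <- matrix(stats::runif(n_re * d), n_re, d)
        fitness[w] <- apply(pop$positions[w, , drop = FALSE], 1, fit_of)
      }
      if (max(fitness) > best_fit) {
        bi <- which.max(fitness)
        best_fit <- fitness[bi]
        pop$best <- pop$positions[bi, ]
      }
      history[it] <- best_fit
    }
    list(best = pop$best, best_fit = best_fit, history = history)
  })
  mask <- binarize_mask(res$best, binarize_threshold)
  structure(list(mask = mask, position = res$best, selected_names = nm[mask],
                 fitness_history = res$history, best_fitness = res$best_fit,
                 params = list(foxes = foxes, iterations = iterations,
                               lambda = lambda,
                               binarize_threshold = binarize_threshold,
                               reinit_fraction = reinit_fraction, seed = seed)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d/%d features, best fitness %.4f\n",
              sum(x$mask), length(x$mask), x$best_fitness))
  invisible(x)
}

#' Red-fox optimization of a continuous function
#'
#' The same migration dynamics as [rfo_select] applied directly to an
#' objective to minimize, bypassing the mask/fitness layer. Useful for
#' benchmarking the optimizer on analytic test functions.
#'
#' @param fn Objective to minimize, taking a d-vector.
#' @param d Dimension.
#' @param lower,upper Box bounds (scalars).
#' @param foxes,iterations,reinit_fraction,seed As in [rfo_select].
#' @return List: `par`, `value`, `history` (best-so-far per iteration,
#'   non-increasing).
#' @export
rfo_optimize <- function(fn, d, lower = -1, upper = 1, foxes = 20,
                         iterations = 200, reinit_fraction = 0.1, seed = 1L) {
  if (iterations < 1L) stop("iterations must be >= 1")
  with_seed(seed, {
    positions <- matrix(stats::runif(foxes * d, lower, upper), foxes, d)
    value <- apply(positions, 1, fn)
    bi <- which.min(value)
    best <- positions[bi, ]; best_val <- value[bi]
    history <- numeric(iterations)
    pop <- list(positions = positions, best = best, lower = lower, upper = upper)
    n_re <- floor(reinit_fraction * foxes)
    for (it in seq_len(iterations)) {
      pop <- global_move(pop)
      value <- apply(pop$positions, 1, fn)
      if (n_re > 0L) {
        w <- order(value, decreasing = TRUE)[seq_len(n_re)]
        pop$positions[w, ] <- matrix(stats::runif(n_re * d, lower, upper), n_re, d)
        value[w] <- apply(pop$positions[w, , drop = FALSE], 1, fn)
      }
      if (min(value) < best_val) {
        bi <- which.min(value)
        best_val <- value[bi]
        pop$best <- pop$positions[bi, ]
      }
      history[it] <- best_val
    }
    list(par = pop$best, value = best_val, history = history)
  })
}
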