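# Uncertainty-driven sample selection around a binary classifier.

#' Prediction uncertainty of a probability
#'
#' Default measure is the binary entropy `-p log p - (1-p) log(1-p)`
#' (natural log), maximal at p = 0.5 and zero at 0 or 1; `"margin"` uses
#' `0.5 - |p - 0.5|` as a cheaper alternative with the same ordering.
#'
#' @param p Probabilities in [0, 1].
#' @param measure `"entropy"` (default) or `"margin"`.
#' @return Non-negative uncertainty scores.
#' @export
uncertainty <- function(p, measure = c("entropy", "margin")) {
  measure <- match.arg(measure)
  if (any(p < 0 | p > 1)) stop("uncertainty: p outside [0, 1]",
                               call. = FALSE)
  if (measure == "margin") return(0.5 - abs(p - 0.5))
  term <- function(q) ifelse(q <= 0, 0, -q * log(q))
  term(p) + term(1 - p)
}

#' Select the most uncertain pool samples
#'
#' Returns the indices of the `k` highest-uncertainty pool probabilities,
#' ties broken by ascending index, so selection is deterministic given the
#' scores.
#'
#' @param pool_probs Predicted probabilities for the unlabeled pool.
#' @param k Batch size (<= pool size).
#' @param measure Uncertainty measure id, see [uncertainty()].
#' @return Integer indices into `pool_probs`.
#' @export
select_batch <- function(pool_probs, k, measure = "entropy") {
  if (length(pool_probs) == 0L) stop("select_batch: empty pool",
                                     call. = FALSE)
  if (k > length(pool_probs))
    stop("select_batch: k exceeds pool size", call. = FALSE)
  u <- uncertainty(pool_probs, measure)
  order(-u, seq_along(u))[seq_len(k)]
}

#' Active-learning loop
#'
#' Starting from a small labeled seed set, repeatedly: train a model,
#' score the unlabeled pool, select the `k` most uncertain samples (or a
#' random batch under `strategy = "random"`), reveal their labels, and
#' retrain from scratch. Validation AUROC is recorded after every round.
#'
#' @param X Feature container indexable as `X[idx]` via the factory's
#'   convention: either an `N x T x n` array or a plain matrix.
#' @param y Full label vector (labels of pool samples are only read when
#'   revealed).
#' @param labeled,pool,validation Disjoint index sets.
#' @param factory Function `(X_subset, y_subset, seed)` returning an object
#'   with a working `predict(model, X_subset)` method giving probabilities.
#' @param rounds Number of acquisition rounds (>= 0).
#' @param k Samples revealed per round.
#' @param strategy `"entropy"`, `"margin"` or `"random"`.
#' @param seed Seed (controls retraining and random acquisition).
#' @return Data frame `round`, `labels_used`, `auroc` of class
#'   `al_curve`.
#' @export
al_loop <- function(X, y, labeled, pool, validation, factory,
                    rounds = 5L, k = 20L, strategy = "entropy",
                    seed = 1L) {
  stopifnot(length(intersect(labeled, pool)) == 0L,
            length(intersect(labeled, validation)) == 0L,
            length(intersect(pool, validation)) == 0L)
  if (rounds * k > length(pool))
    stop("al_loop: label budget exceeds pool size", call. = FALSE)
  take <- function(idx) {
    if (length(dim(X)) == 3L) X[idx, , , drop = FALSE]
    else X[idx, , drop = FALSE]
  }
  seeds <- split_seed(seed, rounds + 1L)
  curve <- data.frame(round = integer(0), labels_used = integer(0),
                      auroc = numeric(0))
  for (r in 0:rounds) {
    model <- factory(take(labeled), y[labeled], seeds[r + 1L])
    val_scores <- predict(model, take(validation))
    curve <- rbind(curve, data.frame(
      round = r, labels_used = length(labeled),
      auroc = metrics(val_scores, y[validation])$auroc))
    if (r == rounds || length(pool) == 0L) break
    kk <- min(k, length(pool))
    if (strategy == "random") {
      set.seed(seeds[r + 1L])
      pick <- sample(length(pool), kk)
    } else {
      pool_scores <- predict(model, take(pool))
      pick <- select_batch(pool_scores, kk, measure = strategy)
    }
    labeled <- c(labeled, pool[pick])
    pool <- pool[-pick]
  }
  class(curve) <- c("al_curve", class(curve))
  curve
}

#' Model factories for the active-learning loop
#'
#' `darnn_factory` wraps [darnn_train()] on sequence arrays;
#' `glm_factory` fits a logistic regression on flattened features (a cheap
#' reference learner).
#'
#' @param ... Configuration forwarded to [darnn_train()].
#' @return A factory function `(X, y, seed) -> model`.
#' @export
darnn_factory <- function(...) {
  args <- list(...)
  function(X, y, seed) {
    do.call(darnn_train, c(list(X = X, y = y, seed = seed), args))
  }
}

#' @rdname darnn_factory
#' @export
glm_factory <- function() {
  function(X, y, seed) {
    flat <- if (length(dim(X)) == 3L)
      matrix(X, dim(X)[1], prod(dim(X)[-1])) else X
    df <- as.data.frame(flat)
    fit <- suppressWarnings(
      stats::glm(y ~ ., data = cbind(y = y, df), family = "binomial"))
    structure(list(fit = fit), class = "glm_al_model")
  }
}

#' @export
predict.glm_al_model <- function(object, X, ...) {
  flat <- if (length(dim(X)) == 3L)
    matrix(X, dim(X)[1], prod(dim(X)[-1])) else X
  as.numeric(suppressWarnings(
    stats::predict(object$fit, newdata = as.data.frame(flat),
                   type = "response")))
}
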