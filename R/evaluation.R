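# Metrics, cross-validation and the ablation harness.

#' Classification metrics for scored samples
#'
#' AUROC is the rank statistic with 0.5 credit for ties; PR-AUC uses
#' step-wise (non-interpolated) integration of the precision-recall curve;
#' confusion metrics use the rule `score >= threshold`; MSE is the mean of
#' `(score - label)^2` and RMSE its square root.
#'
#' @param scores Numeric scores (probabilities or any monotone score).
#' @param labels Binary 0/1 labels; both classes must be present.
#' @param threshold Decision threshold for the confusion metrics.
#' @return List of class `metric_report`: `auroc`, `pr_auc`, `acc`, `bacc`,
#'   `prec`, `recall`, `f1`, `mse`, `rmse`.
#' @export
metrics <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L)
    stop("metrics: AUROC undefined with a single class", call. = FALSE)
  r <- rank(scores)                       # average ranks = 0.5 tie credit
  auroc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # Step-wise PR integration over the descending-score sweep.
  ord <- order(-scores)
  yl <- labels[ord]
  tp <- cumsum(yl)
  prec_curve <- tp / seq_along(yl)
  rec_curve <- tp / n1
  pr_auc <- sum(diff(c(0, rec_curve)) * prec_curve)
  pred <- as.integer(scores >= threshold)
  tp_ <- sum(pred == 1 & labels == 1); fp_ <- sum(pred == 1 & labels == 0)
  fn_ <- sum(pred == 0 & labels == 1); tn_ <- sum(pred == 0 & labels == 0)
  prec <- if (tp_ + fp_ > 0) tp_ / (tp_ + fp_) else 0
  recall <- tp_ / (tp_ + fn_)
  f1 <- if (prec + recall > 0) 2 * prec * recall / (prec + recall) else 0
  acc <- (tp_ + tn_) / length(labels)
  bacc <- (recall + tn_ / (tn_ + fp_)) / 2
  mse <- mean((scores - labels)^2)
  structure(list(auroc = auroc, pr_auc = pr_auc, acc = acc, bacc = bacc,
                 prec = prec, recall = recall, f1 = f1, mse = mse,
                 rmse = sqrt(mse)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("AUROC %.3f  PR-AUC %.3f  ACC %.3f  BACC %.3f  F1 %.3f\n",
              x$auroc, x$pr_auc, x$acc, x$bacc, x$f1))
  invisible(x)
}

#' Stratified k-fold cross-validation
#'
#' Shuffles within each class and deals samples to `k` disjoint folds whose
#' sizes differ by at most one and whose class proportions track the global
#' ones; optionally fits and scores a model per fold.
#'
#' @param x Feature container (matrix or `N x T x n` array).
#' @param y Binary labels.
#' @param k Number of folds (2 <= k <= n).
#' @param seed Seed controlling the shuffle.
#' @param train_fn Optional `(x_train, y_train)` returning a model.
#' @param predict_fn Optional `(model, x_test)` returning scores.
#' @return List with `folds` (fold id per sample) and, when a model is
#'   supplied, `per_fold` metric reports and `mean` metrics.
#' @export
kfold_cv <- function(x, y, k = 5L, seed = 1L, train_fn = NULL,
                     predict_fn = NULL) {
  n <- length(y)
  if (k > n) stop("kfold_cv: k exceeds the number of samples",
                  call. = FALSE)
  set.seed(split_seed(seed, 1L))
  folds <- integer(n)
  off <- 0L
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    # rotate the fold assignment across classes so total fold sizes differ
    # by at most one
    folds[idx] <- ((seq_along(idx) - 1L + off) %% k) + 1L
    off <- off + length(idx)
  }
  out <- list(folds = folds)
  if (!is.null(train_fn)) {
    take <- function(idx) {
      if (length(dim(x)) == 3L) x[idx, , , drop = FALSE]
      else x[idx, , drop = FALSE]
    }
    per <- lapply(seq_len(k), function(f) {
      tr <- which(folds != f); te <- which(folds == f)
      model <- train_fn(take(tr), y[tr])
      metrics(predict_fn(model, take(te)), y[te])
    })
    out$per_fold <- per
    nm <- names(per[[1]])
    out$mean <- lapply(stats::setNames(nm, nm), function(s)
      mean(vapply(per, `[[`, numeric(1), s)))
  }
  out
}

.ABLATION_COMPONENTS <- c("mfsyndcp", "ggi", "ctf", "lstm",
                          "active_learning", "bayes")

#' Run the prediction pipeline with components disabled
#'
#' Trains and evaluates the full pipeline on a synthetic benchmark with the
#' listed components replaced by their neutral stand-ins: zeroed feature
#' blocks for the encoders (`mfsyndcp` zeroes both drug blocks, `ggi`,
#' `ctf` and `bayes` their blocks -- the latter carrying the
#' report-derived beta-binomial evidence features), an identity
#' pass-through instead of the recurrent encoder for `lstm` (features
#' mean-pooled over the pseudo-time axis and fed to a linear head), and
#' random instead of uncertainty-driven subset selection for
#' `active_learning`.
#'
#' @param config Benchmark configuration from [benchmark_config()].
#' @param disable Character vector of component ids to disable.
#' @param bench Optional prebuilt benchmark (from [make_benchmark()]);
#'   built from `config` when missing.
#' @return One-row data.frame: `config` label plus the metric report.
#' @export
run_ablation <- function(config = benchmark_config(), disable = character(0),
                         bench = NULL) {
  bad <- setdiff(disable, .ABLATION_COMPONENTS)
  if (length(bad) > 0L)
    stop(sprintf("run_ablation: unknown component id(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  if (is.null(bench)) bench <- make_benchmark(config)
  X <- bench$X; y <- bench$y
  # Zero disabled feature blocks (rows of the T x n per-sample matrix).
  block_rows <- list(mfsyndcp = 1:2, ggi = 3L, ctf = 4L, bayes = 6L)
  for (comp in intersect(disable, names(block_rows)))
    X[, block_rows[[comp]], ] <- 0
  set.seed(split_seed(config$seed, 1L))
  n <- length(y)
  test <- unlist(lapply(split(seq_len(n), y), function(ix)
    sample(ix, max(1L, round(0.2 * length(ix))))))
  train <- setdiff(seq_len(n), test)
  # Training-subset selection: a random half of the budget seeds a probe
  # model; the other half is acquired over two uncertainty-sampling rounds
  # with the probe retrained in between. Disabling active learning
  # replaces the acquisition by a random draw of the same size.
  budget <- max(10L, round(config$label_budget * length(train)))
  pooled <- apply(X, c(1, 3), mean)
  init <- sample(train, max(5L, round(budget / 2)))
  rest <- setdiff(train, init)
  if ("active_learning" %in% disable) {
    sel <- c(init, sample(rest, budget - length(init)))
  } else {
    fit_probe <- function(idx, seed) {
      if ("lstm" %in% disable)
        glm_factory()(pooled[idx, , drop = FALSE], y[idx], seed)
      else
        darnn_train(X[idx, , , drop = FALSE], y[idx],
                    hidden = config$hidden, epochs = config$epochs,
                    batch_size = config$batch_size, lr = config$lr,
                    patience = config$patience, dropout = config$dropout,
                    seed = seed)
    }
    score_pool <- function(probe, idx) {
      if ("lstm" %in% disable) predict(probe, pooled[idx, , drop = FALSE])
      else predict(probe, X[idx, , , drop = FALSE])
    }
    sel <- init
    pseeds <- split_seed(config$seed, 4L)
    for (round_i in 1:2) {
      k <- min(ceiling((budget - length(init)) / 2), length(rest))
      if (k <= 0) break
      probe <- fit_probe(sel, pseeds[round_i + 1L])
      pick <- select_batch(score_pool(probe, rest), k)
      sel <- c(sel, rest[pick])
      rest <- rest[-pick]
    }
    sel <- sel[seq_len(min(budget, length(sel)))]
  }
  if (length(unique(y[sel])) < 2L) sel <- train[seq_len(budget)]
  if ("lstm" %in% disable) {
    # identity pass-through: no sequence modeling, linear head on the
    # time-averaged features
    model <- glm_factory()(pooled[sel, , drop = FALSE], y[sel],
                           config$seed)
    scores <- predict(model, pooled[test, , drop = FALSE])
  } else {
    ne <- config$n_ensemble %||% 1L
    eseeds <- split_seed(config$seed, ne + 3L)[-(1:3)]
    scores <- 0
    for (es in eseeds) {
      model <- darnn_train(X[sel, , , drop = FALSE], y[sel],
                           hidden = config$hidden, epochs = config$epochs,
                           batch_size = config$batch_size, lr = config$lr,
                           patience = config$patience,
                           dropout = config$dropout, seed = es)
      scores <- scores + predict(model, X[test, , , drop = FALSE]) / ne
    }
  }
  rep <- metrics(scores, y[test])
  label <- if (length(disable) == 0L) "full"
           else paste0("no_", paste(disable, collapse = "+"))
  cbind(data.frame(config = label, stringsAsFactors = FALSE),
        as.data.frame(rep[ ]))
}

#' Ablation table over single (and optionally pairwise) removals
#'
#' @param config Benchmark configuration, see [benchmark_config()].
#' @param components Component ids to ablate.
#' @param pairwise Also include all pairwise removals.
#' @param bench Optional prebuilt benchmark shared across rows.
#' @return Data frame, one row per configuration (full model first).
#' @export
ablation_table <- function(config = benchmark_config(),
                           components = .ABLATION_COMPONENTS,
                           pairwise = FALSE, bench = NULL) {
  if (is.null(bench)) bench <- make_benchmark(config)
  rows <- list(run_ablation(config, character(0), bench = bench))
  for (comp in components)
    rows[[length(rows) + 1L]] <- run_ablation(config, comp, bench = bench)
  if (pairwise) {
    cmb <- utils::combn(components, 2L)
    for (ci in seq_len(ncol(cmb)))
      rows[[length(rows) + 1L]] <-
        run_ablation(config, cmb[, ci], bench = bench)
  }
  do.call(rbind, rows)
}
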