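# Dual-stage attention recurrent predictor.
#
# Each sample is a short driving-series matrix: T pseudo-time steps (the
# ordered fused feature blocks) by n driving features. Stage one (input
# attention) reweights the n driving features at every step using the
# encoder LSTM's previous hidden and cell state; stage two (temporal
# attention) pools the encoder states into a context vector that a sigmoid
# head turns into an interaction probability. Forward, backward (full
# analytic backprop, checked against finite differences) and Adam training
# with early stopping are implemented in plain matrix code.

#' Initialize DA-RNN parameters
#'
#' @param n Number of driving features (columns of each sample).
#' @param T_steps Number of pseudo-time steps.
#' @param hidden Hidden dimension of the encoder LSTM (also used for the
#'   attention projections).
#' @param seed Initialization seed.
#' @return List of class `darnn_params`.
#' @export
darnn_params <- function(n, T_steps, hidden = 16L, seed = 1L) {
  stopifnot(n >= 1L, T_steps >= 1L, hidden >= 1L)
  set.seed(split_seed(seed, 1L))
  m <- hidden
  init <- function(r, c) matrix(rnorm(r * c, sd = sqrt(1 / max(c, 1))), r, c)
  structure(list(
    Wl = init(4 * m, n + m), bl = rep(0, 4 * m),
    We = init(m, 2 * m), Ue = init(m, T_steps), ve = rnorm(m, sd = 0.3),
    Wt = init(m, m), Ut = matrix(0, m, m), vt = rnorm(m, sd = 0.3),
    wo = rnorm(m, sd = sqrt(1 / m)), bo = 0,
    n = as.integer(n), T_steps = as.integer(T_steps), m = as.integer(m)),
    class = "darnn_params")
}

#' Input attention over driving features
#'
#' For driving series `x^k` (the k-th column of the T x n sample),
#' `e^k = ve' tanh(We [h_prev; s_prev] + Ue x^k)` and
#' `alpha = softmax(e)`; the weights sum to 1.
#'
#' @param x Driving-series matrix for one sample (T_steps x n).
#' @param h_prev,s_prev Previous encoder hidden and cell state (length m;
#'   zeros at the first step).
#' @param params A [darnn_params()].
#' @return Attention weights over the n driving features.
#' @export
input_attention <- function(x, h_prev, s_prev, params) {
  stopifnot(inherits(params, "darnn_params"))
  x <- rbind(x)
  if (ncol(x) < 1L) stop("input_attention: no driving features",
                         call. = FALSE)
  base <- drop(params$We %*% c(h_prev, s_prev))
  logits <- vapply(seq_len(ncol(x)), function(k)
    sum(params$ve * tanh(base + drop(params$Ue %*% x[, k]))), numeric(1))
  softmax(logits)
}

#' Temporal attention over encoder states
#'
#' `l_i = vt' tanh(Wt h_i + Ut d)` and `beta = softmax(l)`; the context is
#' `c = sum_i beta_i h_i`.
#'
#' @param H Encoder state matrix (m x T_steps), one column per step.
#' @param d Decoder state (length m; the classifier uses a single decoding
#'   step with d = 0).
#' @param params A [darnn_params()].
#' @return List with `beta` (sums to 1) and `context`.
#' @export
temporal_attention <- function(H, d, params) {
  stopifnot(inherits(params, "darnn_params"))
  H <- cbind(H)
  if (ncol(H) < 1L) stop("temporal_attention: empty state list",
                         call. = FALSE)
  logits <- vapply(seq_len(ncol(H)), function(i)
    sum(params$vt * tanh(drop(params$Wt %*% H[, i] + params$Ut %*% d))),
    numeric(1))
  beta <- softmax(logits)
  list(beta = beta, context = drop(H %*% beta))
}

# Batched forward pass. X: array (N, T, n). Returns probabilities and, when
# keep_cache, everything the backward pass needs.
.darnn_forward <- function(params, X, keep_cache = FALSE) {
  if (any(!is.finite(X))) stop("darnn: non-finite input", call. = FALSE)
  dims <- dim(X)
  N <- dims[1]; Tt <- dims[2]; n <- dims[3]
  m <- params$m
  stopifnot(Tt == params$T_steps, n == params$n)
  UeX <- lapply(seq_len(n), function(k)
    params$Ue %*% t(matrix(X[, , k], N, Tt)))        # each m x N
  h <- matrix(0, m, N); s <- matrix(0, m, N)
  cache <- if (keep_cache) vector("list", Tt) else NULL
  Hs <- vector("list", Tt)
  for (t in seq_len(Tt)) {
    z <- params$We %*% rbind(h, s)                   # m x N
    Tk <- array(0, dim = c(m, N, n))
    E <- matrix(0, N, n)
    for (k in seq_len(n)) {
      tk <- tanh(z + UeX[[k]])
      Tk[, , k] <- tk
      E[, k] <- colSums(params$ve * tk)
    }
    alpha <- softmax_rows(E)
    xt <- matrix(X[, t, ], N, n)
    xtld <- alpha * xt
    inp <- rbind(t(xtld), h)                         # (n+m) x N
    a <- params$Wl %*% inp + params$bl
    gi <- sigmoid(a[seq_len(m), , drop = FALSE])
    gf <- sigmoid(a[m + seq_len(m), , drop = FALSE])
    go <- sigmoid(a[2 * m + seq_len(m), , drop = FALSE])
    gg <- tanh(a[3 * m + seq_len(m), , drop = FALSE])
    s_new <- gf * s + gi * gg
    ts_new <- tanh(s_new)
    h_new <- go * ts_new
    if (keep_cache)
      cache[[t]] <- list(z = z, Tk = Tk, alpha = alpha, xt = xt,
                         inp = inp, gi = gi, gf = gf, go = go, gg = gg,
                         s_prev = s, h_prev = h, s = s_new, ts = ts_new)
    h <- h_new; s <- s_new
    Hs[[t]] <- h
  }
  # Temporal attention with a single decoding step, d = 0.
  Q <- vector("list", Tt)
  Lmat <- matrix(0, N, Tt)
  for (i in seq_len(Tt)) {
    q <- tanh(params$Wt %*% Hs[[i]])
    Q[[i]] <- q
    Lmat[, i] <- colSums(params$vt * q)
  }
  beta <- softmax_rows(Lmat)
  ctx <- matrix(0, m, N)
  for (i in seq_len(Tt)) ctx <- ctx + t(t(Hs[[i]]) * beta[, i])
  logit <- drop(crossprod(params$wo, ctx)) + params$bo
  p <- sigmoid(logit)
  out <- list(p = p, logit = logit)
  if (keep_cache) {
    out$cache <- cache; out$Hs <- Hs; out$Q <- Q; out$beta <- beta
    out$ctx <- ctx; out$UeX <- UeX; out$X <- X
  }
  out
}

#' DA-RNN forward pass
#'
#' Deterministic (evaluation-mode) forward pass mapping a batch of driving
#' series to interaction probabilities.
#'
#' @param params A [darnn_params()].
#' @param X Array `N x T_steps x n` (a single `T_steps x n` matrix is
#'   promoted to a batch of one).
#' @return Probabilities in (0, 1), one per sample.
#' @export
darnn_forward <- function(params, X) {
  if (is.matrix(X)) X <- array(X, dim = c(1L, nrow(X), ncol(X)))
  .darnn_forward(params, X)$p
}

# Mean binary cross-entropy and full analytic gradient.
.darnn_loss_grad <- function(params, X, y, weight_decay = 0) {
  fw <- .darnn_forward(params, X, keep_cache = TRUE)
  N <- dim(X)[1]; Tt <- params$T_steps; n <- params$n; m <- params$m
  p <- pmin(pmax(fw$p, 1e-12), 1 - 1e-12)
  loss <- -mean(y * log(p) + (1 - y) * log(1 - p))
  dlogit <- (fw$p - y) / N
  g <- list(Wl = 0 * params$Wl, bl = 0 * params$bl, We = 0 * params$We,
            Ue = 0 * params$Ue, ve = 0 * params$ve, Wt = 0 * params$Wt,
            Ut = 0 * params$Ut, vt = 0 * params$vt, wo = 0 * params$wo,
            bo = 0)
  g$wo <- drop(fw$ctx %*% dlogit)
  g$bo <- sum(dlogit)
  dctx <- outer(params$wo, dlogit)                   # m x N
  # Temporal attention backward.
  beta <- fw$beta
  dbeta <- matrix(0, N, Tt)
  dH <- lapply(seq_len(Tt), function(i) matrix(0, m, N))
  for (i in seq_len(Tt)) {
    dbeta[, i] <- colSums(fw$Hs[[i]] * dctx)
    dH[[i]] <- dH[[i]] + t(t(dctx) * beta[, i])
  }
  dL <- beta * (dbeta - rowSums(beta * dbeta))
  for (i in seq_len(Tt)) {
    q <- fw$Q[[i]]
    g$vt <- g$vt + drop(q %*% dL[, i])
    dpre <- (1 - q^2) * outer(params$vt, dL[, i])
    g$Wt <- g$Wt + dpre %*% t(fw$Hs[[i]])
    dH[[i]] <- dH[[i]] + crossprod(params$Wt, dpre)
  }
  # BPTT through encoder steps.
  dh_rec <- matrix(0, m, N)
  ds <- matrix(0, m, N)
  for (t in rev(seq_len(Tt))) {
    cc <- fw$cache[[t]]
    dh <- dH[[t]] + dh_rec
    do_ <- dh * cc$ts
    ds <- ds + dh * cc$go * (1 - cc$ts^2)
    di <- ds * cc$gg
    dgg <- ds * cc$gi
    df <- ds * cc$s_prev
    ds_prev <- ds * cc$gf
    da <- rbind(di * cc$gi * (1 - cc$gi),
                df * cc$gf * (1 - cc$gf),
                do_ * cc$go * (1 - cc$go),
                dgg * (1 - cc$gg^2))
    g$Wl <- g$Wl + da %*% t(cc$inp)
    g$bl <- g$bl + rowSums(da)
    dinp <- crossprod(params$Wl, da)
    dxtld <- t(dinp[seq_len(n), , drop = FALSE])     # N x n
    dh_prev <- dinp[n + seq_len(m), , drop = FALSE]
    # Input attention backward.
    dalpha <- dxtld * cc$xt
    alpha <- cc$alpha
    dE <- alpha * (dalpha - rowSums(alpha * dalpha))
    dz <- matrix(0, m, N)
    for (k in seq_len(n)) {
      tk <- matrix(cc$Tk[, , k], m, N)
      g$ve <- g$ve + drop(tk %*% dE[, k])
      dpre <- (1 - tk^2) * outer(params$ve, dE[, k])
      dz <- dz + dpre
      g$Ue <- g$Ue + dpre %*% matrix(fw$X[, , k], N, Tt)
    }
    g$We <- g$We + dz %*% t(rbind(cc$h_prev, cc$s_prev))
    dhs <- crossprod(params$We, dz)
    dh_rec <- dh_prev + dhs[seq_len(m), , drop = FALSE]
    ds <- ds_prev + dhs[m + seq_len(m), , drop = FALSE]
  }
  if (weight_decay > 0) {
    for (nm in c("Wl", "We", "Ue", "Wt", "wo")) {
      g[[nm]] <- g[[nm]] + weight_decay * params[[nm]]
      loss <- loss + weight_decay / 2 * sum(params[[nm]]^2)
    }
  }
  list(loss = loss, grad = g)
}

#' Named training presets
#'
#' `"darnn"` (default): lr 0.001 with cosine annealing, batch 256, patience
#' 10. `"mfsyndcp"`: lr 1e-4, weight decay 1e-5, batch 2048, patience 15,
#' up to 200 epochs. Both use dropout 0.3 on the context vector during
#' training and hidden dimension 256 unless overridden.
#'
#' @param preset Preset name.
#' @return List of training configuration values.
#' @export
darnn_preset <- function(preset = c("darnn", "mfsyndcp")) {
  preset <- match.arg(preset)
  if (preset == "darnn")
    list(lr = 0.001, batch_size = 256L, epochs = 100L, patience = 10L,
         hidden = 256L, dropout = 0.3, weight_decay = 0, cosine = TRUE)
  else
    list(lr = 1e-4, batch_size = 2048L, epochs = 200L, patience = 15L,
         hidden = 256L, dropout = 0.3, weight_decay = 1e-5, cosine = FALSE)
}

#' Train the DA-RNN
#'
#' Adam optimization of mean binary cross-entropy with early stopping on
#' validation loss; the best-validation parameters are returned. With a
#' fixed seed the run is fully reproducible.
#'
#' @param X Array `N x T_steps x n` of driving series.
#' @param y Binary labels.
#' @param hidden,lr,batch_size,epochs,patience,dropout,weight_decay,cosine
#'   Training configuration; any value left `NULL` comes from the preset.
#' @param preset Named preset, see [darnn_preset()].
#' @param val_frac Fraction held out for validation (stratified).
#' @param seed Seed for initialization, shuffling and the validation split.
#' @param verbose Print per-epoch losses.
#' @return List of class `darnn_model`: `params`, `history` (per-epoch
#'   train/validation loss), `config`.
#' @export
darnn_train <- function(X, y, hidden = NULL, lr = NULL, batch_size = NULL,
                        epochs = NULL, patience = NULL, dropout = NULL,
                        weight_decay = NULL, cosine = NULL,
                        preset = "darnn", val_frac = 0.2, seed = 1L,
                        verbose = FALSE) {
  if (length(y) == 0L || dim(X)[1] == 0L)
    stop("darnn_train: empty training set", call. = FALSE)
  cfg <- darnn_preset(preset)
  cfg$hidden <- hidden %||% cfg$hidden
  cfg$lr <- lr %||% cfg$lr
  cfg$batch_size <- batch_size %||% cfg$batch_size
  cfg$epochs <- epochs %||% cfg$epochs
  cfg$patience <- patience %||% cfg$patience
  cfg$dropout <- dropout %||% cfg$dropout
  cfg$weight_decay <- weight_decay %||% cfg$weight_decay
  cfg$cosine <- cosine %||% cfg$cosine
  N <- dim(X)[1]; Tt <- dim(X)[2]; n <- dim(X)[3]
  seeds <- split_seed(seed, 3L)
  set.seed(seeds[1])
  # Stratified validation split.
  idx1 <- which(y == 1); idx0 <- which(y == 0)
  val <- c(sample(idx1, max(1L, round(val_frac * length(idx1)))),
           sample(idx0, max(1L, round(val_frac * length(idx0)))))
  if (length(val) >= N) val <- sample(N, max(1L, round(val_frac * N)))
  tr <- setdiff(seq_len(N), val)
  params <- darnn_params(n, Tt, hidden = cfg$hidden, seed = seeds[2])
  pn <- c("Wl", "bl", "We", "Ue", "ve", "Wt", "vt", "wo", "bo")
  mom <- lapply(params[pn], function(p) 0 * p)
  vel <- lapply(params[pn], function(p) 0 * p)
  b1 <- 0.9; b2 <- 0.999; epsa <- 1e-8; step <- 0
  best <- list(loss = Inf, params = params, epoch = 0L)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))
  set.seed(seeds[3])
  Xtr <- X[tr, , , drop = FALSE]; ytr <- y[tr]
  Xval <- X[val, , , drop = FALSE]; yval <- y[val]
  bce <- function(p, y) {
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }
  bad <- 0L
  for (ep in seq_len(cfg$epochs)) {
    lr_ep <- if (cfg$cosine)
      cfg$lr * 0.5 * (1 + cos(pi * (ep - 1) / cfg$epochs)) else cfg$lr
    ord <- sample(length(ytr))
    nb <- ceiling(length(ytr) / cfg$batch_size)
    ep_loss <- 0
    for (bi in seq_len(nb)) {
      sel <- ord[((bi - 1) * cfg$batch_size + 1):
                 min(bi * cfg$batch_size, length(ytr))]
      Xb <- Xtr[sel, , , drop = FALSE]
      if (cfg$dropout > 0) {
        # Training-time dropout on the driving features (inverted scaling);
        # evaluation-mode forward stays deterministic.
        mask <- array(rbinom(length(Xb), 1L, 1 - cfg$dropout) /
                        (1 - cfg$dropout), dim = dim(Xb))
        Xb <- Xb * mask
      }
      lg <- .darnn_loss_grad(params, Xb, ytr[sel],
                             weight_decay = cfg$weight_decay)
      ep_loss <- ep_loss + lg$loss * length(sel)
      step <- step + 1
      for (nm in pn) {
        gr <- lg$grad[[nm]]
        mom[[nm]] <- b1 * mom[[nm]] + (1 - b1) * gr
        vel[[nm]] <- b2 * vel[[nm]] + (1 - b2) * gr^2
        mhat <- mom[[nm]] / (1 - b1^step)
        vhat <- vel[[nm]] / (1 - b2^step)
        params[[nm]] <- params[[nm]] - lr_ep * mhat / (sqrt(vhat) + epsa)
      }
    }
    vloss <- bce(.darnn_forward(params, Xval)$p, yval)
    hist <- rbind(hist, data.frame(epoch = ep,
                                   train_loss = ep_loss / length(ytr),
                                   val_loss = vloss))
    if (verbose)
      message(sprintf("epoch %d train %.4f val %.4f", ep,
                      ep_loss / length(ytr), vloss))
    if (vloss < best$loss - 1e-6) {
      best <- list(loss = vloss, params = params, epoch = ep)
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= cfg$patience) break
    }
  }
  structure(list(params = best$params, history = hist, config = cfg,
                 best_epoch = best$epoch),
            class = "darnn_model")
}

#' Predict interaction probabilities with a trained DA-RNN
#' @param object A `darnn_model`.
#' @param X Array `N x T_steps x n`.
#' @param ... Unused.
#' @return Probabilities in (0, 1).
#' @export
predict.darnn_model <- function(object, X, ...) {
  darnn_forward(object$params, X)
}
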