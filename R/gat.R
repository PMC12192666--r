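# Graph attention encoding of molecular graphs, granule decomposition with
# granule-granule interaction (GGI) scoring, feature fusion with pruning,
# and attention-based substructure importance.

#' Graph attention layer parameters
#'
#' Per-head weight matrix `W` (d_in x d_out) and attention vector `a`
#' (length 2*d_out), shared LeakyReLU negative slope, and the head
#' combination rule. Defaults follow the encoder configuration used
#' throughout the package: 2 stacked layers of 16 heads with dropout 0.3 and
#' edge dropout 0.1 at training time; the printed update averages heads, and
#' `head_combine = "concat"` is available as a switch.
#'
#' @param d_in,d_out Input/output feature dimensions per head.
#' @param K Number of attention heads (>= 1).
#' @param leaky_slope LeakyReLU negative slope in (0, 1).
#' @param head_combine `"mean"` or `"concat"`.
#' @param activation Nonlinearity applied to the aggregated output
#'   (`"elu"`, `"relu"`, or `"identity"`).
#' @param seed Seed for Glorot-style random initialization.
#' @return List of class `gat_params` with `W` and `a` as per-head lists.
#' @export
gat_params <- function(d_in, d_out, K = 16L, leaky_slope = 0.2,
                       head_combine = c("mean", "concat"),
                       activation = c("elu", "relu", "identity"),
                       seed = 1L) {
  stopifnot(K >= 1L, leaky_slope > 0, leaky_slope < 1)
  head_combine <- match.arg(head_combine)
  activation <- match.arg(activation)
  set.seed(split_seed(seed, 1L))
  sdw <- sqrt(2 / (d_in + d_out))
  W <- lapply(seq_len(K), function(k)
    matrix(rnorm(d_in * d_out, sd = sdw), d_in, d_out))
  a <- lapply(seq_len(K), function(k) rnorm(2 * d_out, sd = sdw))
  structure(list(W = W, a = a, K = as.integer(K),
                 leaky_slope = leaky_slope, head_combine = head_combine,
                 activation = activation, d_in = d_in, d_out = d_out),
            class = "gat_params")
}

.leaky_relu <- function(x, slope) ifelse(x >= 0, x, slope * x)

.gat_activation <- function(x, kind) {
  switch(kind,
         elu = ifelse(x >= 0, x, exp(x) - 1),
         relu = pmax(x, 0),
         identity = x)
}

#' Attention weights of one node over its neighbors (one head)
#'
#' Computes `alpha_ij = softmax_j(LeakyReLU(a' [W h_i || W h_j]))` over the
#' neighbor set. The weights are strictly positive and sum to 1.
#'
#' @param h_i Feature vector of the center node.
#' @param neighbors Matrix of neighbor feature vectors (one per row; at
#'   least one neighbor -- callers add a self-loop for isolated nodes).
#' @param params A [gat_params()].
#' @param head Head index in `1..K`.
#' @return Numeric vector of attention weights over the neighbor rows.
#' @export
gat_attention <- function(h_i, neighbors, params, head = 1L) {
  stopifnot(inherits(params, "gat_params"), head >= 1L, head <= params$K)
  neighbors <- rbind(neighbors)
  if (nrow(neighbors) < 1L)
    stop("gat_attention: at least one neighbor required", call. = FALSE)
  W <- params$W[[head]]; a <- params$a[[head]]
  wi <- drop(h_i %*% W)
  wj <- neighbors %*% W
  logits <- .leaky_relu(
    drop(wj %*% a[-(seq_along(wi))]) + sum(wi * a[seq_along(wi)]),
    params$leaky_slope)
  softmax(logits)
}

#' One graph attention layer over a whole graph
#'
#' Updates every node as the head-averaged (or concatenated) attention
#' aggregation `h_i' = sigma((1/K) sum_k sum_{j in N_i} alpha_ij^k W^k h_j)`.
#' Self-loops are added to every node so no neighborhood is empty.
#'
#' @param feats Node feature matrix (n x d_in).
#' @param adj Symmetric 0/1 adjacency matrix (n x n).
#' @param params A [gat_params()].
#' @return Updated node feature matrix (n x d_out, or n x K*d_out under
#'   `head_combine = "concat"`).
#' @export
gat_layer <- function(feats, adj, params) {
  stopifnot(inherits(params, "gat_params"))
  feats <- rbind(feats)
  n <- nrow(feats)
  if (ncol(feats) != params$d_in)
    stop_shape(sprintf("gat_layer: feature dim %d != d_in %d",
                       ncol(feats), params$d_in))
  if (!is.matrix(adj) || nrow(adj) != n || ncol(adj) != n)
    stop_shape("gat_layer: adjacency must be n x n")
  diag(adj) <- 1   # self-loops
  per_head <- lapply(seq_len(params$K), function(k) {
    out <- matrix(0, n, params$d_out)
    Wh <- feats %*% params$W[[k]]
    for (i in seq_len(n)) {
      nb <- which(adj[i, ] != 0)
      alpha <- gat_attention(feats[i, ], feats[nb, , drop = FALSE],
                             params, head = k)
      out[i, ] <- drop(alpha %*% Wh[nb, , drop = FALSE])
    }
    out
  })
  agg <- if (params$head_combine == "mean") {
    Reduce(`+`, per_head) / params$K
  } else {
    do.call(cbind, per_head)
  }
  .gat_activation(agg, params$activation)
}

#' Sum-pooled GAT embedding of a molecule
#'
#' Runs `n_layers` attention layers (the first maps atom features to
#' `d_out`, later layers are `d_out` to `d_out`) and sum-pools atoms.
#' Sum pooling keeps molecule size information in the embedding.
#'
#' @param g A `molecular_graph`.
#' @param params A [gat_params()] for the first layer (its `d_in` must match
#'   `ncol(atom_features(g))`).
#' @param n_layers Number of stacked layers (default 2).
#' @return Numeric embedding vector.
#' @export
gat_encode <- function(g, params, n_layers = 2L) {
  feats <- atom_features(g)
  n <- nrow(feats)
  adj <- matrix(0, n, n)
  if (nrow(g$bonds) > 0L) {
    adj[cbind(g$bonds$i, g$bonds$j)] <- 1
    adj[cbind(g$bonds$j, g$bonds$i)] <- 1
  }
  h <- gat_layer(feats, adj, params)
  if (n_layers > 1L) {
    d <- ncol(h)
    p2 <- gat_params(d, params$d_out, K = params$K,
                     leaky_slope = params$leaky_slope,
                     head_combine = params$head_combine,
                     activation = params$activation, seed = 7L)
    for (l in seq_len(n_layers - 1L)) h <- gat_layer(h, adj, p2)
  }
  colSums(rbind(h))
}

#' Decompose a molecule into granules
#'
#' Default scheme: every ring system (biconnected component with >= 3
#' atoms, merged when sharing atoms) is one granule, and each maximal
#' connected non-ring fragment left after removing ring atoms is one
#' granule. The `"singleton"` scheme makes each atom its own granule. Each
#' granule carries the mean of its atoms' feature rows.
#'
#' @param g A `molecular_graph`.
#' @param scheme `"rings"` (default) or `"singleton"`.
#' @return List of class `granule_set`: `granules` (list of atom index
#'   vectors), `features` (one pooled row per granule), `scheme`.
#' @export
granulate <- function(g, scheme = c("rings", "singleton")) {
  scheme <- match.arg(scheme)
  feats <- atom_features(g)
  n <- nrow(feats)
  if (scheme == "singleton" || nrow(g$bonds) == 0L) {
    members <- as.list(seq_len(n))
  } else {
    ig <- igraph::graph_from_edgelist(
      cbind(g$bonds$i, g$bonds$j), directed = FALSE)
    ig <- igraph::add_vertices(ig, max(0, n - igraph::vcount(ig)))
    bc <- igraph::biconnected_components(ig)
    ring_sets <- Filter(function(v) length(v) >= 3L,
                        lapply(bc$components, as.integer))
    # Merge ring systems sharing atoms (fused/spiro systems).
    merged <- list()
    for (rs in ring_sets) {
      hit <- which(vapply(merged, function(m) length(intersect(m, rs)) > 0,
                          logical(1)))
      if (length(hit) == 0L) merged[[length(merged) + 1L]] <- rs
      else {
        merged[[hit[1]]] <- sort(unique(c(unlist(merged[hit]), rs)))
        merged <- merged[-hit[-1]]
      }
    }
    ring_atoms <- sort(unique(unlist(merged)))
    rest <- setdiff(seq_len(n), ring_atoms)
    frag <- list()
    if (length(rest) > 0L) {
      sub <- igraph::induced_subgraph(ig, rest)
      comp <- igraph::components(sub)
      for (cid in seq_len(comp$no))
        frag[[cid]] <- sort(rest[comp$membership == cid])
    }
    members <- c(merged, frag)
    members <- members[order(vapply(members, min, integer(1)))]
  }
  pooled <- do.call(rbind, lapply(members, function(m)
    colMeans(feats[m, , drop = FALSE])))
  structure(list(granules = members, features = pooled, scheme = scheme,
                 id = g$id),
            class = "granule_set")
}

#' Granule-granule interaction parameters
#'
#' @param d Granule feature dimension.
#' @param d_out Output units of the bilinear-affine map (summed to the
#'   scalar score).
#' @param seed Seed for random initialization.
#' @return List of class `ggi_params` with `W1`, `W2` (d_out x d), `b`.
#' @export
ggi_params <- function(d, d_out = 4L, seed = 1L) {
  set.seed(split_seed(seed, 1L))
  sdw <- sqrt(1 / d)
  structure(list(W1 = matrix(rnorm(d_out * d, sd = sdw), d_out, d),
                 W2 = matrix(rnorm(d_out * d, sd = sdw), d_out, d),
                 b = rnorm(d_out, sd = sdw)),
            class = "ggi_params")
}

#' Interaction score of one granule pair
#'
#' `GGI(g_i, g_j) = sigmoid(W1 g_i + W2 g_j + b)`, reduced to a scalar by
#' averaging the output units, so the score lies in (0, 1).
#'
#' @param g_i,g_j Granule feature vectors.
#' @param params A [ggi_params()].
#' @return Scalar in (0, 1).
#' @export
ggi_score <- function(g_i, g_j, params) {
  stopifnot(inherits(params, "ggi_params"))
  if (length(g_i) != ncol(params$W1) || length(g_j) != ncol(params$W2))
    stop_shape("ggi_score: granule vector length does not match W1/W2")
  mean(sigmoid(drop(params$W1 %*% g_i + params$W2 %*% g_j + params$b)))
}

#' Total masked granule interaction score for a drug pair
#'
#' `Score = sum_i sum_j GGI(g_i, g_j) * M_ij`; the mask `M` defaults to all
#' ones (every granule pair valid).
#'
#' @param gsA,gsB `granule_set`s of the two drugs.
#' @param params A [ggi_params()].
#' @param M Optional 0/1 mask, `Ng(A) x Ng(B)`.
#' @return Scalar total score.
#' @export
ggi_total <- function(gsA, gsB, params, M = NULL) {
  stopifnot(inherits(gsA, "granule_set"), inherits(gsB, "granule_set"))
  na <- nrow(gsA$features); nb <- nrow(gsB$features)
  if (is.null(M)) M <- matrix(1, na, nb)
  if (!is.matrix(M) || nrow(M) != na || ncol(M) != nb)
    stop_shape(sprintf("ggi_total: mask must be %d x %d", na, nb))
  total <- 0
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    if (M[i, j] != 0)
      total <- total + ggi_score(gsA$features[i, ], gsB$features[j, ],
                                 params) * M[i, j]
  }
  total
}

#' Fusion MLP parameters with input pruning
#'
#' @param layer_sizes Integer vector of MLP layer widths, input first.
#' @param dropout Dropout rate in [0, 1) (training-time only; fusion here is
#'   deterministic inference).
#' @param prune_threshold Coordinates whose importance (mean absolute
#'   first-layer weight) falls below this are pruned from the input.
#' @param seed Seed for initialization.
#' @return List of class `fusion_params`.
#' @export
fusion_params <- function(layer_sizes, dropout = 0.3, prune_threshold = 0,
                          seed = 1L) {
  stopifnot(length(layer_sizes) >= 2L, all(layer_sizes > 0),
            dropout >= 0, dropout < 1)
  set.seed(split_seed(seed, 1L))
  Ws <- list(); bs <- list()
  for (l in seq_len(length(layer_sizes) - 1L)) {
    din <- layer_sizes[l]; dout <- layer_sizes[l + 1L]
    Ws[[l]] <- matrix(rnorm(dout * din, sd = sqrt(2 / (din + dout))),
                      dout, din)
    bs[[l]] <- rep(0, dout)
  }
  structure(list(W = Ws, b = bs, sizes = layer_sizes, dropout = dropout,
                 prune_threshold = prune_threshold),
            class = "fusion_params")
}

#' Fuse per-source feature blocks into one vector
#'
#' Concatenates the drug, GGI, tensor-factor, and cell-line blocks, prunes
#' input coordinates whose importance (mean absolute first-layer weight)
#' falls below the threshold, and passes the rest through the ReLU MLP.
#' Missing blocks may be zero-filled, but at least one must be present.
#'
#' @param drugA,drugB,ggi,ctf,cell Numeric vectors (any may be `NULL` when
#'   `zero_fill` is TRUE; `NULL` blocks are replaced by zeros of the length
#'   recorded in `layout`).
#' @param params A [fusion_params()] whose input size matches the total
#'   concatenated length.
#' @param zero_fill Allow missing blocks.
#' @param layout Named block lengths, required to zero-fill `NULL` blocks.
#' @return Fused numeric vector with attributes `layout` (block lengths) and
#'   `kept` (surviving input coordinates).
#' @export
fuse_features <- function(drugA, drugB, ggi, ctf, cell, params,
                          zero_fill = TRUE, layout = NULL) {
  blocks <- list(drugA = drugA, drugB = drugB, ggi = ggi, ctf = ctf,
                 cell = cell)
  if (all(vapply(blocks, is.null, logical(1))))
    stop("fuse_features: all component blocks missing", call. = FALSE)
  if (any(vapply(blocks, is.null, logical(1)))) {
    if (!zero_fill || is.null(layout))
      stop("fuse_features: missing blocks need zero_fill and a layout",
           call. = FALSE)
    for (nm in names(blocks))
      if (is.null(blocks[[nm]])) blocks[[nm]] <- rep(0, layout[[nm]])
  }
  x <- unlist(blocks, use.names = FALSE)
  stopifnot(inherits(params, "fusion_params"))
  if (length(x) != params$sizes[1])
    stop_shape(sprintf("fuse_features: input length %d != declared %d",
                       length(x), params$sizes[1]))
  importance <- colMeans(abs(params$W[[1]]))
  keep <- which(importance >= params$prune_threshold)
  if (length(keep) == 0L)
    stop("fuse_features: pruning threshold above maximal importance ",
         "would empty the input", call. = FALSE)
  h <- x
  h[-keep] <- 0   # pruned coordinates contribute nothing
  for (l in seq_along(params$W)) {
    h <- drop(params$W[[l]] %*% h + params$b[[l]])
    if (l < length(params$W)) h <- pmax(h, 0)
  }
  structure(h, layout = vapply(blocks, length, integer(1)), kept = keep)
}

# ---- attention-based substructure importance ------------------------------

#' Train a granule attention classifier
#'
#' A compact attention-pooling model over granule features: each granule g
#' gets a score `e_g = q' x_g`, attention `a = softmax(e)`, and the label
#' probability is `sigmoid(w' (sum_g a_g x_g) + b)`. Trained by full-batch
#' gradient descent on binary cross-entropy. The attention weights of a
#' trained model score the importance of each substructure.
#'
#' @param granule_sets List of `granule_set`s (one per molecule).
#' @param labels Binary labels per molecule.
#' @param epochs,lr Training schedule.
#' @param seed Seed for initialization.
#' @return Object of class `granule_attention_model`.
#' @export
train_granule_attention <- function(granule_sets, labels, epochs = 300L,
                                    lr = 0.1, seed = 1L) {
  stopifnot(length(granule_sets) == length(labels))
  d <- ncol(granule_sets[[1]]$features)
  set.seed(split_seed(seed, 1L))
  q <- rnorm(d, sd = 0.1); w <- rnorm(d, sd = 0.1); b <- 0
  y <- as.numeric(labels)
  for (ep in seq_len(epochs)) {
    gq <- rep(0, d); gw <- rep(0, d); gb <- 0
    for (s in seq_along(granule_sets)) {
      Xg <- granule_sets[[s]]$features
      a <- softmax(drop(Xg %*% q))
      ctx <- drop(a %*% Xg)
      p <- sigmoid(sum(w * ctx) + b)
      dlogit <- p - y[s]
      gw <- gw + dlogit * ctx
      gb <- gb + dlogit
      dctx <- dlogit * w
      da <- drop(Xg %*% dctx)
      de <- a * (da - sum(a * da))
      gq <- gq + drop(de %*% Xg)
    }
    n <- length(granule_sets)
    q <- q - lr * gq / n; w <- w - lr * gw / n; b <- b - lr * gb / n
  }
  structure(list(q = q, w = w, b = b, trained = TRUE),
            class = "granule_attention_model")
}

#' Per-granule (and per-atom) importance scores of a trained model
#'
#' Returns the trained attention distribution over the molecule's granules
#' (non-negative, summing to 1) and the same mass spread uniformly over each
#' granule's atoms.
#'
#' @param model A trained `granule_attention_model`.
#' @param g Either a `molecular_graph` or a `granule_set`.
#' @param scheme Granulation scheme when `g` is a graph.
#' @return List with `granule_scores`, `atom_scores` (both sum to 1), and
#'   `granules`.
#' @export
attention_importance <- function(model, g, scheme = "rings") {
  if (!inherits(model, "granule_attention_model") || !isTRUE(model$trained))
    stop("attention_importance: model is not a trained granule attention ",
         "model", call. = FALSE)
  gs <- if (inherits(g, "granule_set")) g else granulate(g, scheme)
  a <- softmax(drop(gs$features %*% model$q))
  n_atoms <- max(unlist(gs$granules))
  atom <- rep(0, n_atoms)
  for (k in seq_along(gs$granules)) {
    m <- gs$granules[[k]]
    atom[m] <- atom[m] + a[k] / length(m)
  }
  list(granule_scores = a, atom_scores = atom, granules = gs$granules)
}

#' Predict with a granule attention classifier
#' @param object A `granule_attention_model`.
#' @param granule_sets List of `granule_set`s.
#' @param ... Unused.
#' @return Probabilities in (0, 1).
#' @export
predict.granule_attention_model <- function(object, granule_sets, ...) {
  vapply(granule_sets, function(gs) {
    a <- softmax(drop(gs$features %*% object$q))
    sigmoid(sum(object$w * drop(a %*% gs$features)) + object$b)
  }, numeric(1))
}
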