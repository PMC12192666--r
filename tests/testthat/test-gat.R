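test_that("attention over neighbors is a proper distribution", {
  p <- gat_params(3, 2, K = 2, seed = 1)
  # single neighbor -> weight 1
  a1 <- gat_attention(c(1, 0, 1), matrix(c(0, 1, 0), 1), p, head = 1)
  expect_equal(a1, 1)
  # identical neighbors -> uniform
  nb <- matrix(rep(c(0.5, -1, 2), 4), 4, byrow = TRUE)
  a4 <- gat_attention(c(1, 2, 3), nb, p, head = 2)
  expect_equal(a4, rep(0.25, 4))
  expect_equal(sum(a4), 1)
})

test_that("1-d attention matches the hand-evaluated LeakyReLU softmax", {
  # W = 1, a = (1, 1), slope 0.2, h_i = 1, neighbors {1, -3}:
  # logits LeakyReLU(1 + 1) = 2 and LeakyReLU(1 - 3) = -0.4
  p <- gat_params(1, 1, K = 1, leaky_slope = 0.2, seed = 1)
  p$W[[1]] <- matrix(1, 1, 1)
  p$a[[1]] <- c(1, 1)
  a <- gat_attention(1, matrix(c(1, -3), 2), p, head = 1)
  expect_equal(a, exp(c(2, -0.4)) / sum(exp(c(2, -0.4))))
})

test_that("attention is permutation-equivariant in the neighbor order", {
  set.seed(5)
  p <- gat_params(4, 3, K = 2, seed = 2)
  nb <- matrix(rnorm(20), 5, 4)
  h <- rnorm(4)
  a <- gat_attention(h, nb, p, head = 1)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(gat_attention(h, nb[perm, ], p, head = 1), a[perm])
})

test_that("a GAT layer reduces to identity and zero in degenerate cases", {
  # K = 1, identity W, single node with self-loop, identity activation
  p <- gat_params(2, 2, K = 1, activation = "identity", seed = 1)
  p$W[[1]] <- diag(2)
  h <- matrix(c(1.5, -2), 1)
  expect_equal(gat_layer(h, matrix(0, 1, 1), p), h,
               ignore_attr = TRUE)
  # zero weights -> activation(0) everywhere
  p$W[[1]] <- matrix(0, 2, 2)
  out <- gat_layer(matrix(rnorm(6), 3), matrix(1, 3, 3), p)
  expect_equal(out, matrix(0, 3, 2))
})

test_that("a GAT layer equals a naive double-loop evaluation", {
  leaky <- function(x, s) ifelse(x >= 0, x, s * x)
  set.seed(11)
  n <- 3; din <- 3; dout <- 2
  feats <- matrix(rnorm(n * din), n)
  adj <- matrix(0, n, n); adj[1, 2] <- adj[2, 1] <- 1
  adj[2, 3] <- adj[3, 2] <- 1                     # path graph 1-2-3
  p <- gat_params(din, dout, K = 2, activation = "identity", seed = 4)
  got <- gat_layer(feats, adj, p)
  adj2 <- adj; diag(adj2) <- 1
  expected <- matrix(0, n, dout)
  for (k in 1:2) {
    W <- p$W[[k]]; a <- p$a[[k]]
    for (i in 1:n) {
      nbrs <- which(adj2[i, ] != 0)
      logits <- sapply(nbrs, function(j)
        leaky(sum(a * c(feats[i, ] %*% W, feats[j, ] %*% W)),
              p$leaky_slope))
      al <- exp(logits - max(logits)); al <- al / sum(al)
      for (jj in seq_along(nbrs))
        expected[i, ] <- expected[i, ] +
          al[jj] * drop(feats[nbrs[jj], ] %*% W) / 2
    }
  }
  expect_equal(got, expected, tolerance = 1e-10)
})

test_that("granulation covers molecules with disjoint granules", {
  g1 <- granulate(parse_smiles("C"))
  expect_equal(length(g1$granules), 1L)
  gb <- granulate(parse_smiles("c1ccccc1"))
  expect_equal(length(gb$granules), 1L)          # one ring system
  expect_equal(sort(gb$granules[[1]]), 1:6)

  # aspirin: independent ring-perception + flood-fill oracle
  asp <- parse_smiles("CC(=O)OC1=CC=CC=C1C(=O)O")
  gs <- granulate(asp)
  ig <- igraph::graph_from_edgelist(cbind(asp$bonds$i, asp$bonds$j),
                                    directed = FALSE)
  ring_atoms <- sort(unique(unlist(Filter(
    function(v) length(v) >= 3,
    lapply(igraph::biconnected_components(ig)$components, as.integer)))))
  rest <- setdiff(seq_len(nrow(asp$atoms)), ring_atoms)
  sub <- igraph::induced_subgraph(ig, rest)
  n_oracle <- 1L + igraph::components(sub)$no     # 1 ring system + frags
  expect_equal(length(gs$granules), n_oracle)
  # granules partition the atom set
  expect_equal(sort(unlist(gs$granules)), seq_len(nrow(asp$atoms)))

  # singleton fallback
  gsing <- granulate(asp, scheme = "singleton")
  expect_equal(length(gsing$granules), 13L)
})

test_that("GGI scores follow the affine-sigmoid form", {
  p <- ggi_params(3, d_out = 4, seed = 1)
  p0 <- p; p0$W1[] <- 0; p0$W2[] <- 0; p0$b[] <- 0
  expect_equal(ggi_score(c(1, 2, 3), c(0, 0, 1), p0), 0.5)
  psat <- p0; psat$b[] <- 50
  expect_equal(ggi_score(c(1, 2, 3), c(0, 0, 1), psat), 1, tolerance = 1e-12)
  # 2-d hand evaluation with d_out = 1
  ph <- ggi_params(2, d_out = 1, seed = 1)
  ph$W1 <- matrix(c(1, -1), 1); ph$W2 <- matrix(c(0.5, 2), 1); ph$b <- 0.3
  gi <- c(0.2, 0.4); gj <- c(1, -0.5)
  expect_equal(ggi_score(gi, gj, ph),
               1 / (1 + exp(-(0.2 - 0.4 + 0.5 - 1 + 0.3))))
  expect_error(ggi_score(c(1, 2), c(0, 0, 1), p), "match")
})

test_that("total granule interaction equals the masked double sum", {
  mols <- c("CC1CCCC1CO", "c1ccccc1C(=O)O")
  gsA <- granulate(parse_smiles(mols[1]))
  gsB <- granulate(parse_smiles(mols[2]))
  p <- ggi_params(ncol(gsA$features), d_out = 2, seed = 3)
  na_ <- length(gsA$granules); nb_ <- length(gsB$granules)
  # M = 0 -> 0
  expect_equal(ggi_total(gsA, gsB, p, M = matrix(0, na_, nb_)), 0)
  # zero parameters, all-ones mask -> 0.5 per granule pair
  p0 <- p; p0$W1[] <- 0; p0$W2[] <- 0; p0$b[] <- 0
  expect_equal(ggi_total(gsA, gsB, p0), 0.5 * na_ * nb_)
  # explicit double loop oracle with a random mask
  set.seed(2)
  M <- matrix(rbinom(na_ * nb_, 1, 0.6), na_, nb_)
  want <- 0
  for (i in seq_len(na_)) for (j in seq_len(nb_))
    want <- want + M[i, j] * ggi_score(gsA$features[i, ],
                                       gsB$features[j, ], p)
  expect_equal(ggi_total(gsA, gsB, p, M = M), want)
  # linear in the mask
  expect_equal(ggi_total(gsA, gsB, p, M = 2 * M),
               2 * ggi_total(gsA, gsB, p, M = M))
  expect_error(ggi_total(gsA, gsB, p, M = matrix(1, na_ + 1, nb_)), "mask")
})

test_that("feature fusion prunes by first-layer importance", {
  fp <- fusion_params(c(12, 6, 4), prune_threshold = 0, seed = 1)
  blocks <- list(drugA = rnorm(3), drugB = rnorm(3), ggi = rnorm(2),
                 ctf = rnorm(2), cell = rnorm(2))
  fused <- do.call(fuse_features, c(blocks, list(params = fp)))
  expect_length(fused, 4L)
  expect_length(attr(fused, "kept"), 12L)   # threshold 0 keeps everything
  expect_equal(unname(attr(fused, "layout")),
               c(3L, 3L, 2L, 2L, 2L))
  # threshold above the maximal importance is a degenerate guard
  fbad <- fusion_params(c(12, 6, 4), prune_threshold = 1e6, seed = 1)
  expect_error(do.call(fuse_features, c(blocks, list(params = fbad))),
               "empty")
  # all blocks missing
  expect_error(fuse_features(NULL, NULL, NULL, NULL, NULL, fp), "missing")
  # zero-fill reproduces explicit zero blocks
  lay <- c(drugA = 3L, drugB = 3L, ggi = 2L, ctf = 2L, cell = 2L)
  f1 <- fuse_features(blocks$drugA, blocks$drugB, NULL, blocks$ctf,
                      blocks$cell, fp, layout = lay)
  f2 <- fuse_features(blocks$drugA, blocks$drugB, c(0, 0), blocks$ctf,
                      blocks$cell, fp)
  expect_equal(as.numeric(f1), as.numeric(f2))
})

test_that("attention importance is normalized and recovers planted rules", {
  mols <- gen_molecules(40, seed = 6)
  gsets <- lapply(mols$smiles, function(s) granulate(parse_smiles(s)))
  # importance over a single-granule molecule is 1
  single <- granulate(parse_smiles("CCC"))
  m0 <- train_granule_attention(gsets[1:10], rep(0:1, 5), epochs = 5)
  expect_equal(attention_importance(m0, single)$granule_scores, 1)
  expect_error(attention_importance(list(trained = FALSE), single),
               "trained")

  # planted rule: the label is carried by the aromatic-ring granule
  hits <- 0L; tries <- 0L
  for (sd in 1:5) {
    ms <- gen_molecules(60, seed = sd)
    graphs <- lapply(ms$smiles, parse_smiles)
    gs <- lapply(graphs, granulate)
    has_arom <- vapply(graphs, function(g) any(g$atoms$aromatic),
                       logical(1))
    keep <- which(vapply(gs, function(g) length(g$granules), integer(1)) > 1)
    model <- train_granule_attention(gs[keep], as.numeric(has_arom[keep]),
                                     epochs = 200, lr = 0.3, seed = sd)
    for (i in keep) {
      if (!has_arom[i]) next
      imp <- attention_importance(model, gs[[i]])
      expect_equal(sum(imp$granule_scores), 1, tolerance = 1e-10)
      arom_granules <- which(vapply(gs[[i]]$granules, function(g)
        any(graphs[[i]]$atoms$aromatic[g]), logical(1)))
      tries <- tries + 1L
      if (which.max(imp$granule_scores) %in% arom_granules)
        hits <- hits + 1L
    }
  }
  expect_gt(hits / tries, 0.8)
})
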