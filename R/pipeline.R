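# Benchmark assembly: turns the synthetic generators into the sequence
# inputs the predictor consumes.
#
# Each (drugA, drugB, cell) triplet becomes a T = 6 x n = 10 driving-series
# matrix whose ordered pseudo-time steps are the fused feature blocks:
# drugA encoding | drugB encoding | granule interaction | tensor factors |
# cell line | report-derived signal. The last block carries the
# beta-binomial evidence (log Bayes factor, posterior mean, excess rate)
# computed from a report corpus tied to the benchmark's high-propensity
# pairs, mirroring how stratified adverse-event rates feed the predictor
# as drug-pair features.

#' Benchmark configuration
#'
#' Defaults define the packaged synthetic prediction task: 16 molecules
#' crossed into 120 unordered pairs over 16 cell lines (1,920 triplets), a
#' 10,000-report corpus for the calibration feature, and a compact
#' training configuration sized for CPU runs.
#'
#' @param seed Master seed.
#' @param n_mol,n_cells,n_reports Benchmark sizes.
#' @param hidden,epochs,batch_size,patience,dropout,lr [darnn_train()]
#'   settings.
#' @param label_budget Fraction of the training split revealed for training
#'   (the active-learning component selects which samples).
#' @param n_ensemble Number of training replicates averaged per evaluated
#'   configuration (reduces optimization variance).
#' @param risk_ratio Injected risk ratio of the tied report corpus.
#' @return List of class `benchmark_config`.
#' @export
benchmark_config <- function(seed = 1L, n_mol = 16L, n_cells = 16L,
                             n_reports = 30000L, hidden = 32L,
                             epochs = 60L, batch_size = 64L, patience = 12L,
                             dropout = 0.1, lr = 0.002, label_budget = 0.6,
                             n_ensemble = 2L, risk_ratio = 4) {
  structure(as.list(environment()), class = "benchmark_config")
}

#' Block-summary interaction features of a sequence array
#'
#' Flattens each sample's feature blocks into their per-block means plus
#' all pairwise products of those means, giving a compact design matrix on
#' which linear models can represent block-by-block interactions (for
#' instance structure-by-cell-context synergy). Used as the feature map
#' for cheap reference learners in label-efficiency experiments.
#'
#' @param X Sequence array `N x T x n`.
#' @return Matrix with `T + choose(T, 2)` columns.
#' @export
interaction_features <- function(X) {
  bm <- apply(X, c(1, 2), mean)
  Tt <- ncol(bm)
  inter <- NULL
  for (i in seq_len(Tt - 1)) for (j in (i + 1):Tt)
    inter <- cbind(inter, bm[, i] * bm[, j])
  cbind(bm, inter)
}

.zscore_cols <- function(M) {
  mu <- colMeans(M)
  sdv <- apply(M, 2, stats::sd)
  sdv[sdv < 1e-9] <- 1
  sweep(sweep(M, 2, mu), 2, sdv, "/")
}

#' Assemble the synthetic prediction benchmark
#'
#' Generates molecules, labeled triplets, encoder features, tensor-factor
#' embeddings and a tied report corpus, and packs everything into the
#' `N x 5 x 10` sequence array the predictor consumes. All feature columns
#' are z-scored across the dataset.
#'
#' @param config A [benchmark_config()].
#' @return List: `X` (N x 6 x 10 array), `y` (labels), `triplets`,
#'   `pair_id` (per-sample pair key), `bayes_z` (per-sample standardized
#'   log-Bayes-factor of the pair), `molecules`, `signals` (the pair-AE
#'   signal table), `truth` (report-corpus ground truth).
#' @export
make_benchmark <- function(config = benchmark_config()) {
  stopifnot(inherits(config, "benchmark_config"))
  seeds <- split_seed(config$seed, 6L)
  mols <- gen_molecules(config$n_mol, seed = seeds[1])
  tri <- gen_triplets(mols, n_cells = config$n_cells, rule = "synergy",
                      seed = seeds[2])
  graphs <- lapply(seq_len(nrow(mols)), function(i)
    parse_smiles(mols$smiles[i], id = mols$id[i]))
  afeat_dim <- ncol(atom_features(graphs[[1]]))

  # Drug blocks: sum-pooled 2-layer GAT embeddings plus per-drug size and
  # hydrogen-bonding descriptors. Bond counts are deliberately left out so
  # ring complexity stays the granule block's view and the blocks remain
  # complementary.
  gp <- gat_params(afeat_dim, 6L, K = 4L, seed = 11L)
  emb <- t(vapply(graphs, function(g) gat_encode(g, gp, n_layers = 2L),
                  numeric(6L)))
  desc <- tri$descriptors
  drug_block <- cbind(.zscore_cols(cbind(emb, desc$heavy_atoms, desc$hbd,
                                         desc$hba)),
                      matrix(0, nrow(emb), 1L))

  # Granule interaction block per pair: masked interaction totals plus
  # granule composition summaries (ring vs fragment granules, granule
  # sizes) of the pair.
  gsets <- lapply(graphs, granulate)
  ggp <- ggi_params(afeat_dim, d_out = 4L, seed = 12L)
  pairs <- .all_pairs(nrow(mols))
  # Coarse composition summaries only -- granule and ring counts, not the
  # exact atom tally -- so this block is a complementary noisy view of
  # molecular size rather than a clean copy of it.
  gstats <- t(vapply(gsets, function(gs) {
    sizes <- lengths(gs$granules)
    rings <- sum(sizes >= 3)
    c(n = length(gs$granules), rings = rings,
      frags = length(gs$granules) - rings)
  }, numeric(3L)))
  ggi_block <- t(vapply(seq_len(nrow(pairs)), function(r) {
    a <- pairs[r, 1]; b <- pairs[r, 2]
    tot <- ggi_total(gsets[[a]], gsets[[b]], ggp)
    sa <- gstats[a, ]; sb <- gstats[b, ]
    c(tot, sa["n"] + sb["n"], abs(sa["n"] - sb["n"]),
      sa["rings"] + sb["rings"], sa["frags"] + sb["frags"], rep(0, 5))
  }, numeric(10L)))
  ggi_block[, 1:5] <- .zscore_cols(ggi_block[, 1:5, drop = FALSE])

  # Tensor-factor block: CP embeddings of a 3-view similarity tensor.
  set.seed(seeds[3])
  afsum <- t(vapply(graphs, function(g) colSums(atom_features(g)),
                    numeric(afeat_dim)))
  dmat <- as.matrix(desc[, c("mol_weight", "heavy_atoms", "bonds",
                             "hbd", "hba")])
  profile <- scale(dmat) %*% matrix(rnorm(5 * 6), 5, 6) +
    matrix(rnorm(nrow(dmat) * 6, sd = 0.3), nrow(dmat), 6)
  chi <- similarity_tensor(list(structural = scale(dmat),
                                fingerprint = afsum,
                                profile = profile))
  cf <- ctf_fit(chi, rank = min(6L, config$n_mol), lambda1 = 0.01,
                lambda2 = 0.01, max_iter = 150L, seed = seeds[4])
  U <- drug_ctf_embedding(cf)
  ctf_pair <- t(vapply(seq_len(nrow(pairs)), function(r) {
    u <- U[pairs[r, 1], ] + U[pairs[r, 2], ]
    c(u, rep(0, 10L - length(u)))
  }, numeric(10L)))
  nz <- which(colSums(abs(ctf_pair)) > 0)
  ctf_pair[, nz] <- .zscore_cols(ctf_pair[, nz, drop = FALSE])

  # Cell block: the latent context factor plus gene-expression coordinates.
  cell_block <- .zscore_cols(cbind(attr(tri$cells, "latent"),
                                   tri$cells[, 1:9, drop = FALSE]))

  # Tied report corpus: pairs whose label propensity across cells is high
  # are the injected interacting pairs.
  tt <- tri$triplets
  pair_key <- paste(tt$drugA, tt$drugB)
  all_key <- paste(mols$id[pairs[, 1]], mols$id[pairs[, 2]])
  q_pair <- tapply(tt$label, factor(pair_key, levels = all_key), mean)
  flagged <- pairs[which(q_pair >= 0.5), , drop = FALSE]
  rc <- sim_report_config(n_drugs = config$n_mol,
                          n_reports = config$n_reports,
                          risk_ratio = config$risk_ratio, seed = seeds[5])
  rep_out <- gen_reports(rc, flagged_pairs = flagged)
  sig <- signal_table(rep_out$reports, drugs = rep_out$truth$drugs,
                      aes = rep_out$truth$aes)
  # Per-pair evidence summaries across AEs. Report drugs are indexed D01..
  # in pair order; map back to molecule-pair keys.
  sig$pair <- paste(sig$drugA, sig$drugB)
  pair_summary <- function(v, f) {
    s <- tapply(v, sig$pair, function(x) {
      x <- x[is.finite(x)]
      if (length(x) == 0L) NA_real_ else f(x)
    })
    names(s) <- all_key[match(names(s),
                              paste(rep_out$truth$drugs[pairs[, 1]],
                                    rep_out$truth$drugs[pairs[, 2]]))]
    s <- s[all_key]
    s[!is.finite(s)] <- mean(s[is.finite(s)])
    s
  }
  logbf <- pair_summary(log(sig$bf), max)
  pmax_ <- pair_summary(sig$posterior_mean, max)
  dadd <- pair_summary(sig$delta_add, max)
  bayes_block <- .zscore_cols(cbind(logbf, pmax_, dadd))
  bayes_block <- cbind(bayes_block, matrix(0, nrow(bayes_block), 7L))
  z_pair <- (logbf - mean(logbf)) / max(stats::sd(logbf), 1e-9)

  # Pack the sequence array.
  n_samp <- nrow(tt)
  ai <- match(tt$drugA, mols$id)
  bi <- match(tt$drugB, mols$id)
  pi_ <- match(pair_key, all_key)
  ci <- match(tt$cell, rownames(tri$cells))
  X <- array(0, dim = c(n_samp, 6L, 10L))
  X[, 1, ] <- drug_block[ai, ]
  X[, 2, ] <- drug_block[bi, ]
  X[, 3, ] <- ggi_block[pi_, ]
  X[, 4, ] <- ctf_pair[pi_, ]
  X[, 5, ] <- cell_block[ci, ]
  X[, 6, ] <- bayes_block[pi_, ]
  list(X = X, y = tt$label, triplets = tt, pair_id = pair_key,
       bayes_z = as.numeric(z_pair[pair_key]), molecules = mols,
       signals = sig, truth = rep_out$truth)
}
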