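test_that("report generator validates its configuration", {
  expect_error(sim_report_config(n_drugs = 0), "positive")
  expect_error(sim_report_config(risk_ratio = 0.5), "risk_ratio")
  expect_error(sim_report_config(p_combo = 1.2), "\\[0, 1\\]")
  expect_error(beta_params(0, 1), "positive")
})

test_that("identical seeds give byte-identical report tables", {
  cfg <- sim_report_config(n_drugs = 8, n_reports = 1500, seed = 42)
  r1 <- gen_reports(cfg)
  r2 <- gen_reports(cfg)
  expect_identical(r1$reports, r2$reports)
  expect_identical(r1$truth$interacting, r2$truth$interacting)
  r3 <- gen_reports(sim_report_config(n_drugs = 8, n_reports = 1500,
                                      seed = 43))
  expect_false(identical(r1$reports, r3$reports))
})

test_that("null pairs hit the independence baseline p1+p2-p1*p2", {
  cfg <- sim_report_config(n_drugs = 4, n_reports = 40000,
                           frac_interacting = 0, seed = 7)
  out <- gen_reports(cfg)
  rates <- out$truth$baseline_rates
  sig <- signal_table(out$reports, drugs = out$truth$drugs,
                      aes = out$truth$aes)
  checked <- 0L
  for (r in seq_len(nrow(sig))) {
    if (sig$n_combo[r] < 200) next
    p1 <- rates[sig$drugA[r], sig$ae[r]]
    p2 <- rates[sig$drugB[r], sig$ae[r]]
    e <- p1 + p2 - p1 * p2
    se <- sqrt(e * (1 - e) / sig$n_combo[r])
    expect_lt(abs(sig$d_combo[r] / sig$n_combo[r] - e), 3.5 * se)
    checked <- checked + 1L
  }
  expect_gt(checked, 20L)
})

test_that("stratified counts of a flagged pair recover the risk ratio", {
  # inject the signal into the best-exposed pair so the empirical rate
  # ratio is estimable from 5,000 reports
  cfg <- sim_report_config(n_drugs = 20, n_reports = 5000,
                           frac_interacting = 0.1, risk_ratio = 3,
                           seed = 7)
  rr_hat <- sapply(c(7, 8, 9), function(sd) {
    cfg$seed <- sd
    out <- gen_reports(cfg, flagged_pairs = cbind(1L, 2L))
    tr <- out$truth$interacting[1, ]
    cnt <- recount_oracle(out$reports, tr$drugA, tr$drugB, tr$ae)
    expect_gt(unname(cnt["n_combo"]), 60)
    # package stratification agrees with the independent recount
    s <- stratify(out$reports, tr$drugA, tr$drugB, tr$ae)
    expect_equal(s$d_combo, unname(cnt["d_combo"]))
    expect_equal(s$n_combo, unname(cnt["n_combo"]))
    p1 <- out$truth$baseline_rates[tr$drugA, tr$ae]
    p2 <- out$truth$baseline_rates[tr$drugB, tr$ae]
    (cnt["d_combo"] / cnt["n_combo"]) / (p1 + p2 - p1 * p2)
  })
  expect_lt(abs(mean(rr_hat) - 3), 0.75)
})

test_that("risk-ratio estimation error shrinks as the corpus grows", {
  sizes <- c(4000L, 16000L, 64000L)
  err <- sapply(sizes, function(nr) {
    es <- sapply(1:10, function(sd) {
      out <- gen_reports(sim_report_config(
        n_drugs = 10, n_reports = nr, frac_interacting = 0.2,
        risk_ratio = 3, seed = sd))
      sig <- signal_table(out$reports, drugs = out$truth$drugs,
                          aes = out$truth$aes)
      key <- paste(sig$drugA, sig$drugB, sig$ae)
      tk <- paste(out$truth$interacting$drugA,
                  out$truth$interacting$drugB, out$truth$interacting$ae)
      rows <- sig[key %in% tk & sig$n_combo > 0 &
                    is.finite(sig$expected_rate), ]
      mean(abs(rows$d_combo / rows$n_combo / rows$expected_rate - 3))
    })
    mean(es)
  })
  expect_true(err[2] < err[1])
  expect_true(err[3] < err[2])
})

test_that("generated molecules parse, are deterministic, and non-trivial", {
  m1 <- gen_molecules(50, seed = 5)
  m2 <- gen_molecules(50, seed = 5)
  expect_identical(m1, m2)
  expect_equal(nrow(m1), 50L)
  heavies <- vapply(m1$smiles, function(s)
    descriptors(parse_smiles(s))$heavy_atom_count, numeric(1))
  expect_true(all(heavies >= 3))
  expect_equal(nrow(gen_molecules(1, seed = 9)), 1L)
})

test_that("triplet labels are symmetric, deterministic and recomputable", {
  mols <- gen_molecules(10, seed = 2)
  t1 <- gen_triplets(mols, n_cells = 6, seed = 4)
  t2 <- gen_triplets(mols, n_cells = 6, seed = 4)
  expect_identical(t1$triplets, t2$triplets)
  expect_error(gen_triplets(mols[1, , drop = FALSE]), "at least 2")

  # independent rule re-evaluation from descriptors reproduces every label
  desc <- descriptor_table(mols)
  latent <- attr(t1$cells, "latent")
  for (r in seq_len(nrow(t1$triplets))) {
    row <- t1$triplets[r, ]
    iA <- match(row$drugA, desc$id); iB <- match(row$drugB, desc$id)
    l <- latent[match(row$cell, rownames(t1$cells))]
    expect_equal(row$label,
                 triplet_label_rule(desc$heavy_atoms[iA],
                                    desc$heavy_atoms[iB], l,
                                    bondsA = desc$bonds[iA],
                                    bondsB = desc$bonds[iB]))
    # symmetry under swapping the drugs
    expect_equal(triplet_label_rule(desc$heavy_atoms[iA],
                                    desc$heavy_atoms[iB], l,
                                    bondsA = desc$bonds[iA],
                                    bondsB = desc$bonds[iB]),
                 triplet_label_rule(desc$heavy_atoms[iB],
                                    desc$heavy_atoms[iA], l,
                                    bondsA = desc$bonds[iB],
                                    bondsB = desc$bonds[iA]))
  }
})

test_that("default triplet task is class-balanced within [0.3, 0.7]", {
  tri <- gen_triplets(gen_molecules(16, seed = 1), n_cells = 16, seed = 1)
  bal <- mean(tri$triplets$label)
  expect_gte(bal, 0.3)
  expect_lte(bal, 0.7)
})

test_that("toy biological networks wire every drug to an AE", {
  ed <- gen_bio_network(n_drugs = 3, n_targets = 4, n_enzymes = 2,
                        n_transporters = 1, n_aes = 2, seed = 8)
  expect_true(all(c("src", "dst", "type", "weight") %in% names(ed)))
  ppi <- ed[ed$type == "ppi", ]
  expect_true(all(ppi$weight >= 0 & ppi$weight <= 1000))
  net <- build_network(ed, ppi_min_conf = 0)
  for (d in c("D01", "D02", "D03")) {
    sp <- shortest_path(net, d, "AE01")
    if (!sp$found) sp <- shortest_path(net, d, "AE02")
    expect_true(sp$found)
  }
  expect_identical(gen_bio_network(seed = 3), gen_bio_network(seed = 3))
})

test_that("reports CSV dialect round-trips", {
  out <- gen_reports(sim_report_config(n_drugs = 5, n_reports = 200,
                                       seed = 2))
  path <- tempfile(fileext = ".csv")
  write_reports_csv(out$reports, path)
  back <- read_reports_csv(path)
  expect_equal(back, out$reports)
})
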