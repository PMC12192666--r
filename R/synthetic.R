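# Synthetic pharmacovigilance data with injected interaction signals.
#
# The generator emulates a curated, deduplicated FAERS-like corpus: one row
# per spontaneous report, each listing one or two standardized drug ids and
# the adverse-event (AE) terms observed. A configurable fraction of drug
# pairs is flagged as truly interacting: for those pairs one designated AE
# occurs under co-administration at `risk_ratio` times the no-interaction
# baseline. The no-interaction baseline for an AE with per-drug rates p1, p2
# is the independence-of-causes rate p1 + p2 - p1*p2, which makes the null
# analytically checkable.

#' Beta distribution parameters
#' @param alpha,beta Strictly positive shape parameters.
#' @return List of class `beta_params`.
#' @export
beta_params <- function(alpha, beta) {
  if (!is.numeric(alpha) || !is.numeric(beta) || alpha <= 0 || beta <= 0)
    stop("beta_params: alpha and beta must be strictly positive",
         call. = FALSE)
  structure(list(alpha = alpha, beta = beta), class = "beta_params")
}

#' @export
print.beta_params <- function(x, ...) {
  cat(sprintf("Beta(%.4g, %.4g), mean %.4g\n", x$alpha, x$beta,
              x$alpha / (x$alpha + x$beta)))
  invisible(x)
}

#' Configuration for the FAERS-like report simulator
#'
#' Defaults give the packaged benchmark corpus: 20 drugs, 50,000 reports,
#' 41.68% of reports listing a drug pair (the multi-drug share of the curated
#' corpus the simulator emulates), per-drug AE rates drawn from Beta(2, 38)
#' (mean 5%), 10% of pairs truly interacting at risk ratio 3, 10 AE terms.
#' Drug popularity follows a Zipf-like 1/rank law so pair exposure is
#' heavy-tailed, as in real spontaneous-report data.
#'
#' @param n_drugs,n_reports,n_aes Positive counts.
#' @param p_combo Probability a report lists two drugs.
#' @param baseline_prior `beta_params` prior for per-drug, per-AE rates.
#' @param frac_interacting Fraction of drug pairs flagged as true signals.
#' @param risk_ratio Multiplier (>= 1) on the no-interaction combination rate.
#' @param seed Integer master seed.
#' @return List of class `sim_report_config`.
#' @export
sim_report_config <- function(n_drugs = 20L, n_reports = 50000L,
                              p_combo = 0.4168,
                              baseline_prior = beta_params(2, 38),
                              frac_interacting = 0.1, risk_ratio = 3,
                              n_aes = 10L, seed = 1L) {
  if (n_drugs < 2L || n_reports < 1L || n_aes < 1L)
    stop("sim_report_config: counts must be positive (n_drugs >= 2)",
         call. = FALSE)
  if (p_combo < 0 || p_combo > 1 || frac_interacting < 0 ||
      frac_interacting > 1)
    stop("sim_report_config: probabilities must lie in [0, 1]", call. = FALSE)
  if (risk_ratio < 1)
    stop("sim_report_config: risk_ratio must be >= 1", call. = FALSE)
  stopifnot(inherits(baseline_prior, "beta_params"))
  structure(list(n_drugs = as.integer(n_drugs),
                 n_reports = as.integer(n_reports),
                 p_combo = p_combo, baseline_prior = baseline_prior,
                 frac_interacting = frac_interacting,
                 risk_ratio = risk_ratio, n_aes = as.integer(n_aes),
                 seed = as.integer(seed)),
            class = "sim_report_config")
}

# All unordered drug pairs as a two-column matrix of indices (i < j).
.all_pairs <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  cbind(i = idx[, "row"], j = idx[, "col"])
}

#' Generate a synthetic spontaneous-report corpus
#'
#' @param config A [sim_report_config()].
#' @param flagged_pairs Optional explicit set of interacting pairs (matrix
#'   with columns `i`, `j` of drug indices, `i < j`) overriding the random
#'   `frac_interacting` draw; injected AEs are still drawn per pair.
#' @return List with `reports` (data.frame: `report_id`, `drugs`, `aes`,
#'   sets `;`-separated) and `truth` (ground truth: `interacting` data.frame
#'   of flagged pairs with their injected AE and risk ratio, `baseline_rates`
#'   matrix of per-drug per-AE rates, `drug_weights`, `drugs`, `aes`).
#' @export
gen_reports <- function(config, flagged_pairs = NULL) {
  stopifnot(inherits(config, "sim_report_config"))
  seeds <- split_seed(config$seed, 4L)
  nd <- config$n_drugs; nr <- config$n_reports; na <- config$n_aes
  drugs <- sprintf("D%02d", seq_len(nd))
  aes <- sprintf("AE%02d", seq_len(na))

  # Per-drug, per-AE baseline rates from the Beta prior.
  set.seed(seeds[1])
  rates <- matrix(rbeta(nd * na, config$baseline_prior$alpha,
                        config$baseline_prior$beta),
                  nrow = nd, ncol = na, dimnames = list(drugs, aes))

  # Flag interacting pairs and assign each an injected AE.
  pairs <- .all_pairs(nd)
  set.seed(seeds[2])
  if (is.null(flagged_pairs)) {
    n_int <- round(config$frac_interacting * nrow(pairs))
    flagged <- if (n_int > 0L) sample(nrow(pairs), n_int) else integer(0)
  } else {
    key <- paste(pairs[, 1], pairs[, 2])
    flagged <- match(paste(pmin(flagged_pairs[, 1], flagged_pairs[, 2]),
                           pmax(flagged_pairs[, 1], flagged_pairs[, 2])),
                     key)
    if (anyNA(flagged))
      stop("gen_reports: invalid flagged_pairs indices", call. = FALSE)
    n_int <- length(flagged)
  }
  inj_ae <- if (n_int > 0L) sample(na, n_int, replace = TRUE) else integer(0)
  interacting <- data.frame(
    drugA = drugs[pairs[flagged, 1]], drugB = drugs[pairs[flagged, 2]],
    ae = aes[inj_ae], risk_ratio = rep(config$risk_ratio, n_int),
    stringsAsFactors = FALSE)

  # Drug exposure: Zipf-like popularity, pair draws weighted by product.
  w <- (1 / seq_len(nd)); w <- w / sum(w)
  set.seed(seeds[3])
  is_combo <- runif(nr) < config$p_combo
  d1 <- sample.int(nd, nr, replace = TRUE, prob = w)
  d2 <- rep(NA_integer_, nr)
  need <- which(is_combo)
  d2[need] <- sample.int(nd, length(need), replace = TRUE, prob = w)
  # Redraw collisions so a pair is always two distinct drugs.
  while (length(bad <- which(is_combo & d2 == d1)) > 0L)
    d2[bad] <- sample.int(nd, length(bad), replace = TRUE, prob = w)
  lo <- pmin(d1, d2); hi <- pmax(d1, d2)

  # Per-report AE probabilities: independence of causes for unflagged sets,
  # risk_ratio times the baseline for a flagged pair's injected AE.
  pmat <- rates[d1, , drop = FALSE]
  if (any(is_combo)) {
    p1 <- rates[lo[need], , drop = FALSE]
    p2 <- rates[hi[need], , drop = FALSE]
    pmat[need, ] <- p1 + p2 - p1 * p2
  }
  if (n_int > 0L && any(is_combo)) {
    key <- paste(lo, hi)
    fkey <- paste(pairs[flagged, 1], pairs[flagged, 2])
    hit <- match(key, fkey)           # report -> flagged-pair index or NA
    hh <- which(!is.na(hit) & is_combo)
    if (length(hh) > 0L) {
      cols <- inj_ae[hit[hh]]
      pmat[cbind(hh, cols)] <-
        pmin(1, config$risk_ratio * pmat[cbind(hh, cols)])
    }
  }
  set.seed(seeds[4])
  occ <- matrix(runif(nr * na), nr, na) < pmat

  drug_str <- ifelse(is_combo, paste(drugs[lo], drugs[hi], sep = ";"),
                     drugs[d1])
  ae_str <- apply(occ, 1L, function(z) paste(aes[z], collapse = ";"))
  reports <- data.frame(report_id = sprintf("R%07d", seq_len(nr)),
                        drugs = drug_str, aes = ae_str,
                        stringsAsFactors = FALSE)
  truth <- list(interacting = interacting, baseline_rates = rates,
                drug_weights = w, drugs = drugs, aes = aes)
  list(reports = reports, truth = truth)
}

#' Write / read the reports CSV dialect (`report_id,drugs,aes`)
#' @param reports Report data.frame from [gen_reports()].
#' @param path File path.
#' @export
write_reports_csv <- function(reports, path) {
  utils::write.csv(reports, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_reports_csv
#' @export
read_reports_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c("character", "character", "character"))
}

# Template library for toy drug-like molecules: a prefix substituent, a core
# scaffold, and a suffix substituent, all chosen so the assembled SMILES is
# valid and has at least 3 heavy atoms.
.MOL_CORES <- c("c1ccccc1", "C1CCCCC1", "c1ccncc1", "C1CCNCC1", "C1CCOC1",
                "c1ccc2ccccc2c1", "c1ccsc1", "C1CCCC1",
                "C1Cc2ccccc2C1", "c1ccc2ncccc2c1", "c1ccccc1c1ccccc1",
                "C1CCC2CCCCC2C1")
.MOL_PREFIX <- c("", "C", "CC", "CCC", "OC", "NC", "Cl", "FC")
.MOL_SUFFIX <- c("", "C", "O", "N", "CO", "CN", "C(=O)O", "C(=O)N", "CC(=O)O")

#' Generate toy drug-like molecules
#'
#' Draws SMILES from a packaged template set (small drug-like scaffolds with
#' random substituents). Every generated string parses with [parse_smiles()]
#' and has at least 3 heavy atoms.
#'
#' @param n Number of molecules (>= 1).
#' @param seed Integer seed.
#' @return Data frame with columns `id`, `smiles`.
#' @export
gen_molecules <- function(n, seed = 1L) {
  if (n < 1L) stop("gen_molecules: n must be >= 1", call. = FALSE)
  set.seed(split_seed(seed, 1L))
  combos <- expand.grid(p = .MOL_PREFIX, c = .MOL_CORES, s = .MOL_SUFFIX,
                        stringsAsFactors = FALSE)
  # A bare 5-membered ring with no substituent can collide with cyclopentane
  # spelled differently; that is fine -- ids stay unique.
  pick <- sample.int(nrow(combos), n, replace = n > nrow(combos))
  smiles <- paste0(combos$p[pick], combos$c[pick], combos$s[pick])
  data.frame(id = sprintf("M%03d", seq_len(n)), smiles = smiles,
             stringsAsFactors = FALSE)
}

#' Deterministic label rule for synthetic triplets
#'
#' All rules are symmetric in the two drugs by construction and can be
#' recomputed from descriptors alone. The structural term combines
#' molecular size with ring complexity via the cyclomatic number
#' `cyc = bonds - heavy_atoms + 1` (independent rings of a connected
#' molecule, available from the descriptor set):
#' `z = (0.2 * (heavyA + heavyB) + 0.8 * (cycA + cycB) - 6.75) / 1.30`,
#' the constants standardizing `z` over the template library; ring
#' complexity carries about a third of the structural variance.
#'
#' * `"synergy"` (default): label 1 iff `z * latent + 0.5 z + 0.5 latent
#'   > 0`. The multiplicative term makes the synergy context-dependent --
#'   structurally complex pairs interact in high-latent cell lines and
#'   simple pairs in low-latent ones -- emulating the cell-line
#'   specificity of real drug combination screens.
#' * `"linear"`: label 1 iff `z + latent > 0`.
#' * `"and"`: label 1 iff `z > 0` and `latent > 0`.
#'
#' @param heavyA,heavyB Heavy-atom counts of the two drugs.
#' @param latent Cell-line latent factor.
#' @param rule Rule id, `"synergy"`, `"linear"` or `"and"`.
#' @param bondsA,bondsB Bond counts of the two drugs (default assumes
#'   acyclic molecules).
#' @return Integer 0/1 labels.
#' @export
triplet_label_rule <- function(heavyA, heavyB, latent, rule = "synergy",
                               bondsA = heavyA - 1, bondsB = heavyB - 1) {
  cyc <- (bondsA - heavyA + 1) + (bondsB - heavyB + 1)
  z <- (0.2 * (heavyA + heavyB) + 0.8 * cyc - 6.75) / 1.30
  switch(rule,
    synergy = as.integer(z * latent + 0.5 * z + 0.5 * latent > 0),
    linear = as.integer(z + latent > 0),
    and = as.integer(z > 0 & latent > 0),
    stop(sprintf("unknown label rule '%s'", rule), call. = FALSE))
}

#' Generate labeled (drugA, drugB, cell) triplets
#'
#' All unordered drug pairs are crossed with `n_cells` synthetic cell lines.
#' Each cell line carries a latent factor plus a 20-gene expression profile
#' correlated with it; labels come from [triplet_label_rule()], so they are
#' deterministic given descriptors and symmetric under swapping the drugs.
#'
#' @param molecules Data frame `id`, `smiles` (>= 2 molecules).
#' @param n_cells Number of cell lines.
#' @param rule Label rule id passed to [triplet_label_rule()].
#' @param seed Integer seed.
#' @return List with `triplets` (data.frame `drugA`, `drugB`, `cell`,
#'   `label`), `cells` (cell x gene matrix with attribute `latent`),
#'   `molecules`, `descriptors` (per-molecule descriptor table).
#' @export
gen_triplets <- function(molecules, n_cells = 8L, rule = "synergy",
                         seed = 1L) {
  if (nrow(molecules) < 2L)
    stop("gen_triplets: need at least 2 molecules", call. = FALSE)
  seeds <- split_seed(seed, 2L)
  desc <- descriptor_table(molecules)
  set.seed(seeds[1])
  latent <- rnorm(n_cells)
  genes <- matrix(rnorm(n_cells * 20L, sd = 0.5), n_cells, 20L)
  genes[, 1:5] <- genes[, 1:5] + latent   # latent factor leaks into genes
  rownames(genes) <- sprintf("CELL%02d", seq_len(n_cells))
  attr(genes, "latent") <- latent
  pairs <- .all_pairs(nrow(molecules))
  grid <- expand.grid(p = seq_len(nrow(pairs)), c = seq_len(n_cells))
  hA <- desc$heavy_atoms[pairs[grid$p, 1]]
  hB <- desc$heavy_atoms[pairs[grid$p, 2]]
  bA <- desc$bonds[pairs[grid$p, 1]]
  bB <- desc$bonds[pairs[grid$p, 2]]
  lab <- triplet_label_rule(hA, hB, latent[grid$c], rule,
                            bondsA = bA, bondsB = bB)
  triplets <- data.frame(
    drugA = molecules$id[pairs[grid$p, 1]],
    drugB = molecules$id[pairs[grid$p, 2]],
    cell = rownames(genes)[grid$c], label = lab, stringsAsFactors = FALSE)
  list(triplets = triplets, cells = genes, molecules = molecules,
       descriptors = desc)
}

#' Generate a toy drug-target-enzyme-transporter-AE network
#'
#' Typed edge lists with protein-protein edges carrying integer STRING-style
#' confidences in [0, 1000]. Every drug is wired through at least one
#' enzyme-mediated chain to an AE, so a drug-to-AE path always exists.
#'
#' @param n_drugs,n_targets,n_enzymes,n_transporters,n_aes Positive counts.
#' @param seed Integer seed.
#' @return Data frame `src`, `dst`, `type`, `weight`. PPI rows (`type ==
#'   "ppi"`) carry raw confidence 0-1000 in `weight`; all other types carry
#'   weights in [0, 1].
#' @export
gen_bio_network <- function(n_drugs = 4L, n_targets = 6L, n_enzymes = 3L,
                            n_transporters = 2L, n_aes = 3L, seed = 1L) {
  if (min(n_drugs, n_targets, n_enzymes, n_transporters, n_aes) < 1L)
    stop("gen_bio_network: counts must be positive", call. = FALSE)
  set.seed(split_seed(seed, 1L))
  dr <- sprintf("D%02d", seq_len(n_drugs))
  tg <- sprintf("T%02d", seq_len(n_targets))
  en <- sprintf("E%02d", seq_len(n_enzymes))
  tr <- sprintf("TR%02d", seq_len(n_transporters))
  ae <- sprintf("AE%02d", seq_len(n_aes))
  ed <- list()
  # Injected mechanism: drug -> enzyme -> AE chain per drug.
  for (k in seq_len(n_drugs)) {
    e <- en[1L + (k - 1L) %% n_enzymes]
    a <- ae[1L + (k - 1L) %% n_aes]
    ed[[length(ed) + 1L]] <- data.frame(
      src = c(dr[k], e), dst = c(e, a),
      type = c("drug_enzyme", "enzyme_ae"),
      weight = round(runif(2, 0.6, 1), 3), stringsAsFactors = FALSE)
  }
  # Random drug-target, drug-transporter, target-AE edges.
  for (k in seq_len(n_drugs)) {
    t1 <- sample(tg, min(2L, n_targets))
    ed[[length(ed) + 1L]] <- data.frame(
      src = dr[k], dst = t1, type = "drug_target",
      weight = round(runif(length(t1)), 3), stringsAsFactors = FALSE)
  }
  tr_pick <- sample(dr, min(n_drugs, 2L))
  ed[[length(ed) + 1L]] <- data.frame(
    src = tr_pick, dst = sample(tr, length(tr_pick), replace = TRUE),
    type = "drug_transporter", weight = round(runif(length(tr_pick)), 3),
    stringsAsFactors = FALSE)
  ta <- sample(tg, min(n_targets, 3L))
  ed[[length(ed) + 1L]] <- data.frame(
    src = ta, dst = sample(ae, length(ta), replace = TRUE),
    type = "target_ae", weight = round(runif(length(ta)), 3),
    stringsAsFactors = FALSE)
  # PPI edges among targets with integer confidences.
  if (n_targets >= 2L) {
    pp <- .all_pairs(n_targets)
    keep <- sample(nrow(pp), max(1L, round(nrow(pp) / 2)))
    ed[[length(ed) + 1L]] <- data.frame(
      src = tg[pp[keep, 1]], dst = tg[pp[keep, 2]], type = "ppi",
      weight = sample(0:1000, length(keep), replace = TRUE),
      stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, ed)
  rownames(edges) <- NULL
  edges
}
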