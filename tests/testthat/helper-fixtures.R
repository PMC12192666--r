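# Shared in-code fixtures for the test suite.

# Six-report toy corpus: 2 combo reports (1 with the AE), 2 A-alone
# (1 with the AE), 2 B-alone (1 with the AE).
toy_reports <- function() {
  data.frame(
    report_id = sprintf("R%d", 1:6),
    drugs = c("A;B", "A;B", "A", "A", "B", "B"),
    aes = c("HEADACHE", "", "HEADACHE", "", "HEADACHE", ""),
    stringsAsFactors = FALSE)
}

# Plain-loop recount oracle for one (drugA, drugB, ae) triple, independent
# of the data.table implementation used by the package.
recount_oracle <- function(reports, drugA, drugB, ae) {
  out <- c(d_combo = 0, n_combo = 0, d_first = 0, n_first = 0,
           d_second = 0, n_second = 0)
  for (r in seq_len(nrow(reports))) {
    ds <- strsplit(reports$drugs[r], ";", fixed = TRUE)[[1]]
    as_ <- strsplit(reports$aes[r], ";", fixed = TRUE)[[1]]
    hasA <- drugA %in% ds; hasB <- drugB %in% ds; hasE <- ae %in% as_
    if (hasA && hasB) {
      out["n_combo"] <- out["n_combo"] + 1
      if (hasE) out["d_combo"] <- out["d_combo"] + 1
    } else if (hasA) {
      out["n_first"] <- out["n_first"] + 1
      if (hasE) out["d_first"] <- out["d_first"] + 1
    } else if (hasB) {
      out["n_second"] <- out["n_second"] + 1
      if (hasE) out["d_second"] <- out["d_second"] + 1
    }
  }
  out
}

# Pairwise-concordance AUROC oracle (all positive/negative pairs).
auroc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# AUROC used when ranking signal tables (NA scores sink to the bottom).
rank_auroc <- function(scores, labels) {
  scores[!is.finite(scores)] <- min(scores[is.finite(scores)], 0) - 1
  r <- rank(scores)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Label signal-table rows against a ground-truth interacting set.
truth_labels <- function(sig, truth) {
  key <- paste(sig$drugA, sig$drugB, sig$ae)
  tk <- paste(truth$interacting$drugA, truth$interacting$drugB,
              truth$interacting$ae)
  as.integer(key %in% tk)
}
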