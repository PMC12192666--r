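# Beta-binomial Bayesian calibration of drug-drug interaction signals.
#
# Spontaneous reports are stratified per (drugA, drugB, AE) triple into six
# counts: AE occurrences and exposure totals under co-administration, under
# the first drug alone, and under the second drug alone. A conjugate
# beta-binomial model with empirical-Bayes (method-of-moments) priors turns
# the co-administration counts into posteriors and Bayes factors contrasting
# an interaction hypothesis against an independence-of-causes null, and
# classical disproportionality statistics provide baselines.

#' Stratify reports for one (drugA, drugB, AE) triple
#'
#' The co-administration stratum holds reports listing both drugs; the
#' monotherapy strata hold reports listing exactly one of the two (other
#' co-medications are ignored, all drugs being treated equivalently).
#'
#' @param reports Data frame `report_id`, `drugs`, `aes` with `;`-separated
#'   sets (the [gen_reports()] dialect).
#' @param drugA,drugB Distinct drug ids.
#' @param ae AE term.
#' @return List of class `pair_ae_contingency` with counts `d_combo`,
#'   `n_combo`, `d_first`, `n_first`, `d_second`, `n_second` and rates
#'   `p_combo`, `p_first`, `p_second` (NA where the exposure total is 0).
#' @export
stratify <- function(reports, drugA, drugB, ae) {
  if (identical(drugA, drugB))
    stop("stratify: drugA and drugB must differ", call. = FALSE)
  dl <- strsplit(reports$drugs, ";", fixed = TRUE)
  al <- strsplit(reports$aes, ";", fixed = TRUE)
  hasA <- vapply(dl, function(s) drugA %in% s, logical(1))
  hasB <- vapply(dl, function(s) drugB %in% s, logical(1))
  hasE <- vapply(al, function(s) ae %in% s, logical(1))
  combo <- hasA & hasB; first <- hasA & !hasB; second <- hasB & !hasA
  cont <- list(d_combo = sum(combo & hasE), n_combo = sum(combo),
               d_first = sum(first & hasE), n_first = sum(first),
               d_second = sum(second & hasE), n_second = sum(second))
  cont$p_combo <- if (cont$n_combo > 0) cont$d_combo / cont$n_combo else NA
  cont$p_first <- if (cont$n_first > 0) cont$d_first / cont$n_first else NA
  cont$p_second <- if (cont$n_second > 0) cont$d_second / cont$n_second else NA
  structure(cont, class = "pair_ae_contingency")
}

# Vectorized stratification of a whole corpus over all drug pairs and AEs.
# Returns a data.table with one row per (pair, ae).
stratify_all <- function(reports, drugs, aes) {
  nr <- nrow(reports)
  dl <- strsplit(reports$drugs, ";", fixed = TRUE)
  al <- strsplit(reports$aes, ";", fixed = TRUE)
  M <- matrix(FALSE, nr, length(drugs), dimnames = list(NULL, drugs))
  len <- lengths(dl)
  ridx <- rep(seq_len(nr), len)
  cidx <- match(unlist(dl), drugs)
  ok <- !is.na(cidx)
  M[cbind(ridx[ok], cidx[ok])] <- TRUE
  A <- matrix(FALSE, nr, length(aes), dimnames = list(NULL, aes))
  lena <- lengths(al)
  ridx <- rep(seq_len(nr), lena)
  cidx <- match(unlist(al), aes)
  ok <- !is.na(cidx)
  A[cbind(ridx[ok], cidx[ok])] <- TRUE

  pairs <- .all_pairs(length(drugs))
  out <- vector("list", nrow(pairs))
  Anum <- A * 1
  for (r in seq_len(nrow(pairs))) {
    a <- pairs[r, 1]; b <- pairs[r, 2]
    combo <- M[, a] & M[, b]
    first <- M[, a] & !M[, b]
    second <- M[, b] & !M[, a]
    out[[r]] <- data.table::data.table(
      drugA = drugs[a], drugB = drugs[b], ae = aes,
      d_combo = as.integer(colSums(Anum[combo, , drop = FALSE])),
      n_combo = sum(combo),
      d_first = as.integer(colSums(Anum[first, , drop = FALSE])),
      n_first = sum(first),
      d_second = as.integer(colSums(Anum[second, , drop = FALSE])),
      n_second = sum(second))
  }
  data.table::rbindlist(out)
}

#' Method-of-moments empirical-Bayes fit of a Beta prior
#'
#' Matches the Beta mean and variance to the sample moments of observed AE
#' rates: with mean `m` and variance `v`, `c = m(1-m)/v - 1`, `alpha = m*c`,
#' `beta = (1-m)*c`. When the rates are over-dispersed beyond Beta support
#' (`v >= m(1-m)`) or degenerate (`v = 0`), the fit falls back to the
#' uniform Beta(1, 1) with a warning.
#'
#' @param rates Numeric vector of observed rates in [0, 1], or `NULL` when
#'   `d` and `n` are given.
#' @param d,n Optional AE and exposure count vectors; rates are `d/n` over
#'   strata with `n > 0`.
#' @return A [beta_params()] object.
#' @export
fit_prior_mom <- function(rates = NULL, d = NULL, n = NULL) {
  if (is.null(rates)) {
    stopifnot(!is.null(d), !is.null(n), length(d) == length(n))
    rates <- (d / n)[n > 0]
  }
  rates <- rates[is.finite(rates)]
  if (length(rates) < 2L)
    stop("fit_prior_mom: need at least 2 rate observations", call. = FALSE)
  m <- mean(rates); v <- stats::var(rates)
  if (v <= 0 || m <= 0 || m >= 1 || v >= m * (1 - m)) {
    warning("fit_prior_mom: moments outside Beta support; ",
            "falling back to Beta(1, 1)", call. = FALSE)
    return(beta_params(1, 1))
  }
  cc <- m * (1 - m) / v - 1
  beta_params(m * cc, (1 - m) * cc)
}

#' Conjugate beta-binomial posterior update
#'
#' @param prior A [beta_params()] prior over the AE rate.
#' @param X AE count (0 <= X <= n).
#' @param n Exposure count.
#' @return Posterior [beta_params()]: Beta(alpha + X, beta + n - X).
#' @export
posterior <- function(prior, X, n) {
  stopifnot(inherits(prior, "beta_params"))
  if (X < 0 || n < 0 || X > n)
    stop("posterior: need 0 <= X <= n", call. = FALSE)
  beta_params(prior$alpha + X, prior$beta + n - X)
}

#' Bayes factor for interaction vs no-interaction
#'
#' Ratio of beta-binomial marginal likelihoods of the observed counts under
#' the interaction-hypothesis prior and the null prior. The binomial
#' coefficient cancels; everything is evaluated via log-gamma for stability.
#'
#' @param X AE count under co-administration.
#' @param n Co-administration exposure total.
#' @param prior_h1 Prior under the interaction hypothesis.
#' @param prior_h0 Prior under the no-interaction null.
#' @return Positive scalar Bayes factor (vectorized over `X`, `n`).
#' @export
bayes_factor <- function(X, n, prior_h1, prior_h0) {
  stopifnot(inherits(prior_h1, "beta_params"),
            inherits(prior_h0, "beta_params"))
  if (any(X < 0) || any(X > n))
    stop("bayes_factor: need 0 <= X <= n", call. = FALSE)
  lm1 <- lbeta(prior_h1$alpha + X, prior_h1$beta + n - X) -
    lbeta(prior_h1$alpha, prior_h1$beta)
  lm0 <- lbeta(prior_h0$alpha + X, prior_h0$beta + n - X) -
    lbeta(prior_h0$alpha, prior_h0$beta)
  exp(lm1 - lm0)
}

# One-sided variant: the interaction hypothesis is excess risk, so the H1
# prior is truncated to theta > e (the stratum's no-interaction baseline).
# The truncated beta-binomial marginal has the closed form
#   m1 = BB(X; a1, b1) * P(Beta(a1+X, b1+n-X) > e) / P(Beta(a1, b1) > e),
# evaluated in log space via the regularized incomplete beta function.
.bayes_factor_onesided <- function(X, n, prior_h1, prior_h0, e) {
  lt1 <- stats::pbeta(e, prior_h1$alpha + X, prior_h1$beta + n - X,
                      lower.tail = FALSE, log.p = TRUE)
  lt0 <- stats::pbeta(e, prior_h1$alpha, prior_h1$beta,
                      lower.tail = FALSE, log.p = TRUE)
  lm1 <- lbeta(prior_h1$alpha + X, prior_h1$beta + n - X) -
    lbeta(prior_h1$alpha, prior_h1$beta) + lt1 - lt0
  lm0 <- lbeta(prior_h0$alpha + X, prior_h0$beta + n - X) -
    lbeta(prior_h0$alpha, prior_h0$beta)
  exp(lm1 - lm0)
}

#' Probability that one Beta-distributed rate exceeds another
#'
#' Computes P(theta_combo > theta_ref) for independent Beta posteriors by
#' 1-d numerical integration of the density-CDF product.
#'
#' @param post_combo,post_ref [beta_params()] posteriors.
#' @return Probability in [0, 1].
#' @export
prob_excess <- function(post_combo, post_ref) {
  stopifnot(inherits(post_combo, "beta_params"),
            inherits(post_ref, "beta_params"))
  f <- function(t) stats::dbeta(t, post_combo$alpha, post_combo$beta) *
    stats::pbeta(t, post_ref$alpha, post_ref$beta)
  val <- stats::integrate(f, 0, 1, rel.tol = 1e-9)$value
  min(max(val, 0), 1)
}

#' F1-optimal Bayes-factor threshold
#'
#' Scans candidate thresholds at midpoints between sorted unique BF values
#' (plus sentinels below the minimum and above the maximum) and returns the
#' threshold maximizing the F1 score of the rule `BF > tau`; ties go to the
#' smallest threshold.
#'
#' @param bf Positive Bayes factors.
#' @param labels Binary 0/1 labels (both classes must be present).
#' @return List of class `threshold_result`: `tau`, `f1`, `n_used`.
#' @export
choose_threshold <- function(bf, labels) {
  stopifnot(length(bf) == length(labels))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("choose_threshold: both classes must be present", call. = FALSE)
  u <- sort(unique(bf))
  cand <- c(u[1] - 1, if (length(u) > 1) (head(u, -1) + u[-1]) / 2,
            u[length(u)] + 1)
  f1s <- vapply(cand, function(t) {
    pred <- as.integer(bf > t)
    tp <- sum(pred == 1 & labels == 1)
    fp <- sum(pred == 1 & labels == 0)
    fn <- sum(pred == 0 & labels == 1)
    if (tp == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  best <- which(f1s == max(f1s))[1]   # candidates ascend: first max = smallest tau
  structure(list(tau = cand[best], f1 = f1s[best], n_used = length(bf)),
            class = "threshold_result")
}

#' Classical disproportionality baselines for one contingency
#'
#' With monotherapy rates `p1`, `p2`, the expected no-interaction rate is
#' `e = p1 + p2 - p1*p2`; with observed count `O = d_combo` and expected
#' count `E = e * n_combo`:
#' omega = log2((O + 0.5)/(E + 0.5)); intss = (O + 0.5)/(E + 0.5);
#' delta_add = d_combo/n_combo - e; llr is the one-sided binomial
#' log-likelihood ratio of the observed rate against `e` (0 when the
#' observed rate does not exceed `e`). These shrinkage forms follow standard
#' pharmacovigilance practice.
#'
#' @param cont A `pair_ae_contingency` from [stratify()] (or any list with
#'   the six counts).
#' @return List `omega`, `llr`, `intss`, `delta_add`, `flag` (TRUE when a
#'   monotherapy stratum had zero exposure and the statistics are NA).
#' @export
baseline_stats <- function(cont) {
  if (cont$n_combo <= 0)
    stop("baseline_stats: n_combo must be positive", call. = FALSE)
  if (cont$n_first <= 0 || cont$n_second <= 0)
    return(list(omega = NA_real_, llr = NA_real_, intss = NA_real_,
                delta_add = NA_real_, flag = TRUE))
  p1 <- cont$d_first / cont$n_first
  p2 <- cont$d_second / cont$n_second
  e <- p1 + p2 - p1 * p2
  O <- cont$d_combo
  E <- e * cont$n_combo
  pc <- O / cont$n_combo
  llr <- 0
  if (pc > e) {
    logl <- function(p) {
      p <- min(max(p, 1e-12), 1 - 1e-12)
      O * log(p) + (cont$n_combo - O) * log(1 - p)
    }
    llr <- logl(pc) - logl(e)
  }
  list(omega = log2((O + 0.5) / (E + 0.5)),
       llr = llr,
       intss = (O + 0.5) / (E + 0.5),
       delta_add = pc - e,
       flag = FALSE)
}

#' Full signal table for a report corpus
#'
#' Stratifies every (drug pair, AE) triple and scores each one with a
#' Bayes factor contrasting interaction against the independence null.
#' The empirical-Bayes prior construction works per AE term: the
#' interaction prior H1 is a method-of-moments fit to the observed
#' co-administration rates across pairs, and the null prior for each triple
#' is a Beta centered at that triple's monotherapy-derived expected rate
#' `e = p1 + p2 - p1*p2` whose concentration matches the sampling
#' uncertainty of `e` propagated from the monotherapy strata
#' (`Var(e) = (1-p2)^2 p1(1-p1)/n1 + (1-p1)^2 p2(1-p2)/n2`). The null thus
#' says "the combination rate is the no-interaction baseline, known up to
#' its estimation error", and the Bayes factor measures departure from the
#' pair-specific baseline rather than from the population average.
#'
#' @param reports Reports data frame (the [gen_reports()] dialect).
#' @param drugs,aes Optional vocabularies; defaults are scraped from the
#'   corpus.
#' @param priors Either `"auto"` (empirical Bayes as above) or a list with
#'   `h1` and `h0` [beta_params()] applied globally.
#' @param one_sided Truncate the interaction prior to rates above the
#'   stratum's expected baseline (default), so only excess risk counts as
#'   evidence for interaction. With `FALSE` the plain two-sided factor is
#'   returned; its null distribution concentrates near 1, whereas the
#'   truncated factor is deflated under the null by roughly the prior tail
#'   odds.
#' @param with_prob_excess Also compute the posterior excess probability
#'   P(theta_combo > theta_null) per triple (slower; off by default).
#' @return data.frame, one row per (drugA, drugB, ae): the six counts,
#'   `expected_rate` (independence null), `bf`, `posterior_mean`, baseline
#'   statistics, `flag`, and optionally `prob_excess`. Rows with no
#'   co-administration exposure or missing monotherapy strata carry NA
#'   scores and `flag = TRUE`.
#' @export
signal_table <- function(reports, drugs = NULL, aes = NULL,
                         priors = "auto", one_sided = TRUE,
                         with_prob_excess = FALSE) {
  split_vals <- function(col) sort(unique(unlist(
    strsplit(col, ";", fixed = TRUE))))
  if (is.null(drugs)) drugs <- split_vals(reports$drugs)
  if (is.null(aes)) aes <- setdiff(split_vals(reports$aes), "")
  tab <- stratify_all(reports, drugs, aes)
  tab <- as.data.frame(tab)
  p1 <- ifelse(tab$n_first > 0, tab$d_first / tab$n_first, NA)
  p2 <- ifelse(tab$n_second > 0, tab$d_second / tab$n_second, NA)
  tab$expected_rate <- p1 + p2 - p1 * p2
  obs_rate <- ifelse(tab$n_combo > 0, tab$d_combo / tab$n_combo, NA)

  eclip <- function(e) pmin(pmax(e, 1e-4), 1 - 1e-4)
  tab$bf <- NA_real_
  tab$posterior_mean <- NA_real_
  prior_info <- list()
  for (a in aes) {
    rows <- which(tab$ae == a)
    ok <- rows[is.finite(tab$expected_rate[rows]) & tab$n_combo[rows] > 0]
    if (length(ok) < 2L) next
    fit_or_unif <- function(x) {
      tryCatch(suppressWarnings(fit_prior_mom(rates = x)),
               error = function(e) beta_params(1, 1))
    }
    h1 <- if (identical(priors, "auto"))
      fit_or_unif(obs_rate[ok]) else priors$h1
    conc0 <- function(r) {
      if (!identical(priors, "auto"))
        return(priors$h0$alpha + priors$h0$beta)
      e <- eclip(tab$expected_rate[r])
      q1 <- eclip(p1[r]); q2 <- eclip(p2[r])
      ve <- (1 - q2)^2 * q1 * (1 - q1) / tab$n_first[r] +
        (1 - q1)^2 * q2 * (1 - q2) / tab$n_second[r]
      max(e * (1 - e) / max(ve, 1e-12) - 1, 2)
    }
    for (r in ok) {
      e <- eclip(tab$expected_rate[r])
      c0 <- conc0(r)
      h0 <- beta_params(e * c0, (1 - e) * c0)
      tab$bf[r] <- if (one_sided)
        .bayes_factor_onesided(tab$d_combo[r], tab$n_combo[r], h1, h0, e)
      else bayes_factor(tab$d_combo[r], tab$n_combo[r], h1, h0)
      post <- posterior(h1, tab$d_combo[r], tab$n_combo[r])
      tab$posterior_mean[r] <- post$alpha / (post$alpha + post$beta)
    }
    prior_info[[a]] <- list(h1 = h1, h0_concentration = conc0)
  }
  bs <- lapply(seq_len(nrow(tab)), function(r) {
    if (tab$n_combo[r] <= 0)
      return(list(omega = NA_real_, llr = NA_real_, intss = NA_real_,
                  delta_add = NA_real_, flag = TRUE))
    baseline_stats(tab[r, ])
  })
  tab$omega <- vapply(bs, `[[`, numeric(1), "omega")
  tab$llr <- vapply(bs, `[[`, numeric(1), "llr")
  tab$intss <- vapply(bs, `[[`, numeric(1), "intss")
  tab$delta_add <- vapply(bs, `[[`, numeric(1), "delta_add")
  tab$flag <- vapply(bs, `[[`, logical(1), "flag") | !is.finite(tab$bf)
  if (with_prob_excess) {
    tab$prob_excess <- vapply(seq_len(nrow(tab)), function(r) {
      er <- tab$expected_rate[r]
      if (!is.finite(er) || tab$n_combo[r] <= 0 ||
          is.null(prior_info[[tab$ae[r]]])) return(NA_real_)
      pri <- prior_info[[tab$ae[r]]]
      pc <- posterior(pri$h1, tab$d_combo[r], tab$n_combo[r])
      e <- eclip(er)
      c0 <- pri$h0_concentration(r)
      h0 <- beta_params(e * c0, (1 - e) * c0)
      # Null reference posterior: null prior updated with the expected count.
      pr <- posterior(h0, round(e * tab$n_combo[r]), tab$n_combo[r])
      prob_excess(pc, pr)
    }, numeric(1))
  }
  attr(tab, "priors") <- prior_info
  tab
}

#' Gaussian naive-Bayes classifier over posterior features
#'
#' Fits a Gaussian naive-Bayes model that predicts an AE category for a drug
#' combination from two features: the beta-binomial posterior probability of
#' the AE under co-administration and the log usage frequency of the
#' combination.
#'
#' @param features Numeric matrix or data.frame with columns
#'   `posterior_prob` and `log_freq`, one row per combination.
#' @param labels AE category per row (>= 2 distinct categories).
#' @return Object of class `ae_classifier`.
#' @export
classify_ae <- function(features, labels) {
  features <- as.data.frame(features)
  stopifnot(all(c("posterior_prob", "log_freq") %in% names(features)))
  labels <- factor(labels)
  if (nlevels(labels) < 2L)
    stop("classify_ae: need at least 2 AE categories", call. = FALSE)
  fit <- e1071::naiveBayes(features[, c("posterior_prob", "log_freq")],
                           labels)
  structure(list(fit = fit, levels = levels(labels)),
            class = "ae_classifier")
}

#' Rank drug combinations by confidence for one AE
#'
#' @param model An `ae_classifier` from [classify_ae()].
#' @param ae AE category to query (must have been seen at fit time).
#' @param combos Data frame with `posterior_prob`, `log_freq`, and a
#'   `combo` identifier column.
#' @return Data frame `combo`, `score` sorted by descending confidence.
#' @export
rank_for_ae <- function(model, ae, combos) {
  stopifnot(inherits(model, "ae_classifier"))
  if (!ae %in% model$levels)
    stop(sprintf("rank_for_ae: unseen AE category '%s'", ae), call. = FALSE)
  probs <- stats::predict(model$fit,
                          combos[, c("posterior_prob", "log_freq")],
                          type = "raw")
  sc <- probs[, ae]
  out <- data.frame(combo = combos$combo, score = sc,
                    stringsAsFactors = FALSE)
  out[order(-out$score, out$combo), , drop = FALSE]
}

#' Write a signal table to CSV
#' @param signals Output of [signal_table()].
#' @param path File path.
#' @export
write_signals_csv <- function(signals, path) {
  utils::write.csv(signals, path, row.names = FALSE)
  invisible(path)
}
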