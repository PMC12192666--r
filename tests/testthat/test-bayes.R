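test_that("stratification reproduces direct enumeration", {
  s <- stratify(toy_reports(), "A", "B", "HEADACHE")
  expect_equal(unclass(s)[c("d_combo", "d_first", "d_second",
                            "n_combo", "n_first", "n_second")],
               list(d_combo = 1L, d_first = 1L, d_second = 1L,
                    n_combo = 2L, n_first = 2L, n_second = 2L),
               ignore_attr = TRUE)
  expect_equal(s$p_combo, 0.5)
  empty <- data.frame(report_id = character(0), drugs = character(0),
                      aes = character(0))
  s0 <- stratify(empty, "A", "B", "X")
  expect_equal(s0$n_combo + s0$n_first + s0$n_second, 0L)
  expect_true(is.na(s0$p_combo))
  expect_error(stratify(toy_reports(), "A", "A", "X"), "differ")
})

test_that("bulk stratification agrees with a single-pass recount", {
  out <- gen_reports(sim_report_config(n_drugs = 6, n_reports = 5000,
                                       seed = 13))
  sig <- signal_table(out$reports, drugs = out$truth$drugs,
                      aes = out$truth$aes)
  set.seed(1)
  for (r in sample(nrow(sig), 12)) {
    cnt <- recount_oracle(out$reports, sig$drugA[r], sig$drugB[r],
                          sig$ae[r])
    expect_equal(unname(c(sig$d_combo[r], sig$n_combo[r], sig$d_first[r],
                          sig$n_first[r], sig$d_second[r],
                          sig$n_second[r])),
                 unname(cnt[c("d_combo", "n_combo", "d_first", "n_first",
                              "d_second", "n_second")]))
  }
})

test_that("method-of-moments prior fitting matches the closed form", {
  # m = 0.2, v = 0.016 -> c = 9, alpha = 1.8, beta = 7.2
  a <- sqrt(0.008)                   # two points with sample var 0.016
  fit <- fit_prior_mom(rates = c(0.2 - a, 0.2 + a))
  expect_equal(fit$alpha, 1.8)
  expect_equal(fit$beta, 7.2)
  # degenerate variance falls back to the uniform prior with a warning
  expect_warning(f0 <- fit_prior_mom(rates = rep(0.3, 5)), "Beta\\(1, 1\\)")
  expect_equal(c(f0$alpha, f0$beta), c(1, 1))
  expect_error(fit_prior_mom(rates = 0.5), "at least 2")
})

test_that("moment fits recover Beta(2, 8) within 15% at n = 5000", {
  set.seed(31)
  draws <- rbeta(5000, 2, 8)
  fit <- fit_prior_mom(rates = draws)
  expect_lt(abs(fit$alpha - 2) / 2, 0.15)
  expect_lt(abs(fit$beta - 8) / 8, 0.15)
})

test_that("conjugate updates obey the Beta-binomial algebra", {
  post <- posterior(beta_params(1, 1), 3, 10)
  expect_equal(c(post$alpha, post$beta), c(4, 8))
  expect_equal(post$alpha / (post$alpha + post$beta), 1 / 3)
  # no data -> prior unchanged
  p0 <- posterior(beta_params(2.5, 7), 0, 0)
  expect_equal(c(p0$alpha, p0$beta), c(2.5, 7))
  expect_error(posterior(beta_params(1, 1), 5, 3), "X <= n")
  # coherence: two sequential updates equal one pooled update
  pA <- posterior(posterior(beta_params(2, 3), 4, 9), 1, 6)
  pB <- posterior(beta_params(2, 3), 5, 15)
  expect_equal(c(pA$alpha, pA$beta), c(pB$alpha, pB$beta))
  # posterior mean vs large Monte-Carlo mean
  set.seed(11)
  sim <- rbeta(1e6, post$alpha, post$beta)
  expect_equal(mean(sim), 1 / 3, tolerance = 2e-3)
})

test_that("Bayes factors match quadrature integration of the marginals", {
  expect_equal(bayes_factor(4, 9, beta_params(2, 5), beta_params(2, 5)), 1)
  # X = n with a higher-mean H1 prior favors H1
  expect_gt(bayes_factor(10, 10, beta_params(5, 1), beta_params(1, 5)), 1)
  quad_marginal <- function(X, n, a, b) {
    stats::integrate(function(t)
      stats::dbinom(X, n, t) * stats::dbeta(t, a, b), 0, 1,
      rel.tol = 1e-12)$value
  }
  # the printed worked example
  bf <- bayes_factor(8, 10, beta_params(2, 2), beta_params(1, 9))
  want <- (beta(10, 4) / beta(2, 2)) / (beta(9, 11) / beta(1, 9))
  expect_equal(bf, want, tolerance = 1e-12)
  # random cases up to n = 50 against adaptive quadrature
  set.seed(21)
  for (i in 1:25) {
    n <- sample(50, 1); X <- sample(0:n, 1)
    h1 <- beta_params(runif(1, 0.5, 6), runif(1, 0.5, 6))
    h0 <- beta_params(runif(1, 0.5, 6), runif(1, 0.5, 6))
    want <- quad_marginal(X, n, h1$alpha, h1$beta) /
      quad_marginal(X, n, h0$alpha, h0$beta)
    expect_equal(bayes_factor(X, n, h1, h0), want, tolerance = 1e-6)
  }
  expect_error(bayes_factor(5, 3, beta_params(1, 1), beta_params(1, 1)),
               "X <= n")
})

test_that("excess-risk probabilities agree with closed forms and sampling", {
  expect_equal(prob_excess(beta_params(3, 4), beta_params(3, 4)), 0.5,
               tolerance = 1e-8)
  # P(theta1 > theta2) = E[F2(theta1)] = E[theta1] = 2/3 for Beta(1,1) ref
  expect_equal(prob_excess(beta_params(2, 1), beta_params(1, 1)), 2 / 3,
               tolerance = 1e-8)
  set.seed(17)
  for (i in 1:4) {
    a <- beta_params(runif(1, 0.5, 8), runif(1, 0.5, 8))
    b <- beta_params(runif(1, 0.5, 8), runif(1, 0.5, 8))
    mc <- mean(rbeta(1e6, a$alpha, a$beta) > rbeta(1e6, b$alpha, b$beta))
    expect_lt(abs(prob_excess(a, b) - mc), 2e-3)
  }
})

test_that("F1-optimal thresholds scan midpoints with ties to the smallest", {
  res <- choose_threshold(c(0.1, 0.2, 5, 10), c(0, 0, 1, 1))
  expect_equal(res$tau, 2.6)
  expect_equal(res$f1, 1)
  expect_error(choose_threshold(c(1, 2), c(1, 1)), "classes")
  # exhaustive grid oracle
  set.seed(23)
  bf <- rexp(40); y <- rbinom(40, 1, 0.4)
  res <- choose_threshold(bf, y)
  grid <- sort(unique(c(bf - 1e-9, bf + 1e-9)))
  f1_at <- function(t) {
    pred <- as.integer(bf > t)
    tp <- sum(pred & y); if (tp == 0) return(0)
    2 * tp / (2 * tp + sum(pred & !y) + sum(!pred & y))
  }
  expect_equal(res$f1, max(sapply(grid, f1_at)))
})

test_that("disproportionality baselines match direct formula evaluation", {
  # O = E: omega 0, intss 1; observed rate = e: delta_add 0, llr 0
  cont <- list(d_combo = 30, n_combo = 200, d_first = 30, n_first = 300,
               d_second = 20, n_second = 350)
  p1 <- 0.1; p2 <- 20 / 350
  e <- p1 + p2 - p1 * p2
  cont$d_combo <- round(e * 200)   # make O = E (up to rounding)
  bs <- baseline_stats(cont)
  O <- cont$d_combo; E <- e * 200
  expect_equal(bs$omega, log2((O + 0.5) / (E + 0.5)))
  expect_equal(bs$intss, (O + 0.5) / (E + 0.5))
  expect_equal(bs$delta_add, O / 200 - e)
  # construct an exact O = E case
  c2 <- list(d_combo = 19, n_combo = 100, d_first = 10, n_first = 100,
             d_second = 10, n_second = 100)
  e2 <- 0.1 + 0.1 - 0.01
  expect_equal(baseline_stats(c2)$omega, 0)
  expect_equal(baseline_stats(c2)$intss, 1)
  expect_equal(baseline_stats(c2)$delta_add, 0)
  expect_equal(baseline_stats(c2)$llr, 0)
  # llr equals its one-sided binomial form on an excess case
  c3 <- list(d_combo = 40, n_combo = 100, d_first = 10, n_first = 100,
             d_second = 10, n_second = 100)
  pc <- 0.4
  want_llr <- (40 * log(pc) + 60 * log(1 - pc)) -
    (40 * log(e2) + 60 * log(1 - e2))
  expect_equal(baseline_stats(c3)$llr, want_llr)
  # degenerate monotherapy stratum flags the row
  c4 <- list(d_combo = 5, n_combo = 50, d_first = 0, n_first = 0,
             d_second = 2, n_second = 30)
  expect_true(baseline_stats(c4)$flag)
  expect_true(is.na(baseline_stats(c4)$omega))
  # random contingencies against an independent re-evaluation
  set.seed(29)
  for (i in 1:10) {
    n1 <- sample(50:400, 3)
    d1 <- rbinom(3, n1, 0.15)
    cc <- list(d_combo = d1[1], n_combo = n1[1], d_first = d1[2],
               n_first = n1[2], d_second = d1[3], n_second = n1[3])
    bs <- baseline_stats(cc)
    q1 <- d1[2] / n1[2]; q2 <- d1[3] / n1[3]
    ee <- q1 + q2 - q1 * q2
    expect_equal(bs$omega, log2((d1[1] + 0.5) / (ee * n1[1] + 0.5)))
    expect_equal(bs$delta_add, d1[1] / n1[1] - ee)
  }
})

test_that("the posterior-feature classifier separates and ranks", {
  # perfectly separated 1-d classes
  set.seed(5)
  feats <- data.frame(posterior_prob = c(runif(20, 0, 0.2),
                                         runif(20, 0.8, 1)),
                      log_freq = rnorm(40))
  labs <- rep(c("mild", "severe"), each = 20)
  model <- classify_ae(feats, labs)
  rk <- rank_for_ae(model, "severe",
                    cbind(feats, combo = sprintf("c%02d", 1:40)))
  expect_equal(nrow(rk), 40L)
  expect_true(all(diff(rk$score) <= 1e-12))
  pred <- ifelse(rk$score > 0.5, "severe", "mild")
  truth <- labs[match(rk$combo, sprintf("c%02d", 1:40))]
  expect_equal(mean(pred == truth), 1)
  expect_error(rank_for_ae(model, "unknown_ae", feats), "unseen")
  expect_error(classify_ae(feats, rep("one", 40)), "2")

  # monotone synthetic task: the top-ranked combo has the highest true rate
  hits <- 0L
  for (sd in 1:20) {
    set.seed(400 + sd)
    # a clear margin between the top combination and the runner-up, so
    # the monotone relationship decides the top rank
    true_rate <- sample(c(0.9, runif(5, 0.5, 0.7), runif(6, 0.05, 0.35)))
    f <- data.frame(posterior_prob = pmin(pmax(
      true_rate + rnorm(12, sd = 0.02), 0), 1),
      log_freq = rnorm(12), combo = sprintf("p%02d", 1:12))
    cat_lab <- ifelse(true_rate > 0.45, "high", "low")
    f <- f[, c("posterior_prob", "log_freq", "combo")]
    m <- classify_ae(f[, 1:2], cat_lab)
    rk <- rank_for_ae(m, "high", f)
    if (true_rate[match(rk$combo[1], f$combo)] == max(true_rate))
      hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("null corpora keep the plain Bayes factor near one", {
  meds <- sapply(c(101, 102), function(sd) {
    out <- gen_reports(sim_report_config(n_reports = 20000,
                                         frac_interacting = 0, seed = sd))
    sig <- signal_table(out$reports, drugs = out$truth$drugs,
                        aes = out$truth$aes, one_sided = FALSE)
    median(sig$bf, na.rm = TRUE)
  })
  expect_true(all(meds >= 0.5 & meds <= 2))
  # and high-threshold exceedances are rare for the detector itself
  out <- gen_reports(sim_report_config(n_reports = 20000,
                                       frac_interacting = 0, seed = 103))
  sig <- signal_table(out$reports, drugs = out$truth$drugs,
                      aes = out$truth$aes)
  expect_lt(mean(sig$bf > 10, na.rm = TRUE), 0.01)
})
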