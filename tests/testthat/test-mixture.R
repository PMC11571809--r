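# Binomial-mixture fraction-new estimation, conversion rates, kinetics, QC.

test_that("EM recovers the closed-form estimate when pbg = 0", {
  # with pbg = 0 any converted read is surely new, and a new read converts
  # with probability 1 - (1 - 0.5)^2 = 0.75, so theta = (45/100) / 0.75
  fit <- fit_fraction_new(c(2, 2, 2), c(0, 1, 2), c(55, 30, 15),
                          pnew = 0.5, pbg = 0)
  expect_equal(fit$theta, 0.6, tolerance = 1e-6)
  expect_true(fit$converged)
  grid <- grid_theta_hat(c(2, 2, 2), c(0, 1, 2), c(55, 30, 15), 0.5, 0)
  expect_equal(fit$theta, grid, tolerance = 1e-3)
  # boundary: all reads unconverted
  fit0 <- fit_fraction_new(2, 0, 100, pnew = 0.5, pbg = 0)
  expect_equal(fit0$theta, 0, tolerance = 1e-9)
  expect_true(is.finite(fit0$se_logit) && fit0$se_logit > 0)
  # all reads converted at pnew: theta -> 1
  fit1 <- fit_fraction_new(c(2, 2), c(1, 2), c(50, 50), pnew = 0.5, pbg = 0)
  expect_equal(fit1$theta, 1, tolerance = 1e-9)
})

test_that("EM matches dense grid search and never decreases the likelihood", {
  set.seed(77)
  for (case in 1:50) {
    theta <- runif(1)
    pnew <- runif(1, 0.02, 0.3)
    pbg <- runif(1, 0, pnew / 5)
    h <- random_histogram(500, theta, pnew, pbg)
    fit <- fit_fraction_new(h$n_t, h$k, h$count, pnew, pbg)
    expect_true(all(diff(fit$loglik_trace) > -1e-9))
    grid <- grid_theta_hat(h$n_t, h$k, h$count, pnew, pbg)
    expect_lt(abs(fit$theta - grid), 1e-3)
  }
})

test_that("degenerate and empty histograms are flagged, not fitted", {
  expect_error(fit_fraction_new(2, 1, 10, pnew = 0.05, pbg = 0.05),
               "unidentifiable")
  fit <- fit_fraction_new(c(0, 0), c(0, 0), c(5, 5), pnew = 0.05, pbg = 0.001)
  expect_true(fit$unidentifiable)
  expect_true(is.na(fit$theta))
  expect_error(fit_fraction_new(2, 1, 0, pnew = 0.05, pbg = 0.001),
               "reads")
})

test_that("conversion-rate estimation recovers truth and honors controls", {
  # -s4U control pooled arithmetic: 1000 reads, n_T = 2, 4 conversions
  ctrl <- data.frame(sample_id = "ctrl_rep1", condition = "untreated",
                     replicate = 1, transcript_id = "tx_0001",
                     n_T = 2, k_TC = c(0, 1), n_A = c(100, 100),
                     k_AG = c(0, 0), read_count = c(996, 4),
                     stringsAsFactors = FALSE)
  cfg <- quick_config(n = 30, depth = 2000, seed = 8,
                      class_proportions = c(null = 1))
  tab <- simulate_counts(make_truth(cfg), cfg, "untreated")
  r <- estimate_conversion_rates(tab, no_s4u_table = ctrl)
  expect_equal(r$pbg, 4 / 2000, tolerance = 1e-12)
  expect_equal(r$source, "control")

  # EM recovery within 10% at ~1e5 reads
  r2 <- estimate_conversion_rates(tab)
  expect_lt(abs(r2$pnew - cfg$pnew) / cfg$pnew, 0.10)
  expect_lt(abs(r2$pbg - cfg$pbg) / cfg$pbg, 0.10)

  # pnew == pbg in truth: unidentifiable
  cfg_eq <- quick_config(n = 20, depth = 1000, seed = 9, pnew = 0.002,
                         pbg = 0.002, class_proportions = c(null = 1))
  tab_eq <- simulate_counts(make_truth(cfg_eq), cfg_eq, "untreated")
  expect_error(estimate_conversion_rates(tab_eq), "unidentifiable")
})

test_that("kdeg/half-life inversion round-trips the labeling identity", {
  k <- kdeg_from_theta(0.5, 1)
  expect_equal(k$kdeg, log(2), tolerance = 1e-12)
  expect_equal(k$half_life, 1, tolerance = 1e-12)
  k2 <- kdeg_from_theta(0.75, 2)
  expect_equal(k2$kdeg, log(2), tolerance = 1e-12)
  # round trip theta -> kdeg -> theta, exact to 1e-12
  thetas <- seq(0.01, 0.99, by = 0.01)
  kk <- kdeg_from_theta(thetas, 1.7)
  expect_equal(fraction_new_steady_state(kk$kdeg, 1.7), thetas,
               tolerance = 1e-12)
  # boundaries flagged, not errors
  kb <- kdeg_from_theta(c(0, 1), 1)
  expect_true(all(kb$boundary))
  expect_equal(kb$half_life, c(Inf, 0))
  expect_error(kdeg_from_theta(1.2, 1), "theta")
})

test_that("replicate combination is inverse-variance weighting on logits", {
  est <- data.frame(transcript_id = "t1", sample_id = c("a", "b"),
                    condition = "untreated", replicate = 1:2,
                    theta = c(0.4, 0.6), se_theta = c(0.02, 0.04),
                    logit_theta = qlogis(c(0.4, 0.6)),
                    se_logit = c(0.1, 0.2),
                    loglik = 0, n_reads = c(100, 100),
                    converged = TRUE, unidentifiable = FALSE,
                    stringsAsFactors = FALSE)
  comb <- combine_fraction_new(est)
  w <- 1 / c(0.1, 0.2)^2
  expect_equal(comb$logit_theta,
               sum(w * qlogis(c(0.4, 0.6))) / sum(w), tolerance = 1e-12)
  expect_equal(comb$se_logit, 1 / sqrt(sum(w)), tolerance = 1e-12)
  # an unidentifiable replicate is dropped; all-unidentifiable flags NA
  est$unidentifiable[2] <- TRUE
  comb2 <- combine_fraction_new(est)
  expect_equal(comb2$theta, 0.4, tolerance = 1e-12)
  est$unidentifiable <- TRUE
  comb3 <- combine_fraction_new(est)
  expect_true(comb3$unidentifiable && is.na(comb3$theta))
})

test_that("reported standard errors track the empirical spread", {
  set.seed(123)
  theta <- 0.35; pnew <- 0.05; pbg <- 0.002
  fits <- replicate(200, {
    h <- random_histogram(2000, theta, pnew, pbg)
    f <- fit_fraction_new(h$n_t, h$k, h$count, pnew, pbg)
    c(f$theta, f$se_theta)
  })
  emp_sd <- sd(fits[1, ])
  mean_se <- mean(fits[2, ])
  expect_lt(abs(mean_se - emp_sd) / emp_sd, 0.30)
  expect_lt(median(abs(fits[1, ] - theta)), 0.02)
})

test_that("chemistry QC passes good chemistry and fails broken chemistry", {
  cfg <- quick_config(n = 25, depth = 1500, seed = 14,
                      class_proportions = c(null = 1))
  tr <- make_truth(cfg)
  plus <- simulate_counts(tr, cfg, "untreated")
  ctrl_cfg <- cfg; ctrl_cfg$seed <- 999
  minus <- simulate_counts(tr, ctrl_cfg, "untreated", pnew = cfg$pbg)
  expect_true(qc_conversion_bias(plus, minus)$pass)

  # null chemistry (pnew = pbg in the +s4U sample): T-to-C criterion fails
  null_cfg <- cfg; null_cfg$seed <- 1000
  plus_null <- simulate_counts(tr, null_cfg, "untreated", pnew = cfg$pbg)
  qc2 <- qc_conversion_bias(plus_null, minus)
  expect_false(qc2$tc_pass)
  expect_false(qc2$pass)

  # elevated A-to-G rate in the +s4U sample only: decoy criterion fails
  ag_cfg <- cfg; ag_cfg$seed <- 1001
  plus_ag <- simulate_counts(tr, ag_cfg, "untreated", pag = cfg$pag * 5)
  qc3 <- qc_conversion_bias(plus_ag, minus)
  expect_false(qc3$ag_pass)
})
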