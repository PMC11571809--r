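# Synthetic-data generator: ground truth, kinetic pools, count simulation.

test_that("perturbed_pools matches the closed-form special cases", {
  # unperturbed steady state: theta = 1 - exp(-kdeg * t)
  p <- perturbed_pools(1, 2, 2, 1, 1)
  expect_equal(p$theta, 1 - exp(-2), tolerance = 1e-12)
  # stabilization: total rises while theta falls
  p <- perturbed_pools(1, 2, 0.2, 1, 1)
  expect_equal(p$old, 0.4093654, tolerance = 1e-6)
  expect_equal(p$new, 0.9063462, tolerance = 1e-6)
  expect_equal(p$theta, 0.6888639, tolerance = 1e-6)
  expect_gt(p$new + p$old, 0.5)                     # above steady state 0.5
  # synthesis induction: theta rises above steady state
  p <- perturbed_pools(1, 1, 1, 4, 1)
  expect_equal(p$old, exp(-1), tolerance = 1e-9)
  expect_equal(p$theta, 0.8729857, tolerance = 1e-6)
  expect_gt(p$theta, 1 - exp(-1))
  expect_error(perturbed_pools(1, -2, 1, 1, 1), "rates")
})

test_that("perturbed_pools agrees with numerical ODE integration", {
  set.seed(101)
  ksyn <- runif(100, 0.1, 10); kd_old <- runif(100, 0.05, 5)
  kd_new <- runif(100, 0.05, 5); ks_new <- runif(100, 0.1, 10)
  t_end <- runif(100, 0.1, 4)
  num <- rk4_pools(ksyn, kd_old, kd_new, ks_new, t_end)
  cf <- perturbed_pools(ksyn, kd_old, kd_new, ks_new, t_end)
  max_rel <- max(abs(cf$old - num$old) / num$old,
                 abs(cf$new - num$new) / num$new)
  expect_lt(max_rel, 1e-8)

  # secondary route: adaptive lsoda at its practical accuracy
  skip_if_not_installed("deSolve")
  for (i in sample(100, 5)) {
    sol <- deSolve::lsoda(
      y = c(old = ksyn[i] / kd_old[i], new = 0),
      times = c(0, t_end[i]),
      func = function(t, y, p) {
        list(c(-p["kd"] * y["old"], p["ks"] - p["kd"] * y["new"]))
      },
      parms = c(kd = kd_new[i], ks = ks_new[i]),
      rtol = 1e-11, atol = 1e-14)
    expect_equal(unname(sol[2, c("old", "new")]),
                 c(num$old[i], num$new[i]), tolerance = 1e-7)
  }
})

test_that("theta is monotone in the perturbation factors", {
  kd <- 0.8; ks <- 2; t <- 1
  kdeg_factors <- c(0.1, 0.3, 1, 3, 10)
  th_kd <- perturbed_pools(ks, kd, kd * kdeg_factors, ks, t)$theta
  expect_true(all(diff(th_kd) > 0))   # faster decay -> higher fraction new
  ksyn_factors <- c(0.2, 0.5, 1, 2, 5)
  th_ks <- perturbed_pools(ks, kd, kd, ks * ksyn_factors, t)$theta
  expect_true(all(diff(th_ks) > 0))
})

test_that("make_truth respects class structure and determinism", {
  cfg_null <- quick_config(n = 30, class_proportions = c(null = 1))
  tr <- make_truth(cfg_null)
  expect_equal(nrow(tr), 30)
  expect_true(all(tr$ksyn_factor == 1 & tr$kdeg_factor == 1))
  expect_true(all(tr$kdeg > 0 & tr$ksyn > 0))
  expect_true(all(nchar(tr$cds) %% 3 == 0))
  expect_true(all(tr$u_freq > 0 & tr$u_freq < 1))
  # determinism
  expect_identical(tr, make_truth(cfg_null))

  # binomial sampling of class counts: within 3 SD of n * p
  cfg <- sim_config(n_transcripts = 1000,
                    class_proportions = c(null = 0.9, stabilized = 0.1),
                    seed = 9)
  tr2 <- make_truth(cfg)
  n_stab <- sum(tr2$class_label == "stabilized")
  expect_lt(abs(n_stab - 100), 3 * sqrt(1000 * 0.1 * 0.9))
  expect_true(all(tr2$kdeg_factor[tr2$class_label == "stabilized"] < 1))

  # config validation
  expect_error(sim_config(class_proportions = c(null = 0.5)), "sum to 1")
  expect_error(
    sim_config(class_proportions = c(null = 0.5, stabilized = 0.5),
               effect_size_ranges = list()),
    "effect_size_ranges")
})

test_that("stabilized-class CDSs are enriched in suboptimal codons", {
  cfg <- sim_config(n_transcripts = 200,
                    class_proportions = c(null = 0.5, stabilized = 0.5),
                    seed = 4)
  tr <- make_truth(cfg)
  csc <- default_csc()
  stats <- codon_stats_table(setNames(tr$cds, tr$transcript_id), csc)
  spkb <- split(stats$subopt_per_kb, tr$class_label)
  expect_gt(median(spkb$stabilized), median(spkb$null))
  # Cys/His codons overrepresented in the stabilized class
  cnts <- attr(stats, "codon_counts")
  enr <- codon_enrichment(colSums(cnts[tr$class_label == "stabilized", ]),
                          colSums(cnts))
  expect_true(all(enr[c("TGT", "TGC", "CAT", "CAC")] > 1))
})

test_that("simulate_counts obeys its sampling contracts", {
  cfg <- quick_config(n = 25, depth = 400, seed = 12,
                      class_proportions = c(null = 1))
  tr <- make_truth(cfg)
  tab <- simulate_counts(tr, cfg, "untreated")
  expect_identical(tab, simulate_counts(tr, cfg, "untreated"))
  expect_true(all(tab$k_TC <= tab$n_T))
  expect_true(all(tab$k_AG <= tab$n_A))

  # total reads ~ Poisson sum: n * depth + spikes, within 3 SE
  tot <- sum(tab$read_count[!grepl("^spike", tab$transcript_id)])
  expected <- 25 * 400 * cfg$n_reps
  expect_lt(abs(tot - expected), 3 * sqrt(expected) + 0.1 * expected)
  spike_tot <- sum(tab$read_count[grepl("^spike", tab$transcript_id)])
  expect_lt(abs(spike_tot - 4 * 300 * 2), 3 * sqrt(4 * 300 * 2) + 50)

  # pbg = 0 and theta ~ 1: zero-conversion fraction of n_T = 2 reads is
  # (1 - pnew)^2
  cfg1 <- sim_config(n_transcripts = 5, depth_per_transcript = 20000,
                     half_life_range = c(0.03, 0.035),   # theta ~ 1
                     pbg = 0, pnew = 0.3, n_spikes = 0, seed = 3,
                     class_proportions = c(null = 1))
  tr1 <- make_truth(cfg1)
  tr1$u_freq <- 0.02                                  # makes n_T = 2 common
  tab1 <- simulate_counts(tr1, cfg1, "untreated")
  two <- tab1[tab1$n_T == 2, ]
  n2 <- sum(two$read_count)
  frac0 <- sum(two$read_count[two$k_TC == 0]) / n2
  p0 <- (1 - 0.3)^2
  expect_lt(abs(frac0 - p0), 3 * sqrt(p0 * (1 - p0) / n2))
})

test_that("simulate_ribo shifts disome ratios by the configured factor", {
  base <- quick_config(n = 400, seed = 21,
                       class_proportions = c(null = 0.5, stabilized = 0.5),
                       ribo_depth = 3000)
  # null inflation: classes indistinguishable
  cfg0 <- base; cfg0$disome_inflation <- c(stabilized = 1)
  tr <- make_truth(cfg0)
  rb0 <- simulate_ribo(tr, cfg0)
  lr0 <- disome_monosome(rb0$disome, rb0$monosome, c(1, 1), pseudocount = 0.5)
  d0 <- mean(lr0[rb0$class_label == "stabilized"]) -
    mean(lr0[rb0$class_label == "null"])
  expect_lt(abs(d0), 0.1)
  # inflation 2: ~1 log2 unit shift
  rb2 <- simulate_ribo(tr, base)
  lr2 <- disome_monosome(rb2$disome, rb2$monosome, c(1, 1), pseudocount = 0.5)
  d2 <- mean(lr2[rb2$class_label == "stabilized"]) -
    mean(lr2[rb2$class_label == "null"])
  expect_lt(abs(d2 - 1), 0.15)
})

test_that("simulate_qpcr follows the Ct model exactly at zero noise", {
  cfg <- quick_config(n = 10, seed = 30, qpcr_noise_sd = 0,
                      class_proportions = c(null = 0.5,
                                            synthesis_induced = 0.5),
                      effect_size_ranges = list(synthesis_induced = c(2, 2)),
                      half_life_range = c(0.02, 0.03))  # fast equilibration
  tr <- make_truth(cfg)
  ct <- simulate_qpcr(tr, cfg)
  # controls identical across conditions
  ctrl <- ct[ct$target %in% c("18S", "U2"), ]
  for (tg in c("18S", "U2")) {
    expect_equal(unique(ct$Ct[ct$target == tg]), ct$Ct[ct$target == tg][1])
  }
  # doubled abundance -> Ct lower by ~1 cycle (exact at steady state)
  syn <- tr$transcript_id[tr$class_label == "synthesis_induced"][1]
  d <- mean(ct$Ct[ct$target == syn & ct$condition == "untreated"]) -
    mean(ct$Ct[ct$target == syn & ct$condition == "treated"])
  expect_equal(d, 1, tolerance = 1e-6)
  # ddct of controls against each other is 1
  folds <- ddct(ct, targets = "18S", controls = "U2")
  expect_equal(folds$fold_change, 1, tolerance = 1e-9)
})
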