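# Differential statistics: fraction-new score, DE, decay lfc, mechanism.

make_combined <- function(ids, theta, se_logit, condition) {
  data.frame(transcript_id = ids, condition = condition, theta = theta,
             logit_theta = qlogis(theta), se_logit = se_logit,
             n_reads = 1000, n_reps = 2, unidentifiable = FALSE,
             stringsAsFactors = FALSE)
}

test_that("fraction_new_score is zero under the null and antisymmetric", {
  u <- make_combined(c("a", "b"), c(0.3, 0.6), c(0.1, 0.1), "untreated")
  t1 <- make_combined(c("a", "b"), c(0.3, 0.6), c(0.1, 0.1), "treated")
  fn <- fraction_new_score(u, t1)
  expect_equal(fn$z_fn, c(0, 0))
  t2 <- make_combined(c("a", "b"), c(0.2, 0.8), c(0.15, 0.05), "treated")
  fwd <- fraction_new_score(u, t2)
  rev <- fraction_new_score(t2, u)
  expect_equal(fwd$z_fn, -rev$z_fn, tolerance = 1e-12)
  expect_lt(fwd$z_fn[1], 0)      # theta fell
  expect_gt(fwd$z_fn[2], 0)      # theta rose
  # unidentifiable propagates NA
  u$unidentifiable[1] <- TRUE
  fn_na <- fraction_new_score(u, t2)
  expect_true(is.na(fn_na$z_fn[fn_na$transcript_id == "a"]))
})

test_that("differential expression handles nulls, doublings and spike-ins", {
  set.seed(5)
  base <- matrix(rpois(200 * 4, 300), nrow = 200,
                 dimnames = list(sprintf("t%03d", 1:200),
                                 c("untreated_rep1", "untreated_rep2",
                                   "treated_rep1", "treated_rep2")))
  cond <- c("untreated", "untreated", "treated", "treated")

  # identical conditions: all lfc and z are 0
  same <- cbind(base[, 1:2], base[, 1:2])
  colnames(same) <- colnames(base)
  de0 <- differential_expression(same, cond)
  expect_true(all(de0$lfc == 0))
  expect_true(all(de0$z_de == 0))

  # every treated count doubled, constant spike-ins, spike normalization:
  # lfc exactly 1 for every non-spike transcript
  doubled <- base
  doubled[, 3:4] <- base[, 1:2] * 2
  spikes <- matrix(500, nrow = 5, ncol = 4,
                   dimnames = list(sprintf("spike_%02d", 1:5),
                                   colnames(base)))
  m <- rbind(doubled, spikes)
  de_sp <- differential_expression(m, cond, spike_rows = rownames(spikes))
  expect_equal(attr(de_sp, "size_factors"), setNames(rep(1, 4),
               colnames(base)), tolerance = 1e-12)
  expect_equal(de_sp$lfc[!de_sp$is_spike], rep(1, 200), tolerance = 1e-12)

  # same doubling under median-of-ratios: the global shift is absorbed
  # into size factors and lfc collapses to 0
  de_mr <- differential_expression(doubled, cond)
  expect_equal(de_mr$lfc, rep(0, 200), tolerance = 1e-12)

  # all-zero rows flagged, excluded from adjustment
  withz <- rbind(doubled, zero_tx = c(0, 0, 0, 0))
  de_z <- differential_expression(withz, cond)
  expect_true(de_z$low_expression[de_z$transcript_id == "zero_tx"])
  expect_true(is.na(de_z$padj_de[de_z$transcript_id == "zero_tx"]))

  expect_error(differential_expression(doubled, cond[1:3]))
  expect_error(
    differential_expression(rbind(doubled, spikes * 0), cond,
                            spike_rows = rownames(spikes)),
    "zero")
})

test_that("decay_lfc inverts the forward model and is monotone", {
  # matches the simulator's stabilization example: kdeg 2 -> 0.2
  d <- decay_lfc(1 - exp(-2), 0.6888639, 1)
  expect_equal(d$kdeg_treated, 0.2, tolerance = 1e-4)
  expect_equal(d$lfc_kdeg, log2(0.2 / 2), tolerance = 1e-3)
  expect_false(d$fallback)
  # no change
  d0 <- decay_lfc(0.6, 0.6, 1)
  expect_equal(d0$lfc_kdeg, 0, tolerance = 1e-9)
  # strictly increasing in theta_treated over the model-invertible range
  # (theta_untreated = 0.7 bounds theta_treated above ~0.546 as kdeg -> 0)
  grid <- seq(0.58, 0.95, by = 0.02)
  lf <- decay_lfc(rep(0.7, length(grid)), grid, 1)$lfc_kdeg
  expect_true(all(diff(lf) > 0))
  # below the reachable range: naive fallback, flagged
  lim <- 1 * 0.5 / (1 + 1 * 0.5)    # kd = 0.5, t = 1
  d_fb <- decay_lfc(fraction_new_steady_state(0.5, 1), lim * 0.9, 1)
  expect_true(d_fb$fallback)
  expect_true(is.finite(d_fb$lfc_kdeg))
  # boundary thetas give NA
  expect_true(is.na(decay_lfc(0, 0.5, 1)$lfc_kdeg))
})

test_that("mechanism score separates synthesis- from decay-driven changes", {
  t_label <- 1
  # pure synthesis x4 at kdeg = 1: observed == expected, mech ~ 0
  th_u <- 1 - exp(-1)
  pools <- perturbed_pools(1, 1, 1, 4, 1)
  lfc <- log2((pools$new + pools$old) / 1)
  delta <- qlogis(pools$theta) - qlogis(th_u)
  m_syn <- mechanism_score(delta, se_pooled = 0.05, lfc, th_u, t_label)
  expect_lt(abs(m_syn), 1e-6)

  # pure stabilization /10 at kdeg = 2: strongly negative
  th_u2 <- 1 - exp(-2)
  pools2 <- perturbed_pools(1, 2, 0.2, 1, 1)
  lfc2 <- log2((pools2$new + pools2$old) / 0.5)
  delta2 <- qlogis(pools2$theta) - qlogis(th_u2)
  m_stab <- mechanism_score(delta2, 0.05, lfc2, th_u2, t_label)
  expect_lt(m_stab, -10)

  # pure destabilization x5 at kdeg = 0.5: strongly positive
  pools3 <- perturbed_pools(1, 0.5, 2.5, 1, 1)
  th_u3 <- 1 - exp(-0.5)
  lfc3 <- log2((pools3$new + pools3$old) / 2)
  delta3 <- qlogis(pools3$theta) - qlogis(th_u3)
  m_destab <- mechanism_score(delta3, 0.05, lfc3, th_u3, t_label)
  expect_gt(m_destab, 10)

  # null: no change anywhere scores exactly 0
  expect_equal(mechanism_score(0, 0.05, 0, 0.5, 1), 0)
  # NA propagation
  expect_true(is.na(mechanism_score(NA, 0.05, 1, 0.5, 1)))
})

test_that("tl_dynamics detects a stabilized transcript end to end", {
  cfg <- quick_config(n = 60, depth = 4000, seed = 2,
                      class_proportions = c(null = 0.9, stabilized = 0.1))
  tr <- make_truth(cfg)
  tab <- rbind(simulate_counts(tr, cfg, "untreated"),
               simulate_counts(tr, cfg, "treated"))
  dyn <- tl_dynamics(tab, t_label = 1)
  res <- merge(dyn$results,
               tr[, c("transcript_id", "class_label")], by = "transcript_id")
  stab <- res[res$class_label == "stabilized", ]
  # stabilized transcripts are short-lived and hence low-abundance, so
  # coverage varies widely; direction must hold everywhere, significance
  # wherever coverage is adequate
  expect_true(all(stab$z_fn < 0))
  expect_true(all(stab$lfc > 0))
  expect_true(all(stab$mech < 0))
  cnt <- conversion_count_matrix(tab)
  reads_u <- rowSums(cnt[stab$transcript_id,
                         grep("untreated", colnames(cnt)), drop = FALSE])
  expect_true(all(stab$padj_fn[reads_u >= 1000] < 0.01))
  expect_true(all(stab$lfc_kdeg < 0, na.rm = TRUE))
  # spike-ins carry no test results
  sp <- dyn$results[dyn$results$is_spike, ]
  expect_gt(nrow(sp), 0)
  expect_true(all(is.na(sp$padj_de)))
})
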