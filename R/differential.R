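# Differential statistics: fraction-new score, expression z-score,
# decay-rate fold change, and the kinetic mechanism score.

#' Fraction new score between conditions
#'
#' Signed z statistic for the change in fraction new:
#' `z_fn = (logit theta_treated - logit theta_untreated) / pooled SE`,
#' negative when treatment lowers the labeled fraction (decreased ratio of
#' labeled to unlabeled reads). Two-sided p-values, Benjamini-Hochberg
#' adjusted across transcripts.
#'
#' @param combined_untreated,combined_treated Per-condition outputs of
#'   [combine_fraction_new()].
#' @return data.frame per transcript: `theta_untreated`, `theta_treated`,
#'   `delta_logit`, `se_pooled`, `z_fn`, `p_fn`, `padj_fn`. Transcripts
#'   unidentifiable in either condition carry NA.
#' @export
fraction_new_score <- function(combined_untreated, combined_treated) {
  m <- merge(combined_untreated, combined_treated, by = "transcript_id",
             suffixes = c("_u", "_t"))
  bad <- m$unidentifiable_u | m$unidentifiable_t
  delta <- m$logit_theta_t - m$logit_theta_u
  se <- sqrt(m$se_logit_u^2 + m$se_logit_t^2)
  z <- delta / se
  z[bad] <- NA_real_
  p <- 2 * pnorm(-abs(z))
  padj <- p.adjust(p, method = "BH")
  data.frame(transcript_id = m$transcript_id,
             theta_untreated = m$theta_u, theta_treated = m$theta_t,
             delta_logit = ifelse(bad, NA_real_, delta),
             se_pooled = ifelse(bad, NA_real_, se),
             z_fn = z, p_fn = p, padj_fn = padj,
             stringsAsFactors = FALSE)
}

# Median-of-ratios size factors (optionally restricted to spike-in rows),
# scaled to geometric mean 1 so normalized counts stay on the data scale.
.size_factors <- function(counts, rows = NULL) {
  ref <- if (is.null(rows)) counts else counts[rows, , drop = FALSE]
  pos <- rowSums(ref == 0) == 0
  if (!any(pos)) stop("no rows with all-positive counts for size factors")
  lg <- rowMeans(log(ref[pos, , drop = FALSE]))
  sf <- apply(ref[pos, , drop = FALSE], 2, function(col) {
    exp(median(log(col) - lg))
  })
  if (any(!is.finite(sf) | sf <= 0)) stop("size factors must be positive")
  sf / exp(mean(log(sf)))
}

#' Differential expression with variance shrinkage
#'
#' Log-normal Wald test on log2 normalized counts. Size factors are
#' median-of-ratios over all transcripts, or over spike-in rows only when
#' `spike_rows` is supplied (appropriate when a global abundance shift,
#' e.g. widespread stabilization, must not be absorbed into normalization).
#' Per-transcript variances are shrunk toward a mean-variance trend over
#' expression strata with `prior_df` pseudo-degrees of freedom. The
#' reported `lfc` is `log2(mean treated / mean untreated)` of normalized
#' counts (so a clean doubling yields exactly 1 under spike-in
#' normalization).
#'
#' @param counts Integer matrix, transcripts x samples, with rownames.
#' @param condition Character/factor per column, values in
#'   `{untreated, treated}`.
#' @param spike_rows Optional rownames (or logical/integer index) of
#'   spike-in rows. Spike rows are always excluded from testing and
#'   multiplicity adjustment; under `normalization = "spike-in"` they are
#'   also the sole basis of the size factors.
#' @param normalization `"spike-in"` (default when `spike_rows` is given)
#'   or `"median-ratios"` over the non-spike rows.
#' @param prior_df Prior degrees of freedom for the variance trend.
#' @param n_bins Expression strata for the trend.
#' @return data.frame per transcript: `base_mean`, `lfc`, `z_de`, `p_de`,
#'   `padj_de`, `low_expression`, `is_spike`; size factors in
#'   `attr(, "size_factors")`.
#' @export
differential_expression <- function(counts, condition, spike_rows = NULL,
                                    normalization = if (is.null(spike_rows))
                                      "median-ratios" else "spike-in",
                                    prior_df = 10, n_bins = 10) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have rownames")
  if (any(counts < 0)) stop("counts must be nonnegative")
  condition <- as.character(condition)
  if (!all(condition %in% c("untreated", "treated"))) {
    stop("condition values must be 'untreated' or 'treated'")
  }
  iu <- which(condition == "untreated")
  it <- which(condition == "treated")
  if (length(iu) < 2 || length(it) < 2) {
    stop("need >= 2 replicates per condition for variance estimation")
  }
  normalization <- match.arg(normalization,
                             c("median-ratios", "spike-in"))
  is_spike <- rep(FALSE, nrow(counts))
  if (!is.null(spike_rows)) {
    if (is.character(spike_rows)) {
      is_spike <- rownames(counts) %in% spike_rows
    } else {
      is_spike[spike_rows] <- TRUE
    }
    if (!any(is_spike)) stop("spike_rows match no rows")
  }
  if (normalization == "spike-in") {
    if (!any(is_spike)) stop("spike-in normalization requires spike_rows")
    if (all(counts[is_spike, ] == 0)) {
      stop("spike-in rows are all zero; cannot normalize")
    }
    sf <- .size_factors(counts, which(is_spike))
  } else {
    sf <- .size_factors(counts, if (any(is_spike)) which(!is_spike))
  }
  norm <- sweep(counts, 2, sf, "/")
  low <- rowSums(counts) == 0

  m_u <- rowMeans(norm[, iu, drop = FALSE])
  m_t <- rowMeans(norm[, it, drop = FALSE])
  lfc <- ifelse(m_u > 0 & m_t > 0, log2(m_t / m_u),
                log2((m_t + 0.5) / (m_u + 0.5)))

  y <- log2(norm + 0.5)
  res_u <- y[, iu, drop = FALSE] - rowMeans(y[, iu, drop = FALSE])
  res_t <- y[, it, drop = FALSE] - rowMeans(y[, it, drop = FALSE])
  df <- length(iu) + length(it) - 2
  s2 <- (rowSums(res_u^2) + rowSums(res_t^2)) / df
  base_mean <- rowMeans(norm)

  # mean-variance trend over expression strata
  usable <- !low & !is_spike
  trend <- rep(NA_real_, nrow(counts))
  if (sum(usable) >= 2) {
    nb <- max(1, min(n_bins, floor(sum(usable) / 5)))
    br <- unique(quantile(base_mean[usable], probs = seq(0, 1, length.out = nb + 1)))
    bin <- cut(base_mean[usable], breaks = br, include.lowest = TRUE)
    bin_mean <- tapply(s2[usable], bin, mean)
    trend[usable] <- bin_mean[as.character(bin)]
  }
  trend[is.na(trend)] <- mean(s2[usable])
  s2_shrunk <- (df * s2 + prior_df * trend) / (df + prior_df)
  se <- sqrt(s2_shrunk * (1 / length(iu) + 1 / length(it)))
  dy <- rowMeans(y[, it, drop = FALSE]) - rowMeans(y[, iu, drop = FALSE])
  z <- ifelse(se > 0, dy / se, 0)
  z[low | is_spike] <- NA_real_
  lfc[low] <- NA_real_
  p <- 2 * pnorm(-abs(z))
  padj <- rep(NA_real_, length(p))
  test_idx <- which(!low & !is_spike)
  padj[test_idx] <- p.adjust(p[test_idx], method = "BH")
  out <- data.frame(transcript_id = rownames(counts),
                    base_mean = base_mean, lfc = lfc, z_de = z,
                    p_de = p, padj_de = padj,
                    low_expression = low, is_spike = is_spike,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "size_factors") <- sf
  out
}

# theta(t_label) as a function of the post-perturbation decay rate, given
# the untreated decay rate; synthesis rate cancels.
.theta_given_kdeg_new <- function(kdeg_new, kdeg_old, t) {
  a <- -expm1(-kdeg_new * t) / kdeg_new      # new pool / ksyn
  b <- exp(-kdeg_new * t) / kdeg_old         # old pool / ksyn
  a / (a + b)
}

#' Decay-rate log2 fold change from the kinetic model
#'
#' Solves the non-steady-state forward model for the post-perturbation
#' decay rate: given the untreated rate (from `theta_untreated`), find
#' `kdeg_new` such that the model's fraction new at `t_label` equals
#' `theta_treated`, then report `log2(kdeg_new / kdeg_untreated)`.
#' Negative values mean stabilization. When `theta_treated` lies below the
#' model's reachable range (old RNA alone bounds theta away from 0), the
#' naive steady-state inversion is used instead and flagged.
#'
#' @param theta_untreated,theta_treated Fractions new per transcript.
#' @param t_label Labeling duration (h).
#' @return data.frame: `kdeg_untreated`, `kdeg_treated`, `lfc_kdeg`,
#'   `fallback`. Boundary thetas give NA.
#' @export
#' @examples
#' decay_lfc(1 - exp(-2), 0.6889, 1)   # recovers kdeg_new ~ 0.2
decay_lfc <- function(theta_untreated, theta_treated, t_label) {
  stopifnot(length(theta_untreated) == length(theta_treated), t_label > 0)
  n <- length(theta_untreated)
  kd_u <- kd_t <- rep(NA_real_, n)
  fallback <- rep(FALSE, n)
  for (i in seq_len(n)) {
    tu <- theta_untreated[i]; tt <- theta_treated[i]
    if (is.na(tu) || is.na(tt) || tu <= 0 || tu >= 1 || tt <= 0 || tt >= 1) {
      next
    }
    kd <- -log1p(-tu) / t_label
    kd_u[i] <- kd
    if (abs(tt - tu) < 1e-12) {
      kd_t[i] <- kd
      next
    }
    lower_lim <- t_label * kd / (1 + t_label * kd)   # kdeg_new -> 0 limit
    if (tt <= lower_lim * (1 + 1e-9)) {
      kd_t[i] <- -log1p(-tt) / t_label               # naive inversion
      fallback[i] <- TRUE
      next
    }
    f <- function(lx) .theta_given_kdeg_new(exp(lx), kd, t_label) - tt
    sol <- tryCatch(
      uniroot(f, lower = log(1e-8), upper = log(1e4), tol = 1e-12),
      error = function(e) NULL)
    if (is.null(sol)) {
      kd_t[i] <- -log1p(-tt) / t_label
      fallback[i] <- TRUE
    } else {
      kd_t[i] <- exp(sol$root)
    }
  }
  data.frame(kdeg_untreated = kd_u, kdeg_treated = kd_t,
             lfc_kdeg = log2(kd_t / kd_u), fallback = fallback)
}

#' Mechanism score: is an expression change synthesis- or decay-driven?
#'
#' Under a pure synthesis step change (decay untouched), an observed
#' expression fold change `2^lfc` pins down the synthesis multiplier
#' `f = (2^lfc - e^{-kdeg t}) / (1 - e^{-kdeg t})` and hence an expected
#' fraction new `theta_exp = f(1-E) / (f(1-E) + E)` with `E = e^{-kdeg t}`.
#' The mechanism score is the standardized residual
#' `(observed delta logit theta - expected delta logit theta) / SE`:
#' approximately standard normal when synthesis alone explains the change,
#' strongly negative for stabilization (theta falls while abundance rises),
#' strongly positive for destabilization. The sign is the contract; the
#' magnitude is diagnostic.
#'
#' @param delta_logit Observed `logit theta_treated - logit theta_untreated`.
#' @param se_pooled Standard error of `delta_logit` (from
#'   [fraction_new_score()]).
#' @param lfc Observed expression log2 fold change.
#' @param theta_untreated Untreated fraction new (fixes `kdeg`).
#' @param t_label Labeling duration (h).
#' @param f_min Floor for the implied synthesis multiplier when the
#'   observed fold change is below what shutting synthesis off entirely
#'   could produce.
#' @return Numeric vector of mechanism scores; NA inputs propagate.
#' @export
mechanism_score <- function(delta_logit, se_pooled, lfc, theta_untreated,
                            t_label, f_min = 1e-6) {
  stopifnot(t_label > 0)
  E <- 1 - theta_untreated
  f <- (2^lfc - E) / pmax(theta_untreated, .Machine$double.eps)
  f <- pmax(f, f_min)
  theta_exp <- f * theta_untreated / (f * theta_untreated + E)
  expected <- qlogis(theta_exp) - qlogis(theta_untreated)
  ok <- !is.na(delta_logit) & !is.na(se_pooled) & se_pooled > 0 &
    !is.na(lfc) & !is.na(theta_untreated) &
    theta_untreated > 0 & theta_untreated < 1
  out <- rep(NA_real_, length(delta_logit))
  out[ok] <- (delta_logit[ok] - expected[ok]) / se_pooled[ok]
  out
}

#' Fit transcript dynamics from a conversion-count table
#'
#' The package's central estimator. From a conversion-count table covering
#' both conditions it (1) estimates global conversion rates (unless given),
#' (2) fits the fraction new per transcript x replicate and combines
#' replicates per condition, (3) computes the fraction new score, (4) runs
#' differential expression on total read counts, (5) converts fractions to
#' decay rates, half-lives, and the decay-rate fold change, and (6) scores
#' the mechanism of each change.
#'
#' @param table Conversion-count data.frame with both conditions.
#' @param t_label Labeling duration (h).
#' @param pnew,pbg Optional known conversion rates; estimated by
#'   [estimate_conversion_rates()] when NULL.
#' @param no_s4u_table Optional -s4U control passed to rate estimation.
#' @param normalization `"median-ratios"` (default) or `"spike-in"`.
#' @param spike_pattern Regular expression identifying spike-in transcript
#'   ids.
#' @return Object of class `tl_dynamics`: a list with `results` (the
#'   per-transcript table), `estimates` (per replicate), `combined` (per
#'   condition), `pnew`, `pbg`, `t_label`, `normalization`,
#'   `size_factors`, `counts`.
#' @seealso [classify_transcripts()], [run_pipeline()]
#' @export
tl_dynamics <- function(table, t_label, pnew = NULL, pbg = NULL,
                        no_s4u_table = NULL,
                        normalization = c("median-ratios", "spike-in"),
                        spike_pattern = "^(spike|ERCC)") {
  normalization <- match.arg(normalization)
  .validate_conversion_table(table)
  if (is.null(pnew) || is.null(pbg)) {
    rates <- estimate_conversion_rates(table, no_s4u_table)
    pnew <- rates$pnew
    pbg <- rates$pbg
  }
  est <- estimate_fraction_new(table, pnew, pbg)
  comb <- combine_fraction_new(est)
  comb_u <- comb[comb$condition == "untreated", ]
  comb_t <- comb[comb$condition == "treated", ]
  fn <- fraction_new_score(comb_u, comb_t)

  counts <- conversion_count_matrix(table)
  cond <- sub("_rep[0-9]+$", "", colnames(counts))
  spike_ids <- grep(spike_pattern, rownames(counts), value = TRUE)
  de <- differential_expression(
    counts, cond,
    spike_rows = if (length(spike_ids)) spike_ids else NULL,
    normalization = normalization)

  res <- merge(fn, de, by = "transcript_id", all = TRUE)
  kin <- kdeg_from_theta(ifelse(is.na(res$theta_untreated), NA_real_,
                                res$theta_untreated), t_label)
  res$kdeg_untreated <- kin$kdeg
  res$half_life <- kin$half_life
  dl <- decay_lfc(res$theta_untreated, res$theta_treated, t_label)
  res$kdeg_treated <- dl$kdeg_treated
  res$lfc_kdeg <- dl$lfc_kdeg
  res$lfc_kdeg_fallback <- dl$fallback
  res$mech <- mechanism_score(res$delta_logit, res$se_pooled, res$lfc,
                              res$theta_untreated, t_label)
  res <- res[order(res$transcript_id), ]
  rownames(res) <- NULL
  out <- list(results = res, estimates = est, combined = comb,
              pnew = pnew, pbg = pbg, t_label = t_label,
              normalization = normalization,
              size_factors = attr(de, "size_factors"),
              counts = counts)
  class(out) <- "tl_dynamics"
  out
}

#' Total read counts per transcript x sample
#'
#' @param table Conversion-count table.
#' @return Integer matrix, transcripts x samples.
#' @export
conversion_count_matrix <- function(table) {
  tapply_sum <- tapply(table$read_count,
                       list(table$transcript_id, table$sample_id),
                       sum, default = 0)
  m <- as.matrix(tapply_sum)
  storage.mode(m) <- "numeric"
  m
}

#' @export
print.tl_dynamics <- function(x, ...) {
  r <- x$results
  cat("Transcript dynamics fit (tlkinetics)\n")
  cat(sprintf("  %d transcripts, t_label = %g h, pnew = %.4g, pbg = %.4g, %s normalization\n",
              nrow(r), x$t_label, x$pnew, x$pbg, x$normalization))
  cat(sprintf("  significant fraction-new changes (padj < 0.01): %d\n",
              sum(r$padj_fn < 0.01, na.rm = TRUE)))
  cat(sprintf("  significant expression changes   (padj < 0.01): %d\n",
              sum(r$padj_de < 0.01, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.tl_dynamics <- function(object, ...) {
  r <- object$results
  out <- list(
    n = nrow(r),
    pnew = object$pnew, pbg = object$pbg,
    median_half_life = median(r$half_life[is.finite(r$half_life)], na.rm = TRUE),
    n_sig_fn = sum(r$padj_fn < 0.01, na.rm = TRUE),
    n_sig_de = sum(r$padj_de < 0.01, na.rm = TRUE),
    n_stab_candidates = sum(r$padj_fn < 0.01 & r$z_fn < 0 & r$lfc > 0,
                            na.rm = TRUE))
  class(out) <- "summary.tl_dynamics"
  out
}

#' @export
print.summary.tl_dynamics <- function(x, ...) {
  cat("tl_dynamics summary\n")
  cat(sprintf("  transcripts: %d; median untreated half-life: %.2f h\n",
              x$n, x$median_half_life))
  cat(sprintf("  conversion rates: pnew %.4g, pbg %.4g\n", x$pnew, x$pbg))
  cat(sprintf("  padj < 0.01: fraction-new %d, expression %d; decay-driven increase candidates %d\n",
              x$n_sig_fn, x$n_sig_de, x$n_stab_candidates))
  invisible(x)
}

#' @export
as.data.frame.tl_dynamics <- function(x, ...) x$results

#' Volcano-style plot of a dynamics fit
#'
#' Expression log2 fold change against -log10 adjusted p-value; decay-driven
#' increase candidates (significant fraction-new drop with rising abundance)
#' are highlighted.
#'
#' @param x A `tl_dynamics` object.
#' @param padj_cutoff Highlight threshold.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.tl_dynamics <- function(x, padj_cutoff = 0.01, ...) {
  r <- x$results[!is.na(x$results$lfc) & !is.na(x$results$padj_de), ]
  plot(r$lfc, -log10(pmax(r$padj_de, 1e-300)),
       xlab = "log2 fold change (treated/untreated)",
       ylab = "-log10 adjusted p", pch = 16, cex = 0.5,
       col = "grey50", ...)
  hl <- !is.na(r$padj_fn) & r$padj_fn < padj_cutoff & r$z_fn < 0 & r$lfc > 0
  points(r$lfc[hl], -log10(pmax(r$padj_de[hl], 1e-300)),
         pch = 16, cex = 0.6, col = "dodgerblue3")
  abline(v = c(-1, 1), lty = 3)
  invisible(x)
}
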