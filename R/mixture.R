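# Two-component binomial mixture for the fraction of new (labeled) reads.
#
# Per read with n Ts and k T-to-C conversions:
#   L(theta) = prod_bins [ theta * Binom(k; n, pnew)
#                        + (1 - theta) * Binom(k; n, pbg) ] ^ count
# Reads with n_T = 0 carry no label information and are excluded from the
# likelihood (they still count toward expression totals).

#' Fit the fraction of new reads for one transcript x sample histogram
#'
#' Maximum-likelihood estimate of theta in the two-component binomial
#' mixture via EM, with standard error from the observed Fisher
#' information. When theta sits at a boundary the logit-scale standard
#' error uses a Jeffreys-style adjustment (half a pseudo-read added to each
#' component).
#'
#' @param n_t Integer vector: T positions per read for each histogram bin.
#' @param k_tc Integer vector: T-to-C conversions per read for each bin.
#' @param count Read count per bin.
#' @param pnew,pbg Conversion probabilities in new / old reads
#'   (`pbg < pnew` required).
#' @param tol Convergence tolerance on theta.
#' @param max_iter Maximum EM iterations.
#' @return An object of class `fn_fit` with elements `theta`, `se_theta`,
#'   `se_logit`, `theta_adj`, `logit_theta`, `loglik`, `loglik_trace`,
#'   `n_reads`, `n_informative`, `pnew`, `pbg`, `converged`,
#'   `unidentifiable`, `iterations`.
#' @export
#' @examples
#' # pbg = 0: converted reads are certainly new; new reads convert with
#' # probability 1 - (1 - 0.5)^2 = 0.75, so theta_hat = (45/100)/0.75 = 0.6
#' fit <- fit_fraction_new(c(2, 2, 2), c(0, 1, 2), c(55, 30, 15),
#'                         pnew = 0.5, pbg = 0)
#' coef(fit)
fit_fraction_new <- function(n_t, k_tc, count, pnew, pbg,
                             tol = 1e-10, max_iter = 1000L) {
  stopifnot(length(n_t) == length(k_tc), length(n_t) == length(count))
  if (any(k_tc > n_t) || any(k_tc < 0) || any(count < 0)) {
    stop("invalid histogram: need 0 <= k_TC <= n_T and count >= 0")
  }
  if (!(pbg < pnew)) stop("unidentifiable: requires pbg < pnew")
  n_reads <- sum(count)
  if (n_reads < 1) stop("total reads must be >= 1")
  keep <- n_t > 0 & count > 0
  n <- n_t[keep]; k <- k_tc[keep]; cnt <- count[keep]
  n_info <- sum(cnt)
  res <- list(theta = NA_real_, se_theta = NA_real_, se_logit = NA_real_,
              theta_adj = NA_real_, logit_theta = NA_real_,
              loglik = NA_real_, loglik_trace = numeric(0),
              n_reads = n_reads, n_informative = n_info,
              pnew = pnew, pbg = pbg,
              converged = FALSE, unidentifiable = FALSE, iterations = 0L)
  class(res) <- "fn_fit"
  if (n_info == 0) {                      # all reads n_T = 0: theta undefined
    res$unidentifiable <- TRUE
    return(res)
  }
  f1 <- dbinom(k, n, pnew)
  f0 <- dbinom(k, n, pbg)
  theta <- 0.5
  ll_trace <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    mix <- theta * f1 + (1 - theta) * f0
    mix[mix < .Machine$double.xmin] <- .Machine$double.xmin
    ll <- sum(cnt * log(mix))
    ll_trace <- c(ll_trace, ll)
    r <- theta * f1 / mix
    theta_new <- sum(cnt * r) / n_info
    moved <- abs(theta_new - theta)
    theta <- theta_new
    if (moved < tol && it > 1) {
      res$converged <- TRUE
      res$iterations <- it
      break
    }
    ll_old <- ll
    res$iterations <- it
  }
  theta <- min(max(theta, 0), 1)
  mix <- theta * f1 + (1 - theta) * f0
  mix[mix < .Machine$double.xmin] <- .Machine$double.xmin
  res$theta <- theta
  res$loglik <- sum(cnt * log(mix))
  res$loglik_trace <- ll_trace
  info <- sum(cnt * (f1 - f0)^2 / mix^2)   # observed Fisher information
  se <- if (info > 0) 1 / sqrt(info) else NA_real_
  theta_adj <- (theta * n_info + 0.5) / (n_info + 1)
  if (!is.finite(se) || se == 0) {
    se <- sqrt(theta_adj * (1 - theta_adj) / n_info)
  }
  res$se_theta <- se
  res$theta_adj <- theta_adj
  res$logit_theta <- qlogis(theta_adj)
  res$se_logit <- se / (theta_adj * (1 - theta_adj))
  res
}

#' @export
print.fn_fit <- function(x, ...) {
  if (x$unidentifiable) {
    cat("Fraction-new fit: unidentifiable (no informative reads)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "Fraction-new fit: theta = %.4f (se %.4f), %d reads (%d informative)\n",
    x$theta, x$se_theta, x$n_reads, x$n_informative))
  cat(sprintf("  logLik %.3f after %d EM iterations (pnew %.4g, pbg %.4g)%s\n",
              x$loglik, x$iterations, x$pnew, x$pbg,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' @export
coef.fn_fit <- function(object, ...) c(theta = object$theta)

#' @export
logLik.fn_fit <- function(object, ...) {
  structure(object$loglik, df = 1, class = "logLik")
}

#' Estimate the fraction new for every transcript x sample
#'
#' Runs [fit_fraction_new()] on each transcript x sample histogram of a
#' conversion-count table.
#'
#' @param table Conversion-count data.frame (see [simulate_counts()] /
#'   [read_conversion_table()]).
#' @param pnew,pbg Conversion probabilities, typically from
#'   [estimate_conversion_rates()].
#' @return data.frame with one row per transcript x sample: `transcript_id`,
#'   `sample_id`, `condition`, `replicate`, `theta`, `se_theta`,
#'   `logit_theta`, `se_logit`, `loglik`, `n_reads`, `converged`,
#'   `unidentifiable`, `pnew_used`, `pbg_used`.
#' @export
estimate_fraction_new <- function(table, pnew, pbg) {
  .validate_conversion_table(table)
  if (!(pbg < pnew)) stop("unidentifiable: requires pbg < pnew")
  key <- paste(table$sample_id, table$transcript_id, sep = "\r")
  groups <- split(seq_len(nrow(table)), key)
  out <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    fit <- fit_fraction_new(table$n_T[idx], table$k_TC[idx],
                            table$read_count[idx], pnew, pbg)
    i1 <- idx[1]
    out[[g]] <- data.frame(
      transcript_id = table$transcript_id[i1],
      sample_id = table$sample_id[i1],
      condition = table$condition[i1],
      replicate = table$replicate[i1],
      theta = fit$theta, se_theta = fit$se_theta,
      logit_theta = fit$logit_theta, se_logit = fit$se_logit,
      loglik = fit$loglik, n_reads = fit$n_reads,
      converged = fit$converged, unidentifiable = fit$unidentifiable,
      pnew_used = pnew, pbg_used = pbg,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$transcript_id, res$condition, res$replicate), ]
}

#' Combine replicate fraction-new estimates per condition
#'
#' Inverse-variance weighting on the logit scale, keeping replicate
#' dispersion observable downstream.
#'
#' @param estimates Output of [estimate_fraction_new()].
#' @return data.frame per transcript x condition with `theta`,
#'   `logit_theta`, `se_logit`, `n_reads`, `n_reps`, `unidentifiable`.
#' @export
combine_fraction_new <- function(estimates) {
  key <- paste(estimates$transcript_id, estimates$condition, sep = "\r")
  groups <- split(seq_len(nrow(estimates)), key)
  out <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    i1 <- idx[1]
    ok <- !estimates$unidentifiable[idx] &
      is.finite(estimates$logit_theta[idx]) &
      is.finite(estimates$se_logit[idx]) & estimates$se_logit[idx] > 0
    if (!any(ok)) {
      out[[g]] <- data.frame(
        transcript_id = estimates$transcript_id[i1],
        condition = estimates$condition[i1],
        theta = NA_real_, logit_theta = NA_real_, se_logit = NA_real_,
        n_reads = sum(estimates$n_reads[idx]), n_reps = length(idx),
        unidentifiable = TRUE, stringsAsFactors = FALSE)
      next
    }
    w <- 1 / estimates$se_logit[idx][ok]^2
    lt <- sum(w * estimates$logit_theta[idx][ok]) / sum(w)
    out[[g]] <- data.frame(
      transcript_id = estimates$transcript_id[i1],
      condition = estimates$condition[i1],
      theta = plogis(lt), logit_theta = lt, se_logit = 1 / sqrt(sum(w)),
      n_reads = sum(estimates$n_reads[idx]), n_reps = length(idx),
      unidentifiable = FALSE, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$transcript_id, res$condition), ]
}

#' Estimate global conversion rates
#'
#' Chemistry is sample-level, so `pnew` and `pbg` are shared across
#' transcripts. With a -s4U control table, `pbg` is that control's pooled
#' conversion rate and only (`pi`, `pnew`) are fit by EM on the pooled
#' (+s4U) histogram; otherwise all three mixture parameters are fit.
#'
#' @param table Conversion-count table (+s4U).
#' @param no_s4u_table Optional -s4U control conversion-count table.
#' @param sep_tol Minimum required separation `pnew - pbg`; smaller fits
#'   raise an unidentifiability error.
#' @param tol,max_iter EM convergence controls (on the log-likelihood).
#' @return List with `pnew`, `pbg`, `pi_new` (pooled mixing weight),
#'   `loglik`, `converged`, `source` ("em" or "control").
#' @export
estimate_conversion_rates <- function(table, no_s4u_table = NULL,
                                      sep_tol = 1e-3, tol = 1e-10,
                                      max_iter = 1000L) {
  .validate_conversion_table(table)
  keep <- table$n_T > 0 & table$read_count > 0
  agg <- rowsum(table$read_count[keep],
                paste(table$n_T[keep], table$k_TC[keep]))
  parts <- strsplit(rownames(agg), " ", fixed = TRUE)
  n <- as.integer(vapply(parts, `[`, "", 1))
  k <- as.integer(vapply(parts, `[`, "", 2))
  cnt <- as.numeric(agg[, 1])
  if (sum(cnt) == 0) stop("no informative reads")

  pbg_fixed <- NULL
  if (!is.null(no_s4u_table)) {
    .validate_conversion_table(no_s4u_table)
    tot_t <- sum(no_s4u_table$n_T * no_s4u_table$read_count)
    if (tot_t == 0) stop("-s4U control has no T positions")
    pbg_fixed <- sum(no_s4u_table$k_TC * no_s4u_table$read_count) / tot_t
  }

  rate <- sum(k * cnt) / sum(n * cnt)
  pnew <- min(max(4 * rate, 1e-4), 0.5)
  pbg <- if (is.null(pbg_fixed)) max(rate / 4, 1e-6) else pbg_fixed
  pi_new <- 0.5
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    f1 <- dbinom(k, n, pnew)
    f0 <- dbinom(k, n, pbg)
    mix <- pi_new * f1 + (1 - pi_new) * f0
    mix[mix < .Machine$double.xmin] <- .Machine$double.xmin
    ll <- sum(cnt * log(mix))
    r <- pi_new * f1 / mix
    pi_new <- sum(cnt * r) / sum(cnt)
    pnew <- sum(cnt * r * k) / max(sum(cnt * r * n), .Machine$double.eps)
    if (is.null(pbg_fixed)) {
      pbg <- sum(cnt * (1 - r) * k) /
        max(sum(cnt * (1 - r) * n), .Machine$double.eps)
    }
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  if (pbg > pnew) {                                   # enforce labeling order
    tmp <- pnew; pnew <- pbg; pbg <- tmp
    pi_new <- 1 - pi_new
  }
  if (pnew - pbg < sep_tol) {
    stop("unidentifiable: fitted conversion rates are not separated ",
         sprintf("(pnew = %.5g, pbg = %.5g, tolerance %.3g)",
                 pnew, pbg, sep_tol))
  }
  list(pnew = pnew, pbg = pbg, pi_new = pi_new, loglik = ll,
       converged = converged,
       source = if (is.null(pbg_fixed)) "em" else "control")
}

#' Decay rate and half-life from the fraction new
#'
#' Inverts the steady-state labeling identity
#' `theta = 1 - exp(-kdeg * t)`: `kdeg = -log(1 - theta) / t`, half-life
#' `ln 2 / kdeg`. Boundary thetas (0 or 1) are flagged rather than raising
#' an error: half-life Inf (never labeled) or 0 (fully labeled).
#'
#' @param theta Fraction new, in `[0, 1]`.
#' @param t_label Labeling duration (h, > 0).
#' @return data.frame with `theta`, `kdeg`, `half_life`, `boundary`.
#' @export
#' @examples
#' kdeg_from_theta(0.5, 1)      # kdeg = ln 2, half-life 1 h
kdeg_from_theta <- function(theta, t_label) {
  stopifnot(all(t_label > 0))
  if (any(theta < 0 | theta > 1, na.rm = TRUE)) {
    stop("theta must lie in [0, 1]")
  }
  kdeg <- -log1p(-theta) / t_label
  half_life <- log(2) / kdeg
  boundary <- !is.na(theta) & (theta <= 0 | theta >= 1)
  kdeg[!is.na(theta) & theta <= 0] <- 0
  half_life[!is.na(theta) & theta <= 0] <- Inf
  half_life[!is.na(theta) & theta >= 1] <- 0
  data.frame(theta = theta, kdeg = kdeg, half_life = half_life,
             boundary = boundary)
}

#' Conversion-chemistry quality control
#'
#' The labeling chemistry should raise the pooled T-to-C conversion rate in
#' +s4U samples well above the -s4U control, while the A-to-G decoy rate
#' stays comparable in both. PASS requires
#' `TtoC(+s4U) / TtoC(-s4U) >= tc_ratio_min` and the A-to-G rates to agree
#' within `ag_ratio_max` (ratio in either direction).
#'
#' @param table +s4U conversion-count table.
#' @param no_s4u_table -s4U control table.
#' @param tc_ratio_min Minimum T-to-C enrichment ratio (default 3).
#' @param ag_ratio_max Maximum tolerated A-to-G rate ratio (default 1.5).
#' @return Object of class `tl_qc`: rates, ratios, per-criterion and
#'   overall pass flags.
#' @export
qc_conversion_bias <- function(table, no_s4u_table,
                               tc_ratio_min = 3, ag_ratio_max = 1.5) {
  .validate_conversion_table(table)
  .validate_conversion_table(no_s4u_table)
  pooled <- function(tab) {
    c(tc = sum(tab$k_TC * tab$read_count) /
        max(sum(tab$n_T * tab$read_count), 1),
      ag = sum(tab$k_AG) / max(sum(tab$n_A), 1))
  }
  plus <- pooled(table)
  minus <- pooled(no_s4u_table)
  tc_ratio <- plus[["tc"]] / max(minus[["tc"]], .Machine$double.eps)
  ag_ratio <- max(plus[["ag"]], minus[["ag"]]) /
    max(min(plus[["ag"]], minus[["ag"]]), .Machine$double.eps)
  res <- list(tc_rate_s4u = plus[["tc"]], tc_rate_control = minus[["tc"]],
              ag_rate_s4u = plus[["ag"]], ag_rate_control = minus[["ag"]],
              tc_ratio = tc_ratio, ag_ratio = ag_ratio,
              tc_ratio_min = tc_ratio_min, ag_ratio_max = ag_ratio_max,
              tc_pass = tc_ratio >= tc_ratio_min,
              ag_pass = ag_ratio <= ag_ratio_max)
  res$pass <- res$tc_pass && res$ag_pass
  class(res) <- "tl_qc"
  res
}

#' @export
print.tl_qc <- function(x, ...) {
  cat("Conversion-chemistry QC:", if (x$pass) "PASS" else "FAIL", "\n")
  cat(sprintf("  T-to-C rate: %.5f (+s4U) vs %.5f (-s4U); ratio %.2f (min %.2f) %s\n",
              x$tc_rate_s4u, x$tc_rate_control, x$tc_ratio, x$tc_ratio_min,
              if (x$tc_pass) "ok" else "FAIL"))
  cat(sprintf("  A-to-G rate: %.5f (+s4U) vs %.5f (-s4U); ratio %.2f (max %.2f) %s\n",
              x$ag_rate_s4u, x$ag_rate_control, x$ag_ratio, x$ag_ratio_max,
              if (x$ag_pass) "ok" else "FAIL"))
  invisible(x)
}
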