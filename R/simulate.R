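#' Closed-form pools of old and new RNA after a step perturbation
#'
#' One-compartment synthesis/decay with a step change applied at t = 0, the
#' instant labeling begins. Pre-existing ("old") RNA starts at the untreated
#' steady state `ksyn / kdeg_old` and decays at the post-perturbation rate;
#' "new" RNA accumulates under the post-perturbation synthesis and decay
#' rates:
#' \deqn{old(t) = (ksyn / kdeg_{old}) e^{-kdeg_{new} t}}
#' \deqn{new(t) = (ksyn_{new} / kdeg_{new}) (1 - e^{-kdeg_{new} t})}
#' \deqn{\theta(t) = new / (new + old)}
#' With no perturbation this reduces to the steady-state labeling identity
#' `theta = 1 - exp(-kdeg * t)`.
#'
#' @param ksyn Untreated synthesis rate (> 0); sets the old pool's initial
#'   steady state.
#' @param kdeg_old Untreated decay rate (1/h, > 0).
#' @param kdeg_new Post-perturbation decay rate (1/h, > 0).
#' @param ksyn_new Post-perturbation synthesis rate (> 0).
#' @param t Time since perturbation/labeling onset (h, >= 0).
#' @return A data.frame with columns `new`, `old`, `theta`. Inputs recycle.
#' @export
#' @examples
#' # unperturbed: theta = 1 - exp(-2)
#' perturbed_pools(1, 2, 2, 1, 1)$theta
#' # 10x stabilization: total abundance rises while theta falls
#' perturbed_pools(1, 2, 0.2, 1, 1)
perturbed_pools <- function(ksyn, kdeg_old, kdeg_new, ksyn_new, t) {
  n <- max(length(ksyn), length(kdeg_old), length(kdeg_new),
           length(ksyn_new), length(t))
  ksyn <- rep_len(ksyn, n); kdeg_old <- rep_len(kdeg_old, n)
  kdeg_new <- rep_len(kdeg_new, n); ksyn_new <- rep_len(ksyn_new, n)
  t <- rep_len(t, n)
  if (any(!is.finite(ksyn) | ksyn <= 0) ||
      any(!is.finite(kdeg_old) | kdeg_old <= 0) ||
      any(!is.finite(kdeg_new) | kdeg_new <= 0) ||
      any(!is.finite(ksyn_new) | ksyn_new <= 0)) {
    stop("all rates must be finite and > 0")
  }
  if (any(!is.finite(t) | t < 0)) stop("t must be finite and >= 0")
  old <- (ksyn / kdeg_old) * exp(-kdeg_new * t)
  new <- (ksyn_new / kdeg_new) * (-expm1(-kdeg_new * t))
  theta <- ifelse(new + old > 0, new / (new + old), 0)
  data.frame(new = new, old = old, theta = theta)
}

#' Steady-state fraction new
#'
#' The labeling identity `theta = 1 - exp(-kdeg * t)`; exact inverse of
#' [kdeg_from_theta()].
#'
#' @param kdeg Decay rate (1/h).
#' @param t_label Labeling duration (h).
#' @return Fraction of reads that are new at steady state.
#' @export
fraction_new_steady_state <- function(kdeg, t_label) {
  stopifnot(all(kdeg >= 0), all(t_label >= 0))
  -expm1(-kdeg * t_label)
}

#' Generate ground-truth transcript kinetics
#'
#' Samples a transcriptome of [sim_config()]'s conditions: per-transcript
#' synthesis and decay rates, class labels, perturbation effect factors, and
#' CDS sequences. Stabilized-class CDSs are drawn from a codon distribution
#' enriched in suboptimal codons (negative codon stability coefficient) with
#' extra weight on Cys/His codons; the T-content of the CDS sets the
#' transcript's `u_freq`, coupling codon composition to labeling information.
#'
#' @param config A [sim_config()] object.
#' @param csc Named codon stability coefficient vector used only to decide
#'   which codons count as suboptimal when building stabilized-class CDSs;
#'   defaults to the synthetic table shipped with the package.
#' @return A data.frame (one row per transcript) with columns
#'   `transcript_id`, `class_label`, `ksyn`, `kdeg`, `ksyn_factor`,
#'   `kdeg_factor`, `u_freq`, `cds`. Deterministic given `config$seed`.
#' @export
#' @examples
#' truth <- make_truth(sim_config(n_transcripts = 20, seed = 1))
#' table(truth$class_label)
make_truth <- function(config, csc = default_csc()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.derive_seed(config$seed, 0L))
  n <- config$n_transcripts
  classes <- names(config$class_proportions)
  class_label <- sample(classes, n, replace = TRUE,
                        prob = config$class_proportions)
  runif_log <- function(m, rng) exp(runif(m, log(rng[1]), log(rng[2])))
  half_life <- runif_log(n, config$half_life_range)
  stab <- class_label == "stabilized"
  half_life[stab] <- runif_log(sum(stab), config$stabilized_half_life_range)
  kdeg <- log(2) / half_life
  ksyn <- runif_log(n, config$ksyn_range)
  ksyn_factor <- rep(1, n)
  kdeg_factor <- rep(1, n)
  for (cl in setdiff(classes, "null")) {
    idx <- class_label == cl
    if (!any(idx)) next
    fac <- runif_log(sum(idx), config$effect_size_ranges[[cl]])
    if (cl == "synthesis_induced") ksyn_factor[idx] <- fac
    else kdeg_factor[idx] <- fac
  }

  codons <- sense_codons()
  w_null <- setNames(rep(1, length(codons)), codons)
  w_stab <- w_null
  subopt <- intersect(names(csc)[csc < 0], codons)
  w_stab[subopt] <- w_stab[subopt] * config$subopt_enrichment
  cys_his <- c("TGT", "TGC", "CAT", "CAC")
  w_stab[cys_his] <- w_stab[cys_his] * config$cys_his_enrichment
  len <- sample(seq(config$cds_length_range[1], config$cds_length_range[2]),
                n, replace = TRUE)
  cds <- character(n)
  for (i in seq_len(n)) {
    w <- if (stab[i]) w_stab else w_null
    body <- sample(codons, len[i], replace = TRUE, prob = w)
    cds[i] <- paste0(paste(c("ATG", body), collapse = ""), "TAA")
  }
  t_count <- nchar(gsub("[^T]", "", cds))
  u_freq <- pmin(pmax(t_count / nchar(cds), 0.01), 0.99)

  data.frame(transcript_id = sprintf("tx_%04d", seq_len(n)),
             class_label = class_label,
             ksyn = ksyn, kdeg = kdeg,
             ksyn_factor = ksyn_factor, kdeg_factor = kdeg_factor,
             u_freq = u_freq, cds = cds,
             stringsAsFactors = FALSE)
}

# Condition-specific rates for a truth table (step perturbation at t = 0).
.condition_rates <- function(truth, condition) {
  treated <- condition == "treated"
  list(kdeg_new = truth$kdeg * (if (treated) truth$kdeg_factor else 1),
       ksyn_new = truth$ksyn * (if (treated) truth$ksyn_factor else 1))
}

#' Simulate a conversion-count table for one condition
#'
#' Read counts per transcript and replicate are Poisson with mean
#' proportional to the condition-specific total abundance at `t_label`,
#' scaled so the untreated mean equals `depth_per_transcript`
#' (library-size coupling). Each read draws its T count from
#' `Binomial(read_len, u_freq)`, is new with probability theta from
#' [perturbed_pools()], and converts Ts at `pnew` (new) or `pbg` (old).
#' Reads are aggregated into `(n_T, k_TC)` bins; the A-to-G decoy channel is
#' carried as per-bin totals (`n_A` = total A positions across the bin's
#' reads, `k_AG` = total A-to-G conversions, at rate `pag` regardless of
#' label). Unlabeled spike-in species (`spike_...`) are added with
#' condition-independent depth.
#'
#' @param truth Truth table from [make_truth()].
#' @param config The [sim_config()] used to build `truth`.
#' @param condition `"untreated"` or `"treated"`.
#' @param pnew,pbg,pag Optional overrides of the config conversion rates
#'   (e.g. to simulate a -s4U control with `pnew = config$pbg`, or an
#'   elevated decoy rate).
#' @return A conversion-count data.frame with columns `sample_id`,
#'   `condition`, `replicate`, `transcript_id`, `n_T`, `k_TC`, `n_A`,
#'   `k_AG`, `read_count`. Deterministic given `config$seed` and
#'   `condition`.
#' @export
simulate_counts <- function(truth, config, condition = c("untreated", "treated"),
                            pnew = config$pnew, pbg = config$pbg,
                            pag = config$pag) {
  condition <- match.arg(condition)
  stopifnot(inherits(config, "sim_config"), nrow(truth) >= 1)
  if (config$depth_per_transcript <= 0) stop("depth must be > 0")
  set.seed(.derive_seed(config$seed, if (condition == "treated") 2L else 1L))

  rates <- .condition_rates(truth, condition)
  t_eff <- max(config$t_label - config$lag, 0)
  pools <- perturbed_pools(truth$ksyn, truth$kdeg, rates$kdeg_new,
                           rates$ksyn_new, t_eff)
  abundance <- pools$new + pools$old
  a0 <- truth$ksyn / truth$kdeg                      # untreated steady state
  scale <- config$depth_per_transcript / mean(a0)
  mean_reads <- scale * abundance
  theta <- pools$theta

  ids <- truth$transcript_id
  u <- truth$u_freq
  if (config$n_spikes > 0) {
    ids <- c(ids, sprintf("spike_%02d", seq_len(config$n_spikes)))
    mean_reads <- c(mean_reads, rep(config$spike_depth, config$n_spikes))
    theta <- c(theta, rep(0, config$n_spikes))
    u <- c(u, rep(0.25, config$n_spikes))
  }

  out <- vector("list", length(ids) * config$n_reps)
  slot <- 0L
  for (rep_i in seq_len(config$n_reps)) {
    for (i in seq_along(ids)) {
      n_reads <- rpois(1, mean_reads[i])
      if (n_reads == 0) next
      n_t <- rbinom(n_reads, config$read_len, u[i])
      is_new <- runif(n_reads) < theta[i]
      k_tc <- rbinom(n_reads, n_t, ifelse(is_new, pnew, pbg))
      key <- n_t * (config$read_len + 1L) + k_tc
      tab <- table(key)
      keyv <- as.integer(names(tab))
      cnt <- as.integer(tab)
      bin_nt <- keyv %/% (config$read_len + 1L)
      bin_k <- keyv %% (config$read_len + 1L)
      n_a <- rbinom(length(cnt), cnt * config$read_len, config$a_freq)
      k_ag <- rbinom(length(cnt), n_a, pag)
      slot <- slot + 1L
      out[[slot]] <- data.frame(
        sample_id = paste0(condition, "_rep", rep_i),
        condition = condition, replicate = rep_i,
        transcript_id = ids[i],
        n_T = bin_nt, k_TC = bin_k, n_A = n_a, k_AG = k_ag,
        read_count = cnt, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out[seq_len(slot)])
  rownames(res) <- NULL
  res
}

#' Simulate ribosome-profiling, monosome, and disome count tables
#'
#' RNA, footprint, and monosome counts are Poisson with means proportional
#' to steady-state abundance times a per-transcript translation efficiency
#' (lognormal around `te_mu`, with per-class multipliers); disome counts are
#' additionally scaled by `disome_base_ratio` and the class's disome
#' inflation factor.
#'
#' @inheritParams simulate_counts
#' @return data.frame with columns `transcript_id`, `class_label`, `rna`,
#'   `ribo`, `monosome`, `disome`, `te_true`. Deterministic given the seed.
#' @export
simulate_ribo <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.derive_seed(config$seed, 3L))
  n <- nrow(truth)
  a0 <- truth$ksyn / truth$kdeg
  lambda_rna <- config$ribo_depth * a0 / mean(a0)
  te_mult <- rep(1, n)
  for (cl in names(config$te_multiplier)) {
    te_mult[truth$class_label == cl] <- config$te_multiplier[[cl]]
  }
  te <- config$te_mu * te_mult * exp(rnorm(n, 0, config$te_sd))
  infl <- rep(1, n)
  for (cl in names(config$disome_inflation)) {
    infl[truth$class_label == cl] <- config$disome_inflation[[cl]]
  }
  data.frame(transcript_id = truth$transcript_id,
             class_label = truth$class_label,
             rna = rpois(n, lambda_rna),
             ribo = rpois(n, lambda_rna * te),
             monosome = rpois(n, lambda_rna * te),
             disome = rpois(n, lambda_rna * te * config$disome_base_ratio * infl),
             te_true = te,
             stringsAsFactors = FALSE)
}

#' Simulate an RT-qPCR Ct table
#'
#' `Ct = intercept - log2(abundance) + N(0, noise)`. Target abundances come
#' from the kinetic model at `t_label` per condition; the control targets
#' (18S and U2 by default) have condition-independent abundance.
#'
#' @inheritParams simulate_counts
#' @param targets Transcript ids to assay; default picks up to
#'   `n_per_class` per class.
#' @param n_per_class Targets per class when `targets` is NULL.
#' @param controls Named abundances for control targets.
#' @return data.frame with columns `target`, `condition`, `replicate`, `Ct`.
#' @export
simulate_qpcr <- function(truth, config, targets = NULL, n_per_class = 2,
                          controls = c(`18S` = 1000, U2 = 500)) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.derive_seed(config$seed, 4L))
  if (is.null(targets)) {
    targets <- unlist(lapply(split(truth$transcript_id, truth$class_label),
                             head, n_per_class), use.names = FALSE)
  }
  tt <- truth[match(targets, truth$transcript_id), , drop = FALSE]
  if (anyNA(tt$transcript_id)) stop("unknown qPCR target(s)")
  rows <- list()
  for (cond in c("untreated", "treated")) {
    rates <- .condition_rates(tt, cond)
    pools <- perturbed_pools(tt$ksyn, tt$kdeg, rates$kdeg_new,
                             rates$ksyn_new, config$t_label)
    ab <- c(setNames(pools$new + pools$old, targets), controls)
    for (rep_i in seq_len(config$n_reps)) {
      ct <- config$qpcr_intercept - log2(ab) +
        rnorm(length(ab), 0, config$qpcr_noise_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        target = names(ab), condition = cond, replicate = rep_i,
        Ct = unname(ct), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
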