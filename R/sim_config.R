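#' Simulation configuration for the synthetic-data generator
#'
#' Defines the conditions of a simulated labeling experiment: a transcriptome
#' with per-transcript synthesis (`ksyn`, molecules/h) and decay (`kdeg`, 1/h)
#' rates at steady state, a step perturbation applied at t = 0 (the moment
#' labeling begins, mirroring a design in which drug and label are added
#' simultaneously), and read-level conversion chemistry: new reads convert
#' T positions to C at rate `pnew`, old reads at the background rate `pbg`,
#' and every read carries an A-to-G decoy channel at rate `pag` regardless of
#' label status.
#'
#' Transcript classes:
#' \describe{
#'   \item{null}{no perturbation effect (both factors 1)}
#'   \item{stabilized}{decay slowed: `kdeg_factor` < 1; CDS enriched in
#'     suboptimal codons (including Cys/His codons, mimicking the codon
#'     signature of C2H2 zinc-finger transcripts); drawn from a short
#'     half-life range because only short-lived transcripts can more than
#'     double in abundance within a 1 h window when decay slows}
#'   \item{synthesis_induced}{transcription increased: `ksyn_factor` > 1}
#'   \item{destabilized}{decay accelerated: `kdeg_factor` > 1}
#' }
#'
#' @param n_transcripts Number of (non-spike-in) transcripts.
#' @param class_proportions Named fractions over the four classes; must sum
#'   to 1. Default: 220/300 null, 40/300 stabilized, 40/300 synthesis-induced.
#' @param effect_size_ranges Named list of `c(low, high)` multiplier ranges
#'   (log-uniform draw) for the effect factor of each non-null class.
#'   Defaults: stabilized `kdeg` x 0.2, synthesis-induced `ksyn` x 4,
#'   destabilized `kdeg` x 5.
#' @param half_life_range Half-life range (h), sampled log-uniformly,
#'   for all classes except stabilized.
#' @param stabilized_half_life_range Half-life range (h) for the stabilized
#'   class (short-lived by construction; see Details).
#' @param ksyn_range Synthesis-rate range (molecules/h), log-uniform.
#' @param a_freq Per-position A frequency used for the decoy channel.
#' @param t_label Labeling duration (h). Default 1.
#' @param pnew,pbg T-to-C conversion probability per T in new / old reads.
#' @param pag A-to-G conversion probability per A (both read classes).
#' @param read_len Read length (nt).
#' @param depth_per_transcript Expected untreated reads per transcript per
#'   replicate; treated depth scales with the condition's total abundance
#'   (library-size coupling).
#' @param n_reps Replicates per condition.
#' @param n_spikes,spike_depth Number of unlabeled spike-in species and their
#'   expected reads per replicate (condition-independent).
#' @param cds_length_range Range of CDS length in codons (excluding the
#'   appended stop codon).
#' @param subopt_enrichment Weight multiplier for suboptimal codons when
#'   sampling stabilized-class CDSs.
#' @param cys_his_enrichment Additional weight multiplier for the Cys/His
#'   codons (TGT, TGC, CAT, CAC) in stabilized-class CDSs.
#' @param te_mu,te_sd Baseline translation efficiency and lognormal spread.
#' @param te_multiplier Named per-class TE multipliers (default: stabilized
#'   1.3).
#' @param disome_base_ratio Baseline disome/monosome count ratio.
#' @param disome_inflation Named per-class disome inflation factors
#'   (default: stabilized 2).
#' @param ribo_depth Expected RNA/footprint reads per transcript for the
#'   ribosome-profiling simulator.
#' @param qpcr_intercept,qpcr_noise_sd Ct model: `Ct = intercept -
#'   log2(abundance) + N(0, sd)`.
#' @param lag Drug-uptake lag (h) before effect multipliers apply; default 0
#'   (simultaneous treatment and labeling).
#' @param seed Integer seed; all generator randomness derives from it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [make_truth()], [simulate_counts()], [run_pipeline()]
#' @export
#' @examples
#' cfg <- sim_config(n_transcripts = 50, depth_per_transcript = 500, seed = 7)
#' cfg$pnew
sim_config <- function(n_transcripts = 300,
                       class_proportions = c(null = 220 / 300,
                                             stabilized = 40 / 300,
                                             synthesis_induced = 40 / 300,
                                             destabilized = 0),
                       effect_size_ranges = list(stabilized = c(0.2, 0.2),
                                                 synthesis_induced = c(4, 4),
                                                 destabilized = c(5, 5)),
                       half_life_range = c(0.25, 8),
                       stabilized_half_life_range = c(0.25, 0.45),
                       ksyn_range = c(1, 10),
                       a_freq = 0.25,
                       t_label = 1,
                       pnew = 0.05,
                       pbg = 0.002,
                       pag = 0.002,
                       read_len = 100,
                       depth_per_transcript = 5000,
                       n_reps = 2,
                       n_spikes = 10,
                       spike_depth = 1000,
                       cds_length_range = c(150, 500),
                       subopt_enrichment = 3,
                       cys_his_enrichment = 2,
                       te_mu = 1,
                       te_sd = 0.25,
                       te_multiplier = c(stabilized = 1.3),
                       disome_base_ratio = 0.1,
                       disome_inflation = c(stabilized = 2),
                       ribo_depth = 2000,
                       qpcr_intercept = 30,
                       qpcr_noise_sd = 0.1,
                       lag = 0,
                       seed = 1L) {
  classes <- c("null", "stabilized", "synthesis_induced", "destabilized")
  if (is.null(names(class_proportions)) ||
      !all(names(class_proportions) %in% classes)) {
    stop("class_proportions must be named with classes among: ",
         paste(classes, collapse = ", "))
  }
  if (abs(sum(class_proportions) - 1) > 1e-8) {
    stop("class_proportions must sum to 1 (got ", sum(class_proportions), ")")
  }
  if (any(class_proportions < 0)) stop("class_proportions must be >= 0")
  active <- setdiff(names(class_proportions)[class_proportions > 0], "null")
  for (cl in active) {
    rng <- effect_size_ranges[[cl]]
    if (is.null(rng) || length(rng) != 2 || any(!is.finite(rng)) ||
        any(rng <= 0) || rng[1] > rng[2]) {
      stop("effect_size_ranges for active class '", cl,
           "' must be a valid c(low, high) with 0 < low <= high")
    }
  }
  if (!is.null(effect_size_ranges$stabilized) &&
      effect_size_ranges$stabilized[2] >= 1) {
    stop("stabilized class must have kdeg_factor < 1")
  }
  for (cl in c("synthesis_induced", "destabilized")) {
    if (!is.null(effect_size_ranges[[cl]]) &&
        effect_size_ranges[[cl]][1] <= 1) {
      stop(cl, " class must have its effect factor > 1")
    }
  }
  stopifnot(n_transcripts >= 1, t_label > 0, n_reps >= 1,
            pnew >= 0, pnew <= 1, pbg >= 0, pbg <= pnew,
            pag >= 0, pag <= 1, read_len >= 1,
            depth_per_transcript > 0,
            half_life_range[1] > 0, half_life_range[1] <= half_life_range[2],
            stabilized_half_life_range[1] > 0,
            ksyn_range[1] > 0, lag >= 0)
  cfg <- list(n_transcripts = as.integer(n_transcripts),
              class_proportions = class_proportions[
                intersect(classes, names(class_proportions))],
              effect_size_ranges = effect_size_ranges,
              half_life_range = half_life_range,
              stabilized_half_life_range = stabilized_half_life_range,
              ksyn_range = ksyn_range,
              a_freq = a_freq,
              t_label = t_label, pnew = pnew, pbg = pbg, pag = pag,
              read_len = as.integer(read_len),
              depth_per_transcript = depth_per_transcript,
              n_reps = as.integer(n_reps),
              n_spikes = as.integer(n_spikes), spike_depth = spike_depth,
              cds_length_range = as.integer(cds_length_range),
              subopt_enrichment = subopt_enrichment,
              cys_his_enrichment = cys_his_enrichment,
              te_mu = te_mu, te_sd = te_sd, te_multiplier = te_multiplier,
              disome_base_ratio = disome_base_ratio,
              disome_inflation = disome_inflation,
              ribo_depth = ribo_depth,
              qpcr_intercept = qpcr_intercept,
              qpcr_noise_sd = qpcr_noise_sd,
              lag = lag,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration (tlkinetics)\n")
  cat(sprintf("  transcripts: %d  replicates: %d  seed: %d\n",
              x$n_transcripts, x$n_reps, x$seed))
  cat("  class proportions:",
      paste(sprintf("%s=%.3g", names(x$class_proportions),
                    x$class_proportions), collapse = ", "), "\n")
  cat(sprintf("  t_label: %g h  pnew: %g  pbg: %g  pag: %g\n",
              x$t_label, x$pnew, x$pbg, x$pag))
  cat(sprintf("  read_len: %d  depth/transcript: %g  spike-ins: %d\n",
              x$read_len, x$depth_per_transcript, x$n_spikes))
  invisible(x)
}

# Module-local seed streams, all derived from the single config seed.
# The modulus keeps derived seeds inside 32-bit integer range.
.derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset) %% 2147483629)
}
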