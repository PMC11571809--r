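# Transcript classification: stabilized (ESM), transcriptionally changed
# (TCM), destabilized, other short-lived (OSL), unchanged.

#' Classification thresholds
#'
#' @param min_counts Expression filter: a transcript is "expressed" iff its
#'   untreated mean read count strictly exceeds this (default 100).
#' @param lfc_cutoff Absolute log2 fold-change cutoff for differential
#'   expression (default 1, i.e. twofold).
#' @param padj_de_cutoff,padj_fn_cutoff Adjusted p-value cutoffs
#'   (default 0.01).
#' @param half_life_cutoff Half-life (h) below which a transcript counts as
#'   short-lived (default 1).
#' @param mech_threshold Decay-decision threshold on the mechanism score.
#'   The score is a standardized residual, approximately N(0, 1) when a
#'   pure synthesis change explains the data, so the default -3 is a
#'   3-sigma outlier rule: scores below it are called decay-driven, scores
#'   inside `[mech_threshold, -mech_threshold]` synthesis-consistent, and
#'   scores above `-mech_threshold` decay-driven in the destabilizing
#'   direction.
#' @return Object of class `classification_config`.
#' @export
classification_config <- function(min_counts = 100, lfc_cutoff = 1,
                                  padj_de_cutoff = 0.01,
                                  padj_fn_cutoff = 0.01,
                                  half_life_cutoff = 1,
                                  mech_threshold = -3) {
  stopifnot(min_counts >= 0, lfc_cutoff > 0,
            padj_de_cutoff > 0, padj_de_cutoff <= 1,
            padj_fn_cutoff > 0, padj_fn_cutoff <= 1,
            half_life_cutoff > 0)
  out <- list(min_counts = min_counts, lfc_cutoff = lfc_cutoff,
              padj_de_cutoff = padj_de_cutoff,
              padj_fn_cutoff = padj_fn_cutoff,
              half_life_cutoff = half_life_cutoff,
              mech_threshold = mech_threshold)
  class(out) <- "classification_config"
  out
}

#' @export
print.classification_config <- function(x, ...) {
  cat("Classification thresholds:\n")
  cat(sprintf("  expressed: untreated mean counts > %g\n", x$min_counts))
  cat(sprintf("  |lfc| > %g, padj_de < %g, padj_fn < %g\n",
              x$lfc_cutoff, x$padj_de_cutoff, x$padj_fn_cutoff))
  cat(sprintf("  short-lived: half-life < %g h; mechanism threshold %g\n",
              x$half_life_cutoff, x$mech_threshold))
  invisible(x)
}

#' Expression filter
#'
#' Retains transcripts whose untreated mean read count strictly exceeds
#' `min_counts` (a mean of exactly `min_counts` is excluded).
#'
#' @param counts Matrix transcripts x samples (rownames required).
#' @param min_counts Strict threshold (default 100).
#' @param condition Per-column condition; defaults to parsing
#'   `"<condition>_rep<k>"` sample names.
#' @return Character vector of retained transcript ids.
#' @export
filter_expressed <- function(counts, min_counts = 100, condition = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (is.null(condition)) {
    condition <- sub("_rep[0-9]+$", "", colnames(counts))
  }
  iu <- which(condition == "untreated")
  if (!length(iu)) stop("no untreated samples found")
  mean_u <- rowMeans(counts[, iu, drop = FALSE])
  rownames(counts)[mean_u > min_counts]
}

#' Classify transcripts into mechanism/stability classes
#'
#' Labels (mutually exclusive, precedence ESM > TCM > destabilized > OSL >
#' unchanged):
#' \describe{
#'   \item{ESM}{significant abundance increase (`padj_de`, `lfc >
#'     lfc_cutoff`) with a significant drop in fraction new (`padj_fn`,
#'     `z_fn < 0`) and a mechanism score below `mech_threshold` - a
#'     decay-driven (stabilized) transcript.}
#'   \item{TCM}{significant expression change of at least `lfc_cutoff` in
#'     either direction whose mechanism score is synthesis-consistent
#'     (within `[mech_threshold, -mech_threshold]`).}
#'   \item{destabilized}{significant abundance decrease with a significant
#'     rise in fraction new and a mechanism score above
#'     `-mech_threshold`.}
#'   \item{OSL}{half-life below `half_life_cutoff` but not an ESM.}
#'   \item{unchanged}{everything else.}
#' }
#' Transcripts failing the expression filter are labeled
#' `low_expression`.
#'
#' @param dynamics A [tl_dynamics()] object or its `results` data.frame
#'   (needs columns `padj_de`, `lfc`, `padj_fn`, `z_fn`, `mech`,
#'   `half_life`).
#' @param config [classification_config()].
#' @param expressed Optional character vector of expressed transcript ids;
#'   computed with [filter_expressed()] from the dynamics object's counts
#'   when available.
#' @return The results data.frame with a `label` column appended (spike-in
#'   rows dropped), of class `tl_classes`.
#' @export
classify_transcripts <- function(dynamics,
                                 config = classification_config(),
                                 expressed = NULL) {
  if (inherits(dynamics, "tl_dynamics")) {
    if (is.null(expressed)) {
      expressed <- filter_expressed(dynamics$counts, config$min_counts)
    }
    res <- dynamics$results
  } else {
    res <- dynamics
  }
  if (!is.null(res$is_spike)) res <- res[!res$is_spike, , drop = FALSE]
  if (is.null(expressed)) expressed <- res$transcript_id

  n <- nrow(res)
  lab <- rep("unchanged", n)
  mt <- config$mech_threshold
  sig_de <- !is.na(res$padj_de) & res$padj_de < config$padj_de_cutoff
  sig_fn <- !is.na(res$padj_fn) & res$padj_fn < config$padj_fn_cutoff
  mech_ok <- !is.na(res$mech)

  esm <- sig_de & !is.na(res$lfc) & res$lfc > config$lfc_cutoff &
    sig_fn & !is.na(res$z_fn) & res$z_fn < 0 & mech_ok & res$mech < mt
  tcm <- sig_de & !is.na(res$lfc) & abs(res$lfc) > config$lfc_cutoff &
    mech_ok & res$mech >= mt & res$mech <= -mt
  destab <- sig_de & !is.na(res$lfc) & res$lfc < -config$lfc_cutoff &
    sig_fn & !is.na(res$z_fn) & res$z_fn > 0 & mech_ok & res$mech > -mt
  osl <- !is.na(res$half_life) & res$half_life < config$half_life_cutoff

  lab[osl] <- "OSL"
  lab[destab] <- "destabilized"
  lab[tcm & !esm] <- "TCM"
  lab[esm] <- "ESM"
  lab[!(res$transcript_id %in% expressed)] <- "low_expression"
  res$label <- lab
  class(res) <- c("tl_classes", "data.frame")
  res
}

#' Per-class summary of a classification
#'
#' @param classes Output of [classify_transcripts()].
#' @return data.frame of class counts, fractions (of expressed), and median
#'   half-lives.
#' @export
class_summary <- function(classes) {
  expressed <- classes$label != "low_expression"
  levels <- c("ESM", "TCM", "destabilized", "OSL", "unchanged",
              "low_expression")
  cnt <- table(factor(classes$label, levels = levels))
  hl <- vapply(levels, function(l) {
    v <- classes$half_life[classes$label == l]
    v <- v[is.finite(v)]
    if (length(v)) median(v) else NA_real_
  }, numeric(1))
  data.frame(label = levels,
             n = as.integer(cnt),
             fraction_of_expressed = as.integer(cnt) /
               max(sum(expressed), 1),
             median_half_life = hl,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Top-quartile threshold
#'
#' 75th percentile with linear interpolation (the convention used to call a
#' transcript "high" in suboptimal-codon density: strictly above the
#' threshold).
#'
#' @param values Numeric vector with at least 4 finite values.
#' @return The 75th percentile.
#' @export
#' @examples
#' top_quartile_threshold(1:100)   # 75.25
top_quartile_threshold <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 4) stop("need at least 4 finite values")
  unname(quantile(v, 0.75, type = 7))
}
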