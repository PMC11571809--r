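# Auxiliary assay statistics: translation efficiency, disome/monosome
# ratios, and ddCt quantification for RT-qPCR validation tables.

#' Translation efficiency
#'
#' `TE = ((ribo + pc) / ribo library size) / ((rna + pc) / rna library
#' size)`: ribosome-footprint read density relative to RNA abundance.
#'
#' @param ribo,rna Nonnegative count vectors (same length).
#' @param lib_sizes Length-2 numeric `c(ribo, rna)` library sizes; defaults
#'   to the column sums.
#' @param pseudocount Added to both counts (default 0.5). With
#'   `pseudocount = 0`, transcripts with zero RNA give NA.
#' @return Numeric TE per transcript.
#' @export
#' @examples
#' translation_efficiency(100, 50, lib_sizes = c(1e6, 1e6), pseudocount = 0)
translation_efficiency <- function(ribo, rna,
                                   lib_sizes = c(sum(ribo), sum(rna)),
                                   pseudocount = 0.5) {
  stopifnot(length(ribo) == length(rna), length(lib_sizes) == 2)
  if (any(ribo < 0) || any(rna < 0)) stop("counts must be nonnegative")
  if (any(lib_sizes <= 0)) stop("library sizes must be > 0")
  num <- (ribo + pseudocount) / lib_sizes[1]
  den <- (rna + pseudocount) / lib_sizes[2]
  ifelse(den > 0, num / den, NA_real_)
}

#' log2 disome/monosome ratio
#'
#' Library-size-normalized log2 ratio of disome to monosome footprint
#' counts; a proxy for ribosome-collision propensity.
#'
#' @param disome,monosome Nonnegative count vectors.
#' @param lib_sizes Length-2 `c(disome, monosome)` library sizes.
#' @param pseudocount Added to both counts; with 0, zero monosome counts
#'   give NA.
#' @return Numeric log2 ratios.
#' @export
disome_monosome <- function(disome, monosome,
                            lib_sizes = c(sum(disome), sum(monosome)),
                            pseudocount = 0.5) {
  stopifnot(length(disome) == length(monosome), length(lib_sizes) == 2)
  if (any(disome < 0) || any(monosome < 0)) stop("counts must be nonnegative")
  if (any(lib_sizes <= 0)) stop("library sizes must be > 0")
  num <- (disome + pseudocount) / lib_sizes[1]
  den <- (monosome + pseudocount) / lib_sizes[2]
  ifelse(den > 0, log2(num / den), NA_real_)
}

#' ddCt relative quantification
#'
#' Per (condition, replicate), the control Ct is the arithmetic mean of the
#' control targets' Cts - equivalently the geometric mean of their linear
#' quantities, matching the "geomean of 18S and U2" convention. Then
#' `dCt = Ct_target - control Ct` per replicate,
#' `ddCt = mean dCt(treated) - mean dCt(untreated)`, and the fold change is
#' `2^(-ddCt)` (amplification efficiency fixed at 2).
#'
#' @param ct data.frame with columns `target`, `condition` (`untreated` /
#'   `treated`), `replicate`, `Ct`.
#' @param targets Targets to quantify; default all non-control targets.
#' @param controls Control target names (default `18S`, `U2`).
#' @param spike Optional spike-in target name; when given it replaces the
#'   controls (spike-normalized mode).
#' @return data.frame: `target`, `delta_delta_ct`, `fold_change`.
#' @export
#' @examples
#' ct <- expand.grid(target = c("geneA", "18S", "U2"),
#'                   condition = c("untreated", "treated"),
#'                   replicate = 1:2, stringsAsFactors = FALSE)
#' ct$Ct <- ifelse(ct$target == "geneA",
#'                 ifelse(ct$condition == "treated", 20, 22), 15)
#' ddct(ct)   # fold change 4
ddct <- function(ct, targets = NULL, controls = c("18S", "U2"),
                 spike = NULL) {
  stopifnot(all(c("target", "condition", "replicate", "Ct") %in% names(ct)))
  if (any(!is.finite(ct$Ct))) stop("Ct values must be finite")
  if (any(ct$Ct < 5 | ct$Ct > 40)) {
    warning("Ct value(s) outside the typical 5-40 range")
  }
  if (!is.null(spike)) controls <- spike
  if (is.null(targets)) targets <- setdiff(unique(ct$target), controls)
  key <- paste(ct$condition, ct$replicate, sep = "\r")
  for (k in unique(key)) {
    present <- ct$target[key == k]
    miss <- setdiff(controls, present)
    if (length(miss)) {
      parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
      stop("control target(s) ", paste(miss, collapse = ", "),
           " missing in condition ", parts[1], ", replicate ", parts[2])
    }
  }
  is_ctrl <- ct$target %in% controls
  ctrl_ct <- tapply(ct$Ct[is_ctrl], key[is_ctrl], mean)
  dct <- ct$Ct - as.numeric(ctrl_ct[key])
  out <- lapply(targets, function(tg) {
    sel <- ct$target == tg
    if (!any(sel)) stop("target ", tg, " not found")
    d_t <- mean(dct[sel & ct$condition == "treated"])
    d_u <- mean(dct[sel & ct$condition == "untreated"])
    ddct_v <- d_t - d_u
    data.frame(target = tg, delta_delta_ct = ddct_v,
               fold_change = 2^(-ddct_v), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
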