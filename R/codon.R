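# Codon-optimality statistics from codon stability coefficients (CSC).
# A codon is "suboptimal" iff its CSC is negative (sign of the
# usage-stability correlation); the threshold is exposed where relevant.

#' Count in-frame codons of a CDS
#'
#' Non-overlapping, in-frame codons; the trailing stop codon (if present)
#' is dropped from both counts and length; internal codons containing
#' ambiguous bases (N) are skipped and counted in `n_skipped`. Lowercase
#' and U/T spellings are normalized.
#'
#' @param cds Coding sequence (single character string, ACGTU/N alphabet).
#' @param id Optional transcript id used in error messages.
#' @return Object of class `codon_stats`: `counts` (named integer),
#'   `n_codons`, `n_skipped`, `id`.
#' @export
#' @examples
#' count_codons("ATGGCGGCGAAATAA")$counts   # ATG:1 GCG:2 AAA:1
count_codons <- function(cds, id = NULL) {
  stopifnot(is.character(cds), length(cds) == 1)
  seq <- chartr("u", "t", tolower(cds))
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) {
    stop("invalid characters in CDS", if (!is.null(id)) paste0(" ", id))
  }
  n <- nchar(seq)
  if (n %% 3 != 0) {
    stop("CDS length not divisible by 3",
         if (!is.null(id)) paste0(" for transcript ", id))
  }
  starts <- seq.int(1, n, by = 3)
  codons <- substring(seq, starts, starts + 2)
  if (length(codons) && codons[length(codons)] %in% STOP_CODONS) {
    codons <- codons[-length(codons)]
  }
  has_n <- grepl("N", codons, fixed = TRUE)
  n_skipped <- sum(has_n)
  if (n_skipped > 0) {
    warning(n_skipped, " codon(s) with ambiguous bases skipped",
            if (!is.null(id)) paste0(" in ", id))
  }
  codons <- codons[!has_n]
  tab <- table(codons)
  out <- list(counts = setNames(as.integer(tab), names(tab)),
              n_codons = length(codons), n_skipped = n_skipped, id = id)
  class(out) <- "codon_stats"
  out
}

#' @export
print.codon_stats <- function(x, ...) {
  cat(sprintf("Codon stats%s: %d codons (%d skipped), %d distinct\n",
              if (!is.null(x$id)) paste0(" [", x$id, "]") else "",
              x$n_codons, x$n_skipped, length(x$counts)))
  invisible(x)
}

#' Suboptimal codons per kilobase of coding sequence
#'
#' `(number of codons with CSC < 0) / (coding kb)`, with coding length
#' `3 * n_codons / 1000` kb (stop codon excluded from numerator and
#' denominator, start codon included).
#'
#' @param stats A [count_codons()] result (or its `counts`/`n_codons` as a
#'   list).
#' @param csc Named numeric: codon -> codon stability coefficient.
#' @return Suboptimal codons per kb.
#' @export
#' @examples
#' s <- count_codons("ATGGCGGCGAAATAA")
#' suboptimal_per_kb(s, c(GCG = -0.1, ATG = 0.1, AAA = 0.2))  # 166.67
suboptimal_per_kb <- function(stats, csc) {
  counts <- stats$counts
  n_codons <- stats$n_codons
  if (n_codons == 0) return(NA_real_)
  missing <- setdiff(names(counts), names(csc))
  if (length(missing)) {
    stop("codon(s) missing from CSC table: ",
         paste(missing, collapse = ", "))
  }
  subopt <- names(csc)[csc < 0]
  sum(counts[names(counts) %in% subopt]) / (3 * n_codons / 1000)
}

#' Per-transcript codon statistics for a set of CDS sequences
#'
#' @param cds_set Named character vector of CDS sequences (or a
#'   `Biostrings::DNAStringSet`).
#' @param csc Named CSC vector; default synthetic table.
#' @return data.frame: `transcript_id`, `n_codons`, `subopt_per_kb`; the
#'   full codon count matrix is attached as `attr(, "codon_counts")`.
#' @export
codon_stats_table <- function(cds_set, csc = default_csc()) {
  if (inherits(cds_set, "DNAStringSet")) {
    cds_set <- setNames(as.character(cds_set), names(cds_set))
  }
  if (is.null(names(cds_set))) stop("cds_set must be named")
  ids <- names(cds_set)
  all_codons <- sense_codons()
  mat <- matrix(0L, nrow = length(ids), ncol = length(all_codons),
                dimnames = list(ids, all_codons))
  n_codons <- integer(length(ids))
  spkb <- numeric(length(ids))
  for (i in seq_along(ids)) {
    s <- count_codons(cds_set[[i]], id = ids[i])
    known <- intersect(names(s$counts), all_codons)
    mat[i, known] <- s$counts[known]
    n_codons[i] <- s$n_codons
    spkb[i] <- suboptimal_per_kb(s, csc)
  }
  out <- data.frame(transcript_id = ids, n_codons = n_codons,
                    subopt_per_kb = spkb, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "codon_counts") <- mat
  out
}

#' Codon enrichment of a transcript set relative to background
#'
#' `ratio_c = (set relative abundance of c) / (background relative
#' abundance of c)`; codons absent from the background are NA (not Inf).
#'
#' @param set_counts,background_counts Named codon count vectors (e.g.
#'   column sums of the matrix attached by [codon_stats_table()]).
#' @return Named numeric vector of enrichment ratios over the background's
#'   codons.
#' @export
codon_enrichment <- function(set_counts, background_counts) {
  if (sum(background_counts) <= 0) stop("background total must be > 0")
  if (length(set_counts) == 0 || sum(set_counts) <= 0) {
    stop("set counts are empty")
  }
  codons <- names(background_counts)
  s <- setNames(rep(0, length(codons)), codons)
  common <- intersect(names(set_counts), codons)
  s[common] <- set_counts[common]
  set_rel <- s / sum(set_counts)
  bg_rel <- background_counts / sum(background_counts)
  ratio <- ifelse(bg_rel > 0, set_rel / bg_rel, NA_real_)
  setNames(ratio, codons)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |F_x - F_y|` over the pooled sample points, with the p-value
#' from the asymptotic Kolmogorov distribution at effective sample size
#' `n_eff = nx * ny / (nx + ny)`.
#'
#' @param x,y Numeric samples (each nonempty; a warning is issued below 10
#'   values, where the asymptotic p-value is unreliable).
#' @return List: `statistic` (D), `p_value`, `n_x`, `n_y`, `n_eff`.
#' @export
#' @examples
#' ks_two_sample(c(1, 2), c(3, 4))$statistic   # disjoint supports: D = 1
ks_two_sample <- function(x, y) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  if (min(length(x), length(y)) < 10) {
    warning("sample size < 10; asymptotic p-value is unreliable")
  }
  sx <- sort(x); sy <- sort(y)
  v <- sort(unique(c(sx, sy)))
  fx <- findInterval(v, sx) / length(sx)
  fy <- findInterval(v, sy) / length(sy)
  d <- max(abs(fx - fy))
  n_eff <- length(x) * length(y) / (length(x) + length(y))
  lambda <- sqrt(n_eff) * d
  if (lambda == 0) {
    p <- 1
  } else {
    j <- seq_len(200)
    p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))
    p <- min(max(p, 0), 1)
  }
  list(statistic = d, p_value = p,
       n_x = length(x), n_y = length(y), n_eff = n_eff)
}
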