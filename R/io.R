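# File formats and the end-to-end pipeline driver.
#
# All TSV outputs begin with provenance comment lines:
#   # schema=<name>_v1
#   # tool=tlkinetics <version>
#   # seed=<seed>  config_sha=<hash>
# Readers skip '#' lines and, when asked, verify the schema tag.

CONVERSION_SCHEMA <- "conversion_counts_v1"
CONVERSION_COLUMNS <- c("sample_id", "condition", "replicate",
                        "transcript_id", "n_T", "k_TC", "n_A", "k_AG",
                        "read_count")

# Small stable content hash for provenance headers (polynomial rolling
# hash over the serialized object, hex). Stays within exact double range.
.config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, ascii = TRUE))
  h <- 17
  for (b in bytes) {
    h <- (h * 257 + b + 1) %% 2147483647
  }
  sprintf("%08x", h)
}

.provenance <- function(schema, seed = NULL, config = NULL) {
  c(paste0("# schema=", schema),
    paste0("# tool=tlkinetics ", as.character(packageVersion("tlkinetics"))),
    paste0("# seed=", if (is.null(seed)) "NA" else seed,
           " config_sha=",
           if (is.null(config)) "NA" else .config_hash(config)))
}

.validate_conversion_table <- function(df) {
  if (!is.data.frame(df) || nrow(df) == 0) {
    stop("conversion-count table must be a nonempty data.frame")
  }
  missing <- setdiff(CONVERSION_COLUMNS, names(df))
  if (length(missing)) {
    stop("conversion-count table lacks column(s): ",
         paste(missing, collapse = ", "),
         "; expected header: ", paste(CONVERSION_COLUMNS, collapse = "\t"))
  }
  bad <- which(df$k_TC > df$n_T | df$k_TC < 0 | df$n_T < 0)
  if (length(bad)) {
    stop("invalid row(s) ", paste(head(bad, 5), collapse = ", "),
         ": need 0 <= k_TC <= n_T")
  }
  bad <- which(df$k_AG > df$n_A | df$k_AG < 0 | df$n_A < 0)
  if (length(bad)) {
    stop("invalid row(s) ", paste(head(bad, 5), collapse = ", "),
         ": need 0 <= k_AG <= n_A")
  }
  if (any(df$read_count < 0)) stop("read_count must be >= 0")
  key <- paste(df$sample_id, df$transcript_id, df$n_T, df$k_TC)
  if (anyDuplicated(key)) {
    stop("duplicate (sample, transcript, n_T, k_TC) key at row ",
         which(duplicated(key))[1])
  }
  invisible(df)
}

#' Write / read a generic provenance-stamped TSV
#'
#' @param df data.frame to write.
#' @param path File path.
#' @param schema Schema tag recorded in (and checked against) the header.
#' @param seed,config Optional provenance fields.
#' @return `write_tl_table()` returns `path` invisibly; `read_tl_table()`
#'   the data.frame.
#' @export
write_tl_table <- function(df, path, schema, seed = NULL, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance(schema, seed, config), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tl_table
#' @export
read_tl_table <- function(path, schema = NULL) {
  first <- readLines(path, n = 1)
  if (!is.null(schema)) {
    tag <- paste0("# schema=", schema)
    if (!identical(first, tag)) {
      stop("schema mismatch in ", path, ": expected '", tag,
           "', found '", first, "'")
    }
  }
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Write / read a conversion-count table
#'
#' The table is validated (column schema, `0 <= k_TC <= n_T`,
#' `0 <= k_AG <= n_A`, unique `(sample, transcript, n_T, k_TC)` keys) on
#' both write and read; violations name the offending row.
#'
#' @param df Conversion-count data.frame.
#' @param path File path.
#' @param seed,config Optional provenance fields.
#' @return The validated data.frame (read) or `path` (write, invisibly).
#' @export
write_conversion_table <- function(df, path, seed = NULL, config = NULL) {
  .validate_conversion_table(df)
  write_tl_table(df[, CONVERSION_COLUMNS], path, CONVERSION_SCHEMA,
                 seed, config)
}

#' @rdname write_conversion_table
#' @export
read_conversion_table <- function(path) {
  df <- read_tl_table(path, CONVERSION_SCHEMA)
  .validate_conversion_table(df)
  df
}

#' Read a codon stability coefficient table
#'
#' Two-column TSV (`codon`, `csc`); codons must be valid 3-letter sense
#' codons (T alphabet), stop codons are rejected.
#'
#' @param path TSV path.
#' @return Named numeric vector codon -> CSC.
#' @export
read_csc <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("codon", "csc") %in% names(df))) {
    stop("CSC table needs columns 'codon' and 'csc'")
  }
  codon <- toupper(chartr("Uu", "Tt", df$codon))
  if (any(codon %in% STOP_CODONS)) {
    stop("CSC table must not contain stop codons: ",
         paste(intersect(codon, STOP_CODONS), collapse = ", "))
  }
  bad <- codon[!codon %in% sense_codons()]
  if (length(bad)) stop("invalid codon(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(codon)) stop("duplicate codons in CSC table")
  setNames(as.numeric(df$csc), codon)
}

#' The synthetic CSC table shipped with the package
#'
#' A synthetic stand-in for published codon stability coefficients (the
#' real tables are experiment-specific): deterministic values in which
#' AT-rich and Cys/His codons tend to be suboptimal (negative CSC).
#'
#' @return Named numeric vector over the 61 sense codons.
#' @export
default_csc <- function() {
  read_csc(system.file("extdata", "csc_synthetic.tsv",
                       package = "tlkinetics", mustWork = TRUE))
}

#' Write / read CDS sequences as FASTA
#'
#' Thin wrappers over Biostrings; reading tolerates wrapped lines and
#' rejects duplicate ids.
#'
#' @param cds_set Named character vector of sequences.
#' @param path FASTA path.
#' @return Named character vector (read) or `path` (write, invisibly).
#' @export
write_cds_fasta <- function(cds_set, path) {
  stopifnot(!is.null(names(cds_set)))
  x <- Biostrings::DNAStringSet(cds_set)
  Biostrings::writeXStringSet(x, filepath = path, width = 60)
  invisible(path)
}

#' @rdname write_cds_fasta
#' @export
read_cds_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (anyDuplicated(names(x))) {
    stop("duplicate transcript ids in ", path)
  }
  setNames(as.character(x), names(x))
}

#' Run the full analysis pipeline on simulated data
#'
#' Simulates a labeling experiment under `config`, then runs every stage:
#' conversion-rate estimation and chemistry QC (against a simulated -s4U
#' control), fraction-new fitting, differential and mechanism statistics,
#' half-lives, classification, codon-optimality statistics, KS comparisons
#' between class distributions, ribosome-profiling and qPCR assay
#' statistics, and a summary. Deterministic given `config$seed`.
#'
#' @param config [sim_config()].
#' @param class_config [classification_config()].
#' @param normalization `"median-ratios"` or `"spike-in"`.
#' @param csc CSC table (named vector).
#' @param outdir Optional directory; when given, all stage outputs are
#'   written as provenance-stamped TSV/JSON/FASTA files.
#' @return Object of class `tl_report`.
#' @export
run_pipeline <- function(config = sim_config(),
                         class_config = classification_config(),
                         normalization = c("median-ratios", "spike-in"),
                         csc = default_csc(),
                         outdir = NULL) {
  normalization <- match.arg(normalization)
  truth <- make_truth(config, csc)
  tab_u <- simulate_counts(truth, config, "untreated")
  tab_t <- simulate_counts(truth, config, "treated")
  table <- rbind(tab_u, tab_t)
  ctrl_cfg <- config
  ctrl_cfg$seed <- .derive_seed(config$seed, 9L)
  no_s4u <- simulate_counts(truth, ctrl_cfg, "untreated",
                            pnew = config$pbg)
  qc <- qc_conversion_bias(table, no_s4u)
  dyn <- tl_dynamics(table, t_label = config$t_label,
                     no_s4u_table = no_s4u,
                     normalization = normalization)
  classes <- classify_transcripts(dyn, class_config)
  classes$class_true <- truth$class_label[
    match(classes$transcript_id, truth$transcript_id)]

  cds_set <- setNames(truth$cds, truth$transcript_id)
  codon <- codon_stats_table(cds_set, csc)
  codon$label <- classes$label[match(codon$transcript_id,
                                     classes$transcript_id)]

  expressed <- classes$label != "low_expression"
  ks_esm <- ks_osl <- NULL
  spkb_all <- codon$subopt_per_kb[match(
    classes$transcript_id[expressed], codon$transcript_id)]
  esm_ids <- classes$transcript_id[classes$label == "ESM"]
  osl_ids <- classes$transcript_id[classes$label == "OSL"]
  if (length(esm_ids) >= 2) {
    ks_esm <- suppressWarnings(ks_two_sample(
      codon$subopt_per_kb[match(esm_ids, codon$transcript_id)], spkb_all))
  }
  if (length(osl_ids) >= 2) {
    ks_osl <- suppressWarnings(ks_two_sample(
      codon$subopt_per_kb[match(osl_ids, codon$transcript_id)], spkb_all))
  }

  ribo <- simulate_ribo(truth, config)
  ribo$te <- translation_efficiency(ribo$ribo, ribo$rna)
  ribo$log2_disome_monosome <- disome_monosome(ribo$disome, ribo$monosome)
  qpcr <- simulate_qpcr(truth, config)
  qpcr_folds <- ddct(qpcr)

  hl_by <- function(lab) {
    v <- classes$half_life[classes$label == lab]
    v <- v[is.finite(v)]
    if (length(v)) median(v) else NA_real_
  }
  summary <- list(
    seed = config$seed,
    n_transcripts = config$n_transcripts,
    n_expressed = sum(expressed),
    class_counts = as.list(table(classes$label)),
    median_half_life_all = median(
      classes$half_life[expressed & is.finite(classes$half_life)]),
    median_half_life_esm = hl_by("ESM"),
    median_half_life_osl = hl_by("OSL"),
    subopt_top_quartile = top_quartile_threshold(codon$subopt_per_kb),
    ks_esm_vs_all = if (!is.null(ks_esm)) {
      list(D = ks_esm$statistic, p = ks_esm$p_value)
    },
    ks_osl_vs_all = if (!is.null(ks_osl)) {
      list(D = ks_osl$statistic, p = ks_osl$p_value)
    },
    qc_pass = qc$pass,
    pnew = dyn$pnew, pbg = dyn$pbg,
    thresholds = unclass(class_config))

  report <- list(truth = truth, table = table, qc = qc, dynamics = dyn,
                 classes = classes, codon = codon, ribo = ribo,
                 qpcr = qpcr, qpcr_folds = qpcr_folds,
                 summary = summary, config = config,
                 class_config = class_config,
                 normalization = normalization)
  class(report) <- "tl_report"
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

#' Write every pipeline output to a directory
#'
#' @param report A `tl_report`.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg <- report$config
  seed <- cfg$seed
  p <- function(f) file.path(outdir, f)
  write_conversion_table(report$table, p("conversion_counts.tsv"),
                         seed = seed, config = cfg)
  truth_cols <- setdiff(names(report$truth), "cds")
  write_tl_table(report$truth[, truth_cols], p("truth.tsv"),
                 "truth_v1", seed, cfg)
  write_cds_fasta(setNames(report$truth$cds, report$truth$transcript_id),
                  p("cds.fasta"))
  write_tl_table(report$dynamics$estimates, p("mixture_estimates.tsv"),
                 "mixture_estimates_v1", seed, cfg)
  write_tl_table(report$dynamics$results, p("dynamics_results.tsv"),
                 "dynamics_results_v1", seed, cfg)
  write_tl_table(as.data.frame(report$classes), p("classification.tsv"),
                 "classification_v1", seed, cfg)
  write_tl_table(report$codon, p("codon_stats.tsv"),
                 "codon_stats_v1", seed, cfg)
  write_tl_table(report$ribo, p("assays.tsv"), "assays_v1", seed, cfg)
  write_tl_table(report$qpcr, p("qpcr_ct.tsv"), "qpcr_ct_v1", seed, cfg)
  write_tl_table(report$qpcr_folds, p("qpcr_folds.tsv"),
                 "qpcr_folds_v1", seed, cfg)
  jsonlite::write_json(unclass(report$qc), p("qc.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(report$summary, p("summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' @export
print.tl_report <- function(x, ...) {
  s <- x$summary
  cat("tlkinetics pipeline report (seed ", s$seed, ")\n", sep = "")
  cat(sprintf("  chemistry QC: %s (pnew %.4g, pbg %.4g)\n",
              if (s$qc_pass) "PASS" else "FAIL", s$pnew, s$pbg))
  cat(sprintf("  expressed transcripts: %d of %d\n",
              s$n_expressed, s$n_transcripts))
  cc <- s$class_counts
  cat("  classes:", paste(sprintf("%s=%d", names(cc), unlist(cc)),
                          collapse = ", "), "\n")
  cat(sprintf("  median half-life (h): all %.2f, ESM %.2f, OSL %.2f\n",
              s$median_half_life_all,
              if (is.null(s$median_half_life_esm)) NA else s$median_half_life_esm,
              if (is.null(s$median_half_life_osl)) NA else s$median_half_life_osl))
  if (!is.null(s$ks_esm_vs_all)) {
    cat(sprintf("  suboptimal codons/kb, ESM vs all: KS D = %.3f (p = %.3g)\n",
                s$ks_esm_vs_all$D, s$ks_esm_vs_all$p))
  }
  cat(sprintf("  suboptimal/kb top-quartile threshold: %.1f\n",
              s$subopt_top_quartile))
  invisible(x)
}
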