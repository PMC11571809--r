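# tlkinetics

Kinetic analysis of nucleotide-recoding RNA-seq (s4U metabolic labeling
with T-to-C recoding chemistry, e.g. TimeLapse-/SLAM-style protocols) for
experiments in which a perturbation is applied **at the same instant
labeling begins**. The central question it answers, per transcript:
*is an expression change driven by a change in synthesis or a change in
decay?*

## Who this is for

Transcriptomics researchers with conversion-count tables (reads binned by
T positions and T-to-C conversions per transcript and sample) from a
labeling experiment run concurrently with a treatment — the motivating
design is low-dose translation-elongation inhibition, which stabilizes a
distinct set of short-lived, suboptimal-codon-rich mRNAs — and anyone who
wants a fully seeded simulator of such experiments to validate an analysis
chain.

## The model

Each transcript follows first-order kinetics with synthesis rate `ksyn`
and decay rate `kdeg`; at steady state the fraction of reads that are new
after labeling for time `t` is

```
theta = 1 - exp(-kdeg * t),     t_half = ln(2) / kdeg
```

A step perturbation at `t = 0` (multipliers `f_syn`, `f_deg`) gives
closed-form old/new pools:

```
old(t) = (ksyn / kdeg) * exp(-f_deg * kdeg * t)
new(t) = (f_syn * ksyn / (f_deg * kdeg)) * (1 - exp(-f_deg * kdeg * t))
```

Per transcript and sample, `theta` is estimated by maximum likelihood in a
two-component binomial mixture over read histograms (new reads convert Ts
at `pnew`, old reads at background `pbg`), via EM with Fisher-information
standard errors. Downstream statistics:

* **fraction new score** `z_fn`: standardized change in logit theta
  between conditions (negative = fewer labeled reads under treatment);
* **differential expression**: log-normal Wald test with median-of-ratios
  or spike-in size factors and trend-shrunk variances;
* **decay-rate fold change**: non-steady-state inversion of the forward
  model for the treated decay rate;
* **mechanism score**: standardized residual of the observed theta change
  against the change a pure-synthesis explanation of the observed fold
  change would produce — near 0 for transcription-driven changes,
  strongly negative for stabilization;
* **classification** into ESM (stabilized), TCM (transcriptionally
  changed), destabilized, OSL (other short-lived), unchanged;
* **codon-optimality statistics** (suboptimal codons per kb from a codon
  stability coefficient table, per-codon enrichment, Kolmogorov-Smirnov
  comparisons) and assay statistics (translation efficiency,
  disome/monosome ratios, ddCt fold changes).

A synthetic-data generator (`sim_config()`, `make_truth()`,
`simulate_counts()`, `simulate_ribo()`, `simulate_qpcr()`) produces ground
truth with exactly the statistical structure the analysis assumes, so the
whole chain is testable end to end. See the methods vignette
(`vignettes/nucleotide-recoding-kinetics.Rmd`) for assumptions, defaults,
numerical choices, and limitations.

## Worked example

```r
library(tlkinetics)
cfg <- sim_config(n_transcripts = 100, depth_per_transcript = 8000, seed = 42)
report <- run_pipeline(cfg)
print(report)
```

```
tlkinetics pipeline report (seed 42)
  chemistry QC: PASS (pnew 0.0495, pbg 0.001975)
  expressed transcripts: 100 of 100
  classes: ESM=23, OSL=29, TCM=4, unchanged=44
  median half-life (h): all 0.76, ESM 0.33, OSL 0.49
  suboptimal codons/kb, ESM vs all: KS D = 0.770 (p = 4.69e-10)
  suboptimal/kb top-quartile threshold: 186.4
```

Reading this: the conversion chemistry QC passed (T-to-C rate far above
the -s4U background, A-to-G decoy rates flat); the estimated conversion
rates recover the simulation truth (0.05 / 0.002); 23 transcripts are
called ESM — stabilized, i.e. their abundance rose while their fraction
new fell and the mechanism score rules out a synthesis explanation. As the
biology predicts, ESMs are the short-lived transcripts (median half-life
0.33 h vs 0.76 h for all expressed) and their suboptimal-codon density is
strongly right-shifted against the background (KS D = 0.77). Individual
calls:

```r
head(subset(report$classes, label == "ESM",
     select = c(transcript_id, theta_untreated, theta_treated, lfc, mech)), 2)
```

```
   transcript_id theta_untreated theta_treated      lfc      mech
13       tx_0003       0.8373869     0.6924635 1.181060 -10.89839
17       tx_0007       0.8942767     0.7279268 1.239105 -20.81662
```

`tx_0003`: abundance up 2.3-fold (`lfc` 1.18) while theta dropped from
0.84 to 0.69 — eleven standard errors below what a synthesis change could
explain (`mech` = -10.9): a decay-driven increase.

Real data enter through `read_conversion_table()` (schema documented in
`?write_conversion_table`), then `tl_dynamics()` +
`classify_transcripts()`.

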