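# ire1ridd

IRE1 is an endoplasmic-reticulum stress sensor whose endoribonuclease both
splices *XBP1* mRNA (producing the active transcription factor XBP1s) and
degrades other mRNAs that present a CNGCNG consensus inside an RNA stem–loop —
a process called **regulated IRE1-dependent decay (RIDD)**. `ire1ridd` is an R
package for asking, from bulk transcript-level expression data of a
two-condition cohort (e.g. patients vs controls), whether IRE1 activity is
elevated and whether isoform switching changes which transcripts RIDD can
recognize.

It is aimed at computational biologists working with transcript-level
quantifications (TPM), transcript models (GTF), transcript and promoter
sequences (FASTA), and optionally a matched protein-abundance matrix.

## What it computes

**RIDD target-site prediction.** Transcripts are scanned for the degenerate
10-mer `NNCNGCNGNN`. Each match is embedded in a window (motif ± 15 nt) and
scored with a single-hairpin Boltzmann ensemble: every stem of *s* contiguous
pairs (AU/UA, GC/CG, GU/UG; *s* ≥ 4) enclosing a loop of 4–12 nt gets weight
e^(βs) against an open chain of weight 1, and the site probability is

&nbsp;&nbsp;&nbsp;&nbsp;P(site) = Z_loop / Z_total,

where Z_loop sums only hairpins whose loop fully contains the CNGCNG hexamer.
Sites with P > 0.9 are called; a gene whose isoforms disagree on carrying a
site is *differentially RIDD-recognizable*.

**Isoform switching.** Per-sample isoform fractions IF(t) = TPM(t)/Σ gene TPM,
dIF = mean IF(disease) − mean IF(control), significance by a label-permutation
test (batch-stratified) with BH correction; a switch needs FDR < 0.05 *and*
|dIF| > 0.10 (both strict). Switch consequences are classified from the
transcript models: 3'/5' UTR gain (A3/A5), domain loss, coding → non-coding,
with Wilson 95% intervals on per-event gene fractions.

**IRE1 activity score.** For a panel of RIDD targets plus the XBP1s/XBP1u
pair, each feature's samples are assigned quantile bins 1..Q (RIDD targets and
XBP1u inverted: lower expression ⇒ higher bin); a sample's score is the sum of
its bins divided by the number of features. Scores are split into
low/medium/high tertiles and tested against condition with Pearson chi-squared
(Monte-Carlo null when expected counts are small), with Cramér's V as effect
size.

**Splice-event × RIDD association.** Per gene, the phi coefficient between
binary event flags and RIDD flags across isoforms (|phi| > 0.5 reported);
globally, chi-squared, Cramér's V and plug-in mutual information (bits) on the
pooled 2×2 table. RIDD *candidates* are isoforms that carry a site and are
significantly downregulated.

**XBP1s promoter scanning.** FIMO-style PWM scanning of promoter sequences on
both strands with exact p-values computed by dynamic programming over
integer-discretized log2-odds scores (p < 0.0005, strict); genes hit by both
RIDD and XBP1s are intersected and checked for the discordant
transcript-down/protein-up pattern.

**Synthetic cohort generator.** `make_cohort()` builds a fully seeded 12 vs 12
study — transcript models, sequences with planted stem-loops, promoters with
planted PWM instances, expression with planted RIDD degradation / XBP1s shift
/ isoform switches, and a correlated protein layer — plus a machine-readable
truth table, so every stage is testable without external data.

## Worked example

```r
library(ire1ridd)

co <- make_cohort(cohort_config(seed = 1))   # 12 vs 12 synthetic cohort
co$expr
#> <expression_matrix> 150 features x 24 samples (control: 12, disease: 12)

sites <- scan_transcriptome(co$models)
head(sites[, c("transcript_id", "motif_start", "motif_seq", "hairpin_prob", "region")], 3)
#>   transcript_id motif_start  motif_seq hairpin_prob region
#> 1       g001.t2         485 CACTGCAGGG    0.9646068   3UTR
#> 2       g005.t2         634 CTCCGCGGGT    0.9769787   3UTR
#> 3       g014.t2         416 CACCGCCGGG    0.9971169   3UTR

evaluate_site_recovery(sites, co$truth)[c("sensitivity", "fdr")]
#> sensitivity 1.00, FDR 0.00 over 18 planted sites

records <- test_switches(isoform_fractions(co$expr, co$models),
                         n_perm = 10000, seed = 2, expr = co$expr)
event_fractions(call_consequences(records, co$models))
#>                  event n fraction ci_lower ci_upper
#> 1              A3_gain 7   0.2692  0.13704    0.461
#> 2              A5_gain 5   0.1923  0.08507    0.379
#> 3          domain_loss 6   0.2308  0.11034    0.421
#> 4 transcript_noncoding 1   0.0385  0.00682    0.189

scores <- categorize(score_samples(co$expr, co$panel, Q = 4))
head(scores, 3)
#>   sample_id score condition category
#> 1       C01  1.65   control   medium
#> 2       C02  1.80   control   medium
#> 3       C03  1.40   control      low

association_test(scores$category, scores$condition, seed = 3)
#> chi2 = 16.00 (df 2), p = 0.00019, Cramers V = 0.816
```

The scan recovers all 18 planted stem-loop sites with no false calls; the
event fractions are the per-consequence shares of the 26 switching genes with
their Wilson intervals; and the disease samples' higher IRE1 scores give a
strong score-category × condition association (the Monte-Carlo chi-squared p
and Cramér's V above). `run_synthetic(run_config(seed = 1))` runs all stages
in order and returns the aggregated report; with `outdir=` it also writes the
per-stage TSVs and `report.json`, each with a seed/threshold provenance
header.

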