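---
title: "Models and methods behind ire1ridd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ire1ridd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models: what each stage
computes, which choices were genuinely open and how they were decided, what
the synthetic cohort does and does not emulate, and the numerical details a
user should know before trusting a result.

## The biological question

IRE1's endoribonuclease has two outputs: splicing of *XBP1* mRNA (shifting
usage from the unspliced XBP1u isoform to the active XBP1s), and degradation
of mRNAs that present a CNGCNG consensus within a stem–loop (RIDD). Both
leave footprints in bulk transcript-level expression: XBP1 isoform usage
shifts, known RIDD targets drop, and — because isoforms of one gene can differ
in UTRs and exon content — isoform switching can move a transcript into or out
of RIDD's substrate space. The package quantifies these footprints in a
two-condition cohort and tests their association with disease status. It does
not, and cannot, establish causal direction: whether switching creates RIDD
sites or IRE1 activity drives the switching is left open by design.

## RIDD site model

**Motif.** The scanner reports every occurrence of the degenerate 10-mer
`NNCNGCNGNN` (fixed C/G/C/G at positions 3, 5, 6, 8), including overlaps. `N`
in a sequence never satisfies a fixed position and never pairs in structures.
Sequences are stored in a single ACGT alphabet (U is normalized to T on
input) and treated as the mRNA sense strand.

**Structure ensemble.** No standard definition exists for "the probability
that a window forms a stem–loop", so the package uses the smallest model that
has one: the window (motif ± `flank` = 15 nt, clipped to the transcript) is
assigned an ensemble containing the open chain (weight 1) and every single
hairpin — a stem of `s` contiguous pairs from {AU/UA, GC/CG, GU/UG} directly
enclosing a loop of length 4–12, with `min_stem` = 4 ≤ `s` ≤ `flank` — with
Boltzmann weight e^(βs), β = 1 per pair. The site probability is
Z_loop/Z_total, where Z_loop restricts to hairpins whose loop fully contains
the CNGCNG hexamer. The implementation groups hairpins by loop placement,
extends the stem outward to its maximal run, and sums the geometric series in
log space, so it is exact (the test suite checks equality with brute-force
enumeration to 1e-9) and overflow-safe for large β (the β → ∞ limit selects
the maximum-pair structure). Windows shorter than `2·min_stem + 4` score 0.

The defaults — flank 15 nt, hence windows ≤ 40 nt and stems ≤ 15 bp — cover
IRE1-type hairpins while keeping the enumeration oracle feasible; GU pairs are
allowed because the substrate is RNA even though storage is DNA-alphabet. A
transcript is *RIDD-recognizable* if at least one motif exceeds the
probability threshold (0.9, strict). Among retained sites with overlapping
windows only the most probable is kept, so downstream 2×2 tables do not count
one physical hairpin twice. This ensemble is deliberately not a thermodynamic
folder: it has one energy parameter, no stacking or loop-entropy terms, and no
multi-branch structures. Users wanting physical energies should treat the
probability as a calibrated score, not a partition function over real RNA.

**Region annotation** uses the hexamer start against the transcript's
UTR/CDS boundaries; non-coding transcripts annotate all sites `non_coding`.
The scan covers the whole transcript (which regions the original analyses
restricted to is not documented anywhere authoritative), and the region column
lets users filter afterwards.

## Isoform switching

Isoform fraction IF(t, sample) = TPM(t)/Σ TPM over the gene; samples where a
gene totals zero are excluded for that gene. dIF is the difference of
condition means. Significance uses a two-sided permutation test on that
statistic (10,000 label permutations by default, stratified within batch when
batch labels exist), with the `(1 + #better)/(B + 1)` estimator so a constant
isoform gets p = 1; an arcsine-square-root linear model with a batch covariate
is available as `method = "lm"`. The dedicated exon-part GLM machinery used by
isoform-switch tools built on read-level counts is intentionally *not*
re-implemented — the package's contribution is the downstream IRE1 logic, and
the permutation test is exactly specified, assumption-light, and
oracle-testable (type-I calibration is asserted in the test suite). P-values
are BH-adjusted across all isoforms; a switch requires FDR < 0.05 **and**
|dIF| > 0.10, both strict — boundary cases at exactly 0.05 or 0.10 are
excluded, and the test suite pins this.

Consequences compare each switching gene's most-increased against its
most-decreased significant isoform ("count each gene once per event"): 3'UTR
longer ⇒ A3 gain (5'UTR ⇒ A5), domain set strictly smaller ⇒ domain loss,
coding → non-coding ⇒ non-coding transcript; several events may co-occur.
Domains are user-supplied per-isoform annotations; the package does not
predict them. Per-event gene fractions carry Wilson score 95% intervals.

Differential expression (gene, transcript or protein level) is deliberately
minimal: drop features with > 50% zeros, log2(x+1), per-sample median
centring, per-batch feature-mean removal, Welch t-test, BH. The protein layer
follows the convention of using the raw p < 0.05 for significance rather than
the FDR; log2 fold changes use a pseudocount of 1 TPM so they stay bounded at
zero. Note log2(x+1) makes a planted 2-fold change slightly less than 1
log2-unit at finite abundance; tests assert recovery to 1%.

## IRE1 activity score

For each panel feature (published RIDD targets plus the XBP1 isoform pair),
samples are ranked by that feature's TPM and binned into Q quantiles (Q = 4 by
default; the choice of Q is exposed because nothing deeper fixes it). RIDD
targets are scored inverted — degradation means *lower* expression signals
*higher* activity — and XBP1u is inverted for the same reason, while XBP1s is
direct. A sample's score is the sum of its bins divided by the number of
features, so it lives in [1, Q]. Ties share the average-rank bin, rounded
half-up; with position bins `ceiling(i·Q/n)` the score is invariant under any
monotone per-feature transform, and when Q divides n reversing every
feature's direction maps s → (Q+1) − s (both tested). The expression basis is
TPM per transcript, not isoform fraction, and the XBP1 isoforms enter as two
features rather than one ratio — both choices exposed as configuration.

Scores are categorized into low/medium/high tertiles (sizes differ by ≤ 1;
ties broken lexically by sample id for determinism; fewer than three distinct
scores raises a degeneracy flag) and tested against condition with Pearson
chi-squared without continuity correction. With 24 samples in 3×2 tables the
expected counts are 4 < 5, so the asymptotic p is replaced by a Monte-Carlo
p-value from tables drawn with both margins fixed (R's `r2dtable` engine
behind `chisq.test(simulate.p.value = TRUE)`; 100,000 draws by default, seeded)
and flagged as such. Cramér's V = sqrt(chi2/(n·min(r−1, c−1))) is reported as
effect size.

## Splice-event × RIDD association

The per-gene "correlation" is the phi coefficient — Pearson correlation of
two binary vectors, equal to ±sqrt(chi2/n) on a 2×2 layout — because both
variables (event flag, site flag) are binary; genes qualify when they have ≥ 2
isoforms, differential recognizability, and the event present, and pairs are
reported when |phi| strictly exceeds 0.5. Zero-variance genes are excluded
with a note rather than given an arbitrary value. Event flags are assigned
relative to the gene's canonical isoform (highest mean control isoform
fraction), which is the one structural choice this analysis needed that no
documentation fixes; it is encoded in `isoform_flags()` and can be bypassed by
passing your own flag table. Globally, all isoform rows pool into one 2×2
table per event type — genes contribute isoforms unweighted — scored with
chi-squared, Cramér's V and plug-in mutual information in bits. The plug-in
MI estimator is biased upward in small tables and is reported without
correction; MI = 0 exactly when chi2 = 0 on the plug-in estimates, and
candidates require site + significant downregulation (log2fc < 0, FDR <
0.05).

## Promoter scanning

PWMs come from the standard four-row JASPAR count format, regularized per
column with pseudocount 0.1 against the background (uniform by default) and
scored as log2-odds bits. Exact p-values are computed by dynamic programming
over integer-discretized scores at 1/1000 bit granularity — the same grid the
scanner uses for window scores, so scores and p-values are mutually
consistent; for widths ≤ 8 the DP provably matches full 4^w enumeration (a
test asserts it on random matrices). Scores above the maximal attainable one
return the smallest positive double rather than 0, keeping p ∈ (0, 1]. Both
strands are scanned, N-containing windows are skipped, all overlapping hits
are reported (no greedy masking), and a gene is an XBP1s candidate when its
promoter has ≥ 1 hit with p strictly below 5e-4. The promoter window itself
(length, anchor) is a user decision; synthetic promoters default to 1,000 nt.
The packaged 8-wide XBP1s-like matrix is a synthetic fixture (its filename
says so), not a database matrix: nothing in the package fetches external
resources.

## The synthetic cohort

`cohort_config()` defaults describe the emulated study: 12 control vs 12
disease samples; 60 genes with 2–3 isoforms; 30% RIDD genes, 30% switch
genes, one XBP1-like two-isoform gene; planted stem-loops with 6–8 bp stems
and 7–10 nt loops; RIDD isoforms divided by 2 in disease; XBP1s multiplied by
2 with XBP1u absorbing the difference so the pair total is conserved; switch
genes moving dIF = 0.30 of the gene total between their top two isoforms;
lognormal baselines (log2 mean 5, sd 2) with multiplicative noise at CV 0.2;
optional balanced batches with lognormal per-feature batch effects; TPM
column normalization to 1e6. Sequence lengths (~400–700 nt) and the cohort
size keep a full generate–scan–test–score cycle in seconds, which is what
makes the replicate-based calibration and power tests affordable; those are
the problem sizes used throughout the test suite.

Non-RIDD sequences are scrubbed of `NNCNGCNGNN` matches by iterative
scan-and-patch (mutating one fixed motif position per match and rescanning,
with a bounded attempt cap) — plain whole-sequence rejection would essentially
never terminate at kb scale, where a random sequence carries ~4 expected
matches. Planted sites are rejection-sampled until (a) the only motif match
near the site is the planted one and (b) the site's ensemble probability under
default scan parameters is ≥ 0.95 (`plant_min_prob`). The second condition
defines what "planted" means: GC-rich hexamers such as CGGCCG readily self-pair
in shifted registers, and an insert whose dominant fold buries the consensus
in a stem has not actually planted a stem-loop presentation of the motif.

Every planted fact — event types, site spans, effect sizes, XBP1 roles,
promoter offsets — is emitted in a truth table, and all recovery tests read
only that table. What the generator does *not* emulate: read-level sampling
noise (no FASTQ), realistic splice-graph complexity (isoforms differ by
exactly one event; sequences of sibling isoforms are drawn independently
rather than shared), length-coupled TPM bias, correlated gene programs, or
any estimate of a real dataset's noise parameters. Passing recovery tests
therefore demonstrates the pipeline's logic is correct under its own model of
the data, not that real-data sensitivity is 100%.

The generator is seeded end to end: one master seed fans out to per-stage
child seeds by fixed offsets, so stages are reproducible standalone and two
runs with the same configuration are byte-identical (asserted down to the
serialized report).

## Numerical and degenerate-input conventions

* Strict inequalities at all five thresholds (FDR 0.05, |dIF| 0.10, site
  probability 0.9, PWM p 5e-4, |phi| 0.5); boundary fixtures are tested.
* Permutation and Monte-Carlo p-values use `(1 + k)/(B + 1)`, never 0.
* Hairpin partition sums are accumulated in log space (`logsumexp`), exact for
  β = 1 and stable for β → ∞.
* Ties: quantile bins share the average-rank bin rounded half-up; tertile
  assignment breaks score ties by sample id.
* Degenerate inputs fail loudly or are flagged: zero-exon transcripts are
  skipped with a warning, all-zero panel features dropped with a warning,
  empty contingency margins collapsed with a warning or reported as NA,
  fewer than three distinct scores flagged degenerate, constant isoform
  fractions give p = 1.

## Known limitations

The structure model is a one-parameter ensemble, not thermodynamics; the
switch test replaces exon-level count machinery with a fraction-level
permutation test and so ignores read-level uncertainty; plug-in MI is biased
for small tables; the IRE1 score's bin count and tertile categorization are
conventions, exposed as parameters rather than estimated; and all association
results are correlational. The synthetic cohort validates internal
consistency, not field performance on real brain transcriptomes.
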