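---
title: "Classifying type II toxin–antitoxin operons from RNA-seq evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying type II toxin–antitoxin operons from RNA-seq evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taclass)
```

## The biological question

Type II toxin–antitoxin (TA) systems are two-gene bacterial operons encoding
a stable toxin and an unstable, protease-degraded antitoxin. A cell stays in
the normal (non-persister) state only while antitoxin production outpaces
toxin production; how the operon guarantees that excess — transcriptionally,
post-transcriptionally, or translationally — varies between systems and has
been argued about system by system. `taclass` operationalizes a four-class
regulatory taxonomy driven by operon organization and transcript evidence:

* **Class 1 — translational regulation.** One transcript covers both genes,
  so antitoxin and toxin mRNA concentrations are about equal (A/T coverage
  ratio below two-fold). The antitoxin excess must come from a higher
  translation initiation rate (TIR). The downstream gene's ribosome-binding
  site (RBS) typically lies inside the upstream gene's coding region.
* **Class 2 — transcriptional and translational.** A second *external*
  promoter close to the first CDS start produces a slightly shorter
  transcript with a weakened toxin RBS (HicAB is the model case: toxin
  upstream, non-overlapping genes).
* **Class 3 — transcript truncation.** The antitoxin mRNA exceeds the toxin
  mRNA about two-fold or more, without any promoter that could explain it;
  the toxin-coding region is truncated by an early terminator or targeted
  degradation, visible as a coverage step-down inside the toxin CDS.
* **Class 4 — internal promoter.** A promoter *inside* the operon's coding
  span produces an antitoxin-only transcript, visible as a coverage step-up
  upstream of the antitoxin CDS (RnlAB is the model case).

## Evidence channels and their statistics

### Coverage ratios

Per-gene coverage is RPKM, $10^9 n / (L T)$, with $n$ the reads mapped to
the CDS (reads mapping to more than one genomic region count 0.5 each — so
counts are half-integers), $L$ the CDS length and $T$ the library's total
mapped reads. The operon's A/T ratio is the **median** of the per-dataset
ratios across all replicate datasets (the reference design is 13 datasets:
one condition in triplicate plus five conditions in duplicate), and the
spread is the standard deviation of the same 13 values. Because the ratio is
$(n_A/L_A)/(n_T/L_T)$, the library size cancels exactly; the package tests
assert this invariance. An operon is excluded when toxin or antitoxin
averages below one read per base ($n/L < 1$) in strictly more than half of
the datasets — "more than half" is read strictly, so 6 of 13 low datasets
still pass and 7 do not.

The standard deviation uses the sample ($n-1$) denominator by default
(`sd_denom = "sample"`); the population denominator is available because
published pipelines differ and the choice is not derivable from the printed
tables.

### Replicate log-error in two directions

Replicate uncertainty is decomposed along the two natural axes of a
log–log coverage scatter: the **log-ratio** $\ln c_A - \ln c_T$ and the
**log-magnitude** $\ln c_A + \ln c_T$. Each standard error is the sample SD
over a condition's replicates divided by $\sqrt{m}$, reported both in
natural-log and (scaled by $1/\ln 10$) in log10 units for plotting. The
log-ratio error is exactly zero whenever all replicates share the same
ratio, however much the overall magnitude varies — that separation is the
point of the decomposition. Conditions are analyzed separately (triplicate
and duplicate groups); the additional pooled estimate, whose variance is
the mean of the per-condition variances, is this package's own convention
and both are emitted.

### Coverage changepoints

Classes 3 and 4 leave a step in base-resolution coverage. The detector fits
piecewise-constant means to $\ln(1+x)$ — a variance-stabilizing transform
for overdispersed counts — over every breakpoint leaving both segments at
least `min_segment` (50) nt, and accepts the best split only if it beats
the single-segment fit by `bic_threshold` (10) BIC units (Gaussian SSE
approximation, two extra parameters for the second mean and the breakpoint
location) **and** the raw-coverage fold across the step reaches `min_fold`
(2). One breakpoint is searched, because each class architecture implies at
most one internal feature; both thresholds are configurable and the BIC
form is an explicit heuristic, not a calibrated test. An all-zero profile
returns no call.

### TIR consensus

Sequence-based TIR calculators disagree in magnitude, so only the *sign* —
is the antitoxin TIR above the toxin TIR? — is combined, by a two-of-three
majority. Fewer than two usable calls is "insufficient"; a method whose two
values tie is rejected rather than counted as half a vote, since published
sign tables contain only +/− entries. For operons with two promoter
variants the consensus is computed per variant; the HicAB case flips from
toxin-higher (P1) to antitoxin-higher (P2), which is exactly the behavior
the class-2 mechanism predicts.

The built-in scorer is a deliberately simple **surrogate**: a log-linear
sum of per-position base coefficients over the −11..+1 window plus an
anti-Shine-Dalgarno complementarity term (consensus `AGGAGG`) with a
spacing penalty. Its shipped coefficients are synthetic (see
`inst/extdata/tir_surrogate_config.yaml`) and only sign-level comparisons
are meaningful; thermodynamic calculators are consumed as external tables,
never reimplemented.

### Synthesis rates are advisory

Ribosome-profiling synthesis rates validate but never define a class. A
gene with fewer than 128 mapped Ribo-Seq reads is low confidence and its
record is ignored; a confident antitoxin/toxin rate ratio below one raises
the `synthesis_ratio_below_one` anomaly flag (the RnlAB situation, where a
third interacting protein, RNase HI, changes the system's requirements).
Rates carry an assumed 30% relative error.

## The decision procedure

`classify_operon()` applies, in order of precedence:

1. internal promoter annotated, **or** a significant up-step located at or
   after the first CDS start and strictly before the antitoxin CDS start
   → class 4. The positional form covers the RnlAB geometry, where the
   internal promoter sits ~280 nt upstream of the antitoxin *inside* the
   toxin CDS. If a proximal second external promoter coexists, class 4
   still wins and the contradiction is recorded in the evidence trail.
2. else ≥2 external promoters with a second TSS within `proximal_window`
   (50) nt of the first CDS start → class 2. Distal extra promoters do not
   count: they do not change the coverage ratio.
3. else antitoxin excess → class 3, where excess means a median ratio above
   $2 + \delta$, or a median inside the borderline band $[2-\delta,
   2+\delta]$ together with a toxin-higher consensus, or a significant
   down-step inside the toxin CDS.
4. else class 1 — but a borderline median additionally requires an
   antitoxin-higher consensus; without one the operon stays unclassified.

`borderline_delta` $\delta = 0.25$ is this package's operationalization of
"near the two-fold cutoff": it is the single band that, with the TIR
tie-break, sends the 1.99 and 1.89 borderline systems to class 1 and the
2.08 system to class 3, as the curated labels require. `proximal_window`
= 50 nt operationalizes "near the toxin RBS". Both are exposed as
parameters. When several transcript variants have consensus calls, the
alphabetically first variant (P1 in practice) is the tie-breaker.

All thresholds being fixed, the classifier is deterministic, and increasing
the median ratio (other evidence fixed) can only move assignments toward
class 3, never back — both properties are asserted in the test suite.

## The bundled ten-system evidence set

`ecoli_ta_fixture()` assembles the curated E. coli K-12 evidence: median
A/T ratios and SDs over 13 datasets for FicAT (1.99), YefM-YoeB (1.89),
MazEF (1.42), PrlF-YhaV (1.11), MqsAR (0.69), RelBE (0.95), HicAB (0.93),
DinJ-YafQ (2.89), YafNO (2.08) and RnlAB (1.01); promoter structure (one
external promoter everywhere except HicAB, two external, and RnlAB,
external plus internal); per-method TIR signs including both HicAB
variants; and sign-level synthesis-rate records with FicAT and HicAB under
the 128-read rule. Gene coordinates are synthetic-but-typical
reconstructions (the classifier never consults them beyond promoter
geometry); synthesis-rate magnitudes are synthetic except RelBE's
published 7.5-fold antitoxin excess. Running `ta_classify()` on the
fixture reproduces all ten class labels (6/1/2/1).

## What the generator emulates — and what it does not

`simulate_ta()` produces labelled operons (default 50 per class), 13
replicate count tables in the reference design, per-base profiles, TIR
tables and synthesis rates:

* gene counts are negative binomial with dispersion 0.1 around
  depth × length × ratio-factor × a per-library scale factor drawn from
  U(0.8, 1.2); the default depth is 50 reads/base. The NB/Poisson choice is
  the minimal standard RNA-seq noise model, not a claim from the curated
  analysis;
* full-operon expected gene ratios default to 1.3 (class 1), 1.0 (class 2),
  2.9 (class 3) and 1.0 (class 4, whole-operon level);
* base profiles are Poisson with a 4-fold step inside the toxin CDS
  (class 3, down) or from the internal promoter (class 4, up). Count tables
  and profiles are drawn independently from their own expected-coverage
  laws; for class 4 this mirrors the real situation where the gene-level
  ratio prints near 1 while base-level coverage shows the internal
  promoter's step;
* toxin CDS lengths are drawn from 250–350 nt and antitoxin from
  200–300 nt, typical of type II systems; class 2 operons get a ≥25 nt
  intergenic gap so the RBS-overlap predicate is false, all other classes
  overlap by 3 nt;
* TIR signs give classes 1/2 an antitoxin-higher two-of-three majority,
  class 3 a toxin-higher majority, and class 4 a mixed-but-resolvable
  pattern; synthesis rates are antitoxin-higher except class 4.

What it does **not** emulate: positional coverage bias, fragment-length
effects, multi-mapping structure (all counts are whole reads), real
promoter motifs or sequence composition, and between-condition biological
differences beyond the library factor. Passing the synthetic recovery tests
therefore shows the pipeline's rules and statistics are implemented
coherently at realistic noise levels — not that real libraries meet the
generator's assumptions.

## Problem sizes and numerical choices

The validation study in the test suite uses 200 operons (50 per class) at
the default depth and the default classifier thresholds, a size chosen so
the whole suite runs in well under a minute while leaving the recovery
criteria (≥90% class recovery, class-1 ratio estimates within 10%,
changepoint localization within ±10 nt in ≥95% of class-3/4 operons)
statistically meaningful. Determinism is by a single integer seed; the
changepoint search is exact (exhaustive) rather than approximate, so no
tolerance enters there beyond the BIC/fold acceptance rules. Degenerate
inputs have defined behavior: zero toxin counts exclude a dataset (no
pseudocounts — the pipeline filters rather than imputes), zero coverages
drop a replicate from the error analysis, fewer than two replicates flag
the estimate undefined, and an all-zero profile yields no changepoint.

## Known limitations

* The classifier consumes curated promoter annotations; it does not
  discover promoters from sequence, and dRNA-seq TSS mapping is out of
  scope.
* One changepoint per operon: architectures with both a truncation and an
  internal promoter would need the multi-step extension.
* Class 3's mechanism (terminator vs. RNase degradation) is deliberately
  left unresolved: the label records `transcript_truncation` without
  committing to either.
* The surrogate TIR scorer is for plumbing and sign-level experiments
  only; real analyses should import calculator outputs as TSV.
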