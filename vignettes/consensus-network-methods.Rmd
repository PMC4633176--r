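---
title: "Methods: consensus miRNA:mRNA network inference and its calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus miRNA:mRNA network inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirconsensus)
```

## The integration model

`mirconsensus` treats a putative repressive interaction as credible only
when three independent lines of evidence agree:

* the miRNA is *consistently* reported deregulated in the tumor type
  (vote counting over studies, no effect-size pooling);
* the gene is a *reproducibly predicted* target (multi-algorithm consensus);
* the gene's expression change across tumor-vs-normal datasets is
  *anti-correlated* with the miRNA's direction (an upregulated miRNA should
  repress, so its credible targets should fall, and vice versa).

The intersection is a bipartite network; direction logic, not quantitative
correlation coefficients, defines the edges. This reflects the structure of
the input evidence: literature calls and GEO2R-style tables carry signs and
significance, not paired per-sample measurements, so a correlation
coefficient could not be computed without the raw series.

### Vote counting (literature stage)

Within a tumor type, each miRNA's reports are counted over *distinct*
studies. With threshold `min_studies` (default 3):

* `selected` — ≥ 3 reports, unanimous direction;
* `inconsistent` — ≥ 3 reports, both directions present;
* `insufficient` — fewer than 3 reports.

Concordance is read as **unanimity**: a single opposite report disqualifies
a miRNA even when three or more studies agree. This is the strictest
reading, and the one consistent with the packaged survey, where a
2-down/1-up miRNA (miR-26a-5p in PTC) is excluded while every selected
miRNA is conflict-free. A study contributing to both tumor types counts
once per type; evidence never crosses types.

Name normalization precedes tallying: reported names are mapped through a
two-column alias table derived from miRBase naming conventions. Arm-ambiguous
shorthand (`miR-221` vs `miR-221-3p`) resolves only through that table — no
heuristic arm guessing. Strict mode (unknown name = error) is the default
because a silent passthrough would fragment tallies; lenient mode warns and
passes names through. If renaming makes two calls from one study collide,
they collapse when the directions agree and raise an error otherwise.

### Target consensus

Votes are tuples (miRNA, gene, algorithm) from a declared roster of
`n_algorithms` = 8. A pair is a consensus target at `min_algorithms` = 5
votes, boundary inclusive. Duplicated tuples and votes from undeclared
algorithms are errors rather than data: both almost always indicate a bad
join upstream. Gene identifiers are opaque symbols; no Entrez/symbol
mapping is attempted, so inputs must arrive pre-harmonized.

### Expression concordance

A dataset *supports* a direction for a gene iff the adjusted p is strictly
below `alpha` = 0.05 and the log fold-change has the matching sign. A
significant row with `log_fc == 0` is directionless and supports nothing
(it is counted and reported via a message). A gene reaches `consensus` when
the supporting fraction is at least `fraction` = 0.5 **of the datasets in
which the gene is measured** and no significant opposite support exists;
opposite significant evidence vetoes consensus outright, mirroring the
unanimity rule of the literature stage.

The measured-datasets denominator is a deliberate choice: microarray
platforms differ in gene coverage, and a gene absent from a platform should
not be penalized as if it had failed there. `denominator = "all"` restores
the stricter reading, and `min_datasets` can exclude genes measured only
once (by default a 1/1 gene may reach consensus).

### Network construction

An edge (m, g) exists iff m is selected, (m, g) is a consensus target, g
has a consensus call, and the directions differ. Concordant candidate pairs
are kept in a `discarded` log with a reason, because exclusions of this
kind are scientific output, not noise, and tests audit them. Edges carry
`vote_count` so consumers can re-threshold without re-joining. Matching is
case-sensitive exact equality after upstream normalization. The per-pair
rule is applied literally: a gene targeted by several selected miRNAs keeps
exactly the anti-correlated pairings.

### Enrichment

Over-representation uses the one-sided hypergeometric upper tail
`P(X >= k)` (via `stats::phyper`, stable in log space), or by default the
EASE variant `P(X >= k - 1)` — the conservative score popularized by DAVID,
chosen as default because these target lists are typically analyzed with
DAVID-style tooling; the plain tail is one flag away. Reported columns are
the DAVID-style `k, n, K, N`, `percent = 100 k/n`, and
`fold = (k/n)/(K/N)` (defined as 0 when `k = 0`). Correction defaults to
none — published tables of this kind show raw p-values — with
Benjamini–Hochberg opt-in. The background defaults to the caller's gene
universe (in the pipeline, all genes measured at the consensus-DE stage);
a user-supplied background overrides it. Published "%" columns from DAVID
are not always consistent with `k/n` because DAVID's internal denominator
(annotated genes per category) is not recoverable; this package defines
percent as `100 k/n` and documents the discrepancy rather than emulating an
unknown denominator.

### Clinical stage

A sample is *altered* when any listed gene deviates from the cohort mean by
at least `z_star` = 2.0 standard deviations (inclusive, matching the
"Z-score ±2.0" convention of cBioPortal-style exports). The reference
population is the whole cohort; cBioPortal's diploid-reference variant is
not recoverable from typical exports, so all-samples is the default and the
choice is configurable in principle by pre-standardizing the matrix.
Zero-variance and missing genes are skipped with warnings; an empty list
classifies nobody as altered.

Two-group comparisons follow the normality-gated convention common in
clinical figure legends: a one-sample Kolmogorov–Smirnov check per group
against a normal with the group's sample mean and sd (the Lilliefors
correction is available behind a flag, since the plain KS check with
estimated parameters is conservative); Student's t when both groups pass,
two-sided Mann–Whitney otherwise, with `*`/`**`/`***` at 0.05/0.01/0.001.
The Mann–Whitney p is exact by complete enumeration of all labelings for
combined n ≤ 12 — average ranks make it well-defined under ties, where the
classical exact distribution is unavailable — and the normal approximation
with tie correction beyond. Survival uses the Kaplan–Meier product-limit
estimate and the two-group log-rank test (`survival::survfit` /
`survival::survdiff`); time units are whatever the cohort file uses (months
assumed for TCGA-style exports) and are never converted.

## What the synthetic generator emulates

`sim_config()` fixes the reference study conditions; each generator is a
pure function of the configuration, with a fixed per-generator seed offset
so that, e.g., resizing the cohort never perturbs the call matrix.

| Stage | Default | Rationale |
|---|---|---|
| studies / miRNAs / planted | 10 / 200 / 20 | a literature base of ~10 usable studies per tumor type and a panel of tens of recurrent miRNAs among hundreds reported once or twice |
| planted reports, noise rate | 4 unanimous calls; 5% spurious call rate, 10% of planted given one opposite call | planted miRNAs clear the 3-study rule; noise occasionally fabricates a unanimous triple (precision < 1), and planted inconsistents mirror the few mixed-direction miRNAs real surveys contain |
| algorithms, background vote prob. | 8; 0.10 | an 8-algorithm panel where a background pair rarely (P ≈ 4×10⁻⁴) reaches 5 votes by chance |
| datasets, planted support | 5; significant in 3 with adj. p < 0.01, \|log2FC\| ≈ 2 | five usable expression datasets is a realistic public-compendium size; support 3/5 sits exactly at the half-or-more boundary |
| gene sets | 20 sets of 50; planted overlap 25 | one strongly enriched set among unrelated ones |
| cohort | n = 388, 33% altered, shift ≥ 3 sd, HR 3, 20% censoring, baseline rate 0.01/month | a TCGA-scale cohort; alteration and hazard-ratio magnitudes are chosen for clear desk-scale recovery, not to mimic any real-data effect size |

The planted alteration *replaces* a gene's value with one at least
`expression_shift_sd` = 3 reference sd from the mean (random sign). An
additive 3-sd shift on top of unit noise would be detected at z ≥ 2 only
~84% of the time; the at-least-3-sd construction makes recovery structural,
which is what a planted-truth generator should provide. Likewise,
noise calls land only on non-planted miRNAs, so selection recall is
structural and precision is the stochastic quantity. Censoring is applied
by truncating a record at a uniform fraction of its event time with
probability `censoring_rate`, giving the nominal censoring fraction in
expectation with censoring independent of group.

What the generator does **not** emulate: probe-level microarray structure
(adjusted p-values are drawn directly — uniform for nulls, sub-threshold
for planted — because the pipeline consumes adjusted values), sequence-based
target prediction, miRNA nomenclature drift, correlated genes, or
non-proportional hazards. Passing recovery tests therefore demonstrates the
correctness of the integration logic under the stated signal model, not
performance on real archival data, where probe collapse, platform batch
effects and annotation drift dominate.

## Numerical and degenerate-input choices

* Hypergeometric tails are computed in log space; enumeration oracles in the
  test suite agree to ≤ 1e-10 over every configuration with N ≤ 60.
* `hypergeom_p(0, ...) = 1` exactly; EASE equals 1 whenever k ≤ 1.
* Exact Mann–Whitney uses an epsilon of 1e-9 when comparing U values so
  average-rank ties are not split by floating-point noise.
* Empty call matrices, empty networks and all-censored survival input are
  valid and return empty/flat results (with warnings where the contrast is
  undefined, e.g. a log-rank test with no events returns p = 1).
* Output orderings are stable radix sorts (tallies: tumor type, then
  descending report count, then name; edges: miRNA, then gene), so equal
  inputs give byte-identical outputs.

## Problem sizes used by the test suite

The calibration tests run 2000 null cohorts of n = 100 for log-rank size,
10⁴ null genes for the false-consensus rate, 50 seeds for selection
precision/recall, 20 full pipeline seeds for edge precision/recall, and 40
seeds for enrichment ranking. These sizes give Monte-Carlo standard errors
comfortably below the margins being asserted (e.g. ±0.005 on a 0.05
rejection rate) while keeping the default suite quick to run.

## Known limitations

* Vote counting ignores study size and quality; a small qPCR panel counts
  as much as a sequencing cohort. That is inherent to the method, not a
  defect of the implementation.
* The anti-correlation rule uses direction only; genes regulated below the
  significance radar, or feedback loops where target repression rebounds on
  the miRNA, are invisible.
* Enrichment p-values depend strongly on the chosen background; defaults
  are sensible but results should be reported with the background stated.
* The clinical stage treats risk-group labels as given; deriving risk from
  attribute combinations is cohort-specific policy and out of scope.
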