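---
title: "Unstable methylation genes: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unstable methylation genes: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methinstab)
```

## The problem

Signal-level nanopore callers emit, for every genomic site, a
methylation score in [0, 1] — the estimated fraction of methylated
molecules. With paired tumor/normal tissue this yields two dual-mark
methylomes per patient: 5-methylcytosine (5mC, CpG methylation, the
dominant mammalian mark) and N6-methyladenine (6mA, rare in mammals but
detectable from raw signal). `methinstab` implements the downstream
analysis that turns these per-site score tables into gene-level
statements:

1. **Differential sites.** Sites whose aggregated tumor/normal scores
   differ by more than 2-fold, plus a rescue rule for sites scored zero
   in one condition.
2. **Unstable methylation genes.** Genes whose bodies carry differential
   sites of *both* marks in *both* directions — the four-way
   conjunction. These are candidate loci of general epigenetic
   dysregulation.
3. **Mark-expression coupling.** 2x2 chi-square tests of each mark's
   gene classes against fold-change differentially expressed (DE)
   genes, quantifying the observation that 5mC instability couples to
   transcription while 6mA instability largely does not.
4. **Survival screen.** Kaplan-Meier / log-rank tests on median
   expression splits over the most unstable genes, selecting
   tumor-suppressor candidates: genes down-regulated in tumor whose low
   expression associates with worse overall survival.

Because the motivating cohort data are controlled-access, the package
ships a synthetic cohort generator that plants all of the above effect
structure with known ground truth; every pipeline stage is validated
against it.

## The differential-site rules

Scores are aggregated per condition (arithmetic mean across samples of
the condition, the default `mean_by_condition` policy) and then, per
site:

* sites with **all-zero** scores across every sample are removed before
  anything else;
* if both aggregated scores are positive, the site is called *up* when
  `tumor/normal > 2` and *down* when `normal/tumor > 2` (the
  `fold_change` rule);
* if exactly one aggregated score is zero, the site is called toward the
  non-zero side when that score exceeds 0.6 (the `zero_rescue` rule).

Both thresholds are strict: a ratio of exactly 2, or a score of exactly
0.6 against a zero, is **not** called. The thresholds are configurable
(`fold`, `zero_rescue`) but default to the printed cut-offs. The fold
change is computed without a pseudocount; the zero case is handled
exclusively by the rescue rule, which is why the two rules partition the
retained sites cleanly.

Two aggregation policies are provided because the underlying study used
two tumor/normal pairs without stating how they were combined, and
"scores in part of tissues were zero" can be read per sample or per
condition. `mean_by_condition` (default) applies the rules to condition
means; `per_pair_consensus` applies them within each pair and reports a
site only when every pair calls the same direction. Neither is asserted
to be the original study's choice; on the synthetic cohort both policies
recover the planted truth because planted sites satisfy the rules within
every pair by construction.

## Gene mapping and classification

Sites are 1-bp intervals `[pos0, pos0+1)`; genes are BED-convention
half-open intervals. A site is assigned to every gene overlapping it by
at least 1 bp (bedtools-intersect defaults: strand ignored, no
deduplication across overlapping genes). Gene extent is the annotated
gene body; a `flank` option (default 0) permits promoter-inclusive
reruns. Per-gene profiles count assigned differential sites by
mark x direction; a gene is **unstable** when all four counts are
positive. The top-N list ranks unstable genes by total differential
sites across marks and directions (configurable to per-mark sums), with
ties broken by gene id for reproducibility.

## Expression association

RPKM is computed from the standard formula
`count * 1e9 / (library_size * length_bp)` with library sizes defaulting
to column sums. DE genes are those with condition-mean RPKM fold change
strictly above 2 (either direction); a pseudocount (default 0.01 RPKM)
keeps zero-expression genes defined. The association report builds, for
each mark, 2x2 tables of class membership against DE status under three
class definitions — up-specific, down-specific, and both-up-and-down —
because the original figures' exact constructions are ambiguous; all are
reported, none asserted. The chi-square statistic is the plain Pearson
`sum((O-E)^2/E)` without continuity correction (a Yates flag exists),
and no multiplicity adjustment is applied, matching the raw p-values the
analysis style reports. The default gene universe is all annotated
genes; `genes_with_any_signal` restricts to genes seen in the labels or
the DE table, since the original denominators are not fully specified.

## Survival screen

The Kaplan-Meier estimator is the product-limit form
`S(t) = prod(1 - d_i/n_i)` over distinct event times; the log-rank test
uses the hypergeometric variance with a chi-square (df = 1) reference.
Patients are split at the median expression of each screened gene with
ties assigned to the low group — the original grouping rule is unstated,
so this is a documented assumption. Risk direction is read from the two
KM curves at the largest time observed in both groups. A gene is
*selected* at strict `p < 0.05`, and a **tumor-suppressor candidate**
must additionally be DE-down and have `low_expression_worse` risk — a
formalisation of the narrative criterion ("expressed at low level, low
expression worsens prognosis"). Genes with constant expression produce a
degenerate split; they are reported with an error field and excluded
from selection without affecting other genes.

## The synthetic cohort: what it emulates and what it does not

The generator writes a complete desk-scale study: a BED annotation with
biotypes, two per-site score tables (one per mark, one score column per
sample, two tumor/normal pairs by default), a featureCounts-like count
table, a survival table, and a `truth.json` with every planted label.

* **Biotypes.** Background composition defaults to roughly 42%
  protein-coding and 29% pseudogene; unstable genes are drawn with a
  target composition of 77% protein-coding — the enrichment pattern the
  pipeline should recover.
* **Planted site counts.** For genes carrying both directions of a
  mark, (up, down) counts are drawn from a bivariate Poisson with a
  shared component (`rbicount`): `x = s + e1`, `y = s + e2`, which hits
  any target correlation in [0, 1] exactly in the population with
  Poisson-light tails. The stated design sketch (shared gamma factor
  with a numerically solved mixing weight) was implemented first and
  abandoned: its heavy-tailed shared factor inflated the sampling
  variance of the planted correlation well beyond the Fisher-z band the
  recovery criterion is derived from. Targets default to 0.15 (5mC) and
  0.85 (6mA), mirroring the asymmetry the analysis is built around. On
  top of the model, the generator enforces its contract by
  construction: the count matrix is redrawn (up to 50 attempts) until
  the planted sample correlation is within 0.02 of the target, so the
  planted world carries its declared structure rather than one noisy
  realisation of it. A +1 shift guarantees every planted unstable gene
  has at least one site in each category without changing the
  correlation.
* **Scores.** Planted sites draw condition-level base scores that
  satisfy the rules with margin (fold sites use ratios in [2.3, 3.2];
  rescue sites use 0 against [0.68, 0.92]); background sites are
  constructed so no rule can fire (score ratio within [1/2, 2], a zero
  never faces more than 0.6, plus a stratum of all-zero sites for the
  removal rule). Per-sample jitter is bounded relative noise; the bound
  (`score_noise_sd < 0.06`) is exactly what keeps planted sites called
  and background sites uncalled under *both* aggregation policies, so
  planted truth is recovered exactly, not approximately.
* **Expression.** Negative-binomial counts; planted DE genes have their
  tumor mean multiplied/divided by the planted fold change (default 4).
  DE status couples to per-mark unstable status through odds ratios on
  the logistic scale (defaults: OR 3 for 5mC, OR 1 for 6mA). With
  dispersion 0 the generator returns expected counts exactly (possibly
  non-integer), which makes planted ratios algebraically exact — the
  deterministic limit used by the tests.
* **Survival.** Exponential event times with hazard
  `baseline * exp(log_hr * n_low)` where `n_low` counts planted effect
  genes for which the patient falls in the low-expression half. Effect
  genes are taken from the top of the planted unstable ranking and
  forced DE-down, i.e. they are planted tumor-suppressor candidates.
  Censoring is independent with the configured probability, at a uniform
  fraction of the event time. With `expr_noise_sd = 0`, non-effect genes
  have constant expression, so in the noiseless world only planted
  effect genes can be selected — this is what makes exact TSG recovery a
  meaningful test rather than a coin flip against the 5% false-positive
  rate.

What the generator does **not** emulate: raw signal or read-level error,
realistic chromosome sizes or site spacing, strand structure, batch
effects, library-composition bias, or any correlation between
methylation scores at neighbouring sites. A green recovery test
therefore establishes that the pipeline's logic is faithful to its
rules, not that the rules are robust to real nanopore noise.

## Numerical and degenerate-input choices

* All internal coordinates are 0-based half-open; GFF3 conversion
  (`start-1`, `end`) happens in the reader and nowhere else.
* Chromosomes sort in natural order (chr1..chr22, chrX, chrY, chrM);
  unknown names go last, alphabetically.
* An undefined Pearson correlation (constant vector, support < 3) is a
  raised error, never a silent 0.
* A contingency table with an empty margin is reported as degenerate
  with NA statistics rather than a crash of the whole report; expected
  cells below 5 warn.
* The log-rank variance term skips risk sets of size 1; zero total
  variance (no events) is a degenerate-statistics error.
* Error classes map to CLI exit codes: configuration 2, data/format 3,
  degenerate statistics 4.
* Determinism: every generator stage reseeds from a per-stage sub-seed
  derived from the master seed, so stages are individually reproducible
  and `simulate_cohort` output is byte-identical under a fixed
  configuration.

## Design decisions taken where the design was open

* **Association worlds for calibration.** When testing that a neutral
  6mA odds ratio yields a null marginal 2x2, the planted mark classes
  must be statistically independent; if the two classes are planted as
  disjoint gene sets, the complement of the 6mA class is enriched for
  5mC-coupled genes and the 6mA marginal odds ratio is not 1. The
  calibration world therefore plants `P(both) = P(5mC) * P(6mA)` with
  fixed margins, which makes the marginal independence exact.
* **Configuration format.** Pipeline and simulation configurations are
  JSON rather than YAML (no YAML parser among the package's
  dependencies); the structure is unchanged.
* **Interval engine.** Site-to-gene assignment uses IRanges overlap
  queries behind the module's contract; the acceptance suite checks it
  against an independent all-pairs overlap oracle, exactly.
* **Survival-effect placement.** Planted effect genes are taken from the
  top of the planted unstable ranking so that the default top-100 screen
  necessarily sees them; placing them uniformly would make the screen's
  power depend on an arbitrary ranking cut.

## Known limitations

The per-site model treats sites independently, so the pipeline inherits
whatever multiple-counting the annotation implies for overlapping genes
(deliberately, as the bedtools default). The DE caller is a plain
fold-change rule without variance moderation — faithful to the analysis
it re-implements, but not a substitute for a shrinkage-based DE method.
The survival screen applies no multiplicity correction (a deliberate
match to the original selection rule); at 100 genes and alpha 0.05 the
expected number of false selections on null data is 5, which is why
candidate status requires the DE and risk-direction conjunctions.
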