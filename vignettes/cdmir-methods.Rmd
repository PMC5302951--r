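---
title: "Methods: identifying cell-death-related miRNAs with cdmir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: identifying cell-death-related miRNAs with cdmir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdmir)
```

## Overview

`cdmir` prioritises miRNAs that regulate programmed cell death in a given
disease context by combining three evidence layers:

1. **knowledge filtering** — a miRNA whose predicted targets are
   over-represented in apoptosis or autophagy gene sets is a candidate
   cell-death miRNA (CD-miR);
2. **context filtering** — a CD-miR only matters in the studied disease if
   it is differentially expressed there, measured on paired tumour/normal
   cohorts;
3. **evaluation** — the predicted CD-miR set is compared against a curated
   list of experimentally supported cell-death miRNAs through a resampling
   null.

The pipeline consumes four inputs as plain TSV/line files: a miRNA→target
pair table (typically the intersection of two target predictors), a
gene→category annotation (apoptosis/autophagy, pre-resolved — no ontology
traversal is performed), one or more expression matrices with
tumour/normal designs, and a known-miRNA list. All set logic runs on
canonicalized identifiers.

## Identifier canonicalization

miRNA names arrive in incompatible dialects (`hsa-miR-20b` from miRBase,
`HSA-MIR20B` from symbol tables, platform hybrids in between). The
canonical form — trim, uppercase, strip hyphens — is deliberately the
weakest transformation that makes these dialects collide; it never touches
digits or arm suffixes, so `-5p`/`-3p` arms remain distinct molecules.
Collapsing arms to their precursor is a stronger assumption about how a
probe maps to mature strands than the inputs justify, so it is not done;
users who need precursor-level analysis should collapse ids upstream.

## The enrichment test

For a miRNA with targets `T` and an annotation with universe `U` (size
`N`) and category genes `C` (size `M`), the test statistic is
`x = |T ∩ C|` out of `n = |T ∩ U|` draws, with upper-tail p-value
`P(X ≥ x)` for `X ~ Hypergeometric(N, M, n)`.

Two choices here were genuinely open:

* **`n` counts only targets inside the universe.** The draw size of a
  hypergeometric model must count draws *from the urn*; targets with no
  annotation at all cannot be category hits and including them would
  deflate every p-value. The unrestricted variant
  (`restrict_universe = FALSE`) is kept for sensitivity analysis.
* **The hit filter is `x ≥ 2`.** A single-target "enrichment" can reach
  p < 0.05 whenever the category is small relative to the universe, yet
  one predicted edge is weak evidence; requiring two independent category
  targets is the strict reading of a "more than one hit" rule.

Significance is raw `p < 0.05` by default — a per-miRNA screening rule,
not a family-wise claim; an optional Benjamini–Hochberg mode
(`adjust = "BH"`) is available but off by default. miRNAs significant for
both categories are labelled `DUAL` (dual-functional); the three label
classes are disjoint.

Untestable miRNAs (`n = 0`) are reported with `testable = FALSE` and
`p = 1` instead of being dropped, so the count of miRNAs entering and
leaving the filter always reconciles.

### Numerical scheme

The tail is summed directly over `i = x .. min(n, M)` in log space
(`lchoose` plus log-sum-exp). Summing the upper tail avoids the
catastrophic cancellation of `1 − lower_sum` when the tail is tiny, and
log-binomials never overflow; the result is exact to well past 10
significant digits over the tested range. The test suite checks the
implementation against exhaustive subset enumeration for every
configuration with `N ≤ 12` and against the distribution-function oracle
`stats::phyper` on random configurations up to `N = 5000`, along with the
complement identity, draw/marked symmetry, and monotonicity in `x` and
`M`.

## Differential expression

The per-miRNA test is a classical two-tailed t-test at `alpha_dem = 0.01`
(strict), with no fold-change filter and no multiplicity correction — the
cutoff is a deliberate pre-filter, not an inference. The default mode is
the pooled-variance Student test; Welch and paired modes are selectable.
The pooled default implements the plain "two-tailed t-test" reading even
though the intended cohorts are pair-matched; the paired mode is the
statistically stronger choice on such data and is exposed for exactly that
reason, but defaults follow the literal description rather than the
optimal analysis. Rows that are constant across all samples (or whose
paired differences are constant) are flagged untestable and excluded from
DEM totals rather than raising errors mid-scan.

Input matrices are assumed pre-normalized on a log scale; the package does
no normalization and records `mean_diff` (tumour − normal) purely for
reporting.

## Integration and reporting

A candidate is a CD-miR that is differentially expressed in **at least
one** dataset (union rule); an all-datasets intersection mode exists for
robustness checks but is not the default. Candidates are split against the
known list; the novel remainder is the pipeline's final output. Novel
symbols are printed most-significant-first by each miRNA's best (smallest)
enrichment p-value across categories — the ordering is otherwise
arbitrary, and a deterministic, documented order keeps reports
reproducible. Output symbols reinsert the hyphen before `MIR` for
readability; all computation stays on canonical ids.

## Evaluation against the known list

The sampling universe is the set of miRNAs that have target predictions at
all — the known list is first intersected with it, because miRNAs the
network has never seen can neither be predicted nor missed. The
Monte-Carlo estimator draws `n_draws` uniform subsets of the known-list
size and reports the fraction with overlap ≥ observed (inclusive). Since
the drawn overlap is exactly hypergeometric, the analytic tail is computed
alongside; at 10,000 draws the Monte-Carlo fraction has granularity 1e-4,
so the exact tail is the headline number and the Monte-Carlo fraction its
empirical confirmation (the two must agree within 4 Monte-Carlo standard
errors, which the tests enforce).

When the classified CD-miR set contains members outside the sampling
universe, the evaluation reports the discrepancy as a consistency note
rather than silently reconciling the counts — mirroring how such
set-size mismatches should surface in published pipelines rather than
disappear.

## The synthetic-data generator

The generator stands in for the external databases (target predictors,
gene-ontology exports, profiling repositories, curated miRNA lists) and
produces every input with recorded ground truth.

* **Annotation** (`gen_annotation`): exact category sizes with a
  controlled dual overlap; defaults 807 apoptotic / 114 autophagic / 25
  dual genes.
* **Network** (`gen_network`): degrees uniform in `[min_deg, max_deg]`;
  planted miRNAs draw each target from their focal category with
  probability `enrichment_strength`, otherwise uniformly; `DUAL` plants
  split the focal probability evenly between categories. Planted `*_ONLY`
  miRNAs draw focal targets from the category-**exclusive** gene set:
  dual-annotated genes count as hits for both categories, so drawing them
  would plant cross-category signal and contradict the very label being
  planted. At `enrichment_strength = 1` the category allocation is made
  deterministic (all targets in-category; an even split for `DUAL`) so
  extreme planting cannot miss the `x ≥ 2` filter through a rare draw.
  Null miRNAs draw uniformly from the whole universe by default;
  `null_mode = "category_free"` restricts them to unannotated genes,
  forcing `x = 0` — this is what lets a scenario pin its predicted set
  exactly.
* **Expression** (`gen_expression`): per patient and miRNA a shared
  baseline `Normal(mu0, tau)`, with the normal sample adding
  `Normal(0, sigma)` noise and the tumour sample adding the same noise
  plus `d·sigma` for planted rows. The shared baseline (default
  `tau = 0.5`, `sigma = 1`) is the weakest model that makes pair-matching
  meaningful: it cancels exactly in paired tests and inflates group
  variances in unpaired ones, so the pooled test on paired data is
  conservative — which is why the null-calibration checks of the pooled
  test run at `tau = 0` (independent groups, where its nominal level
  applies).
* **Known list** (`gen_known_list`): a `coverage` fraction of the planted
  miRNAs plus `contamination` null miRNAs, emulating a curated resource
  that covers only part of the truth.

What the generator does **not** emulate: probe-level microarray effects,
sequencing depth and count noise, normalization artifacts, correlated
miRNA families, and hub structure in the target network (degrees are
uniform, real target networks are heavy-tailed). Passing tests therefore
demonstrate the pipeline's statistical behaviour under a clean generative
model, not robustness to real-data pathologies upstream of the assumed
pre-normalized input.

### Scenario profiles

`tiny` is a sub-second smoke profile (20 miRNAs, 50 genes, one 6-pair
dataset). `paper_shape` mirrors the scale typical of esophageal-carcinoma
miRNA profiling studies: 629 miRNAs over 16,163
genes, the 807/114/25 annotation, four paired cohorts of 7/52/38/119
patients (one small RNA-seq-like cohort, three microarray-like), planted
DEM effects of 3.5σ with random signs, and a known list of 158 planted
plus 18 contaminant miRNAs (176 total). With planting at strength 1 over
category-free nulls the classified set is exactly the 510 planted miRNAs,
so the evaluation sees overlap 158 of sample 176 in universe 629 by
construction — the printed scale counts become generator invariants
rather than estimates. The per-dataset DEM planting places disjoint novel
candidates (5/1/4/2 across the four cohorts) alongside known CD-miRs and
non-CD miRNAs, but chance DEMs at the 1% level shift per-dataset counts;
only the evaluation counts are exact.

## Determinism and seeds

Every generator and the Monte-Carlo evaluator take an explicit seed and
restore the global RNG state on exit; a fixed (profile, seed) pair writes
byte-identical scenario files, and a fixed configuration reproduces a
pipeline run byte-identically. Sub-generators inside a scenario use fixed
small offsets of the master seed.

## Problem sizes used by the test suite

Oracle equivalence is exhaustive for `N ≤ 12`; null calibration uses
2,000 null miRNAs (enrichment), 1,000 null rows (DEM level) and a joint
null pipeline at 2,000 miRNAs; planted recovery uses 100 planted miRNAs
at strength 0.6 with degrees 20–60, and 50 planted DEMs at `d = 2`, 20
pairs; the uniformity check on null p-values uses 10,000 rows; the
determinism check runs the `paper_shape` scenario twice. These sizes keep
each statistical check's binomial error small relative to its margin
(3·SE bounds throughout) while the full suite stays fast.

## Known limitations

* The hypergeometric model treats target predictions as fixed truth;
  prediction noise propagates directly into `x` and is not modelled.
* The raw `p < 0.05` enrichment rule and `p < 0.01` DEM rule are
  screening filters, not error-controlled discoveries; the BH option
  exists but changes the semantics of downstream counts.
* The evaluation treats the known list as a gold standard although it is
  incomplete by nature; predictions outside it are "additional", not
  false positives, and the reported tail probability measures enrichment,
  not precision.
* Annotation categories arrive as flat gene lists; no ontology structure,
  evidence codes, or term propagation are considered.
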