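---
title: "Family-based rare CNV discovery: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-based rare CNV discovery: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvfam)
```

## The problem

Left-sided congenital heart disease (LS-CHD) — bicuspid aortic valve,
aortic stenosis, coarctation of the aorta, hypoplastic left heart and
related lesions — is highly heritable but genetically heterogeneous, and
individual causal variants are rare.  A family-based design offers a way
in: in multiplex pedigrees, a structural variant that is carried only by
affected relatives, absent from unaffected relatives, from screened
controls and from catalogues of common structural variation, and that
lands in genes plausibly involved in cardiovascular development, is a
strong candidate even at a sample size where association tests are
hopeless.

`cnvfam` implements that design as a reusable pipeline over copy-number
variant (CNV) calls: two-caller consensus merging, cohort quality control,
burden and pooled-region association that respect family structure, a
rarity filter chain, pedigree transmission classification, and
multi-evidence gene prioritization.  A seeded synthetic-cohort generator
with planted ground truth makes every stage testable without any external
data.

## Coordinate and interval conventions

All internal coordinates are 1-based inclusive (`length = end − start +
1`), matching the array-probe convention of the call tables; BED files are
the only 0-based half-open surface and are converted at the I/O boundary
(`internal_start = bed_start + 1`).  Chromosome labels are normalized by
stripping a `chr` prefix on input.  A single convention everywhere
eliminates off-by-one drift between stages.

Two overlap notions are used deliberately:

* **directional** — the fraction of a *query* interval covered by another
  interval (`overlap_fraction(a, b)`); this is the default wherever the
  question is "how much of *this* CNV is explained by that record";
* **reciprocal** — the minimum of the two directional fractions, the
  field's usual symmetric criterion.

The uniqueness and segregation rules are directional in the query CNV by
default, because two-caller outer envelopes inflate asymmetrically
(a parental or comparison call may legitimately be much larger).  The
symmetric alternative is available everywhere through a `mode` argument.
Familial event grouping, which is a symmetric question, uses reciprocal
overlap.

## Consensus merging of two callers

A consensus CNV requires one call from each caller for the same sample
with the same copy-state direction, overlapping by at least 50% of the
caller-A segment; the consensus interval is the *outer envelope* of the
two calls, and consensus calls shorter than 20 kb or supported by fewer
than 5 probes are dropped.  Caller-B calls below confidence 10 are
ignored up front.  Matching is one-to-one and greedy by descending
overlap with deterministic tie-breaking (leftmost caller-A start, then
caller-B start); multi-way merges are not attempted.  The probe count of
a consensus call is the maximum of its sources (conservative), its copy
number is taken from the caller-A anchor.

Whether the 50% rule should be directional or reciprocal is genuinely
ambiguous; the directional form (of the caller-A segment) is the default
because caller A's five-marker segments are the anchor of the merge, and
the reciprocal form is a configuration knob.  Greedy matching was checked
against exhaustive maximum-overlap matching on small random instances and
attains the optimum in ≥95% of them.

Copy states come from two rules.  Common copy-number polymorphisms (CNPs)
are compared against a *population* normal state — the mean copy number
over all individuals rounded to the closest integer (halves away from
zero), since the typical state of a CNP need not be two.  Rare and de
novo calls are compared against the fixed reference: two on autosomes,
sex-specific on X/Y (X: male 1, female 2; Y: male 1, female 0).

## Cohort quality control

Samples with excessive call counts are removed at strictly more than
three sample standard deviations (n − 1 denominator) above the cohort
mean; a boundary sample is retained.  With the reference cohort's values
(mean 49.62, SD 18.14) the threshold is 104.04 calls.

Ancestry outliers are removed with an oval filter in a precomputed 2-D
principal-component projection: a sample at `x` is removed iff
`sum(((x − center) / (10 · axis_sd))^2) > 1`, where `axis_sd` is the
reference cluster's standard deviation along each axis.  Computing the
projection itself is out of scope; coordinates and cluster parameters are
inputs.

## Burden and pooled-region association

Affected-versus-unaffected burden (segments per sample, mean segment
size, deletion and duplication counts, distinct genes intersected — a
gene counts once per sample) is tested by permutation of phenotype labels
*within families*, preserving every family's affected count, with
two-sided p-values from ≥10,000 seeded permutations.  No distributional
assumption is made and relatedness is respected; this is the natural
nonparametric choice where no specific burden test is mandated.

Overlapping CNVs are pooled into loci as connected components of the
≥1 bp-overlap graph (abutting calls do not pool).  Each pool is tested
under three models — duplication vs normal, deletion vs normal, any CNV
vs normal — with a logistic regression of affection on carrier status
with a family-level random intercept, fitted by Laplace approximation
(`lme4::glmer`), Wald p by default and a likelihood-ratio option.  When
the mixed fit does not converge (error, convergence-code failure,
non-finite or quasi-separated estimate) or the carrier predictor is
degenerate, the test falls back to a one-sided Fisher exact test on the
2×2 carrier-by-phenotype table (alternative: carriers enriched in
affecteds), whose p-value is the upper hypergeometric tail.  Carrier
status is coded 0/1 by default — the raw "number of copies" coding is an
option — and results are flagged at the nominal 0.05 level and at the
Bonferroni threshold over the number of pools (the pools × models
denominator is also reported, as either is defensible).  In
case-versus-control mode the family random effect is replaced by the
first two PC coordinates as fixed covariates.

Null calibration was verified by simulation: with carriers and phenotype
drawn independently, the p-values of both the pooled-region test and the
gene-set enrichment test are uniform (Kolmogorov–Smirnov at α = 0.01 over
hundreds of replicate cohorts; the fraction below 0.05 is within 0.05 ±
0.02).

## The rarity filter chain

Five stages in fixed order, every removal attributed to exactly one
stage:

1. **unaffected cohort** — a CNV overlapped more than 50% (of itself) by
   any same-state CNV of an unaffected cohort member is removed; *50% or
   less is kept*;
2. **controls** — the same rule against the control cohort;
3. **segmental duplications** — removed iff the union of segdup records
   covers ≥50% of the CNV (union coverage, so stacked records are not
   double-counted);
4. **known variants** — removed iff at least one known-variant record
   overlaps ≥50% of the CNV; this operationalizes the frequency criterion
   ("more common than ~0.01%") with the catalogue record itself, since a
   desk pipeline cannot know true population frequencies;
5. **family consistency** — removed iff an unaffected member of the same
   family carries a same-state CNV overlapping ≥50% of it; surviving CNVs
   that overlap reciprocally ≥50% among affected relatives are grouped
   into one familial event.

Note the deliberate asymmetry at exactly 50%: uniqueness *keeps* the
boundary case ("50% or less is unique"), while the segdup/known stages
*remove* it ("50% or more is excluded").  Both boundaries follow their
stated rules exactly; harmonizing them would silently change counts.
Comparisons are state-stratified throughout (loss against loss, gain
against gain): the deletion/duplication association models are distinct,
and a deletion is not evidence that a duplication at the same locus is
common.  The segdup and known-variant stages commute; the uniqueness
stages are monotone (adding comparison records can only shrink the kept
set).

## Transmission classification and de novo rates

A parent *carries* an offspring's CNV when one of the parent's same-state
calls overlaps at least 50% **of the offspring's CNV** — offspring-
denominated because boundary jitter inflates envelopes and a parental
call may legitimately be larger.  With both parents genotyped and neither
carrying, the call is de novo; exactly one carrier parent gives
`inherited_paternal`/`inherited_maternal`; both give `inherited_either`;
an ungenotyped parent with no genotyped carrier parent gives `unknown` —
de novo status is never imputed, which makes the reported per-trio de
novo rate a *minimum* estimate.  The rate denominator is the number of
genotyped trios ("per offspring per generation"), reported per phenotype
stratum; the report states the convention because per-trio, per-call and
per-opportunity denominators are not comparable across studies.

A familial event *cosegregates* when at least two affected relatives in
one family carry it; events are reported per family.

## Gene prioritization

Three independent evidences per gene:

1. **Rank fusion** — each evidence source ranks the gene universe by
   descending score (mid-ranks on ties); rank ratios `r = rank/N` are
   fused by the joint order-statistic probability `Q = k!·V_k`, with
   `V_0 = 1` and
   `V_i = Σ_{j=1..i} (−1)^{j−1} · V_{i−j}/j! · r_{k−i+1}^j` —
   the probability that the order statistics of `k` iid uniforms all fall
   below the observed ratios.  `Q` is calibrated into an empirical p by
   ≥1,000 seeded draws of `k` iid uniform ratio vectors (the floor guards
   the calibration's resolution).  The trained data sources of the
   original web service are not reproducible; user-supplied score tables
   replace them while the fusion mathematics is implemented faithfully,
   and was verified against a 10⁶-draw Monte-Carlo oracle.
2. **SAGE fold enrichment** — tags-per-million with a pseudocount of one
   (`10⁶·(tags+1)/(library+1)`, declared in output; avoids division by
   zero at zero tags), outflow tract over the *mean* of atrium and
   ventricle ("versus the atria and ventricles" read as a joint
   comparator; the max is a config option).  Positive at fold ≥ 3,
   inclusive.
3. **Curated expression flag** — a `+`/`−` input column mirroring visual
   inspection of in-situ databases; it is consumed, never computed.

A gene is a **candidate** when at least two of the three evidences are
positive (fusion p < 0.05, fold ≥ 3, flag `+`); absent evidence counts as
negative.  When printed verdicts are supplied alongside, disagreements
are flagged rather than silently matched — on the published 25-gene
table, all 25 verdicts reproduce, including the six genes whose fusion p
is above 0.05 but which pass on the other two evidences.

Gene-set enrichment uses a regression framework: per sample, the
statistic is the number of distinct set genes intersected by the sample's
CNVs; affection is regressed on it with total CNV count and total genic
span as covariates, and the empirical one-sided p is the tail frequency
of the statistic's z over within-family phenotype permutations, run over
all CNVs and again over genic CNVs only.

## The synthetic cohort generator

The generator emulates the study conditions: 60 three-generation
multiplex families (≈7.5 members each in expectation, so a cohort of
≈450), affected fraction 0.375, about 15 autosomal calls per sample, 200
unrelated controls.  The genome is abstract — 22 "chromosomes" of 10 Mb
with uniform placement — because the tests need controlled geometry, not
human coordinates.

* **Common CNPs** (50 loci, allele frequencies 0.05–0.30, gain or loss
  type) drift through pedigrees by Mendelian transmission of carrier
  alleles; carrier calls are what callers would emit.  A DGV-like known-
  variant track mirrors the CNP loci.  These frequencies give ≈15 calls
  per sample, the target call load.
* **Planted causal CNVs** (5 events, each in one family) originate in a
  founder (probability 0.6) or arise de novo in an offspring, and are
  transmitted Mendelian.  Penetrance defaults to 1 and the phenotype
  model is a two-parameter Bernoulli (penetrance for carriers, background
  prevalence solved to hit the 0.375 affected target): the filter chain
  removes any CNV seen in an unaffected relative, so only fully
  penetrant-in-family events are discoverable *by design* — the default
  makes the planted truth identifiable rather than pretending the
  pipeline can find incompletely penetrant alleles, a stated limitation
  of the design.  Reduced penetrance remains a knob.
* **Neutral de novo events** occur per offspring with probability 0.02
  (the scale of reported per-trio rates), in both phenotype strata.
* **Artifacts**: recurrent events embedded in segmental duplications
  assigned to affected individuals (these must survive uniqueness and be
  caught by the segdup stage), plus caller-specific false positives
  (mean 1 per sample per caller, half inside segdups) that cannot merge.
* **Caller noise**: each end of each call is jittered uniformly within
  ±10% of the CNV length per caller, so two-caller outer envelopes vary
  by up to ≈40% — consistent with the observed boundary variability of
  array calls ("identical" calls varying up to 50% in overlap) while
  keeping parent/offspring envelope overlap above the 50% matching
  threshold with certainty (at 10% jitter the worst-case offspring-
  denominated overlap is 0.8L/1.2L = 2/3).  At 20% jitter the worst case
  crosses 50% only with negligible probability; transmission labels were
  verified exact on simulated trios at that level.  The default
  false-negative rate is 0: the consensus merge requires both callers,
  so any dropout destroys single-carrier planted events at rate ≈ 2·fn
  regardless of downstream thresholds; the default therefore represents
  the validated consensus scenario, and dropout is studied through the
  `fn_rate` knob (at `fn_rate = 1` the merge output is empty).
* **Evidence tables**: causal genes get an outflow-tract SAGE boost
  (6-fold), shifted evidence-source scores (+2.5 SD) and a positive
  expression flag with probability 0.9; background genes draw from null
  distributions (flag positive at 0.1).  Causal genes' baseline
  expression is floored at 150 tpm so the planted boost is identifiable
  above Poisson counting noise.

Everything is deterministic under the mandatory seed.  What the generator
does **not** emulate: linkage disequilibrium, array intensity noise,
genome-specific CNV hotspots beyond the planted segdups, phenotype
misclassification, and missing genotypes.  Passing the planted-truth
suite therefore demonstrates the pipeline's logic — interval semantics,
state stratification, pedigree bookkeeping, filter ordering — not its
performance on real array data.

## Numerical choices and degenerate inputs

* Halves round away from zero wherever a printed-precision value is
  reproduced (percentages, CNP normal states); R's default half-to-even
  would disagree with printed tables.
* Strict inequality at the QC threshold; inclusive thresholds at the
  SAGE 3-fold and the segdup/known 50% rules; exclusive at uniqueness —
  each as stated by its rule.
* Mixed-model convergence is defined operationally: fit error,
  optimizer non-convergence, non-finite or quasi-separated estimate
  (|log-odds| > 15, SE > 50) all trigger the Fisher fallback; a boundary
  (singular) random-effect fit does not, since the Wald test remains
  valid there.
* Empirical p-values use the add-one rule `(1 + #{extreme}) / (n + 1)`,
  so they are never zero.
* Degenerate inputs: an all-carrier or no-carrier pool falls back to
  Fisher with p = 1; a sample with no calls contributes zero burden;
  a zero-tag SAGE gene has fold 1 via the pseudocount; an empty pool
  list yields an empty screen.

## Problem sizes used in validation

The shipped validation suite runs the full default synthetic cohort (60
families, ≈480 individuals, ≈7,000 consensus CNVs, 200 controls) once
end-to-end, 500-replicate null calibrations of the association tests at
cohort sizes of 120–240, a 10⁶-draw Monte-Carlo check of the
order-statistic fusion for k ∈ {2, 3, 5}, and an exhaustive comparison of
the Fisher fallback against a binomial-coefficient oracle over the ≈1.3
million 2×2 tables with all margins ≤ 50.  These sizes were chosen as the
smallest at which each property is sharply testable.

## Known limitations

* The family random intercept is the only relatedness adjustment in
  cohort mode; kinship beyond family membership (e.g. inbreeding, which
  the loader rejects anyway) is not modeled.
* The 50% thresholds are conventions, not estimates; results near the
  boundary are sensitive to caller jitter, which is why the boundary
  semantics are documented stage by stage.
* Population frequency of known variants is proxied by catalogue overlap.
* Half-sib and avuncular relations require explicit placeholder founder
  records; implicit relations are not inferred.
* X/Y CNVs use the stricter any-overlap uniqueness rule and are excluded
  from the autosomal burden and pooling stages.
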