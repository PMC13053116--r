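---
title: "Estimating carrier frequency and genetic prevalence of recessive disease from reference allele counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating carrier frequency and genetic prevalence of recessive disease from reference allele counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genoprev)
```

## The estimation problem

For an ultra-rare autosomal-recessive disease, direct epidemiological
counting badly underestimates how many people are affected: patients are
misdiagnosed, diagnosed late, or never sequenced. An alternative is to
estimate *genetic* prevalence from a large reference cohort such as gnomAD:
curate the set of disease-causing variants in the gene, sum their allele
frequencies per genetic-ancestry group, and apply the Hardy–Weinberg
principle. `genoprev` implements this estimator as a tested pipeline, from
raw candidate tables through curation bookkeeping to per-group estimates and
population projections. Its reference use case is GBE1-related disease
(glycogen storage disease type IV, including adult polyglucosan body
disease), and the package ships a deterministic synthetic fixture that
reproduces the published GBE1 figures end to end.

## Model

Let \(q_v\) be the allele frequency of included variant \(v\) in ancestry
group \(g\), computed as \(AC_{g,v} / AN_{g,v}\) from the reference cohort's
allele count and allele number. The pipeline computes, per group:

* **aggregate allele frequency** \(\Sigma q = \sum_v q_v\),
* **cumulative carrier frequency** \(2\,\Sigma q\),
* **genetic prevalence** \((\Sigma q)^2\).

The prevalence identity follows from Hardy–Weinberg equilibrium:
\((\sum_i q_i)^2 = \sum_i \sum_j q_i q_j\) enumerates every ordered pair of
disease alleles, i.e. homozygotes plus compound heterozygotes. The test
suite checks this identity against a literal double-sum oracle.

Modeling assumptions, stated explicitly:

* **Carrier frequency is \(2\Sigma q\), not \(2\Sigma q(1-\Sigma q)\).**
  The linear form is the stated convention of this estimator family; at the
  aggregate frequencies involved (\(\Sigma q < 10^{-2}\)) the two differ by
  under 1%. The JSON report header records the formula used.
* **Random mating within groups.** Consanguinity is not modeled; in
  populations with elevated consanguinity the true prevalence will exceed
  the estimate.
* **Autosomal biallelic locus.** X-linked math is out of scope.
* **Variants absent from the reference cohort contribute zero.** They are
  retained in candidate lists (they still need curation) but add nothing to
  \(\Sigma q\); a run-log warning counts them.
* **The pooled ("all") frequency of a variant is \(\sum_g AC_g / \sum_g
  AN_g\)**, matching how a global AF column is constructed from stratified
  counts — not the mean of group frequencies.

## Curation triage and inclusion sets

Candidates are drawn from three source dialects: ClinVar-style assertion
tables (pathogenic / likely pathogenic, plus conflicting records with at
least one P/LP assertion — an explicit `has_plp` flag is required, and
conflicting rows without it are skipped and logged), HGMD-style
disease-causing-mutation lists, and high-confidence predicted
loss-of-function tables. Database VUSs never become candidates: including
them would inflate the estimate with variants that may later prove benign.

Candidates are deduplicated on the normalized genomic key
(contig, position, ref, alt) after VCF-style left-align-and-trim
normalization; HGVS strings are provenance metadata only, since HGVS
dialects drift across databases.

The triage rule that prioritizes human review is a pure function of the
total allele count and the pLoF flag:

| condition | path |
|---|---|
| AC ≥ 15 (AF above 1e-5 in a gnomAD-v4-sized cohort) | full ACMG/AMP review (plus LoF review if pLoF) |
| AC in (1, 15) and pLoF | LoF curation |
| otherwise | abbreviated review |

Triage only prioritizes; the classification file may assign any final class
regardless of path. Final classifications override source assertions.
Without curation, source assertions map conservatively: P and LP are
honoured, while DM, conflicting-with-P/LP and bare pLoF claims are held at
VUS rather than promoted.

Two inclusion sets drive the sensitivity analysis:

* **conservative** — final P and LP only;
* **relaxed** — P, LP, plus VUSs that entered with a P/LP-type claim and
  were downgraded during curation (tracked by a `downgraded_from_plp` flag,
  never by re-reading sources).

Benign and likely benign variants are excluded from both. The suite
property-checks that the conservative set is always a subset of the relaxed
set and that relaxed estimates dominate conservative ones in every group.

## Numerical and formatting conventions

* "1 in N" strings use \(N = \mathrm{round}(1/f)\) with halves rounded away
  from zero (base R's `round()` is round-half-even, which would turn a
  denominator of 2.5 into 2); percentages are rounded the same way at two
  decimals. All internal arithmetic is unrounded; rounding happens only at
  the formatting boundary.
* An aggregate frequency above 1 is treated as malformed input and raises
  an error rather than being clamped; an aggregate above 0.5 makes the
  linear carrier approximation meaningless and likewise errors.
* Population projections carry an explicit rounding grain (1, 10, 50,
  100...), recorded in the output, because headline counts for large
  populations are conventionally reported to the nearest 50 or 100 while
  small counts are reported exactly. The default is grain 1 below an
  expected count of 1000 and grain 100 above.
* Variant normalization follows the standard shrink-right / extend-left
  algorithm against a supplied reference context and errors if left
  alignment would walk outside the context. Without a context, only
  prefix/suffix trimming is performed.

## What the synthetic data emulates

### The deterministic reference fixture

`generate_paper_fixture()` writes a complete input bundle — source tables
with decoy rows, a frequency table over nine ancestry groups, a
classification file, and population sizes — whose pipeline output lands on
every row of the published GBE1 table: 270 candidates (8 P, 230 LP, 28
curation-downgraded VUS, 4 benign/likely benign), 104 variants triaged to
full or LoF review, 238 conservative / 266 relaxed inclusion counts, and
all ten printed carrier and prevalence denominators.

Two construction details are worth recording:

* The printed prevalence denominators \(D_g\) imply irrational targets
  \(\Sigma q_g = 1/\sqrt{D_g}\), which integer allele counts cannot hit
  exactly. Each group places most alleles at a baseline allele number (92%
  of \(2\times\) the group's individuals, a typical exome call rate) and
  solves the allele numbers of its last two singleton variants by
  enumeration, leaving a residual below ~5e-12 — orders of magnitude inside
  the rounding window of every printed denominator, so both the carrier and
  the prevalence "1 in N" strings reproduce exactly.
* The printed overall row is not exactly consistent with the per-group rows
  at a uniform call rate: pooling the group targets with every allele
  number at its maximum gives an overall \(\Sigma q\) of about 2.066e-3,
  while the printed overall row implies 2.0594e-3. This is expected — in
  real data per-site allele numbers vary — so the fixture varies the allele
  numbers of zero-AC cells (within 75–100% of the group maximum) until the
  pooled aggregate matches the printed overall row. The same mechanism
  explains why the published US projection (1452) is not recoverable from
  the printed rounded prevalence (336e6/235776 ≈ 1425): the original
  calculation evidently used an unrounded aggregate. The package documents
  this rather than targeting it, as it also does for the abstract's
  "1 in 235 784" versus the table's 235776, and for the rounded 1.41%
  Ashkenazi carrier frequency of the c.986A>C missense, which does not
  exactly reproduce the printed 1/20069 homozygote frequency (the fixture
  pins that variant's counts, 192/27200, to the back-derived unrounded
  frequency instead).

The fixture is fully deterministic — no RNG anywhere — and a test asserts
byte-identical regeneration.

### The stochastic cohort simulator

`generate_cohort()` is the statistical stand-in for reference-cohort
sampling: per group, a symmetric Dirichlet splits the target aggregate
frequency across P/LP variants (VUS variants receive one tenth of the
target mass so relaxed estimates stay strictly above conservative ones),
observed counts are drawn \(AC \sim \mathrm{Binomial}(AN, q_v)\), and
homozygote counts are the Hardy–Weinberg expectation rounded down. Seeds
are explicit in the configuration; no global random state leaks.

A 200-seed recovery test (two groups, 12 variants, allele numbers 20 000
and 30 000 — sizes chosen to keep the whole suite under a few seconds
while leaving Monte-Carlo error well-resolved) checks that the mean
estimated \(\Sigma q\) sits within three Monte-Carlo standard errors of
truth, i.e. that the estimator is unbiased under its own sampling model.

What passing these tests does *not* show about real data: the simulator
draws independent binomial counts at a single per-group allele number, with
no sequencing error, no joint-calling artifacts, no relatedness, no
linkage between variants, and no ascertainment bias in who gets sequenced.
Agreement on synthetic data validates the arithmetic and bookkeeping, not
the representativeness of any reference cohort.

## Known limitations

* Estimates inherit every bias of the reference cohort: under-represented
  ancestries (the published Middle Eastern stratum has ~3000 individuals)
  yield unstable aggregates, and variants detectable only by genome
  sequencing (deep intronic variants, large deletions) are missing from
  exome-dominated counts. The reference study could not include a known
  deep-intronic disease allele for exactly this reason.
* No confidence intervals are produced; the upstream convention reports
  point estimates only.
* Penetrance, age of onset and survival are not modeled: genetic
  prevalence counts genotypes, not diagnoses.
* Phase is ignored: two included alleles in one individual are assumed to
  be in trans.
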