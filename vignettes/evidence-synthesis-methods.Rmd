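---
title: "Methods: synthesising replicated genetic association evidence for depression and antidepressant response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evidence synthesis for depression genetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evsyn)
```

## The problem

Hundreds of case-control association studies relate genetic variants to
major depressive disorder (MDD) susceptibility and to antidepressant
response, but most positive findings come from a single study and the
studies that do replicate often disagree about *which* allele carries
the risk. `evsyn` implements the evidence-synthesis computation that
turns a curated catalog of per-study results into:

1. the set of variants and genes replicated in at least two independent
   studies, split by study design (candidate-gene vs GWAS vs both);
2. a minor-allele-frequency filter removing rare variants;
3. a risk-allele consistency classification after harmonizing every
   study's reported allele to a common direction;
4. pooled diagnostic-predictability metrics (sensitivity, specificity,
   positive predictive value) over concordant studies; and
5. a shortlist of replicated variants with a single risk allele and an
   assessable PPV, joined to static functional annotations.

The package ships fixture catalogs transcribing the published tables of
replicated variants/genes for both phenotype domains, and a synthetic
catalog generator with known ground truth so that every stage is
testable without any network access.

## Recomputed allelic statistics

Raw data, when a study provides it, always wins over the published
statistic. For a 2x2 allele table (risk/wild x case/control) the
package computes:

* the cross-product odds ratio
  $\hat\psi = (a d)/(b c)$ with a Woolf (log-normal) 95% interval,
  $\mathrm{SE} = \sqrt{1/a + 1/b + 1/c + 1/d}$, $z = 1.959964$;
* the Pearson chi-square test (1 df, no continuity correction) as the
  "allelic P". The source methodology never names its test; Pearson
  without Yates is the convention for allelic tables, and both a Yates
  and a Fisher-exact switch are exposed (`test` argument).
* Zero cells: Haldane-Anscombe +0.5 on all four cells, applied to the
  estimate and interval only — never to the chi-square counts.
* Genotype counts collapse to alleles as $n_b = 2\,\mathrm{BB} +
  \mathrm{AB}$; frequency-only records reconstruct counts as
  `round(freq * 2n)` (half-up), flagged `reconstructed_freq`.

Significance is strict unadjusted $p < 0.05$, matching the curation
rule of the source tables; a curated `significant` flag stands in when
a table prints only "<.05".

## Risk-allele harmonization

Each study contributes one harmonized risk allele: the allele
overrepresented in cases. Preference order, recorded in a `basis`
field: raw counts (higher case frequency); a reported allele flipped
when its odds ratio is below 1; the allele composing a reported risk
genotype (also direction-flipped); a reported allele without any odds
ratio is taken at face value. An exact case/control frequency tie
yields no allele, and such "undetermined" studies count toward the
inconsistent tally by default (configurable), since a group containing
them cannot demonstrate a single shared risk allele.

Heterozygote contrasts ("LS vs LL+SS") have no recoverable allele
direction; the fixtures transcribe the allele attribution printed in
the source table for those rows rather than guessing.

## Replication accounting

Studies are grouped per variant (or per gene, where any variant in the
gene counts). Two strata of one publication count once; two
publications drawn from one participant cohort also count once
(`cohort_id`). A group is replicated with at least 2 countable studies.
Evidence buckets: `candidate` with >= 2 candidate studies, `gwas` with
>= 2 GWAS studies, `both` with >= 1 of each; a group can hold several
buckets, and headline counts sum bucket sizes — this reproduces the
published accounting in which one PCLO missense variant appears both
among the candidate-replicated and the candidate+GWAS-replicated
variants (bucket sum 31 vs 30 unique ids). The deduplicated unique
count is always reported alongside. GWAS records are admitted at their
reported significance, including sub-genome-wide "suggestive" hits, as
in the source tables.

The MAF filter is strict (`maf_global < 0.05` excluded, `= 0.05` kept);
groups without a recorded global MAF are kept with a warning. The
intron-2 VNTR of the serotonin transporter has no reference-panel
frequency (the literature quotes a 0.025-0.15 range), so its fixture
MAF is `NA` and it is retained, as in the source analysis.

## Diagnostic predictability

With the harmonized risk allele as the "test-positive" state, each
study yields a confusion table: TP = risk alleles in cases, FN =
wild-type alleles in cases, TN/FP analogously in controls. The default
counting unit is the allele (two per subject), matching the extracted
allele frequencies; a carrier unit (>= 1 risk allele, needs genotype
counts) is available behind the `unit` flag because the source text
mixes both readings. Tables are pooled by element-wise summation across
studies that share the harmonized allele — and, for treatment outcomes,
the outcome type (response / remission / resistance) and drug class —
then

$$\mathrm{sens} = \frac{\Sigma TP}{\Sigma TP + \Sigma FN},\quad
  \mathrm{spec} = \frac{\Sigma TN}{\Sigma TN + \Sigma FP},\quad
  \mathrm{PPV} = \frac{\Sigma TP}{\Sigma TP + \Sigma FP}.$$

A stratum is *eligible* with at least `min_pooled = 2` cohort-distinct
studies whose raw data is available; ineligible strata carry a reason
code (`no_raw_data`, `singleton_stratum`, `discordant_only`). A variant
with two concordant opposite-allele strata reports both results.
Unrounded values are kept internally; display rounding is two decimals,
half-up.

The bundled catalogs transcribe raw-data *availability* (mirroring the
"-" cells of the source tables) but not the per-study allele
frequencies, which were published only in a journal supplement. On the
fixtures the package therefore reproduces the eligibility accounting
(19 susceptibility and 5 response variants with an assessable pooled
PPV) while the metric values themselves are exercised end to end on
synthetic counts; the corresponding two acceptance expectations on the
printed metric values are left failing rather than hard-coding numbers
the pipeline cannot compute.

## Functional annotation summary

Annotations are consumed from static tables only (SIFT and PolyPhen
classes, RegulomeDB ranks, splice/miRNA flags, conservation and
regulatory-potential scores, knockout-mouse / drug-target /
brain-expression flags); nothing is queried at run time. "Regulatory
effect" means an assigned rank of category 5 or stronger; "high
regulatory" defaults to a numeric tier below 3 — the source's own
"score <3" list includes a 3a variant, so the threshold is a knob and
the discrepancy documented rather than silently resolved. Summary
fractions are stored exactly (count/denominator).

The susceptibility annotation fixture has 31 rows following the
published bucket-entry denominator (the doubly listed PCLO variant
carries two identical rows), which also reproduces the published "7
missense" and "7 splice-affecting" counts whose unique ids number six.
Per-variant values printed in the source (the shortlist rows, the named
ranks, SIFT/PolyPhen calls, splice/miRNA lists) are transcribed
exactly; values reported only in aggregate are synthetic fill chosen
once to match the aggregate counts, marked as such in
`data-raw/make_fixtures.R` — a green summary test therefore establishes
that the summary logic reproduces the published tallies from a
consistent table, not that the fill is biologically true.

## The synthetic world

`generate_catalog()` draws, per variant, case risk-allele counts
$\sim \mathrm{Bin}(2 n_{case}, p_1)$ and control counts
$\sim \mathrm{Bin}(2 n_{ctrl}, p_0)$ with
$p_1 = \psi p_0 / (1 + p_0(\psi - 1))$ — Hardy-Weinberg at the allele
level, with optional multinomial HWE genotypes for the carrier unit.
Defaults (`p0 = 0.30`, `psi = 1.5`, 2000 per arm, 5 studies) mirror the
moderate effect sizes and frequencies of the replicated susceptibility
variants. Each study self-computes its odds ratio, interval and allelic
p from the drawn counts. Two realistic corruptions are configurable:
`discordance_rate` flips the *reported* risk allele (keeping the >1
magnitude — a study mislabelling the protective allele as risk; raw
counts untouched, so harmonization from raw data is immune and the flip
only propagates when raw data is also withheld), and `missing_raw_rate`
withholds raw counts, leaving only reported statistics. A single master
seed drives deterministic per-(variant, study) substreams, so insertion
order never changes a draw and reruns are byte-identical.

What the generator does not emulate: population stratification, linkage
disequilibrium, covariate effects, publication bias, or GWAS-scale
variant counts. Green recovery tests establish that pooling estimates
$p_1$, $1 - p_0$ and the implied PPV under the stated sampling model —
not that the curated literature behaves this simply.

## Numerical and design choices

* Alleles are opaque strings (VNTR labels "L"/"S" work everywhere); no
  strand flipping at run time. Reported alleles printed on the opposite
  strand were normalised once, during fixture transcription, preserving
  the direction of effect.
* Coordinates are 1-based GRCh38 as printed; the VCF export writes
  VCFv4.3 with symbolic ALT for non-SNVs and skips variants without
  coordinates (warning with a count).
* `NA` is the only missing marker in all TSVs; zeros are never missing.
* Catalog validation is total: a record either loads or produces an
  error naming its publication, field and row.
* Ties: an exact case/control frequency tie harmonizes to no allele;
  an odds ratio of exactly 1 reports allele b as the nominal direction
  in the generator (irrelevant downstream, since such studies are
  non-significant).
* The analysis is presented as numbered drivers under `analysis/`
  (simulation calibration, replication, predictability, annotation +
  shortlist) over the package functions; there is no shell CLI, because
  the artifact is a set of analyses over curated tables rather than a
  command-line tool.

## Known limitations

* No meta-analytic effect pooling, NPV/likelihood ratios, confidence
  intervals on sensitivity/specificity, Hardy-Weinberg testing, or LD
  collapsing — out of scope by design.
* Pooling weights studies by allele counts; whether the original
  computation weighted any variant by carriers instead is not
  recoverable from the text (the `unit` flag preserves both readings).
* Fixture metric values depend on supplementary per-study frequencies
  that are not machine-readable; see the predictability section.
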