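---
title: "Methods: cross-study vote-count meta-analysis of AD brain proteomics"
author: "ProteoMetaAD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-study vote-count meta-analysis of AD brain proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ProteoMetaAD)
```

# The problem and the model

Mass-spectrometry studies of human Alzheimer's disease (AD) brain tissue
each publish a list of differentially expressed proteins (DEPs) between
disease and control, but individually they are limited by small cohorts,
single brain regions, and heterogeneous statistics. ProteoMetaAD implements
a cross-study *vote-count* meta-analysis over such published DEP tables: it
never touches raw spectra or intensities, only the per-protein verdicts the
source studies report (direction of change, fold change, p-value/FDR,
peptide support), harmonized so that the same protein can be recognised
across studies.

The unit of evidence is a **comparison**: one publication x brain region x
clinical stage x tissue fraction combination. A study covering two regions
and two stages contributes four comparisons. Per gene the pipeline counts
the comparisons in which it was reported significantly altered (the
overall score), and separately in bulk-tissue comparisons only (the bulk
score). Unweighted counting is deliberate: the source statistics are too
heterogeneous (FDR lists, ANOVA post-hoc calls, fold-change-plus-p rules,
presence counts) for effect sizes to be poolable, so the meta-analytic
statistic is the number of independent reports, not a combined estimate.

## Directional consistency with one outlier

For a gene with `n_up` + `n_down` = `n` bulk reports:

* `n < 5` — *insufficient* evidence; no consistency class.
* `n >= 5` and at most **one** report against the majority — *increased*
  or *decreased* with the majority sign.
* `n >= 5` with two or more discordant reports — *inconsistent*.

The single-outlier allowance absorbs the one aberrant report that a
different fraction, region or stage can legitimately produce; two
discordant reports are treated as real disagreement. Within a single
stratum (one clinical stage, or one brain region) the rule is stricter:
below five reports unanimity is required, because one outlier among three
reports is weak evidence of a direction. A gene passing the stratum rule
receives a signed score `+/- n` — the magnitude keeps the full evidence
count, outlier included, so that `|score|` always equals the number of
supporting comparisons (the alternative, subtracting the outlier, makes
`|score|` ambiguous between, say, 6-with-outlier and 5-unanimous).

## Staging, regions, phases

Clinical stages are categorical labels from the comparison metadata:
preclinical AD (plaque pathology without cognitive impairment), MCI, and
advanced AD. Because current MCI data are sparse and low-powered, the
preclinical and MCI calls are merged into an **early AD** group: one
sub-stage with a direction decides; agreement sums the signed scores;
disagreement withholds the early call (conservative — no such conflict is
expected in curated data, and the count of conflicts is exposed).

Stage categories compare the early direction with a **high-confidence
advanced** direction (>= 5 advanced bulk reports, one outlier permitted):
same direction = early-AD change; advanced only = advanced change;
opposite direction, or an early direction with no advanced direction at
all = opposite/early-only change; anything else scored in at least one
stage = unable to group. A gene whose advanced direction exists but rests
on fewer than five reports is deliberately *unable to group* rather than
"advanced" or "early-only": the evidence is directional but below the
confidence bar.

The region analysis is restricted to advanced AD (early-stage data are
almost exclusively frontal cortex) and uses the literature-consensus
split: nine vulnerable regions (entorhinal, hippocampus, parahippocampal,
temporal, frontal, parietal, precuneus, cingulate, occipital) and three
resistant ones (sensory cortex, motor cortex, cerebellum). The ventricle
wall is excluded — the literature does not support placing it. Per-region
signed scores (stratum rule as above) are summed within each class;
high-confidence protein changes need a combined vulnerable score of
magnitude >= 5. Seven categories follow from the sign pattern of the
combined vulnerable and resistant scores, with "unchanged in resistant"
meaning a zero/absent resistant score, and mixed signs within a class
mapping to *inconsistent*.

Phases order the protein changes in disease time:

* **Phase 1 (pre-neuropathology)** — same direction in resistant regions,
  early-stage AD *and* advanced AD. These changes precede local plaque
  and tangle pathology.
* **Phase 2 (early AD)** — same direction early and advanced, no
  resistant-region direction.
* **Phase 3 (advanced AD)** — advanced direction only.

Any directional conflict between the three evidence subsets excludes the
gene as inconsistent. The resistant-region direction requires a coherent
sign and `|combined resistant score| >= 1` (the `minResistant` argument):
the source methodology names no numeric bar for the resistant side, so the
weakest coherent evidence is accepted by default and the bar is
configurable. Early-stage evidence is not region-restricted (nearly all of
it is frontal cortex anyway); this is the merged-early reading of "altered
in early-stage AD" and the alternative (requiring each sub-stage) is
available by inspecting the per-sub-stage scores in the stage table.

## Lesion proteomes

Microdissected lesion studies (amyloid plaques, neurofibrillary tangles,
CAA-containing blood vessels) are handled separately from bulk tissue. A
gene is *enriched* in a lesion if any lesion comparison reports a fold
change strictly above 1.5 versus neighbouring control tissue, *depleted*
below 1/1.5 (the reciprocal is the symmetric reading of the published
">1.5-fold" rule), and *present* if detected in >= 3 cases under a
presence-scheme study or reported with a fold change inside the band.
Enrichment calls from multiple studies of one lesion merge by union;
a would-be enriched-and-depleted conflict degrades to *present* with a
flag. Presence alone never promotes a gene into enriched/depleted sets.
Overlaps between the three lesion proteomes are reported as the seven
disjoint cells of a three-set partition, and lesion sets are
cross-tabulated against the bulk consistency classes (genes with < 5 bulk
reports count as *unaltered* there).

# Significance schemes

Each comparison declares the statistical scheme its DEP list was produced
under, and the pipeline re-applies it with strict inequalities:

| scheme | rule |
|---|---|
| `FDR5` | FDR < 0.05 |
| `FC_AND_P` | p < 0.05 **and** (FC > 1.5 or FC < 1/1.5) |
| `ANOVA_POSTHOC`, `KRUSKAL_WALLIS` | the source study's significance call, gated on p < 0.05 when a p-value is carried |
| `PRESENCE_CASES` | present in >= 3 cases (lesion studies) |
| `LESION_FC` | FC > 1.5 or FC < 1/1.5 (lesion vs control tissue) |

ANOVA post-hoc and Kruskal-Wallis statistics are *not* recomputed: they
require per-subject data the published tables do not carry, so the source
study's verdict is ingested. When a study published group values but no
test, `welchTTest()` (unpaired, two-sided, Welch correction — source
variance structures are unknown) and `foldChange()` recompute them, and
`bhFDR()` provides the step-up FDR adjustment; these wrap the standard
`stats` implementations and add only the degenerate-input conventions
(both groups constant and equal gives p = 1; n < 2 is an error).

# Harmonization rules

Identifiers are made comparable across studies with deliberately minimal
surgery: the first symbol of a multi-valued gene field, uppercased and
trimmed; UniProt accessions stripped of `-<digits>` isoform suffixes; no
gene-synonym resolution (none is described by the curation this mirrors,
and silent aliasing creates more problems than it solves). A record with a
UniProt accession but no gene symbol adopts the accession as its grouping
key; a record with neither is dropped with a warning. Fold changes arrive
as linear ratios or log2 values — the per-file schema declares which, and
everything downstream is linear. Proteins supported by a single peptide
are excluded; records without a peptide column are retained on the
assumption that the source study already applied its own filter.
Duplicate gene ids within one comparison collapse to the record with the
smallest p-value (ties: largest |log FC|, then first occurrence) — the
deterministic "strongest evidence" choice, since the curation protocol
says only that duplicates were removed. Harmonization is idempotent, and
every dropped row is counted in a drop log carried into the corpus
metadata and the report.

# The corpus object

The assembled corpus is a `SummarizedExperiment` subclass
(`ProteinCorpus`): rows are genes, columns are comparisons, and the assays
hold the per-report direction, linear fold change, p-value, FDR, peptide
count, lesion case-presence count and the DEP call. Comparison metadata is
`colData`; the rule constants travel in `metadata(x)$thresholds` as an
`AnalysisThresholds` object (k = 5 minimum studies, m = 1 outlier, 1.5
fold-change cutoff, 0.05 alpha and FDR, 3-case presence floor, top-set
cutoff 15, 2-peptide minimum). Class validity enforces the structural
invariants: unique gene and comparison ids, direction/fold-change
agreement, lesion sample types paired with lesion schemes, isoform-free
accessions, ventricle wall unassigned.

# The synthetic-corpus generator

`simulateCorpus()` exists so every pipeline stage is testable with known
ground truth and no access to the curated data. Its default design
(`defaultStudyDesign()`) emulates the real study landscape: 59 bulk
comparisons from 32 publications across 13 regions, three stages and
several fractions and schemes, plus 4 plaque, 2 NFT and 1 CAA lesion
comparisons. Detection power is tiered 0.9 / 0.5 / 0.2 by the size of the
DEP list each study class published, encoding the observation that
low-powered studies produce false negatives, not false positives.

Defaults, chosen once as the study conditions: a 2,000-gene universe, 40%
truly altered (3% phase 1, 10% phase 2, 27% phase 3 — echoing the scale of
the real corpus, where pre-neuropathology changes are a small minority and
advanced-only changes dominate), 40% of altered genes increased (the real
consistent set leans toward decreases), log-normal effect magnitudes
(meanlog 0, sdlog 0.5) scaling per-comparison detection `min(1, power x
magnitude)`, sign-flip rate 0.02, background (false-positive) rate 0.002,
lesion membership 10% / 3% / 3% with 70% of members enriched. Emitted
records draw their fold change strictly on the reported side of the 1.5
cutoff and their p/FDR below the cutoff, i.e. the generator plants DEP
*reports*, not raw abundances — testing the statistics recomputation path
is what `welchTTest()`'s own tests are for.

What the generator does **not** emulate: correlated detection between
comparisons of one publication, gene-specific flip propensities, tissue
fraction effects, abundance-dependent missingness, or curation errors in
the source tables. Passing recovery tests therefore demonstrates the
correctness of the classification algebra under the stated noise model,
not robustness to every pathology of real literature data.

Recovery is measured over genes with at least five bulk DEP reports, the
same floor the classification uses. The three metrics partition the
failure modes: `direction_accuracy` is sign-correctness among floor genes
that received a directional class, `inconsistent_fraction` counts floor
genes denied a direction by discordant reports, and `phase_accuracy` is
exact phase agreement for truly phased floor genes. In the noise-free
limit (power 1, flip and background 0, effect dispersion 0) all detection
is deterministic and direction and phase recovery are exact — the
acceptance tests assert this at 400 genes, and assert >= 95% direction
recovery at flip rate 0.05 / power 0.6 on a 2,000-gene corpus with 12
advanced, 6 early-stage and 4 resistant-region comparisons. With sign
flips at rate `f`, two flips among `n` reports trip the one-outlier rule,
so the inconsistent fraction grows roughly like the binomial tail
`P(Binom(n, f) >= 2)` while a *wrong* directional call needs `n - 1`
flips and is vanishingly rare — which is why sign accuracy stays at 1
while inconsistency absorbs the noise.

# Numerical and procedural choices

* All inequalities strict, matching the published wording of the rules
  ("> 1.5-fold", "FDR < 5%").
* Counting unit: comparisons by default; `countBy = "publication"`
  collapses each publication to the net sign of its comparisons (a
  publication whose comparisons cancel contributes nothing).
* Vulnerability high-confidence: `|combined vulnerable signed score| >= 5`
  by default; `highConfidence = "count"` switches to >= 5 supporting
  comparisons regardless of score cancellation.
* Ties: `n_up == n_down` is always inconsistent/no-score; top-set ordering
  is score-descending with alphabetical tie-break; exports are sorted by
  gene id; floating-point export columns carry 6 significant digits.
* Degenerate inputs: empty corpora flow through every stage and yield
  empty tables and zero counts; comparisons with no surviving records are
  retained as all-NA columns.
* Problem sizes in the shipped tests: 10,000-replicate null-uniformity
  check for the t-test, exhaustive truth tables to n = 12, 100 random
  set triples, 1,000-gene invariant corpus, 2,000-gene recovery runs —
  sizes at which every stochastic bound was verified across 20 seeds
  before being frozen.

# Limitations

* Vote counting ignores effect sizes and study quality; a 20-subject and a
  500-subject study each cast one vote. This mirrors the methodology the
  package implements, and is the honest choice given non-poolable source
  statistics, but it is not a meta-analytic effect estimate.
* Gene-symbol grouping without synonym resolution can split a protein
  reported under different symbols across studies, and conflicting
  gene/UniProt pairs are grouped by gene id only (the accession is kept as
  annotation).
* The phase assignment is set algebra over consistency calls, not a model
  of disease time; "pre-neuropathology" is an inference from region
  vulnerability, not a measurement.
* Reproducing the printed counts of the original compiled dataset
  requires its supplementary export, which cannot be redistributed here;
  the ingestion path for it (long-format TSV through a column-mapping
  block) is exercised against generated data instead.
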