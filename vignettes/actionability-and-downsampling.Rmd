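---
title: "Methods: actionability matching, platform down-sampling, TMB and MSI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: actionability matching, platform down-sampling, TMB and MSI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actiondown)
```

This vignette records the models, conventions and design choices behind
`actiondown`, in the spirit of a statistical-methods section: what is
computed, under which assumptions, and where a genuinely open choice was
made.

## Knowledge base and evidence model

A biomarker–drug knowledge base is a flat table: one row couples a
biomarker (a `(gene, alteration class, variant pattern)` triple) with a
tumour-type set, a drug, an association direction (sensitivity or
resistance) and an evidence tier. Six tiers are recognised, ordered
`FDA_GUIDELINES > NCCN_GUIDELINES > LATE_TRIALS > EARLY_TRIALS >
CASE_REPORT > PRE_CLINICAL`. For headline counts the top four collapse
into two groups — *approved* (both guideline tiers) and *trials* (both
trial tiers) — while case-report and pre-clinical rules are retained but
reported separately; they never enter headline percentages. Grouping NCCN
with FDA under "approved" is a deliberate reading: both are
guideline-level endorsements, and separating them would split biomarkers
whose rows differ only in the endorsing body.

Tumour types are matched through a deliberately minimal ontology: a flat
synonym table mapping dataset cohort labels (e.g. `melanoma_like`) to
knowledge-base labels (`melanoma_cutaneous`), with one optional parent
label (`solid_tumour`). The single parent level is exactly what is needed
to express tumour-agnostic approvals such as NTRK-fusion inhibitors: a
rule targeting `solid_tumour` is on-label for every cohort whose label
has that parent. Deeper ontologies (site hierarchies, histology axes) are
out of scope; the mapping between a given dataset's labels and the
knowledge base's labels is data the user supplies, because no canonical
mapping exists.

Counting uses biomarker identity, not rule identity: a biomarker with five
drug rows is one biomarker. For a tumour type and evidence group,
a biomarker is *on-label* if at least one of its rules in that group
covers the tumour, and *off-label* if it has group-level rules only for
other tumour types — each biomarker lands in exactly one bin, so the two
counts are additive.

## Matching rules

Alterations are normalised into four classes before matching.

* **MUT** — an SNV/indel with a consequence term and optional protein
  change. Rule patterns form a small grammar: an exact change (`V600E`),
  a codon wildcard (`V600.`, any substitution at that codon), `any` (any
  protein-altering variant in the gene), and `LOF` (nonsense, frameshift,
  splice donor/acceptor, start/stop-altering). The grammar is the
  smallest that expresses the recurring catalogue archetypes — hotspot
  inhibitor rules, gene-level resistance rules, loss-of-function
  sensitivity rules — without attempting a full HGVS engine.
* **AMP / DEL** — copy-number calls classified from *total* copy number,
  uncorrected for ploidy: CN ≥ 6 is an amplification (the boundary value
  amplifies), CN < 1 a homozygous deletion, anything between neutral.
  Ploidy correction is deliberately not offered: the convention
  overcalls amplification in polyploid genomes and the documentation says
  so, but a ploidy-aware mode would change the method rather than
  parameterise it. Structural variants predicted to abolish gene function
  also produce DEL alterations, one per affected gene.
* **FUS** — viable gene fusions as ordered 5'/3' pairs. A fusion rule
  fires when its gene is either partner and its partner constraint
  (`any` or a named gene) is satisfied. Intra-intronic fusions are
  excluded outright as events of unknown significance.

Two exclusions apply across the board: synonymous (and any
non-protein-altering) variants never match, and with the default
`driver_only = TRUE` the broad `any`/`LOF` patterns fire only for rules
catalogued as driver alterations. Fully specified patterns are exempt
from the driver gate because the pattern itself identifies the catalogued
alteration. Driver status is carried by the knowledge base, not predicted:
driver-classification models are a separate problem, and the filter here
reproduces catalogue-based matching only.

The consequence vocabulary is a fixed, documented list partitioned into
protein-altering and non-altering terms; `is_nonsynonymous()` is total on
it and errors on anything else, so unannotated records must be handled
explicitly by the caller rather than silently dropped.

## Platforms and down-sampling

A platform is a footprint (merged BED intervals, 0-based half-open), a
fixed megabase denominator and a capability mask. Variant retention uses
the any-overlap rule — a variant is kept when its reference span
(1-based `[pos, pos + nchar(ref) − 1]`) touches at least one footprint
base — matching the default behaviour of interval-intersection tools, so
a deletion straddling a capture boundary is retained. All conversion
between the 0-based half-open footprint convention and 1-based variant
coordinates happens in a single function (`variant_span()`), which is the
only place an off-by-one could live.

Capability masks encode assay physics rather than regions: the hotspot
panel calls no copy-number alterations, and only whole-genome sequencing
and the comprehensive panel detect fusions. Copy-number segments on
CNA-capable restricted platforms are retained when they overlap the
footprint — whether a real pipeline would region-filter segment calls or
keep gene-level calls intact is genuinely unclear, and overlap filtering
is the choice documented here.

Chromosome-name dialects (`chr1` vs `1`) must match exactly; a mismatch
aborts with a message instead of silently retaining nothing, and a rename
map is accepted. Silent empty intersections are the classic failure mode
of footprint filtering, hence the hard error.

## Tumour mutation burden

TMB is `mutation_count / denominator_mb`, exactly. Denominators are
constants of the platform — 3000 Mb for whole-genome counts and the
printed footprint sizes 37.105146, 2.628876 and 0.016951 Mb for the
built-in exome, comprehensive panel and hotspot panel — never recomputed
from the region file, because the convention divides whole-genome counts
by a round 3000 Mb regardless of the mappable genome. Both the count and
the quotient are reported so alternative denominator conventions can be
re-derived. The filter is either `all` or `nonsynonymous`
(protein-altering only); the latter can only decrease TMB.

Concordance between two platforms is a Pearson correlation on paired
per-sample TMB (Spearman available as an option; which of the two a given
published figure used is often unstated, and Pearson is the default here),
plus threshold-discordance counts at a strict `> 10` mutations/Mb rule on
each side. The strict inequality follows the "TMB of >10" phrasing used
in platform comparisons; regulatory definitions sometimes use ≥ 10, and
the threshold is a parameter. Fewer than three shared samples leaves the
correlation `NA` with a warning; discordance counts are still reported.

## Microsatellite instability

Input is per-site tumour and normal repeat-length read-count
distributions, not alignments: extracting length distributions from BAMs
is upstream realignment work, while the statistical decision per site is
the part worth testing. Each site with at least `min_coverage = 20` reads
in both samples is tested with a chi-square homogeneity statistic on the
2 × K length table; bins whose expected count falls below 1 in either row
are pooled into the nearest neighbouring repeat length first, so a single
stray read cannot manufacture a significant site. The per-sample score is
the percentage of unstable sites among evaluable ones, restricted to the
platform footprint by the same any-overlap rule; a footprint covering no
locus is an error naming the platform (expected for hotspot-scale
panels), never a silent zero.

Two defaults deserve justification:

* `threshold_pct = 3.5` for MSI-high classification, the threshold
  suggested for this family of somatic per-site tests; it is configurable
  because published pipelines differ.
* `alpha = 0.001` per site. The reference tools control a false-discovery
  rate across sites; this implementation deliberately simplifies to a
  fixed per-site level, and an uncorrected 0.05 would leave a ~5%
  false-unstable rate under the null — above the 3.5% score threshold, so
  every stable sample would classify MSI-high. 0.001 is a
  Bonferroni-scale level for the ~100 evaluable loci of a typical run and
  plays the role of the omitted FDR machinery.

## The synthetic cohort generator

The generator produces every input the pipeline consumes, with ground
truth, over a toy world: a 10 Mb genome on five contigs, 30 genes
(14 carrying biomarker rules, 16 background), nested footprints
(8 × 1 kb hotspot-panel windows ⊂ an 18-gene comprehensive panel ⊂ a
30-gene exome), and 120 microsatellite loci, half genic and half
intergenic. Footprint sizes are recorded exactly, so toy-world TMB
denominators are exact. The comprehensive panel and hotspot panel
deliberately include background genes: real panels assay many genes
without biomarker rules, and the panel footprints need passenger signal
for burden estimates to mean anything.

Per sample, the generator draws:

* a passenger count from Poisson(rate × 10 Mb), where the per-sample rate
  is the cohort rate times a mean-preserving lognormal factor
  (`rate_dispersion`, default sdlog 0.5). The dispersion emulates the
  several-fold within-cohort TMB spread of real tumours and matters
  qualitatively: in a perfectly homogeneous cohort the correlation
  between genome-wide and panel TMB is a thinning constant independent of
  the rate, and the empirically observed weakening of panel concordance
  in low-burden cohorts only exists when samples differ in underlying
  rate. Setting `rate_dispersion = 0` recovers the homogeneous Poisson
  cohort used by the moment-checking tests.
* passenger positions uniformly over the genome. Passengers are
  non-actionable *by construction*: inside a rule-bearing gene they are
  forced synonymous (synonymous variants never match), inside background
  genes they are protein-altering with probability 2.5/3.5 (a fixed
  toy-world convention of 2.5 non-synonymous per synonymous coding
  mutation, chosen so the non-synonymous filter has a designed, testable
  effect — not a biological estimate), and elsewhere they are intergenic.
  This keeps placement exactly uniform, which the unbiasedness tests for
  panel TMB rely on, while keeping actionability ground truth exact.
* planted events by Bernoulli draws at designed prevalences: hotspot
  SNVs/indels (`"GENE:V600E"` or `"GENE:LOF"`), copy-number events with a
  designed CN, viable fusions, and loss-of-function structural variants.
  With `mutually_exclusive = TRUE` at most one hotspot event is planted
  per sample, so designed prevalences are exact category prevalences —
  used when a test must recover an on-label and an off-label prevalence
  simultaneously.
* MSI status with probability `msi_h_fraction`; MSI-high samples shift
  the tumour length distribution at a designed 30% of loci
  (normal reads centre on repeat length 15, shifted tumours on 13, 200
  reads per site). The separation is intentionally clear: the tests
  verify the scoring machinery and threshold logic, not the resolving
  power of borderline coverage.

What the generator does **not** emulate: mutational signatures and
sequence context, clonal structure and subclonal fractions, read-level
noise, capture-efficiency and coverage variation across the footprint,
FFPE artefacts, and germline contamination. Passing tests therefore
demonstrate that the annotation, down-sampling and scoring logic is
correct under idealised calls — not that any platform would achieve these
sensitivities on real libraries, where depth and capture chemistry add
platform-specific error the in-silico approach assumes away.

## Determinism and problem sizes

All randomness flows from a single integer seed through per-stage derived
seeds (`derive_seed()`), so `run_pipeline()` reproduces its TSV/JSON
bundle byte for byte; the JSON report embeds the seed and a configuration
hash and deliberately no timestamp. The test-suite problem sizes were
chosen as the smallest that make the statistical assertions sharp:
100 random toy genomes for the interval oracle, 100 random
instances (≤ 100 alterations × ≤ 50 rules) for the matcher oracle, a
400-sample cohort for prevalence recovery (3 binomial standard deviations
≈ 6.5 points at 25%), 20 replicate 50-sample cohorts per rate for the
concordance contrast, and 50 + 50 samples for MSI recovery. In the
concordance experiment a replicate whose panel shows zero variance
contributes a correlation of 0 — an all-zero panel carries no concordance
information, and treating it as missing would silently drop exactly the
replicates that make the low-rate regime hard.

## Known limitations

* Biomarker matching is catalogue-driven; there is no variant-effect
  prediction, no pathogenicity scoring, and no germline actionability.
* Drug strings are opaque: combinations are single rows and no
  nomenclature normalisation is attempted.
* Resistance calls are reported alongside sensitivity calls
  (`n_with_resistance`) but do not veto them; a clinical decision layer
  would need to.
* The MSI estimator simplifies FDR control to a conservative fixed
  per-site level, as discussed above.
* Copy-number thresholds are ploidy-uncorrected by design.
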