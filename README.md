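# actiondown

Somatic-variant actionability annotation, drug-repurposing classification
and in-silico sequencing-platform comparison, in R.

## The problem

Tumour sequencing is read against catalogues of biomarker–drug
associations: a somatic alteration that matches a catalogued biomarker
predicts sensitivity or resistance to a drug, either in the patient's own
tumour type (*on-label*) or in another indication (*off-label* — a
repurposing candidate). How many such patients you find, and what you
estimate for tumour mutation burden (TMB) and microsatellite instability
(MSI), depends on the assay: whole-genome sequencing (WGS), whole-exome
sequencing (WES), a comprehensive gene panel (CGP) or a small hotspot
panel all see different slices of the genome and different event classes.

`actiondown` implements that whole analysis as a tested pipeline:

* **Knowledge base** — a flat biomarker–drug rule table with six ordered
  evidence tiers (FDA guidelines > NCCN guidelines > late trials > early
  trials > case report > pre-clinical), a tumour-type ontology with one
  parent level for tumour-agnostic approvals, and on/off-label expansion
  counts per tumour type.
* **Matching** — SNVs/indels, copy-number segments and structural
  variants are normalised to a matcher vocabulary and matched against
  rule patterns: exact amino-acid change (`V600E`), codon wildcard
  (`V600.`), gene-level `any`, or `LOF`. Copy-number calls use total CN
  uncorrected for ploidy, with CN ≥ 6 an amplification and CN < 1 a
  homozygous deletion; loss-of-function SVs count as deletions,
  intra-intronic fusions are excluded; synonymous variants and
  non-driver-catalogued broad matches never fire.
* **Repurposing classification** — each match falls in exactly one of
  {approved, trials} × {on-label, off-label}, or `other_evidence` for
  case-report/pre-clinical rules; cohort summaries count patients once,
  with off-label percentages additive to on-label ones.
* **Platform down-sampling** — BED-defined footprints with
  bedtools-style any-overlap retention, plus capability masks (the
  hotspot panel calls no CNAs; only WGS and the CGP call fusions).
* **TMB** — mutations divided by a fixed platform denominator
  (3000 Mb for WGS; 37.105146, 2.628876 and 0.016951 Mb for WES, CGP and
  hotspot panel), for all or non-synonymous-only mutations, with
  cross-platform correlation and threshold-discordance counts
  (high TMB = strictly > 10 mutations/Mb).
* **MSI** — a chi-square homogeneity test per microsatellite locus on
  tumour versus normal repeat-length read counts (sparse bins pooled),
  percent-unstable scoring with platform-restricted loci, and MSI-high
  classification above 3.5%.
* **Synthetic cohorts** — a generator producing every input above with
  per-sample ground truth (planted hotspot/CNA/fusion events, true
  mutation counts, MSI class), so the full pipeline is testable without
  controlled-access tumour data.

## A worked example

```r
library(actiondown)

ref   <- make_toy_reference(1)   # 10 Mb toy genome, nested footprints
kb    <- make_toy_kb()           # 15-rule biomarker catalogue
plats <- toy_platforms(ref)

prof <- cohort_profile(
  "melanoma_like", n_samples = 200, mutation_rate_per_mb = 10,
  hotspot_prevalences = c("BRAF:V600E" = 0.3),
  cna_events = tibble::tibble(gene = "ERBB2", prob = 0.1, cn = 8),
  fusion_events = c("NTRK1:BG02" = 0.05),
  msi_h_fraction = 0.1, seed = 42
)
sim <- simulate_cohort(prof, ref, kb)

calls <- sample_actionability(sim, kb, plats$WGS) |>
  classify_matches(sim$samples, kb)
summarize_cohort(calls, sim$samples) |>
  dplyr::filter(evidence_group == "approved", association == "sensitivity")
#> # A tibble: 2 × 8
#>   cohort        evidence_group association label_scope n_patients denominator   pct n_with_resistance
#>   <chr>         <chr>          <chr>       <chr>            <int>       <int> <dbl>             <int>
#> 1 melanoma_like approved       sensitivity on_label            70         200    35                 0
#> 2 melanoma_like approved       sensitivity off_label           12         200     6                 0
```

35% of simulated patients have an on-label approved option: the 30%
planted BRAF V600E carriers (dabrafenib, FDA tier, melanoma) plus the
NTRK1-fusion carriers, whose tumour-agnostic approval counts as on-label.
The further 6% carry only an ERBB2 amplification, approved in breast and
oesophageal cancer — an off-label repurposing candidate for a melanoma
cohort. TMB from the same cohort, scored on two footprints:

```r
glance(tmb_concordance(
  compute_tmb(sim$variants, plats$WGS,    samples = sim$samples$sample),
  compute_tmb(sim$variants, plats$CPANEL, samples = sim$samples$sample)
))
#> # A tibble: 1 × 7
#>   comparison            n_samples correlation_r method  threshold discordant_a_high discordant_b_high
#>   <chr>                     <int>         <dbl> <chr>       <dbl>             <int>             <int>
#> 1 WGS/all vs CPANEL/all       200         0.473 pearson        10                19                55
```

The panel estimate correlates with the genome-wide one, but 74 of 200
samples land on opposite sides of the 10 mutations/Mb cutoff — the
platform-dependence of hard TMB thresholds in one row.
`autoplot()` methods exist for cohort summaries
and concordance objects, and `run_pipeline(run_config(...))` orchestrates
simulate → down-sample → match → classify → TMB → MSI → summarise into a
TSV/JSON report bundle, deterministically from one seed.

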