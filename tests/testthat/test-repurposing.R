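toy_match <- function(sample, rule_id, kb, association = NULL) {
  r <- kb$rules[kb$rules$rule_id == rule_id, ]
  tibble::tibble(
    sample = sample, rule_id = rule_id, gene = r$gene,
    alteration = "x", matched_pattern = "exact", drug = r$drug,
    association = association %||% r$association,
    evidence = as.character(r$evidence), chrom = "chr1", pos = 1L
  )
}

test_that("match categories follow evidence group and tumour-type coverage", {
  kb <- make_toy_kb()
  samples <- tibble::tibble(
    sample = c("mel1", "muc1", "ov1", "pnet1"),
    tumour = c("melanoma_like", "mucosal_melanoma_like", "ovarian_like",
               "pnet_like")
  )
  calls <- classify_matches(
    dplyr::bind_rows(
      toy_match("mel1", "R001", kb),   # FDA melanoma rule, melanoma sample
      toy_match("muc1", "R008", kb),   # KIT/imatinib approved in GIST only
      toy_match("ov1", "R009", kb),    # early-trials TP53 rule, ovarian
      toy_match("mel1", "R010", kb),   # pre-clinical rule
      toy_match("pnet1", "R006", kb)   # tumour-agnostic fusion approval
    ),
    samples, kb
  )
  expect_equal(calls$category[calls$rule_id == "R001"], "approved_on_label")
  expect_equal(calls$category[calls$rule_id == "R008"], "approved_off_label")
  expect_equal(calls$category[calls$rule_id == "R009"], "trials_on_label")
  expect_equal(calls$category[calls$rule_id == "R010"], "other_evidence")
  # parent-level (solid tumour) coverage counts as on-label
  expect_equal(calls$category[calls$rule_id == "R006"], "approved_on_label")
  expect_error(
    classify_matches(toy_match("x1", "R001", kb),
                     tibble::tibble(sample = "x1", tumour = "not_a_type"), kb),
    "unknown tumour label"
  )
})

test_that("cohort summaries count patients once with the additive off-label convention", {
  kb <- make_toy_kb()
  samples <- tibble::tibble(
    sample = sprintf("s%02d", 1:10), cohort = "mel",
    tumour = "melanoma_like"
  )
  # 3 patients with on-label approved; one of them also has an off-label
  # approved call; a 4th patient has an off-label approved call only
  calls <- dplyr::bind_rows(
    toy_match(c("s01", "s02", "s03"), "R001", kb),
    toy_match(c("s01", "s04"), "R008", kb)
  ) |> classify_matches(samples, kb)
  summ <- summarize_cohort(calls, samples)
  on <- summ[summ$evidence_group == "approved" &
             summ$association == "sensitivity" &
             summ$label_scope == "on_label", ]
  off <- summ[summ$evidence_group == "approved" &
              summ$association == "sensitivity" &
              summ$label_scope == "off_label", ]
  expect_equal(on$n_patients, 3L)
  expect_equal(on$pct, 30)
  # s01 is already counted on-label, so only s04 is an off-label patient
  expect_equal(off$n_patients, 1L)
  expect_equal(off$pct, 10)
  expect_error(summarize_cohort(calls, samples[0, ]), "empty cohort")
})

test_that("on plus off-label equals the fraction with any call of the group", {
  kb <- make_toy_kb()
  ref <- make_toy_reference(1)
  prof <- cohort_profile(
    "melanoma_like", 60, mutation_rate_per_mb = 3,
    hotspot_prevalences = c("BRAF:V600E" = 0.4, "TSC2:A500V" = 0.3,
                            "KRAS:G12D" = 0.2),
    generate_msi = FALSE, seed = 13
  )
  sim <- simulate_cohort(prof, ref, kb)
  calls <- sample_actionability(sim, kb) |> classify_matches(sim$samples, kb)
  summ <- summarize_cohort(calls, sim$samples)
  for (grp in c("approved", "trials")) {
    for (assoc in c("sensitivity", "resistance")) {
      cell <- summ[summ$evidence_group == grp & summ$association == assoc &
                   !is.na(summ$label_scope), ]
      any_pct <- 100 * dplyr::n_distinct(
        calls$sample[calls$evidence_group == grp & calls$association == assoc]
      ) / nrow(sim$samples)
      expect_equal(sum(cell$pct), any_pct)
      expect_lte(sum(cell$pct), 100)
    }
  }
})

test_that("designed prevalences are recovered within binomial error", {
  kb <- make_toy_kb()
  ref <- make_toy_reference(1)
  p_on <- 0.3
  n <- 200
  prof <- cohort_profile(
    "melanoma_like", n, mutation_rate_per_mb = 2,
    hotspot_prevalences = c("BRAF:V600E" = p_on),
    generate_msi = FALSE, seed = 21
  )
  sim <- simulate_cohort(prof, ref, kb)
  calls <- sample_actionability(sim, kb) |> classify_matches(sim$samples, kb)
  summ <- summarize_cohort(calls, sim$samples)
  got <- summ$pct[summ$evidence_group == "approved" &
                  summ$association == "sensitivity" &
                  summ$label_scope == "on_label"] / 100
  expect_lt(abs(got - p_on), 3 * sqrt(p_on * (1 - p_on) / n))
})

test_that("platform comparison reflects capability masks and footprints", {
  kb <- make_toy_kb()
  ref <- make_toy_reference(1)
  plats <- toy_platforms(ref)
  # cohort whose only actionable events are fusions
  prof <- cohort_profile(
    "oesophageal_like", 30, mutation_rate_per_mb = 1,
    fusion_events = c("NTRK1:BG02" = 0.5),
    generate_msi = FALSE, seed = 31
  )
  sim <- simulate_cohort(prof, ref, kb)
  cmp <- platform_comparison(sim, sim$samples, kb, plats)
  pct <- function(p, ev = "approved") {
    cmp$pct[cmp$platform == p & cmp$evidence == ev & cmp$association == "any"]
  }
  expect_equal(pct("WES"), 0)
  expect_equal(pct("HGP"), 0)
  expect_gt(pct("WGS"), 0)
  expect_equal(pct("WGS"), pct("CPANEL"))

  # hotspot SNVs inside every footprint: all four platforms identical
  prof2 <- cohort_profile(
    "melanoma_like", 30, mutation_rate_per_mb = 1,
    hotspot_prevalences = c("BRAF:V600E" = 0.5),
    generate_msi = FALSE, seed = 32
  )
  sim2 <- simulate_cohort(prof2, ref, kb)
  cmp2 <- platform_comparison(sim2, sim2$samples, kb, plats)
  by_plat <- split(cmp2$pct, cmp2$platform)
  for (p in c("WES", "CPANEL", "HGP")) {
    expect_equal(by_plat[[p]], by_plat$WGS)
  }

  # raising the evidence bar never increases a percentage
  expect_true(all(
    cmp2$pct[cmp2$evidence == "approved"] <=
      cmp2$pct[cmp2$evidence == "approved_plus_trials"]
  ))
})
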