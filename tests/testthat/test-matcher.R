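test_that("copy-number classification honours the exact thresholds", {
  expect_equal(classify_cna(6), "amplification")
  expect_equal(classify_cna(6.5), "amplification")
  expect_equal(classify_cna(1), "neutral")
  expect_equal(classify_cna(0.99), "homozygous_deletion")
  expect_equal(classify_cna(0), "homozygous_deletion")
  expect_equal(classify_cna(2), "neutral")
  expect_error(classify_cna(-1), "negative")
  # thresholds are configurable
  cfg <- matcher_config(amp_cn_threshold = 7)
  expect_equal(classify_cna(6, cfg), "neutral")
  expect_error(matcher_config(amp_cn_threshold = 1, homdel_cn_threshold = 2))
})

test_that("structural variants map to deletions, fusions or exclusion", {
  sv <- tibble::tibble(
    sample = "s",
    chrom1 = "c1", pos1 = 1L, chrom2 = "c1", pos2 = 2L,
    genes = c("NF1;SUZ12", "NTRK1;ETV6", "KIT", "BRAF"),
    effect = c("loss_of_function", "viable_fusion", "intra_intron_fusion",
               "other"),
    fusion5 = c(NA, "ETV6", NA, NA),
    fusion3 = c(NA, "NTRK1", NA, NA)
  )
  alt <- sv_to_alteration(sv)
  # LOF touches two genes -> two deletion biomarkers; others excluded
  expect_equal(sum(alt$alt_class == "DEL"), 2)
  expect_setequal(alt$gene[alt$alt_class == "DEL"], c("NF1", "SUZ12"))
  expect_equal(sum(alt$alt_class == "FUS"), 1)
  expect_equal(alt$fusion3[alt$alt_class == "FUS"], "NTRK1")
  expect_equal(nrow(alt), 3)
})

test_that("hotspot, resistance and synonymous-exclusion matching behave as specified", {
  kb <- make_toy_kb()
  v600e <- normalize_alterations(variants = tibble::tibble(
    sample = "s1", chrom = "chr1", pos = 105000L, ref = "T", alt = "A",
    gene = "BRAF", consequence = "missense_variant", protein_change = "V600E"
  ))
  m <- match_alteration(v600e, kb)
  expect_setequal(m$rule_id, c("R001", "R002"))
  expect_equal(m$matched_pattern[m$rule_id == "R001"], "exact")
  expect_equal(m$matched_pattern[m$rule_id == "R002"], "codon")

  # V600K misses the exact rule but hits the codon wildcard
  v600k <- dplyr::mutate(v600e, protein_change = "V600K")
  expect_equal(match_alteration(v600k, kb)$rule_id, "R002")

  # KRAS gene-level resistance rule fires on any non-synonymous variant
  kras <- normalize_alterations(variants = tibble::tibble(
    sample = "s1", chrom = "chr2", pos = 105000L, ref = "G", alt = "T",
    gene = "KRAS", consequence = "missense_variant", protein_change = "G12D"
  ))
  mk <- match_alteration(kras, kb)
  expect_equal(mk$rule_id, "R004")
  expect_equal(mk$association, "resistance")

  # synonymous variants never match, even against gene-level rules
  syn <- dplyr::mutate(kras, consequence = "synonymous_variant",
                       protein_change = NA_character_)
  expect_equal(nrow(match_alteration(syn, kb)), 0)

  # LOF pattern: splice acceptor counts, missense does not
  brca_splice <- normalize_alterations(variants = tibble::tibble(
    sample = "s1", chrom = "chr4", pos = 105000L, ref = "A", alt = "G",
    gene = "BRCA1", consequence = "splice_acceptor_variant",
    protein_change = NA_character_
  ))
  expect_equal(match_alteration(brca_splice, kb)$rule_id, "R005")
})

test_that("driver-only gating silences broad patterns on non-driver rules", {
  rules <- tibble::tibble(
    rule_id = c("X1", "X2"),
    gene = "KRAS", alteration_class = "MUT",
    variant_pattern = c("any", "G12D"), fusion_partner = "",
    tumour_types = "ta", drug = "d", association = "sensitivity",
    evidence = "FDA_GUIDELINES", driver = FALSE
  )
  kb <- biomarker_kb(rules)
  alt <- normalize_alterations(variants = tibble::tibble(
    sample = "s", chrom = "c", pos = 1L, ref = "A", alt = "T",
    gene = "KRAS", consequence = "missense_variant", protein_change = "G12D"
  ))
  # broad pattern gated out; fully specified pattern still fires
  strict <- match_alteration(alt, kb, matcher_config(driver_only = TRUE))
  expect_equal(strict$rule_id, "X2")
  lax <- match_alteration(alt, kb, matcher_config(driver_only = FALSE))
  expect_setequal(lax$rule_id, c("X1", "X2"))
})

test_that("fusion rules respect partner constraints", {
  rules <- tibble::tibble(
    rule_id = c("F1", "F2"),
    gene = "NTRK1", alteration_class = "FUS", variant_pattern = "",
    fusion_partner = c("any", "ETV6"),
    tumour_types = "any", drug = "d", association = "sensitivity",
    evidence = "FDA_GUIDELINES", driver = TRUE
  )
  kb <- biomarker_kb(rules)
  fus <- function(f5, f3) normalize_alterations(sv = tibble::tibble(
    sample = "s", chrom1 = "c", pos1 = 1L, chrom2 = "c", pos2 = 2L,
    genes = paste(f5, f3, sep = ";"), effect = "viable_fusion",
    fusion5 = f5, fusion3 = f3
  ))
  expect_setequal(match_alteration(fus("NTRK1", "BG01"), kb)$rule_id, "F1")
  expect_setequal(match_alteration(fus("ETV6", "NTRK1"), kb)$rule_id,
                  c("F1", "F2"))
  expect_equal(nrow(match_alteration(fus("BG01", "BG02"), kb)), 0)
})

test_that("the matcher agrees with the exhaustive predicate oracle", {
  genes <- c("G1", "G2", "G3", "G4", "G5")
  for (seed in 1:30) {
    set.seed(200 + seed)
    rules <- random_rules(sample(5:20, 1), genes)
    alts <- random_alterations(sample(10:60, 1), genes)
    kb <- biomarker_kb(rules)
    for (dro in c(TRUE, FALSE)) {
      got <- match_alteration(alts, kb, matcher_config(driver_only = dro))
      exp <- oracle_match(as.data.frame(alts), as.data.frame(rules),
                          driver_only = dro)
      got_key <- sort(paste(got$sample, got$rule_id))
      exp_key <- sort(paste(exp$sample, exp$rule_id))
      expect_equal(got_key, exp_key)
    }
  }
})

test_that("narrow platforms yield subsets of the whole-genome match set", {
  ref <- make_toy_reference(1)
  kb <- make_toy_kb()
  plats <- toy_platforms(ref)
  prof <- cohort_profile(
    "melanoma_like", 15, mutation_rate_per_mb = 10,
    hotspot_prevalences = c("BRAF:V600E" = 0.5, "KRAS:G12D" = 0.3,
                            "BRCA1:LOF" = 0.2),
    cna_events = tibble::tibble(gene = "ERBB2", prob = 0.3, cn = 8),
    fusion_events = c("NTRK1:BG02" = 0.3),
    generate_msi = FALSE, seed = 99
  )
  sim <- simulate_cohort(prof, ref, kb)
  key <- function(m) paste(m$sample, m$rule_id, m$chrom, m$pos)
  m_wgs <- sample_actionability(sim, kb, plats$WGS)
  for (p in c("WES", "CPANEL", "HGP")) {
    m_p <- sample_actionability(sim, kb, plats[[p]])
    expect_true(all(key(m_p) %in% key(m_wgs)), label = p)
  }
  # neutral-only CNA sample matches nothing
  neutral <- list(cna = tibble::tibble(
    sample = "s", chrom = "chr3", pos = NA, start = 1L, end = 10L,
    gene = "ERBB2", copy_number = 3
  ))
  expect_equal(nrow(sample_actionability(neutral, kb, plats$WGS)), 0)
})
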