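test_that("a single guideline rule loads from TSV with all fields intact", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste("rule_id", "gene", "alteration_class", "variant_pattern",
          "fusion_partner", "tumour_types", "drug", "association",
          "evidence", "driver", sep = "\t"),
    paste("B1", "BRAF", "MUT", "V600E", "", "melanoma_cutaneous",
          "dabrafenib", "sensitivity", "FDA guidelines", "true", sep = "\t")
  ), tsv)
  kb <- load_kb(tsv)
  expect_s3_class(kb, "biomarker_kb")
  expect_equal(nrow(kb$rules), 1)
  expect_equal(kb$rules$gene, "BRAF")
  expect_equal(as.character(kb$rules$evidence), "FDA_GUIDELINES")
  expect_equal(kb$rules$tumour_types[[1]], "melanoma_cutaneous")
  expect_true(kb$rules$driver)
})

test_that("a header-only file yields an empty KB and bad rows are rejected with diagnostics", {
  header <- paste("rule_id", "gene", "alteration_class", "variant_pattern",
                  "fusion_partner", "tumour_types", "drug", "association",
                  "evidence", "driver", sep = "\t")
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(header, empty)
  expect_equal(nrow(load_kb(empty)$rules), 0)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(header, paste(
    "B1", "BRAF", "MUT", "V600E", "", "melanoma_cutaneous",
    "dabrafenib", "sensitivity", "Phase I", "true", sep = "\t"
  )), bad)
  expect_error(load_kb(bad), "row 1.*evidence.*FDA_GUIDELINES",
               ignore.case = FALSE)

  # FUS rule without a partner names the row and field
  bad2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(header, paste(
    "F1", "NTRK1", "FUS", "", "", "any",
    "entrectinib", "sensitivity", "FDA guidelines", "true", sep = "\t"
  )), bad2)
  expect_error(load_kb(bad2), "row 1.*fusion_partner")
})

test_that("KB round-trips through its on-disk form", {
  kb <- make_toy_kb()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  ont <- withr::local_tempfile(fileext = ".tsv")
  write_kb(kb, tsv, ont)
  kb2 <- load_kb(tsv, ont)
  expect_equal(kb2$rules$rule_id, kb$rules$rule_id)
  expect_equal(kb2$rules$tumour_types, kb$rules$tumour_types)
  expect_equal(as.character(kb2$rules$evidence), as.character(kb$rules$evidence))
  expect_equal(kb2$ontology, kb$ontology)
})

test_that("tier_group is total over the six tiers and rejects unknowns", {
  expect_equal(
    tier_group(kb_evidence_levels),
    c("approved", "approved", "trials", "trials", "other", "other")
  )
  expect_equal(tier_group("FDA guidelines"), "approved")
  expect_equal(tier_group("EARLY_TRIALS"), "trials")
  expect_equal(tier_group("Pre-clinical"), "other")
  expect_error(tier_group("Phase I"), "Permitted labels")
})

test_that("on/off-label expansion handles the single-rule cases", {
  kb <- biomarker_kb(
    tibble::tibble(
      rule_id = "B1", gene = "BRAF", alteration_class = "MUT",
      variant_pattern = "V600E", fusion_partner = "",
      tumour_types = "melanoma_cutaneous", drug = "dabrafenib",
      association = "sensitivity", evidence = "FDA_GUIDELINES", driver = TRUE
    ),
    tibble::tibble(
      dataset_label = c("melanoma_like", "pdac_like"),
      kb_label = c("melanoma_cutaneous", "pancreatic_adenocarcinoma"),
      parent = "solid_tumour"
    )
  )
  mel <- repurposing_expansion(kb, "melanoma_like", "approved")
  expect_equal(mel$on_label_biomarkers, 1L)
  expect_equal(mel$off_label_biomarkers, 0L)
  pdac <- repurposing_expansion(kb, "pdac_like", "approved")
  expect_equal(pdac$on_label_biomarkers, 0L)
  expect_equal(pdac$off_label_biomarkers, 1L)
  expect_error(repurposing_expansion(kb, "no_such_tumour", "approved"),
               "unknown tumour label")
})

test_that("expansion matches exhaustive enumeration and is monotone under added rules", {
  genes <- c("G1", "G2", "G3", "G4")
  tumours <- c("ta", "tb", "tc")
  for (seed in 1:20) {
    set.seed(seed)
    rules <- random_rules(sample(3:25, 1), genes, tumours)
    # resolvability anchor that cannot affect approved/trials counts
    anchor <- rules[1, ]
    anchor$rule_id <- "ANCHOR"
    anchor$alteration_class <- "MUT"; anchor$variant_pattern <- "any"
    anchor$fusion_partner <- ""
    anchor$tumour_types <- paste(tumours, collapse = ";")
    anchor$evidence <- "PRE_CLINICAL"
    rules <- rbind(rules, anchor)
    kb <- biomarker_kb(rules)
    for (tu in tumours) {
      for (grp in c("approved", "trials")) {
        got <- repurposing_expansion(kb, tu, grp)
        exp <- oracle_expansion(as.data.frame(rules), tu, grp)
        expect_equal(got$on_label_biomarkers, unname(exp["on"]))
        expect_equal(got$off_label_biomarkers, unname(exp["off"]))
        # on + off never exceeds the group's distinct biomarker count
        expect_lte(got$on_label_biomarkers + got$off_label_biomarkers,
                   nrow(kb$rules))
      }
    }
    # monotonicity: adding one approved rule never decreases counts
    extra <- rules[1, ]
    extra$rule_id <- "EXTRA"; extra$gene <- "G9"
    extra$alteration_class <- "AMP"; extra$variant_pattern <- ""
    extra$fusion_partner <- ""; extra$tumour_types <- "ta"
    extra$evidence <- "FDA_GUIDELINES"
    kb2 <- biomarker_kb(rbind(rules, extra))
    for (tu in tumours) {
      before <- repurposing_expansion(kb, tu, "approved")
      after <- repurposing_expansion(kb2, tu, "approved")
      expect_gte(after$on_label_biomarkers, before$on_label_biomarkers)
      expect_gte(after$off_label_biomarkers, before$off_label_biomarkers)
    }
  }
})

test_that("shared-biomarker matrix equals pairwise set intersection", {
  # one tumour-agnostic rule: every pair shares it
  kb <- biomarker_kb(tibble::tibble(
    rule_id = "A1", gene = "NTRK1", alteration_class = "FUS",
    variant_pattern = "", fusion_partner = "any", tumour_types = "any",
    drug = "entrectinib", association = "sensitivity",
    evidence = "FDA_GUIDELINES", driver = TRUE
  ))
  m <- shared_biomarker_matrix(kb, "approved", tumours = c("ta", "tb", "tc"))
  expect_true(all(m == 1))
  expect_true(isSymmetric(m))

  # disjoint per-type rules: zero off-diagonal
  kb2 <- biomarker_kb(tibble::tibble(
    rule_id = c("A1", "A2"), gene = c("G1", "G2"),
    alteration_class = "MUT", variant_pattern = c("V600E", "G12D"),
    fusion_partner = "", tumour_types = c("ta", "tb"),
    drug = "d", association = "sensitivity",
    evidence = "FDA_GUIDELINES", driver = TRUE
  ))
  m2 <- shared_biomarker_matrix(kb2, "approved", tumours = c("ta", "tb"))
  expect_equal(unname(diag(m2)), c(1L, 1L))
  expect_equal(m2["ta", "tb"], 0L)

  # random KBs against a brute-force intersection oracle
  genes <- c("G1", "G2", "G3")
  tumours <- c("ta", "tb", "tc")
  for (seed in 1:10) {
    set.seed(100 + seed)
    rules <- random_rules(sample(5:30, 1), genes, tumours)
    kb3 <- biomarker_kb(rules)
    m3 <- shared_biomarker_matrix(kb3, "approved", tumours = tumours)
    grp <- tier_group(rules$evidence)
    sets <- lapply(tumours, function(tu) {
      sel <- grp == "approved" &
        vapply(strsplit(rules$tumour_types, ";"),
               function(tt) any(tt %in% c("any", tu)), logical(1))
      unique(paste(rules$gene, rules$alteration_class,
                   rules$variant_pattern)[sel])
    })
    for (i in 1:3) for (j in 1:3) {
      expect_equal(m3[i, j], length(intersect(sets[[i]], sets[[j]])))
    }
    expect_true(isSymmetric(m3))
  }
})
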