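# Independent brute-force oracles and random fixture generators.
# Everything here is written against the plain definitions, not against the
# package's implementation paths, so disagreement means a real defect.

# Per-position membership scan: a variant is retained iff any base of its
# 1-based reference span lies in the (0-based half-open) region list.
oracle_filter_variants <- function(variants, intervals) {
  member <- new.env(hash = TRUE)
  for (i in seq_len(nrow(intervals))) {
    s <- intervals$start[i]; e <- intervals$end[i]
    if (e > s) {
      for (p in (s + 1):e) {  # 1-based positions covered
        assign(paste0(intervals$chrom[i], ":", p), TRUE, envir = member)
      }
    }
  }
  keep <- logical(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    span <- variants$pos[i]:(variants$pos[i] + nchar(variants$ref[i]) - 1)
    keep[i] <- any(vapply(
      span,
      function(p) exists(paste0(variants$chrom[i], ":", p), envir = member),
      logical(1)
    ))
  }
  keep
}

oracle_lof_terms <- c("stop_gained", "frameshift_variant",
                      "splice_acceptor_variant", "splice_donor_variant",
                      "start_lost", "stop_lost")
oracle_nonsyn_terms <- c(oracle_lof_terms, "missense_variant",
                         "inframe_insertion", "inframe_deletion",
                         "protein_altering_variant")

# Exhaustive rule-by-alteration predicate double loop over a normalized
# alteration table and a plain rules data frame (tumour_types as string).
# Columns are pulled into plain vectors up front so the double loop stays
# fast; the per-pair predicate itself is written out longhand.
oracle_match <- function(alterations, rules, driver_only = TRUE) {
  a_class <- alterations$alt_class; a_gene <- alterations$gene
  a_cons <- alterations$consequence; a_pc <- alterations$protein_change
  a_f5 <- alterations$fusion5; a_f3 <- alterations$fusion3
  a_sample <- alterations$sample
  out_sample <- character(0); out_rule <- character(0); out_row <- integer(0)

  for (ri in seq_len(nrow(rules))) {
    r_class <- rules$alteration_class[ri]
    r_gene <- rules$gene[ri]
    r_pat <- rules$variant_pattern[ri]
    r_partner <- rules$fusion_partner[ri]
    r_driver <- isTRUE(rules$driver[ri])
    for (ai in seq_along(a_class)) {
      if (a_class[ai] != r_class) next
      ok <- FALSE
      if (r_class == "MUT") {
        if (is.na(a_gene[ai]) || a_gene[ai] != r_gene) next
        if (is.na(a_cons[ai]) || !(a_cons[ai] %in% oracle_nonsyn_terms)) next
        if (r_pat == "any") {
          ok <- !driver_only || r_driver
        } else if (r_pat == "LOF") {
          ok <- (a_cons[ai] %in% oracle_lof_terms) && (!driver_only || r_driver)
        } else if (substr(r_pat, nchar(r_pat), nchar(r_pat)) == ".") {
          stem <- substr(r_pat, 1, nchar(r_pat) - 1)
          pc <- a_pc[ai]
          ok <- !is.na(pc) && nchar(pc) > nchar(stem) &&
            substr(pc, 1, nchar(stem)) == stem &&
            grepl("^[A-Za-z*=]+$", substr(pc, nchar(stem) + 1, nchar(pc)))
        } else {
          ok <- !is.na(a_pc[ai]) && a_pc[ai] == r_pat
        }
      } else if (r_class %in% c("AMP", "DEL")) {
        ok <- !is.na(a_gene[ai]) && a_gene[ai] == r_gene
      } else {
        pair <- c(a_f5[ai], a_f3[ai])
        ok <- r_gene %in% pair &&
          (r_partner == "any" || r_partner %in% pair)
      }
      if (ok) {
        out_sample <- c(out_sample, a_sample[ai])
        out_rule <- c(out_rule, rules$rule_id[ri])
        out_row <- c(out_row, ai)
      }
    }
  }
  data.frame(sample = out_sample, rule_id = out_rule, alt_row = out_row,
             stringsAsFactors = FALSE)
}

# Enumeration oracle for on/off-label biomarker counts in one group.
oracle_expansion <- function(rules, tumour_targets, group) {
  grp <- ifelse(rules$evidence %in% c("FDA_GUIDELINES", "NCCN_GUIDELINES"),
                "approved",
         ifelse(rules$evidence %in% c("LATE_TRIALS", "EARLY_TRIALS"),
                "trials", "other"))
  sel <- rules[grp == group, ]
  if (nrow(sel) == 0) return(c(on = 0L, off = 0L))
  key <- paste(sel$gene, sel$alteration_class,
               ifelse(sel$alteration_class == "MUT", sel$variant_pattern, ""))
  covers <- vapply(strsplit(sel$tumour_types, ";"), function(tt) {
    any(tt %in% c("any", tumour_targets))
  }, logical(1))
  on_keys <- unique(key[covers])
  c(on = length(on_keys), off = length(setdiff(unique(key), on_keys)))
}

# ---- random fixture generators (fixed-seed property tests) ----------------

random_intervals <- function(n, genome_len = 10000, chroms = c("c1", "c2")) {
  start <- sample.int(genome_len, n, replace = TRUE) - 1L
  width <- sample.int(50, n, replace = TRUE)
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = start,
    end = pmin(start + width, genome_len)
  )
}

random_variant_table <- function(n, genome_len = 10000, chroms = c("c1", "c2")) {
  tibble::tibble(
    sample = "s1",
    chrom = sample(chroms, n, replace = TRUE),
    pos = sample.int(genome_len - 60, n, replace = TRUE),
    ref = vapply(sample.int(8, n, replace = TRUE),
                 function(k) paste(rep("A", k), collapse = ""), character(1)),
    alt = "T",
    gene = NA_character_,
    consequence = "intergenic_variant",
    protein_change = NA_character_
  )
}

random_rules <- function(n_rules, genes, seed_tumours = c("ta", "tb", "tc")) {
  classes <- sample(c("MUT", "AMP", "DEL", "FUS"), n_rules, replace = TRUE,
                    prob = c(0.55, 0.15, 0.15, 0.15))
  patterns <- vapply(classes, function(cl) {
    if (cl != "MUT") return("")
    switch(sample.int(4, 1),
      "V600E", "V600.", "any", "LOF")
  }, character(1))
  tibble::tibble(
    rule_id = sprintf("RR%03d", seq_len(n_rules)),
    gene = sample(genes, n_rules, replace = TRUE),
    alteration_class = classes,
    variant_pattern = patterns,
    fusion_partner = ifelse(classes == "FUS",
                            sample(c(genes, "any"), n_rules, replace = TRUE), ""),
    tumour_types = vapply(seq_len(n_rules), function(i) {
      k <- sample.int(length(seed_tumours), 1)
      if (stats::runif(1) < 0.1) "any" else
        paste(sample(seed_tumours, k), collapse = ";")
    }, character(1)),
    drug = sprintf("drug%d", seq_len(n_rules)),
    association = sample(c("sensitivity", "resistance"), n_rules,
                         replace = TRUE, prob = c(0.8, 0.2)),
    evidence = sample(c("FDA_GUIDELINES", "NCCN_GUIDELINES", "LATE_TRIALS",
                        "EARLY_TRIALS", "CASE_REPORT", "PRE_CLINICAL"),
                      n_rules, replace = TRUE),
    driver = sample(c(TRUE, FALSE), n_rules, replace = TRUE, prob = c(0.7, 0.3))
  )
}

random_alterations <- function(n, genes) {
  cls <- sample(c("MUT", "AMP", "DEL", "FUS"), n, replace = TRUE,
                prob = c(0.6, 0.15, 0.1, 0.15))
  conseq <- sample(c("missense_variant", "synonymous_variant", "stop_gained",
                     "frameshift_variant", "splice_acceptor_variant",
                     "intron_variant", "intergenic_variant"),
                   n, replace = TRUE)
  pc <- ifelse(conseq == "missense_variant",
               sample(c("V600E", "V600K", "G12D", "A55V"), n, replace = TRUE),
               NA_character_)
  tibble::tibble(
    sample = sample(c("sA", "sB", "sC"), n, replace = TRUE),
    alt_class = cls,
    gene = sample(genes, n, replace = TRUE),
    chrom = "c1",
    pos = sample.int(100000, n, replace = TRUE),
    protein_change = ifelse(cls == "MUT", pc, NA_character_),
    consequence = ifelse(cls == "MUT", conseq, NA_character_),
    fusion5 = ifelse(cls == "FUS", sample(genes, n, replace = TRUE), NA_character_),
    fusion3 = ifelse(cls == "FUS", sample(genes, n, replace = TRUE), NA_character_),
    copy_number = ifelse(cls == "AMP", 8, ifelse(cls == "DEL", 0, NA_real_))
  )
}
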