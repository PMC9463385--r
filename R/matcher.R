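#' Matcher configuration
#'
#' Thresholds and filters applied when alterations are converted to the
#' matcher vocabulary and matched against the knowledge base.
#'
#' @param amp_cn_threshold Total copy number at or above which a segment is
#'   called an amplification (default 6; the boundary value itself
#'   amplifies). Uncorrected for ploidy — a deliberate convention, so a
#'   tetraploid genome inflates calls rather than hiding them.
#' @param homdel_cn_threshold Copy number strictly below which a segment is
#'   a homozygous deletion (default 1, so CN = 1 is neutral).
#' @param driver_only When `TRUE` (default), broad rule patterns
#'   (`"any"` and `"LOF"`) only fire for rules catalogued as driver
#'   alterations, excluding passenger events from actionability calls.
#'   Fully specified patterns (exact amino-acid change, codon wildcard)
#'   identify the catalogued alteration directly and are unaffected.
#' @return A `matcher_config` list.
#' @export
matcher_config <- function(amp_cn_threshold = 6, homdel_cn_threshold = 1,
                           driver_only = TRUE) {
  if (homdel_cn_threshold >= amp_cn_threshold) {
    abort("homdel_cn_threshold must be below amp_cn_threshold")
  }
  if (homdel_cn_threshold < 0 || amp_cn_threshold < 0) {
    abort("copy-number thresholds must be >= 0")
  }
  structure(
    list(
      amp_cn_threshold = amp_cn_threshold,
      homdel_cn_threshold = homdel_cn_threshold,
      driver_only = isTRUE(driver_only)
    ),
    class = "matcher_config"
  )
}

#' Classify a copy-number value
#'
#' Total copy number at or above the amplification threshold is an
#' amplification (so CN = 6 amplifies under the default); strictly below
#' the homozygous-deletion threshold is a homozygous deletion (so CN = 1 is
#' neutral, CN = 0.99 deleted); anything between is neutral.
#'
#' @param copy_number Numeric vector of total copy numbers (ploidy
#'   uncorrected); negative values are an error.
#' @param config A [matcher_config()].
#' @return Character vector over `{"amplification",
#'   "homozygous_deletion", "neutral"}`.
#' @examples
#' classify_cna(c(0, 0.99, 1, 2, 6, 8))
#' @export
classify_cna <- function(copy_number, config = matcher_config()) {
  if (any(copy_number < 0, na.rm = TRUE)) abort("negative copy number")
  dplyr::case_when(
    copy_number >= config$amp_cn_threshold ~ "amplification",
    copy_number < config$homdel_cn_threshold ~ "homozygous_deletion",
    TRUE ~ "neutral"
  )
}

#' Convert structural variants to matcher alterations
#'
#' Structural variants predicted to abolish gene function become deletion
#' biomarkers on each affected gene; viable gene fusions become fusion
#' alterations; intra-intronic fusions (unknown significance) and any other
#' effect class are excluded.
#'
#' @param sv SV tibble (see [read_sv()]).
#' @return A tibble of normalized alterations with columns `sample`,
#'   `alt_class` (`DEL` or `FUS`), `gene`, `fusion5`, `fusion3`.
#' @export
sv_to_alteration <- function(sv) {
  assert_cols(sv, c("sample", "genes", "effect", "fusion5", "fusion3"), "SV table")
  lof <- sv |> filter(.data$effect == "loss_of_function")
  dels <- if (nrow(lof) == 0) NULL else {
    tibble(
      sample = rep(lof$sample, lengths(split_semi(lof$genes))),
      alt_class = "DEL",
      gene = unlist(split_semi(lof$genes)),
      fusion5 = NA_character_, fusion3 = NA_character_
    )
  }
  fus <- sv |> filter(.data$effect == "viable_fusion")
  fusions <- if (nrow(fus) == 0) NULL else {
    tibble(
      sample = fus$sample, alt_class = "FUS",
      gene = fus$fusion5, fusion5 = fus$fusion5, fusion3 = fus$fusion3
    )
  }
  out <- bind_rows(dels, fusions)
  if (is.null(out) || nrow(out) == 0) {
    out <- tibble(sample = character(0), alt_class = character(0),
                  gene = character(0), fusion5 = character(0),
                  fusion3 = character(0))
  }
  out
}

#' Normalize variants, CNAs and SVs into the matcher vocabulary
#'
#' Produces one table of candidate alterations: every SNV/indel as a `MUT`
#' row, copy-number segments classified by [classify_cna()] contributing
#' `AMP` (amplification) and `DEL` (homozygous deletion) rows, and
#' structural variants via [sv_to_alteration()]. Neutral segments and
#' excluded SV classes contribute nothing.
#'
#' @param variants,cna,sv Tibbles from the readers; any may be `NULL`.
#' @param config A [matcher_config()].
#' @return A tibble with columns `sample`, `alt_class`, `gene`, `chrom`,
#'   `pos`, `protein_change`, `consequence`, `fusion5`, `fusion3`,
#'   `copy_number`.
#' @export
normalize_alterations <- function(variants = NULL, cna = NULL, sv = NULL,
                                  config = matcher_config()) {
  pieces <- list()
  if (!is.null(variants) && nrow(variants) > 0) {
    pieces$mut <- variants |>
      mutate(alt_class = "MUT", fusion5 = NA_character_,
             fusion3 = NA_character_, copy_number = NA_real_) |>
      select("sample", "alt_class", "gene", "chrom", "pos",
             "protein_change", "consequence", "fusion5", "fusion3",
             "copy_number")
  }
  if (!is.null(cna) && nrow(cna) > 0) {
    cls <- classify_cna(cna$copy_number, config)
    keep <- cls != "neutral"
    if (any(keep)) {
      pieces$cna <- tibble(
        sample = cna$sample[keep],
        alt_class = if_else(cls[keep] == "amplification", "AMP", "DEL"),
        gene = cna$gene[keep],
        chrom = cna$chrom[keep], pos = cna$start[keep],
        protein_change = NA_character_, consequence = NA_character_,
        fusion5 = NA_character_, fusion3 = NA_character_,
        copy_number = cna$copy_number[keep]
      )
    }
  }
  if (!is.null(sv) && nrow(sv) > 0) {
    sva <- sv_to_alteration(sv)
    if (nrow(sva) > 0) {
      pieces$sv <- sva |>
        mutate(chrom = NA_character_, pos = NA_integer_,
               protein_change = NA_character_, consequence = NA_character_,
               copy_number = NA_real_) |>
        select("sample", "alt_class", "gene", "chrom", "pos",
               "protein_change", "consequence", "fusion5", "fusion3",
               "copy_number")
    }
  }
  if (length(pieces) == 0) {
    return(tibble(
      sample = character(0), alt_class = character(0), gene = character(0),
      chrom = character(0), pos = integer(0), protein_change = character(0),
      consequence = character(0), fusion5 = character(0),
      fusion3 = character(0), copy_number = double(0)
    ))
  }
  bind_rows(pieces)
}

# Which alterations satisfy one MUT-rule pattern?  Non-synonymous gating is
# applied before the pattern: synonymous and non-protein-altering variants
# never match, whatever the pattern says.
mut_pattern_hits <- function(alts, pattern, driver_ok) {
  nonsyn <- !is.na(alts$consequence) &
    alts$consequence %in% CONSEQ_PROTEIN_ALTERING
  pc <- alts$protein_change
  if (pattern == "any") {
    hits <- nonsyn & driver_ok
    type <- "gene"
  } else if (pattern == "LOF") {
    hits <- nonsyn & alts$consequence %in% CONSEQ_LOF & driver_ok
    type <- "lof"
  } else if (grepl("\\.$", pattern)) {
    prefix <- sub("\\.$", "", pattern)
    hits <- nonsyn & !is.na(pc) &
      grepl(paste0("^", prefix, "[A-Za-z*=]+$"), pc)
    type <- "codon"
  } else {
    hits <- nonsyn & !is.na(pc) & pc == pattern
    type <- "exact"
  }
  list(hits = hits, type = type)
}

#' Match normalized alterations against the knowledge base
#'
#' Applies each rule's predicate to each alteration. Mutation rules fire on
#' non-synonymous variants in the rule's gene whose protein change
#' satisfies the pattern: exact amino-acid change (`"V600E"`), codon
#' wildcard (`"V600."` fires on any substitution at that codon), gene-level
#' `"any"`, or `"LOF"` (nonsense, frameshift, splice donor/acceptor,
#' start/stop-altering). Amplification and deletion rules fire on
#' classified copy-number calls and SV-derived deletions; fusion rules fire
#' when the rule gene is one partner and `fusion_partner` is `"any"` or the
#' other partner. With `driver_only` set, the broad `"any"`/`"LOF"`
#' patterns only fire for driver-catalogued rules.
#'
#' @param alterations Output of [normalize_alterations()].
#' @param kb A `biomarker_kb`.
#' @param config A [matcher_config()].
#' @return A tibble of matches, one row per (alteration, rule) pair that
#'   fired: `sample`, `rule_id`, `gene`, `alteration`, `matched_pattern`,
#'   `drug`, `association`, `evidence`, `chrom`, `pos`; deterministically
#'   ordered by `rule_id` then position. No match returns zero rows.
#' @export
match_alteration <- function(alterations, kb, config = matcher_config()) {
  stopifnot(inherits(kb, "biomarker_kb"))
  rules <- kb$rules
  out <- vector("list", nrow(rules))
  for (i in seq_len(nrow(rules))) {
    r <- rules[i, ]
    cand <- alterations |> filter(.data$alt_class == r$alteration_class)
    if (nrow(cand) == 0) next
    if (r$alteration_class == "MUT") {
      cand <- cand |> filter(!is.na(.data$gene) & .data$gene == r$gene)
      if (nrow(cand) == 0) next
      driver_ok <- !config$driver_only || isTRUE(r$driver)
      pm <- mut_pattern_hits(cand, r$variant_pattern, driver_ok)
      hits <- pm$hits
      type <- pm$type
      desc <- paste0(r$gene, " ", if_else(is.na(cand$protein_change),
                                          cand$consequence,
                                          cand$protein_change))
    } else if (r$alteration_class %in% c("AMP", "DEL")) {
      hits <- !is.na(cand$gene) & cand$gene == r$gene
      type <- tolower(r$alteration_class)
      desc <- rep(paste0(r$gene, ":", type), nrow(cand))
    } else { # FUS
      in_pair <- (cand$fusion5 == r$gene) | (cand$fusion3 == r$gene)
      partner_ok <- if (r$fusion_partner == "any") {
        rep(TRUE, nrow(cand))
      } else {
        (cand$fusion5 == r$fusion_partner) | (cand$fusion3 == r$fusion_partner)
      }
      hits <- in_pair & partner_ok
      type <- "fusion"
      desc <- paste0(cand$fusion5, "--", cand$fusion3)
    }
    if (!any(hits)) next
    hit <- cand[hits, ]
    out[[i]] <- tibble(
      sample = hit$sample,
      rule_id = r$rule_id,
      gene = r$gene,
      alteration = desc[hits],
      matched_pattern = type,
      drug = r$drug,
      association = r$association,
      evidence = as.character(r$evidence),
      chrom = hit$chrom,
      pos = hit$pos
    )
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble(
      sample = character(0), rule_id = character(0), gene = character(0),
      alteration = character(0), matched_pattern = character(0),
      drug = character(0), association = character(0),
      evidence = character(0), chrom = character(0), pos = integer(0)
    ))
  }
  res |> arrange(.data$sample, .data$rule_id, .data$chrom, .data$pos)
}

#' Platform-aware actionability calls for a sample set
#'
#' Convenience wrapper: restricts each sample's alterations to the
#' platform with [downsample_sample()], normalizes them and matches against
#' the knowledge base.
#'
#' @param alterations A list with `variants`, `cna`, `sv` tibbles (possibly
#'   spanning many samples).
#' @param kb A `biomarker_kb`.
#' @param platform A [platform()]; `NULL` means no restriction (equivalent
#'   to `WGS`).
#' @param config A [matcher_config()].
#' @return A match tibble as from [match_alteration()], plus a `platform`
#'   column.
#' @export
sample_actionability <- function(alterations, kb, platform = NULL,
                                 config = matcher_config()) {
  if (!is.null(platform)) {
    alterations <- downsample_sample(alterations, platform)
  }
  norm <- normalize_alterations(alterations$variants, alterations$cna,
                                alterations$sv, config)
  res <- match_alteration(norm, kb, config)
  res$platform <- if (is.null(platform)) "WGS" else platform$name
  res
}
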