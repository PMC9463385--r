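#' Evidence tiers and clinical-evidence groups
#'
#' Biomarker-drug associations carry one of six ordered evidence tiers,
#' from regulatory guidelines down to pre-clinical observations. For
#' headline repurposing counts the top four tiers collapse into two groups:
#' `approved` (FDA or NCCN guidelines) and `trials` (late or early clinical
#' trials); case-report and pre-clinical rules are retained in the knowledge
#' base but reported separately as `other`.
#'
#' @format `kb_evidence_levels` is a character vector of the six tier codes,
#'   ordered from strongest to weakest.
#' @export
kb_evidence_levels <- c(
  "FDA_GUIDELINES", "NCCN_GUIDELINES", "LATE_TRIALS",
  "EARLY_TRIALS", "CASE_REPORT", "PRE_CLINICAL"
)

# Human-readable labels accepted in KB files, mapped to tier codes.
.evidence_label_map <- c(
  "fda guidelines"  = "FDA_GUIDELINES",
  "nccn guidelines" = "NCCN_GUIDELINES",
  "late trials"     = "LATE_TRIALS",
  "early trials"    = "EARLY_TRIALS",
  "case report"     = "CASE_REPORT",
  "pre-clinical"    = "PRE_CLINICAL"
)

parse_evidence <- function(x) {
  x_chr <- as.character(x)
  out <- ifelse(toupper(x_chr) %in% kb_evidence_levels,
    toupper(x_chr),
    unname(.evidence_label_map[tolower(x_chr)])
  )
  factor(out, levels = rev(kb_evidence_levels), ordered = TRUE)
}

#' Map an evidence tier onto its clinical-evidence group
#'
#' @param tier Character or factor vector of tier codes (see
#'   [kb_evidence_levels]) or the equivalent display labels
#'   ("FDA guidelines", ...).
#' @return A character vector over `{"approved", "trials", "other"}`. The
#'   mapping is total: every valid tier falls in exactly one group.
#' @examples
#' tier_group(c("FDA_GUIDELINES", "EARLY_TRIALS", "PRE_CLINICAL"))
#' @export
tier_group <- function(tier) {
  tt <- parse_evidence(tier)
  if (any(is.na(tt) & !is.na(tier))) {
    bad <- unique(as.character(tier)[is.na(tt) & !is.na(tier)])
    abort(sprintf(
      "unknown evidence label(s): %s. Permitted labels: %s",
      paste(bad, collapse = ", "),
      paste(kb_evidence_levels, collapse = ", ")
    ))
  }
  unname(c(
    FDA_GUIDELINES = "approved", NCCN_GUIDELINES = "approved",
    LATE_TRIALS = "trials", EARLY_TRIALS = "trials",
    CASE_REPORT = "other", PRE_CLINICAL = "other"
  )[as.character(tt)])
}

.kb_schema <- c(
  "rule_id", "gene", "alteration_class", "variant_pattern", "fusion_partner",
  "tumour_types", "drug", "association", "evidence", "driver"
)

#' Construct a biomarker knowledge base from a rules table
#'
#' A knowledge base couples a flat table of biomarker-drug rules with a
#' tumour-type ontology: a synonym table that maps dataset cancer labels to
#' the labels used by the rules, with one optional parent level so
#' tumour-agnostic approvals (for example NTRK fusions approved across solid
#' tumours) can target a parent label like `"solid_tumour"`.
#'
#' @param rules A data frame with columns `rule_id`, `gene`,
#'   `alteration_class` (`MUT`/`AMP`/`DEL`/`FUS`), `variant_pattern`
#'   (protein-change pattern for `MUT` rules: exact `"V600E"`, codon
#'   wildcard `"V600."`, `"any"` or `"LOF"`), `fusion_partner` (`FUS`
#'   only; gene symbol or `"any"`), `tumour_types` (semicolon-joined labels
#'   or `"any"`), `drug`, `association` (`sensitivity`/`resistance`),
#'   `evidence` (see [kb_evidence_levels]) and `driver` (logical: the
#'   alteration is a catalogued driver event).
#' @param ontology Optional data frame mapping `dataset_label` to
#'   `kb_label` with an optional `parent` column.
#' @return An object of class `biomarker_kb`: a list with tibbles `rules`
#'   (with `tumour_types` as a list-column and `evidence` as an ordered
#'   factor) and `ontology`.
#' @seealso [load_kb()] to read the tab-separated on-disk form.
#' @export
biomarker_kb <- function(rules, ontology = NULL) {
  rules <- as_tibble(rules)
  assert_cols(rules, .kb_schema, "knowledge base")

  problems <- character(0)
  note <- function(row, field, msg) {
    problems <<- c(problems, sprintf("row %d, field '%s': %s", row, field, msg))
  }

  ev <- parse_evidence(rules$evidence)
  for (i in seq_len(nrow(rules))) {
    if (is.na(ev[i])) {
      note(i, "evidence", sprintf(
        "unknown evidence label '%s'; permitted labels are %s",
        rules$evidence[i], paste(kb_evidence_levels, collapse = ", ")
      ))
    }
    if (!rules$alteration_class[i] %in% c("MUT", "AMP", "DEL", "FUS")) {
      note(i, "alteration_class", "must be one of MUT, AMP, DEL, FUS")
    }
    if (!rules$association[i] %in% c("sensitivity", "resistance")) {
      note(i, "association", "must be 'sensitivity' or 'resistance'")
    }
    fp <- rules$fusion_partner[i]
    has_partner <- !is.na(fp) & nzchar(fp) & fp != "."
    if (rules$alteration_class[i] == "FUS" && !has_partner) {
      note(i, "fusion_partner", "FUS rules require a partner gene or 'any'")
    }
    if (rules$alteration_class[i] != "FUS" && has_partner) {
      note(i, "fusion_partner", "only meaningful for FUS rules")
    }
    tt <- rules$tumour_types[i]
    if (is.na(tt) || !nzchar(tt)) {
      note(i, "tumour_types", "must be non-empty or 'any'")
    }
    if (is.na(rules$gene[i]) || !nzchar(rules$gene[i])) {
      note(i, "gene", "must be a gene symbol")
    }
  }
  if (anyDuplicated(rules$rule_id)) {
    problems <- c(problems, sprintf(
      "duplicated rule_id(s): %s",
      paste(unique(rules$rule_id[duplicated(rules$rule_id)]), collapse = ", ")
    ))
  }
  if (length(problems) > 0) {
    abort(paste0(
      "invalid knowledge base:\n",
      paste0("  - ", problems, collapse = "\n")
    ))
  }

  rules <- rules |>
    mutate(
      evidence = ev,
      driver = as.logical(.data$driver),
      tumour_types = split_semi(.data$tumour_types),
      fusion_partner = if_else(
        .data$alteration_class == "FUS", .data$fusion_partner, NA_character_
      ),
      variant_pattern = if_else(
        .data$alteration_class == "MUT", .data$variant_pattern, NA_character_
      )
    )

  if (is.null(ontology)) {
    ontology <- tibble(
      dataset_label = character(0), kb_label = character(0),
      parent = character(0)
    )
  } else {
    ontology <- as_tibble(ontology)
    assert_cols(ontology, c("dataset_label", "kb_label"), "tumour ontology")
    if (!"parent" %in% names(ontology)) ontology$parent <- NA_character_
  }

  structure(list(rules = rules, ontology = ontology), class = "biomarker_kb")
}

#' @export
print.biomarker_kb <- function(x, ...) {
  cat(sprintf(
    "<biomarker_kb> %d rules, %d genes, %d biomarkers, %d ontology entries\n",
    nrow(x$rules), length(unique(x$rules$gene)),
    nrow(distinct_biomarkers(x)), nrow(x$ontology)
  ))
  invisible(x)
}

#' Load a biomarker knowledge base from its tab-separated form
#'
#' The on-disk schema is one `(biomarker, tumour type set, drug, evidence)`
#' combination per row, tab-separated with header
#' `rule_id gene alteration_class variant_pattern fusion_partner
#' tumour_types drug association evidence driver`; `tumour_types` is a
#' semicolon-joined list or `"any"`. The optional ontology file has columns
#' `dataset_label kb_label parent`.
#'
#' @param path Path to the KB TSV.
#' @param ontology_path Optional path to the tumour-ontology TSV.
#' @return A `biomarker_kb` object; malformed rows abort with row-level
#'   diagnostics naming the row and field.
#' @export
load_kb <- function(path, ontology_path = NULL) {
  if (!file.exists(path)) abort(sprintf("KB file not found: %s", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = character(0))
  missing <- setdiff(.kb_schema, names(raw))
  if (length(missing) > 0) {
    abort(sprintf(
      "KB header does not match schema; missing column(s): %s",
      paste(missing, collapse = ", ")
    ))
  }
  ontology <- NULL
  if (!is.null(ontology_path)) {
    ontology <- readr::read_tsv(
      ontology_path, col_types = readr::cols(.default = "c")
    )
  }
  raw <- raw |> mutate(driver = tolower(.data$driver) %in% c("true", "t", "1", "yes"))
  biomarker_kb(raw, ontology)
}

#' Write a knowledge base back to its tab-separated form
#'
#' @param kb A `biomarker_kb`.
#' @param path Output TSV path.
#' @param ontology_path Optional path for the ontology table.
#' @return `path`, invisibly.
#' @export
write_kb <- function(kb, path, ontology_path = NULL) {
  stopifnot(inherits(kb, "biomarker_kb"))
  flat <- kb$rules |>
    mutate(
      tumour_types = purrr::map_chr(.data$tumour_types, paste, collapse = ";"),
      evidence = as.character(.data$evidence),
      fusion_partner = if_else(is.na(.data$fusion_partner), "", .data$fusion_partner),
      variant_pattern = if_else(is.na(.data$variant_pattern), "", .data$variant_pattern),
      driver = if_else(.data$driver, "true", "false")
    )
  readr::write_tsv(flat, path)
  if (!is.null(ontology_path)) readr::write_tsv(kb$ontology, ontology_path)
  invisible(path)
}

# Resolve a dataset cancer label to (kb_label, parent).  Labels already in
# KB vocabulary pass through; unknown labels abort so an unmapped cohort is
# never silently counted as having no on-label options.
resolve_tumour <- function(kb, tumour, strict = TRUE) {
  ont <- kb$ontology
  hit <- which(ont$dataset_label == tumour)
  if (length(hit) >= 1) {
    return(list(label = ont$kb_label[hit[1]], parent = ont$parent[hit[1]]))
  }
  hit <- which(ont$kb_label == tumour)
  if (length(hit) >= 1) {
    return(list(label = tumour, parent = ont$parent[hit[1]]))
  }
  used <- unique(unlist(kb$rules$tumour_types))
  if (!strict || tumour %in% used) {
    return(list(label = tumour, parent = NA_character_))
  }
  abort(sprintf("unknown tumour label '%s' (not in ontology or KB rules)", tumour))
}

# Does a rule's tumour-type set cover the (resolved) sample tumour?
rule_covers_tumour <- function(tumour_sets, resolved) {
  targets <- c("any", resolved$label)
  if (!is.na(resolved$parent)) targets <- c(targets, resolved$parent)
  vapply(tumour_sets, function(s) any(s %in% targets), logical(1))
}

# Biomarker identity for counting: (gene, alteration_class, variant_pattern).
distinct_biomarkers <- function(kb, rules = kb$rules) {
  rules |>
    mutate(variant_pattern = if_else(
      is.na(.data$variant_pattern), "", .data$variant_pattern
    )) |>
    distinct(.data$gene, .data$alteration_class, .data$variant_pattern)
}

biomarker_key <- function(rules) {
  paste(rules$gene, rules$alteration_class,
        if_else(is.na(rules$variant_pattern), "", rules$variant_pattern),
        sep = "|")
}

#' On-label and off-label biomarker counts for a tumour type
#'
#' Counts distinct biomarkers (a biomarker is a `(gene, alteration class,
#' variant pattern)` triple, so multiple per-drug rows are not double
#' counted) in one clinical-evidence group. A biomarker is *on-label* for a
#' tumour when at least one of its rules in the group covers that tumour
#' type (directly, via the ontology parent, or tumour-agnostically);
#' biomarkers whose group-level rules exist only for other tumour types are
#' *off-label* repurposing candidates. Each biomarker is counted in exactly
#' one of the two.
#'
#' @param kb A `biomarker_kb`.
#' @param tumour A dataset or KB tumour label, resolvable in the ontology.
#' @param group `"approved"` (FDA/NCCN guideline tiers) or `"trials"`
#'   (late/early clinical-trial tiers).
#' @return A tibble with one row: `tumour`, `group`, `on_label_biomarkers`,
#'   `off_label_biomarkers`.
#' @export
repurposing_expansion <- function(kb, tumour, group = c("approved", "trials")) {
  stopifnot(inherits(kb, "biomarker_kb"))
  group <- match.arg(group)
  resolved <- resolve_tumour(kb, tumour)

  in_group <- kb$rules |> filter(tier_group(.data$evidence) == group)
  if (nrow(in_group) == 0) {
    return(tibble(tumour = tumour, group = group,
                  on_label_biomarkers = 0L, off_label_biomarkers = 0L))
  }
  covers <- rule_covers_tumour(in_group$tumour_types, resolved)
  key <- biomarker_key(in_group)
  on_keys <- unique(key[covers])
  off_keys <- setdiff(unique(key), on_keys)
  tibble(
    tumour = tumour, group = group,
    on_label_biomarkers = length(on_keys),
    off_label_biomarkers = length(off_keys)
  )
}

#' Shared-biomarker counts between tumour types
#'
#' For one clinical-evidence group, counts for each pair of tumour types the
#' biomarkers with rules covering both: the raw material for cross-cancer
#' drug repurposing. Tumour-agnostic (`"any"`) rules cover every type.
#'
#' @param kb A `biomarker_kb`.
#' @param group `"approved"` or `"trials"`.
#' @param tumours Optional character vector of tumour labels; defaults to
#'   all KB labels in the ontology, or the labels used by the rules.
#' @return A symmetric integer matrix; the diagonal holds each type's own
#'   biomarker count.
#' @export
shared_biomarker_matrix <- function(kb, group = c("approved", "trials"),
                                    tumours = NULL) {
  stopifnot(inherits(kb, "biomarker_kb"))
  group <- match.arg(group)
  if (is.null(tumours)) {
    tumours <- unique(c(
      kb$ontology$kb_label,
      setdiff(unlist(kb$rules$tumour_types), "any")
    ))
  }
  if (length(tumours) == 0) abort("no tumour types in KB")

  in_group <- kb$rules |> filter(tier_group(.data$evidence) == group)
  key <- biomarker_key(in_group)
  sets <- lapply(tumours, function(t) {
    resolved <- resolve_tumour(kb, t, strict = FALSE)
    unique(key[rule_covers_tumour(in_group$tumour_types, resolved)])
  })
  n <- length(tumours)
  m <- matrix(0L, n, n, dimnames = list(tumours, tumours))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      m[i, j] <- length(intersect(sets[[i]], sets[[j]]))
    }
  }
  m
}
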