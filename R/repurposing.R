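#' Assign repurposing categories to biomarker matches
#'
#' Each match is placed in one of five categories determined solely by the
#' rule's evidence group and whether its tumour-type set covers the
#' sample's tumour: `approved_on_label`, `approved_off_label`
#' (an approved drug from another indication — a repurposing candidate),
#' `trials_on_label`, `trials_off_label`, or `other_evidence` for
#' case-report and pre-clinical rules, which never enter headline counts.
#' Tumour-agnostic rules (`"any"`, or a parent label such as
#' `"solid_tumour"`) count as on-label.
#'
#' @param matches Match tibble from [match_alteration()] or
#'   [sample_actionability()].
#' @param samples Tibble with columns `sample` and `tumour` (the dataset
#'   cancer label of each sample, resolvable in the KB ontology).
#' @param kb The `biomarker_kb` the matches came from.
#' @return The match tibble with added columns `tumour`, `evidence_group`,
#'   `label_scope` (`on_label`/`off_label`, `NA` for `other_evidence`) and
#'   `category`.
#' @export
classify_matches <- function(matches, samples, kb) {
  stopifnot(inherits(kb, "biomarker_kb"))
  assert_cols(samples, c("sample", "tumour"), "sample table")
  assert_cols(matches, c("sample", "rule_id", "evidence"), "match table")

  matches <- matches |>
    left_join(samples[, c("sample", "tumour")], by = "sample")
  if (nrow(matches) == 0) {
    return(matches |> mutate(evidence_group = character(0),
                             label_scope = character(0),
                             category = character(0)))
  }
  if (anyNA(matches$tumour)) {
    abort("some matched samples have no tumour label in `samples`")
  }
  resolved <- lapply(
    setNames(unique(matches$tumour), unique(matches$tumour)),
    function(t) resolve_tumour(kb, t)
  )
  rule_sets <- setNames(kb$rules$tumour_types, kb$rules$rule_id)

  matches |>
    mutate(
      evidence_group = tier_group(.data$evidence),
      on_label = purrr::map2_lgl(
        .data$rule_id, .data$tumour,
        function(rid, t) rule_covers_tumour(rule_sets[rid], resolved[[t]])
      ),
      label_scope = dplyr::case_when(
        .data$evidence_group == "other" ~ NA_character_,
        .data$on_label ~ "on_label",
        TRUE ~ "off_label"
      ),
      category = dplyr::case_when(
        .data$evidence_group == "other" ~ "other_evidence",
        TRUE ~ paste(.data$evidence_group, .data$label_scope, sep = "_")
      )
    ) |>
    select(-"on_label")
}

#' Patient-level repurposing percentages for cohorts
#'
#' Tabulates, per cohort, evidence group and association, the percentage of
#' patients with at least one on-label call and the percentage with
#' off-label options only. Counting is patient-level and *additive*:
#' a patient with both on- and off-label calls of a group appears only in
#' the on-label bar, so the two percentages sum to the percentage of
#' patients with any call of that group. Denominators are always the full
#' cohort size. Case-report/pre-clinical (`other_evidence`) calls are
#' reported as their own rows, never inside the headline groups. For
#' sensitivity rows, `n_with_resistance` flags how many of the counted
#' patients also carry a resistance call of the same evidence group
#' (co-occurring resistance is reported, not used as a veto).
#'
#' @param calls Classified calls from [classify_matches()].
#' @param samples Tibble with columns `sample` and `cohort`; every sample,
#'   with or without calls, must appear (it sets the denominator).
#' @param per_match Diagnostic mode: count calls instead of patients
#'   (percentages are then omitted).
#' @return A tibble of class `cohort_summary` with columns `cohort`,
#'   `evidence_group`, `association`, `label_scope`, `n_patients`,
#'   `denominator`, `pct`, `n_with_resistance`.
#' @export
summarize_cohort <- function(calls, samples, per_match = FALSE) {
  assert_cols(samples, c("sample", "cohort"), "sample table")
  sizes <- samples |> dplyr::count(.data$cohort, name = "denominator")
  if (nrow(sizes) == 0 || any(sizes$denominator == 0)) {
    abort("empty cohort")
  }
  calls <- calls |>
    left_join(samples[, c("sample", "cohort")], by = "sample")

  grid <- tidyr::expand_grid(
    cohort = sizes$cohort,
    evidence_group = c("approved", "trials"),
    association = c("sensitivity", "resistance"),
    label_scope = c("on_label", "off_label")
  )

  if (per_match) {
    counts <- calls |>
      filter(.data$evidence_group %in% c("approved", "trials")) |>
      dplyr::count(.data$cohort, .data$evidence_group, .data$association,
                   .data$label_scope, name = "n_calls")
    out <- grid |>
      left_join(counts, by = c("cohort", "evidence_group", "association",
                               "label_scope")) |>
      mutate(n_calls = dplyr::coalesce(.data$n_calls, 0L)) |>
      left_join(sizes, by = "cohort")
    return(structure(out, class = c("cohort_summary", class(out))))
  }

  headline <- calls |>
    filter(.data$evidence_group %in% c("approved", "trials"))
  # patient-level: which (sample, group, association) cells have on-label /
  # any calls
  cell <- headline |>
    group_by(.data$cohort, .data$sample, .data$evidence_group,
             .data$association) |>
    summarise(
      has_on = any(.data$label_scope == "on_label"),
      has_off = any(.data$label_scope == "off_label"),
      .groups = "drop"
    ) |>
    mutate(scope = if_else(.data$has_on, "on_label", "off_label"))

  # co-occurring resistance per (sample, group)
  res_samples <- headline |>
    filter(.data$association == "resistance") |>
    distinct(.data$sample, .data$evidence_group) |>
    mutate(co_resist = TRUE)

  counts <- cell |>
    left_join(res_samples, by = c("sample", "evidence_group")) |>
    group_by(.data$cohort, .data$evidence_group, .data$association,
             label_scope = .data$scope) |>
    summarise(
      n_patients = dplyr::n_distinct(.data$sample),
      n_with_resistance = sum(!is.na(.data$co_resist)),
      .groups = "drop"
    )

  out <- grid |>
    left_join(counts, by = c("cohort", "evidence_group", "association",
                             "label_scope")) |>
    mutate(
      n_patients = dplyr::coalesce(.data$n_patients, 0L),
      n_with_resistance = if_else(
        .data$association == "sensitivity",
        dplyr::coalesce(.data$n_with_resistance, 0L), NA_integer_
      )
    ) |>
    left_join(sizes, by = "cohort") |>
    mutate(pct = 100 * .data$n_patients / .data$denominator) |>
    select("cohort", "evidence_group", "association", "label_scope",
           "n_patients", "denominator", "pct", "n_with_resistance")

  other <- calls |>
    filter(.data$evidence_group == "other") |>
    group_by(.data$cohort, .data$association) |>
    summarise(n_patients = dplyr::n_distinct(.data$sample), .groups = "drop") |>
    mutate(evidence_group = "other", label_scope = NA_character_,
           n_with_resistance = NA_integer_) |>
    left_join(sizes, by = "cohort") |>
    mutate(pct = 100 * .data$n_patients / .data$denominator) |>
    select("cohort", "evidence_group", "association", "label_scope",
           "n_patients", "denominator", "pct", "n_with_resistance")

  out <- bind_rows(out, other)
  structure(out, class = c("cohort_summary", class(out)))
}

#' Compare platforms on actionable-variant detection
#'
#' For each platform, re-runs the down-sample, match and classify stages
#' and reports the percentage of patients with at least one actionable
#' call, split by association and by evidence scope (approved drugs only
#' versus approved plus clinical trials). Matches on case-report and
#' pre-clinical evidence never count.
#'
#' @param alterations A list with `variants`, `cna`, `sv` tibbles covering
#'   all samples.
#' @param samples Tibble with `sample`, `tumour` and optionally `cohort`
#'   columns; all samples enter the denominator.
#' @param kb A `biomarker_kb`.
#' @param platforms A named list of [platform()] objects.
#' @param config A [matcher_config()].
#' @return A tibble: `platform`, `evidence`, (`approved` or
#'   `approved_plus_trials`), `association` (`any`/`sensitivity`/
#'   `resistance`), `n_patients`, `denominator`, `pct`.
#' @export
platform_comparison <- function(alterations, samples, kb, platforms,
                                config = matcher_config()) {
  assert_cols(samples, c("sample", "tumour"), "sample table")
  denom <- dplyr::n_distinct(samples$sample)
  purrr::map(platforms, function(p) {
    calls <- sample_actionability(alterations, kb, p, config) |>
      classify_matches(samples, kb) |>
      filter(.data$evidence_group %in% c("approved", "trials"))
    purrr::map(
      c(approved = "approved", approved_plus_trials = "both"),
      function(ev) {
        sel <- if (ev == "approved") {
          calls |> filter(.data$evidence_group == "approved")
        } else {
          calls
        }
        tibble(
          association = c("any", "sensitivity", "resistance"),
          n_patients = c(
            dplyr::n_distinct(sel$sample),
            dplyr::n_distinct(sel$sample[sel$association == "sensitivity"]),
            dplyr::n_distinct(sel$sample[sel$association == "resistance"])
          )
        )
      }
    ) |>
      bind_rows(.id = "evidence") |>
      mutate(platform = p$name)
  }) |>
    bind_rows() |>
    mutate(denominator = denom, pct = 100 * .data$n_patients / denom) |>
    select("platform", "evidence", "association", "n_patients",
           "denominator", "pct")
}
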