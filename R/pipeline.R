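#' Assemble a pipeline run configuration
#'
#' Collects everything one end-to-end run needs: the cohort profiles to
#' simulate (or the paths of pre-existing inputs), platform definitions,
#' matcher thresholds, TMB and MSI parameters and the single top-level
#' seed from which every stage derives its own. Referenced files are
#' checked at validation time, before any compute.
#'
#' @param profiles A list of [cohort_profile()]s.
#' @param out_dir Output directory for the report bundle.
#' @param kb A `biomarker_kb`, or `NULL` for the toy KB; alternatively
#'   `kb_path`/`ontology_path` to load one from disk.
#' @param kb_path,ontology_path Optional on-disk KB (see [load_kb()]).
#' @param platform_names Which platforms to run (default all four).
#' @param matcher A [matcher_config()].
#' @param tmb_filter `"all"` or `"nonsynonymous"`.
#' @param tmb_threshold High-TMB cutoff in mutations/Mb.
#' @param msi_alpha,msi_min_coverage,msi_threshold_pct MSI parameters
#'   (see [msi_score()]).
#' @param seed Top-level integer seed.
#' @return A `run_config` list.
#' @export
run_config <- function(profiles, out_dir,
                       kb = NULL, kb_path = NULL, ontology_path = NULL,
                       platform_names = c("WGS", "WES", "CPANEL", "HGP"),
                       matcher = matcher_config(),
                       tmb_filter = "all", tmb_threshold = 10,
                       msi_alpha = 0.001, msi_min_coverage = 20,
                       msi_threshold_pct = 3.5,
                       seed = 1) {
  if (inherits(profiles, "cohort_profile")) profiles <- list(profiles)
  stopifnot(all(vapply(profiles, inherits, logical(1), "cohort_profile")))
  for (p in c(kb_path, ontology_path)) {
    if (!is.null(p) && !file.exists(p)) {
      abort(sprintf("configured file does not exist: %s", p))
    }
  }
  if (!tmb_filter %in% c("all", "nonsynonymous")) {
    abort("tmb_filter must be 'all' or 'nonsynonymous'")
  }
  structure(
    list(
      profiles = profiles, out_dir = out_dir,
      kb = kb, kb_path = kb_path, ontology_path = ontology_path,
      platform_names = match.arg(platform_names,
                                 c("WGS", "WES", "CPANEL", "HGP"),
                                 several.ok = TRUE),
      matcher = matcher,
      tmb_filter = tmb_filter, tmb_threshold = tmb_threshold,
      msi_alpha = msi_alpha, msi_min_coverage = msi_min_coverage,
      msi_threshold_pct = msi_threshold_pct,
      seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Run the full pipeline and write the report bundle
#'
#' Orchestrates simulate, down-sample, match, classify, TMB, MSI and
#' summarize in order, writing per-stage TSVs plus a machine-readable JSON
#' report with a provenance block (config hash, seed, package version).
#' All randomness derives from the configuration's single seed, so
#' rerunning the same configuration reproduces the bundle byte for byte.
#' Platforms whose footprint covers no microsatellite locus are recorded
#' as non-evaluable for MSI rather than failing the run.
#'
#' @param config A [run_config()].
#' @param quiet Suppress stage progress messages.
#' @return Invisibly, a list with the in-memory results: `cohorts`,
#'   `calls`, `summary`, `platform_comparison`, `tmb`, `msi`, `report`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  say("stage simulate: building reference and %d cohort(s)", length(config$profiles))
  reference <- stage("reference", make_toy_reference(derive_seed(config$seed, "reference")))
  kb <- stage("kb", {
    if (!is.null(config$kb)) config$kb
    else if (!is.null(config$kb_path)) load_kb(config$kb_path, config$ontology_path)
    else make_toy_kb(derive_seed(config$seed, "kb"))
  })
  platforms <- toy_platforms(reference)[config$platform_names]

  cohorts <- stage("simulate", {
    purrr::map(config$profiles, function(p) {
      p$seed <- derive_seed(config$seed, paste0("sim_", p$cohort_name))
      simulate_cohort(p, reference, kb,
                      dir = file.path(config$out_dir, "inputs", p$cohort_name))
    })
  })
  alterations <- list(
    variants = bind_rows(purrr::map(cohorts, "variants")),
    cna = bind_rows(purrr::map(cohorts, "cna")),
    sv = bind_rows(purrr::map(cohorts, "sv"))
  )
  msi_sites <- bind_rows(purrr::map(cohorts, "msi_sites"))
  samples <- bind_rows(purrr::map(cohorts, "samples"))

  say("stage match/classify: %d samples x %d platforms",
      nrow(samples), length(platforms))
  calls <- stage("match", {
    purrr::map(platforms, function(p) {
      sample_actionability(alterations, kb, p, config$matcher) |>
        classify_matches(samples, kb)
    }) |> bind_rows()
  })
  readr::write_tsv(calls, file.path(config$out_dir, "matches.tsv"))

  say("stage summarize")
  summary <- stage("summarize", {
    calls |> filter(.data$platform == "WGS") |>
      summarize_cohort(samples)
  })
  readr::write_tsv(summary, file.path(config$out_dir, "cohort_summary.tsv"))

  plat_cmp <- stage("platform_comparison", {
    platform_comparison(alterations, samples, kb, platforms, config$matcher)
  })
  readr::write_tsv(plat_cmp, file.path(config$out_dir, "platform_comparison.tsv"))

  say("stage tmb")
  tmb <- stage("tmb", {
    purrr::map(platforms, function(p) {
      compute_tmb(alterations$variants, p, filter = config$tmb_filter,
                  samples = samples$sample)
    }) |> bind_rows()
  })
  readr::write_tsv(tmb, file.path(config$out_dir, "tmb.tsv"))

  say("stage msi")
  msi <- stage("msi", {
    purrr::map(platforms, function(p) {
      tryCatch(
        msi_score(msi_sites, p, alpha = config$msi_alpha,
                  min_coverage = config$msi_min_coverage,
                  threshold_pct = config$msi_threshold_pct),
        error = function(e) {
          say("  msi: %s", conditionMessage(e))
          NULL
        }
      )
    }) |> bind_rows()
  })
  readr::write_tsv(msi, file.path(config$out_dir, "msi.tsv"))

  report <- list(
    provenance = list(
      package = "actiondown",
      version = as.character(utils::packageVersion("actiondown")),
      seed = config$seed,
      config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
      platforms = unname(purrr::map(platforms, function(p) {
        list(name = p$name, footprint_mb = p$footprint_mb,
             detects_cna = p$detects_cna, detects_fusion = p$detects_fusion)
      }))
    ),
    cohorts = purrr::map(cohorts, function(cc) {
      list(cohort = cc$profile$cohort_name, n_samples = nrow(cc$samples),
           tumour = cc$profile$tumour)
    }),
    summary = summary,
    platform_comparison = plat_cmp,
    tmb_high_counts = tmb |>
      group_by(.data$platform) |>
      summarise(n_high = sum(.data$tmb > config$tmb_threshold), .groups = "drop"),
    msi_counts = if (nrow(msi) > 0) {
      msi |> dplyr::count(.data$platform, .data$classification)
    } else {
      tibble(platform = character(0), classification = character(0), n = integer(0))
    }
  )
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("report bundle written to %s", config$out_dir)
  invisible(list(
    reference = reference, kb = kb, cohorts = cohorts, calls = calls,
    summary = summary, platform_comparison = plat_cmp, tmb = tmb, msi = msi,
    report = report
  ))
}
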