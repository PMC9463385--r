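#' Tumour mutation burden per sample
#'
#' TMB is the somatic SNV/indel count divided by the platform's fixed
#' megabase denominator: 3000 Mb for whole-genome counts and the printed
#' footprint size for the restricted assays (37.105146, 2.628876 and
#' 0.016951 Mb for the built-in WES, comprehensive panel and hotspot
#' panel). The denominator is a platform constant, never recomputed from
#' the region file; both the raw count and the quotient are reported so a
#' different denominator convention can be re-derived downstream.
#'
#' @param variants Variant tibble (see [read_variants()]).
#' @param platform A [platform()].
#' @param filter `"all"` (default) or `"nonsynonymous"`, which keeps only
#'   protein-altering mutations via [is_nonsynonymous()] before counting.
#' @param samples Optional character vector of sample ids defining the
#'   reporting universe, so samples with zero retained mutations still get
#'   a row. Defaults to the samples present in `variants`.
#' @param already_filtered Set `TRUE` when `variants` are already
#'   restricted to the platform footprint; by default the region filter is
#'   applied internally.
#' @return A tibble with columns `sample`, `platform`, `filter`,
#'   `mutation_count`, `denominator_mb`, `tmb`, where
#'   `tmb = mutation_count / denominator_mb` exactly.
#' @export
compute_tmb <- function(variants, platform,
                        filter = c("all", "nonsynonymous"),
                        samples = NULL, already_filtered = FALSE) {
  stopifnot(inherits(platform, "seq_platform"))
  filter <- match.arg(filter)
  if (platform$footprint_mb <= 0) abort("zero or negative TMB denominator")
  samples <- samples %||% unique(variants$sample)

  if (!already_filtered && !is.null(platform$regions)) {
    variants <- filter_variants(variants, platform$regions)
  }
  if (filter == "nonsynonymous" && nrow(variants) > 0) {
    variants <- variants[is_nonsynonymous(variants$consequence), ]
  }
  counts <- variants |> dplyr::count(.data$sample, name = "mutation_count")
  pname <- platform$name
  denom <- platform$footprint_mb
  tibble(sample = samples) |>
    left_join(counts, by = "sample") |>
    mutate(
      mutation_count = dplyr::coalesce(.data$mutation_count, 0L),
      platform = pname,
      filter = filter,
      denominator_mb = denom,
      tmb = .data$mutation_count / .data$denominator_mb
    ) |>
    select("sample", "platform", "filter", "mutation_count",
           "denominator_mb", "tmb")
}

#' Cross-platform TMB concordance
#'
#' Pairs per-sample TMB estimates from two platforms (or two filters),
#' computes their correlation and counts threshold-discordant samples:
#' those called high (strictly above the threshold, default 10
#' mutations/Mb) on one side but not the other. A hard clinical cutoff
#' turns small estimate differences near the threshold into different
#' treatment calls, which is what the discordance counts surface.
#'
#' @param tmb_a,tmb_b Tibbles from [compute_tmb()] sharing sample ids.
#' @param threshold High-TMB cutoff in mutations/Mb (strict `>`).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A `tmb_concordance` object; see [tidy.tmb_concordance()] and
#'   [glance.tmb_concordance()]. Fewer than 3 shared samples leaves the
#'   correlation `NA` with a warning; discordance is still reported.
#' @export
tmb_concordance <- function(tmb_a, tmb_b, threshold = 10,
                            method = c("pearson", "spearman")) {
  method <- match.arg(method)
  paired <- dplyr::inner_join(
    tmb_a |> select("sample", tmb_a = "tmb"),
    tmb_b |> select("sample", tmb_b = "tmb"),
    by = "sample"
  )
  if (nrow(paired) == 0) abort("no shared samples between the two TMB tables")
  r <- if (nrow(paired) < 3) {
    warn("fewer than 3 shared samples; correlation not computed")
    NA_real_
  } else {
    cor(paired$tmb_a, paired$tmb_b, method = method)
  }
  structure(
    list(
      label_a = paste0(tmb_a$platform[1], "/", tmb_a$filter[1]),
      label_b = paste0(tmb_b$platform[1], "/", tmb_b$filter[1]),
      n_samples = nrow(paired),
      correlation_r = r,
      method = method,
      threshold = threshold,
      discordant_a_high = sum(paired$tmb_a > threshold & paired$tmb_b <= threshold),
      discordant_b_high = sum(paired$tmb_b > threshold & paired$tmb_a <= threshold),
      data = paired
    ),
    class = "tmb_concordance"
  )
}

#' @export
print.tmb_concordance <- function(x, ...) {
  cat(sprintf(
    "<tmb_concordance> %s vs %s: R = %s (%s, n = %d); >%g mut/Mb discordant: %d | %d\n",
    x$label_a, x$label_b,
    ifelse(is.na(x$correlation_r), "NA", sprintf("%.3f", x$correlation_r)),
    x$method, x$n_samples, x$threshold,
    x$discordant_a_high, x$discordant_b_high
  ))
  invisible(x)
}

#' Tidy per-sample pairs from a TMB concordance
#' @param x A `tmb_concordance`.
#' @param ... Unused.
#' @return A tibble of paired per-sample estimates with discordance flags.
#' @export
tidy.tmb_concordance <- function(x, ...) {
  x$data |>
    mutate(
      high_a = .data$tmb_a > x$threshold,
      high_b = .data$tmb_b > x$threshold,
      discordant = xor(.data$high_a, .data$high_b)
    )
}

#' One-row summary of a TMB concordance
#' @param x A `tmb_concordance`.
#' @param ... Unused.
#' @return A one-row tibble with the correlation, sample size and
#'   threshold-discordance counts.
#' @export
glance.tmb_concordance <- function(x, ...) {
  tibble(
    comparison = paste(x$label_a, "vs", x$label_b),
    n_samples = x$n_samples,
    correlation_r = x$correlation_r,
    method = x$method,
    threshold = x$threshold,
    discordant_a_high = x$discordant_a_high,
    discordant_b_high = x$discordant_b_high
  )
}
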