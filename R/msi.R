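#' Read microsatellite site length distributions
#'
#' Tab-separated with header
#' `chrom start end unit sample normal_counts tumour_counts`; the two
#' count fields encode repeat-length read-count distributions as
#' `length:count` pairs joined by semicolons, e.g. `"14:30;15:140;16:30"`.
#' Locus coordinates are 0-based half-open.
#'
#' @param path Site TSV path.
#' @return A tibble of sites.
#' @export
read_msi_sites <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    chrom = "c", start = "i", end = "i", unit = "c", sample = "c",
    normal_counts = "c", tumour_counts = "c"
  ))
  assert_cols(df, msi_cols, "microsatellite site TSV")
  df
}

msi_cols <- c("chrom", "start", "end", "unit", "sample",
              "normal_counts", "tumour_counts")

#' @rdname read_msi_sites
#' @param sites A site tibble.
#' @export
write_msi_sites <- function(sites, path) {
  readr::write_tsv(sites[, msi_cols], path)
  invisible(path)
}

# "14:30;15:140" -> named numeric vector c(`14` = 30, `15` = 140)
parse_len_counts <- function(x) {
  pairs <- strsplit(x, ";", fixed = TRUE)[[1]]
  pairs <- pairs[nzchar(pairs)]
  if (length(pairs) == 0) return(setNames(numeric(0), character(0)))
  kv <- strsplit(pairs, ":", fixed = TRUE)
  setNames(
    vapply(kv, function(p) as.numeric(p[2]), numeric(1)),
    vapply(kv, function(p) p[1], character(1))
  )
}

encode_len_counts <- function(counts) {
  paste(sprintf("%s:%g", names(counts), counts), collapse = ";")
}

# Chi-square homogeneity statistic for a 2 x K length-count table, pooling
# sparse bins (expected count < 1 in either row) into their nearest
# neighbour by repeat length before computing the statistic.
msi_chisq <- function(normal, tumour) {
  lens <- sort(as.numeric(union(names(normal), names(tumour))))
  o1 <- unname(normal[as.character(lens)]); o1[is.na(o1)] <- 0
  o2 <- unname(tumour[as.character(lens)]); o2[is.na(o2)] <- 0
  keep <- (o1 + o2) > 0
  o1 <- o1[keep]; o2 <- o2[keep]; lens <- lens[keep]

  repeat {
    k <- length(lens)
    if (k <= 1) return(list(statistic = 0, df = 0))
    n <- sum(o1) + sum(o2)
    e1 <- sum(o1) * (o1 + o2) / n
    e2 <- sum(o2) * (o1 + o2) / n
    emin <- pmin(e1, e2)
    if (all(emin >= 1)) break
    j <- which.min(emin)
    # pool with the adjacent bin closest in repeat length
    nb <- if (j == 1) 2 else if (j == k) k - 1 else {
      if ((lens[j] - lens[j - 1]) <= (lens[j + 1] - lens[j])) j - 1 else j + 1
    }
    lo <- min(j, nb); hi <- max(j, nb)
    o1 <- c(o1[seq_len(lo - 1)], o1[lo] + o1[hi],
            if (hi < k) o1[(hi + 1):k])
    o2 <- c(o2[seq_len(lo - 1)], o2[lo] + o2[hi],
            if (hi < k) o2[(hi + 1):k])
    lens <- c(lens[seq_len(lo - 1)], lens[lo], if (hi < k) lens[(hi + 1):k])
  }
  n <- sum(o1) + sum(o2)
  e1 <- sum(o1) * (o1 + o2) / n
  e2 <- sum(o2) * (o1 + o2) / n
  stat <- sum((o1 - e1)^2 / e1) + sum((o2 - e2)^2 / e2)
  list(statistic = stat, df = length(lens) - 1)
}

#' Chi-square homogeneity statistic for one microsatellite site
#'
#' The statistic behind [site_unstable()], exposed so per-site evidence can
#' be inspected or tabulated: sparse bins are pooled as described there and
#' the usual 2 x K homogeneity statistic and its degrees of freedom are
#' returned.
#'
#' @inheritParams site_unstable
#' @return A list with elements `statistic` and `df` (0 when the pooled
#'   table collapses to a single bin, in which case the statistic is 0).
#' @examples
#' msi_site_statistic(c(`14` = 100, `15` = 100), c(`14` = 50, `15` = 150))
#' @export
msi_site_statistic <- function(normal_counts, tumour_counts) {
  if (is.character(normal_counts)) normal_counts <- parse_len_counts(normal_counts)
  if (is.character(tumour_counts)) tumour_counts <- parse_len_counts(tumour_counts)
  msi_chisq(normal_counts, tumour_counts)
}

#' Test one microsatellite site for instability
#'
#' Compares the tumour and normal repeat-length read-count distributions
#' with a chi-square homogeneity test. Bins whose expected count falls
#' below 1 in either sample are pooled into the neighbouring repeat length
#' first, so a single stray read cannot manufacture instability. The site
#' is unstable when the statistic exceeds the chi-square critical value at
#' `alpha`.
#'
#' @param normal_counts,tumour_counts Named numeric vectors
#'   (names = repeat length, values = read count) or their encoded string
#'   form `"14:30;15:140"`.
#' @param alpha Per-site significance level. The default 0.001 is
#'   deliberately conservative: the per-sample score aggregates a hundred
#'   or more sites and no multiplicity correction is applied per site, so
#'   the default plays the role of MSIsensor's FDR control (roughly a
#'   Bonferroni level for ~100 evaluable loci) and keeps the
#'   false-unstable site rate well below the MSI-H score threshold.
#' @param min_coverage Minimum total reads required in *each* sample
#'   (default 20); below it the site is non-evaluable and `NA` is
#'   returned.
#' @return `TRUE` (unstable), `FALSE` (stable) or `NA` (non-evaluable).
#' @examples
#' site_unstable(c(`15` = 200), c(`13` = 200))          # clear shift
#' site_unstable(c(`15` = 200), c(`15` = 200))          # identical
#' @export
site_unstable <- function(normal_counts, tumour_counts, alpha = 0.001,
                          min_coverage = 20) {
  if (is.character(normal_counts)) normal_counts <- parse_len_counts(normal_counts)
  if (is.character(tumour_counts)) tumour_counts <- parse_len_counts(tumour_counts)
  if (sum(normal_counts) < min_coverage || sum(tumour_counts) < min_coverage) {
    return(NA)
  }
  cs <- msi_chisq(normal_counts, tumour_counts)
  if (cs$df < 1) return(FALSE)
  cs$statistic > qchisq(1 - alpha, df = cs$df)
}

#' Score microsatellite instability per sample
#'
#' Restricts the site list to the platform footprint (any-overlap, like the
#' variant filter), tests each evaluable site with [site_unstable()] and
#' reports the percentage of unstable sites. Samples whose score exceeds
#' `threshold_pct` are classified MSI-high (`MSI_H`), the rest
#' microsatellite-stable (`MSS`). The 3.5% default follows the
#' MSIsensor convention for somatic sites; tiny panels routinely cover
#' zero microsatellite loci, which is an error naming the platform rather
#' than a silent zero.
#'
#' @param sites Site tibble (see [read_msi_sites()]), possibly spanning
#'   many samples.
#' @param platform A [platform()] or `NULL` for no restriction.
#' @param alpha,min_coverage Passed to [site_unstable()].
#' @param threshold_pct MSI-H classification threshold on the percentage
#'   scale (default 3.5; classification is strict `>`).
#' @return A tibble with columns `sample`, `platform`,
#'   `n_evaluable_sites`, `n_unstable_sites`, `msi_score` (percent),
#'   `classification`, `threshold_pct`.
#' @export
msi_score <- function(sites, platform = NULL, alpha = 0.001,
                      min_coverage = 20, threshold_pct = 3.5) {
  assert_cols(sites, msi_cols, "microsatellite site table")
  pname <- if (is.null(platform)) "WGS" else platform$name
  if (!is.null(platform) && !is.null(platform$regions)) {
    gr <- GenomicRanges::GRanges(
      sites$chrom,
      IRanges::IRanges(start = sites$start + 1L, end = pmax(sites$end, sites$start + 1L))
    )
    sites <- sites[IRanges::overlapsAny(gr, regions_as_granges(platform$regions)), ]
  }
  if (nrow(sites) == 0) {
    abort(sprintf("no microsatellite loci fall within the %s footprint", pname))
  }
  per_site <- sites |>
    mutate(unstable = purrr::map2_lgl(
      .data$normal_counts, .data$tumour_counts,
      function(n, t) {
        u <- site_unstable(n, t, alpha = alpha, min_coverage = min_coverage)
        if (is.na(u)) NA else u
      }
    ))
  out <- per_site |>
    group_by(.data$sample) |>
    summarise(
      n_evaluable_sites = sum(!is.na(.data$unstable)),
      n_unstable_sites = sum(.data$unstable, na.rm = TRUE),
      .groups = "drop"
    )
  if (any(out$n_evaluable_sites == 0)) {
    abort(sprintf(
      "sample(s) with zero evaluable microsatellite sites on %s: %s",
      pname,
      paste(out$sample[out$n_evaluable_sites == 0], collapse = ", ")
    ))
  }
  out |>
    mutate(
      platform = pname,
      msi_score = 100 * .data$n_unstable_sites / .data$n_evaluable_sites,
      classification = if_else(.data$msi_score > threshold_pct, "MSI_H", "MSS"),
      threshold_pct = threshold_pct
    ) |>
    select("sample", "platform", "n_evaluable_sites", "n_unstable_sites",
           "msi_score", "classification", "threshold_pct")
}
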