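#' Build a region set from intervals
#'
#' A region set is a sorted, merged list of genomic intervals in the BED
#' convention (0-based half-open), the footprint of a capture kit or panel.
#' Overlapping and abutting intervals are merged, zero-length intervals are
#' dropped with a warning, and the total base count is recorded.
#'
#' @param intervals Data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return A `region_set`: a tibble of merged intervals with attribute
#'   `total_bases`.
#' @export
region_set <- function(intervals) {
  intervals <- as_tibble(intervals)
  assert_cols(intervals, c("chrom", "start", "end"), "interval table")
  bad <- which(intervals$start > intervals$end)
  if (length(bad) > 0) {
    abort(sprintf("interval start > end at line %d", bad[1]))
  }
  zero <- intervals$start == intervals$end
  if (any(zero)) {
    warn(sprintf("dropped %d zero-length interval(s)", sum(zero)))
    intervals <- intervals[!zero, ]
  }
  if (nrow(intervals) == 0) {
    out <- tibble(chrom = character(0), start = integer(0), end = integer(0))
  } else {
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      intervals$chrom,
      IRanges::IRanges(start = intervals$start + 1L, end = intervals$end)
    ))
    gr <- GenomicRanges::sort(gr)
    out <- tibble(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr)
    )
  }
  structure(out,
    total_bases = sum(out$end - out$start),
    class = c("region_set", class(out))
  )
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf(
    "<region_set> %d interval(s), %d bases on %d sequence(s)\n",
    nrow(x), total_bases(x), length(unique(x$chrom))
  ))
  invisible(x)
}

#' Total bases covered by a region set
#' @param regions A `region_set`.
#' @return Integer base count.
#' @export
total_bases <- function(regions) {
  attr(regions, "total_bases") %||% sum(regions$end - regions$start)
}

#' Load a platform footprint from a BED file
#'
#' Reads a 3+-column BED (0-based half-open), merges overlapping and
#' abutting intervals and records the footprint size.
#'
#' @param path BED file path.
#' @return A [region_set()].
#' @export
load_regions <- function(path) {
  if (!file.exists(path)) abort(sprintf("BED file not found: %s", path))
  df <- readr::read_tsv(
    path,
    col_names = FALSE, comment = "#",
    col_types = readr::cols(.default = "c")
  )
  if (ncol(df) < 3) abort("BED file needs at least 3 columns")
  region_set(tibble(
    chrom = df[[1]],
    start = as.integer(df[[2]]),
    end = as.integer(df[[3]])
  ))
}

#' Write a region set as BED3
#' @param regions A `region_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  readr::write_tsv(as_tibble(regions)[, c("chrom", "start", "end")], path,
                   col_names = FALSE)
  invisible(path)
}

regions_as_granges <- function(regions) {
  GenomicRanges::GRanges(
    regions$chrom,
    IRanges::IRanges(start = regions$start + 1L, end = regions$end)
  )
}

#' Sequencing-platform definition
#'
#' A platform couples a genomic footprint with a fixed megabase denominator
#' for TMB and a capability mask saying whether the assay can detect
#' copy-number alterations and gene fusions. The four built-in platforms
#' mirror common practice: whole-genome sequencing (`WGS`, unrestricted,
#' 3000 Mb denominator), whole-exome sequencing (`WES`, 37.105146 Mb, no
#' fusion detection), a comprehensive gene panel (`CPANEL`, 2.628876 Mb)
#' and a hotspot amplicon panel (`HGP`, 0.016951 Mb, neither CNAs nor
#' fusions). The denominator is a platform constant, deliberately not
#' recomputed from the region file: TMB conventions divide whole-genome
#' counts by 3000 Mb regardless of the true mappable genome size.
#'
#' @param name One of `"WGS"`, `"WES"`, `"CPANEL"`, `"HGP"`.
#' @param regions A [region_set()] footprint, or `NULL` for whole-genome.
#'   Required for every platform except `WGS`.
#' @param footprint_mb TMB denominator in Mb; defaults to the platform's
#'   standard constant above.
#' @param detects_cna,detects_fusion Capability overrides; default to the
#'   mask above.
#' @return A `seq_platform` object.
#' @export
platform <- function(name = c("WGS", "WES", "CPANEL", "HGP"),
                     regions = NULL, footprint_mb = NULL,
                     detects_cna = NULL, detects_fusion = NULL) {
  name <- match.arg(name)
  defaults <- list(
    WGS    = list(mb = 3000,      cna = TRUE,  fus = TRUE),
    WES    = list(mb = 37.105146, cna = TRUE,  fus = FALSE),
    CPANEL = list(mb = 2.628876,  cna = TRUE,  fus = TRUE),
    HGP    = list(mb = 0.016951,  cna = FALSE, fus = FALSE)
  )[[name]]
  if (name == "WGS") {
    regions <- NULL
  } else if (is.null(regions)) {
    abort(sprintf("platform %s requires a region set", name))
  }
  footprint_mb <- footprint_mb %||% defaults$mb
  if (footprint_mb <= 0) abort("footprint_mb must be > 0")
  structure(
    list(
      name = name,
      regions = regions,
      footprint_mb = footprint_mb,
      detects_cna = detects_cna %||% defaults$cna,
      detects_fusion = detects_fusion %||% defaults$fus
    ),
    class = "seq_platform"
  )
}

#' @export
print.seq_platform <- function(x, ...) {
  cat(sprintf(
    "<seq_platform> %s: %s, %.6f Mb denominator, CNA %s, fusions %s\n",
    x$name,
    if (is.null(x$regions)) "whole genome" else
      sprintf("%d bases in footprint", total_bases(x$regions)),
    x$footprint_mb,
    if (x$detects_cna) "yes" else "no",
    if (x$detects_fusion) "yes" else "no"
  ))
  invisible(x)
}

#' Filter variants to a platform footprint
#'
#' A variant is retained when its reference span (1-based `[pos,
#' pos + nchar(ref) - 1]`) overlaps at least one footprint base — the
#' any-overlap rule of `bedtools intersect`, so a deletion straddling a
#' region boundary is kept. Input order is preserved and the input is not
#' modified. Disjoint chromosome-name dialects (`"chr1"` vs `"1"`) abort
#' rather than silently retaining nothing; pass `rename_chroms` to
#' translate.
#'
#' @param variants Variant tibble (see [read_variants()]).
#' @param regions A [region_set()].
#' @param rename_chroms Optional named character vector mapping variant
#'   chromosome names to the region dialect, e.g. `c(chr1 = "1")`.
#' @return The retained subset of `variants`.
#' @export
filter_variants <- function(variants, regions, rename_chroms = NULL) {
  assert_cols(variants, c("chrom", "pos", "ref"), "variant table")
  if (nrow(variants) == 0 || nrow(regions) == 0) {
    return(variants[integer(0), ])
  }
  chroms <- variants$chrom
  if (!is.null(rename_chroms)) {
    hit <- chroms %in% names(rename_chroms)
    chroms[hit] <- unname(rename_chroms[chroms[hit]])
  }
  if (length(intersect(unique(chroms), unique(regions$chrom))) == 0) {
    abort(paste0(
      "no variant chromosome matches the region set ",
      sprintf("(variants use e.g. '%s', regions '%s'); ",
              chroms[1], regions$chrom[1]),
      "check the naming dialect or supply rename_chroms"
    ))
  }
  span <- variant_span(variants$pos, variants$ref)
  vgr <- GenomicRanges::GRanges(
    chroms, IRanges::IRanges(start = span$start + 1L, end = span$end)
  )
  keep <- IRanges::overlapsAny(vgr, regions_as_granges(regions))
  variants[keep, ]
}

filter_cna_segments <- function(cna, regions) {
  if (nrow(cna) == 0 || nrow(regions) == 0) return(cna[integer(0), ])
  gr <- GenomicRanges::GRanges(
    cna$chrom, IRanges::IRanges(start = cna$start, end = cna$end)
  )
  cna[IRanges::overlapsAny(gr, regions_as_granges(regions)), ]
}

#' Restrict a sample's alterations to a platform
#'
#' Emulates a smaller assay from whole-genome calls: SNVs/indels are
#' region-filtered, copy-number segments are dropped entirely when the
#' platform cannot call CNAs (otherwise retained when overlapping the
#' footprint), viable gene fusions are dropped when the platform cannot
#' detect fusions, and `WGS` returns the input unchanged.
#'
#' @param alterations A list with elements `variants`, `cna`, `sv`
#'   (any may be `NULL` or empty), as produced by [simulate_cohort()] or
#'   assembled from the readers.
#' @param platform A [platform()].
#' @param rename_chroms Passed on to [filter_variants()].
#' @return A list of the same shape, restricted to the platform.
#' @export
downsample_sample <- function(alterations, platform, rename_chroms = NULL) {
  stopifnot(inherits(platform, "seq_platform"))
  variants <- alterations$variants %||% empty_variants()
  cna <- alterations$cna %||% empty_cna()
  sv <- alterations$sv %||% empty_sv()

  if (platform$name == "WGS") {
    return(list(variants = variants, cna = cna, sv = sv))
  }
  variants <- filter_variants(variants, platform$regions, rename_chroms)
  cna <- if (!platform$detects_cna) {
    cna[integer(0), ]
  } else {
    filter_cna_segments(cna, platform$regions)
  }
  if (!platform$detects_fusion) {
    sv <- sv |> filter(.data$effect != "viable_fusion")
  }
  list(variants = variants, cna = cna, sv = sv)
}

empty_variants <- function() {
  tibble(sample = character(0), chrom = character(0), pos = integer(0),
         ref = character(0), alt = character(0), gene = character(0),
         consequence = character(0), protein_change = character(0))
}

empty_cna <- function() {
  tibble(sample = character(0), chrom = character(0), start = integer(0),
         end = integer(0), gene = character(0), copy_number = double(0))
}

empty_sv <- function() {
  tibble(sample = character(0), chrom1 = character(0), pos1 = integer(0),
         chrom2 = character(0), pos2 = integer(0), genes = character(0),
         effect = character(0), fusion5 = character(0), fusion3 = character(0))
}
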