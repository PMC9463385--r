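test_that("region sets merge abutting and overlapping intervals", {
  rs <- region_set(tibble::tibble(chrom = "c1", start = c(0L, 10L), end = c(10L, 20L)))
  expect_equal(nrow(rs), 1)
  expect_equal(rs$start, 0L)
  expect_equal(rs$end, 20L)
  expect_equal(total_bases(rs), 20L)

  rs2 <- region_set(tibble::tibble(chrom = "c1", start = c(0L, 10L), end = c(15L, 20L)))
  expect_equal(total_bases(rs2), 20L)

  expect_warning(
    rs3 <- region_set(tibble::tibble(chrom = "c1", start = c(5L, 7L), end = c(5L, 9L))),
    "zero-length"
  )
  expect_equal(total_bases(rs3), 2L)
})

test_that("BED loading reports bad lines and computes totals against a position scan", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("c1\t10\t20", "c1\t30\t25"), bed)
  expect_error(load_regions(bed), "line 2")

  set.seed(11)
  for (i in 1:10) {
    intervals <- random_intervals(sample(3:15, 1))
    rs <- region_set(intervals)
    # brute-force membership count over the toy genome
    expected <- 0L
    for (ch in unique(intervals$chrom)) {
      covered <- logical(10000)
      sub <- intervals[intervals$chrom == ch, ]
      for (j in seq_len(nrow(sub))) {
        if (sub$end[j] > sub$start[j]) {
          covered[(sub$start[j] + 1):sub$end[j]] <- TRUE
        }
      }
      expected <- expected + sum(covered)
    }
    expect_equal(total_bases(rs), expected)
  }
})

test_that("variant filtering follows the any-overlap rule at 0/1-based boundaries", {
  rs <- region_set(tibble::tibble(chrom = "c1", start = 10L, end = 20L))
  inside <- tibble::tibble(
    sample = "s", chrom = "c1", pos = 11L, ref = "A", alt = "T",
    gene = NA_character_, consequence = NA_character_,
    protein_change = NA_character_
  )
  expect_equal(nrow(filter_variants(inside, rs)), 1)
  # 1-based 10 is the last base before the region starts at 0-based 10
  expect_equal(nrow(filter_variants(dplyr::mutate(inside, pos = 10L), rs)), 0)
  expect_equal(nrow(filter_variants(dplyr::mutate(inside, pos = 20L), rs)), 1)
  expect_equal(nrow(filter_variants(dplyr::mutate(inside, pos = 21L), rs)), 0)
  # a 5 bp deletion straddling the region start is retained
  straddle <- dplyr::mutate(inside, pos = 8L, ref = "AAAAA")
  expect_equal(nrow(filter_variants(straddle, rs)), 1)
  # empty region set retains nothing
  empty_rs <- region_set(tibble::tibble(chrom = character(0),
                                        start = integer(0), end = integer(0)))
  expect_equal(nrow(filter_variants(inside, empty_rs)), 0)
})

test_that("filtering agrees with the per-position membership oracle", {
  set.seed(7)
  for (i in 1:25) {
    intervals <- random_intervals(sample(2:12, 1))
    variants <- random_variant_table(sample(5:40, 1))
    rs <- region_set(intervals)
    got <- filter_variants(variants, rs)
    keep <- oracle_filter_variants(variants, intervals)
    expect_equal(as.data.frame(got), as.data.frame(variants[keep, ]))
    # idempotence
    expect_equal(as.data.frame(filter_variants(got, rs)), as.data.frame(got))
  }
})

test_that("nested footprints retain nested variant sets", {
  set.seed(8)
  big <- random_intervals(12)
  small_idx <- sample(nrow(big), 5)
  rs_big <- region_set(big)
  rs_small <- region_set(big[small_idx, ])
  v <- random_variant_table(60)
  kept_small <- filter_variants(v, rs_small)
  kept_big <- filter_variants(v, rs_big)
  key <- function(d) paste(d$chrom, d$pos, d$ref)
  expect_true(all(key(kept_small) %in% key(kept_big)))
})

test_that("chromosome dialect mismatches abort unless renamed", {
  rs <- region_set(tibble::tibble(chrom = "1", start = 0L, end = 100L))
  v <- tibble::tibble(
    sample = "s", chrom = "chr1", pos = 50L, ref = "A", alt = "T",
    gene = NA_character_, consequence = NA_character_,
    protein_change = NA_character_
  )
  expect_error(filter_variants(v, rs), "dialect|rename_chroms")
  expect_equal(nrow(filter_variants(v, rs, rename_chroms = c(chr1 = "1"))), 1)
})

test_that("platform constructors carry the printed denominators and masks", {
  wgs <- platform("WGS")
  expect_equal(wgs$footprint_mb, 3000)
  expect_true(wgs$detects_cna && wgs$detects_fusion)
  rs <- region_set(tibble::tibble(chrom = "c1", start = 0L, end = 100L))
  expect_equal(platform("WES", rs)$footprint_mb, 37.105146)
  expect_false(platform("WES", rs)$detects_fusion)
  expect_equal(platform("CPANEL", rs)$footprint_mb, 2.628876)
  expect_true(platform("CPANEL", rs)$detects_fusion)
  hgp <- platform("HGP", rs)
  expect_equal(hgp$footprint_mb, 0.016951)
  expect_false(hgp$detects_cna)
  expect_false(hgp$detects_fusion)
  expect_error(platform("WES"), "region set")
})

test_that("platform capability masks drive down-sampling", {
  ref <- make_toy_reference(1)
  plats <- toy_platforms(ref)
  erbb2 <- ref$genes[ref$genes$gene == "ERBB2", ]
  ntrk1 <- ref$genes[ref$genes$gene == "NTRK1", ]
  g1 <- ref$genes[1, ]
  alts <- list(
    variants = tibble::tibble(
      sample = "s", chrom = "chr1", pos = g1$hotspot_pos,
      ref = "A", alt = "T", gene = g1$gene,
      consequence = "missense_variant", protein_change = "V600E"
    ),
    cna = tibble::tibble(sample = "s", chrom = erbb2$chrom,
                         start = erbb2$start + 1L, end = erbb2$end,
                         gene = "ERBB2", copy_number = 8),
    sv = tibble::tibble(sample = "s", chrom1 = ntrk1$chrom, pos1 = ntrk1$start,
                        chrom2 = "chr2", pos2 = 999L, genes = "NTRK1;BG02",
                        effect = "viable_fusion", fusion5 = "NTRK1",
                        fusion3 = "BG02")
  )
  # ERBB2 amplification invisible to the hotspot panel
  expect_equal(nrow(downsample_sample(alts, plats$HGP)$cna), 0)
  # fusion invisible to WES but retained by the comprehensive panel
  expect_equal(nrow(downsample_sample(alts, plats$WES)$sv), 0)
  expect_equal(nrow(downsample_sample(alts, plats$CPANEL)$sv), 1)
  # whole genome is the identity platform
  wgs_out <- downsample_sample(alts, plats$WGS)
  expect_equal(wgs_out$variants, alts$variants)
  expect_equal(wgs_out$cna, alts$cna)
  expect_equal(wgs_out$sv, alts$sv)
})
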