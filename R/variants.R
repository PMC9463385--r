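#' Read somatic SNV/indel calls into the normalized variant table
#'
#' Accepts either a VCF 4.x file whose `ANN` INFO field carries
#' `gene|consequence|protein_change` annotations (one entry per ALT allele,
#' comma-separated), or the package's annotated-TSV dialect with header
#' `sample chrom pos ref alt gene consequence protein_change`. Multi-allelic
#' VCF rows are decomposed into one record per ALT allele; coordinates stay
#' 1-based throughout. An annotation that cannot be parsed, or a consequence
#' term outside the controlled vocabulary, yields `NA` with a warning while
#' the record itself is retained.
#'
#' @param path Path to a `.vcf` or `.tsv` file.
#' @param sample Sample identifier; defaults to the VCF's `##SAMPLE` meta
#'   line or the file basename. Ignored for TSV input, which carries its own
#'   `sample` column.
#' @return A tibble with columns `sample`, `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `gene`, `consequence`, `protein_change`.
#' @export
read_variants <- function(path, sample = NULL) {
  if (!file.exists(path)) abort(sprintf("variant file not found: %s", path))
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    read_variants_vcf(path, sample)
  } else {
    read_variants_tsv(path)
  }
}

variant_cols <- c("sample", "chrom", "pos", "ref", "alt",
                  "gene", "consequence", "protein_change")

read_variants_tsv <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    sample = "c", chrom = "c", pos = "i", ref = "c", alt = "c",
    gene = "c", consequence = "c", protein_change = "c"
  ))
  assert_cols(df, variant_cols, "annotated variant TSV")
  validate_variants(df)
}

read_variants_vcf <- function(path, sample = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf, getINFO = TRUE)
  if (is.null(sample)) {
    meta <- grep("^##SAMPLE=", vcf@meta, value = TRUE)
    sample <- if (length(meta) > 0) {
      sub("^##SAMPLE=<ID=([^,>]+).*$", "\\1", meta[1])
    } else {
      sub("\\.vcf(\\.gz)?$", "", basename(path))
    }
  }
  if (is.null(fix) || nrow(fix) == 0) {
    return(tibble(
      sample = character(0), chrom = character(0), pos = integer(0),
      ref = character(0), alt = character(0), gene = character(0),
      consequence = character(0), protein_change = character(0)
    ))
  }
  fix <- as_tibble(fix)

  rows <- purrr::pmap(
    list(fix$CHROM, fix$POS, fix$REF, fix$ALT, fix$INFO),
    function(chrom, pos, ref, alt, info) {
      alts <- strsplit(alt, ",", fixed = TRUE)[[1]]
      ann <- stringr::str_match(info, "(?:^|;)ANN=([^;]*)")[, 2]
      anns <- if (!is.na(ann)) {
        strsplit(ann, ",", fixed = TRUE)[[1]]
      } else {
        character(0)
      }
      purrr::map(seq_along(alts), function(i) {
        a <- if (i <= length(anns)) anns[i] else NA_character_
        parts <- if (!is.na(a)) strsplit(a, "|", fixed = TRUE)[[1]] else character(0)
        tibble(
          chrom = chrom, pos = as.integer(pos), ref = ref, alt = alts[i],
          gene = if (length(parts) >= 1 && nzchar(parts[1])) parts[1] else NA_character_,
          consequence = if (length(parts) >= 2 && nzchar(parts[2])) parts[2] else NA_character_,
          protein_change = if (length(parts) >= 3 && nzchar(parts[3])) {
            sub("^p\\.", "", parts[3])
          } else {
            NA_character_
          }
        )
      }) |> bind_rows()
    }
  ) |> bind_rows()
  rows$sample <- sample
  validate_variants(rows[, variant_cols])
}

validate_variants <- function(df) {
  df <- as_tibble(df)
  if (nrow(df) == 0) return(df)
  if (any(df$pos < 1, na.rm = TRUE)) abort("variant pos must be >= 1")
  if (any(df$ref == df$alt, na.rm = TRUE)) abort("variant ref and alt must differ")
  bad <- !is.na(df$consequence) & !(df$consequence %in% CONSEQ_ALL)
  if (any(bad)) {
    warn(sprintf(
      "%d variant(s) carry a consequence outside the controlled vocabulary; set to NA (e.g. '%s')",
      sum(bad), df$consequence[which(bad)[1]]
    ))
    df$consequence[bad] <- NA_character_
  }
  df
}

#' Write variants to the annotated-TSV dialect
#'
#' Writing then re-reading with [read_variants()] is the identity on all
#' eight fields.
#'
#' @param variants A variant tibble as returned by [read_variants()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path) {
  assert_cols(variants, variant_cols, "variant table")
  readr::write_tsv(variants[, variant_cols], path)
  invisible(path)
}

#' Write variants for one sample as a minimal VCF 4.2
#'
#' Emits one row per variant with the package's `ANN` INFO annotation
#' (`gene|consequence|protein_change`) and a `##SAMPLE` meta line, the
#' dialect [read_variants()] consumes.
#'
#' @param variants Variant tibble for a single sample.
#' @param path Output `.vcf` path.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, path) {
  assert_cols(variants, variant_cols, "variant table")
  stopifnot(length(unique(variants$sample)) <= 1)
  sample_id <- if (nrow(variants) > 0) variants$sample[1] else "sample"
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##SAMPLE=<ID=%s>", sample_id),
    "##INFO=<ID=ANN,Number=A,Type=String,Description=\"gene|consequence|protein_change\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- if (nrow(variants) == 0) character(0) else {
    ann <- sprintf(
      "ANN=%s|%s|%s",
      if_else(is.na(variants$gene), "", variants$gene),
      if_else(is.na(variants$consequence), "", variants$consequence),
      if_else(is.na(variants$protein_change), "", paste0("p.", variants$protein_change))
    )
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
            variants$chrom, variants$pos, variants$ref, variants$alt, ann)
  }
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Is a consequence term protein-altering (non-synonymous)?
#'
#' Classifies controlled consequence terms into the protein-altering set
#' (missense, nonsense, frameshift, inframe indels, splice donor/acceptor,
#' start/stop-altering) versus everything else (synonymous, intronic,
#' intergenic, UTR, splice-region). The classification is a partition:
#' every controlled term maps to exactly one of the two outcomes.
#'
#' @param consequence Character vector of consequence terms, or a variant
#'   tibble with a `consequence` column.
#' @return Logical vector. Missing consequences are an error: the caller
#'   decides how unannotated records are handled.
#' @examples
#' is_nonsynonymous(c("missense_variant", "synonymous_variant"))
#' @export
is_nonsynonymous <- function(consequence) {
  if (is.data.frame(consequence)) consequence <- consequence$consequence
  if (anyNA(consequence)) {
    abort("consequence is missing for some variants; filter or annotate them first")
  }
  unknown <- setdiff(unique(consequence), CONSEQ_ALL)
  if (length(unknown) > 0) {
    abort(sprintf(
      "consequence term(s) outside the controlled vocabulary: %s",
      paste(unknown, collapse = ", ")
    ))
  }
  consequence %in% CONSEQ_PROTEIN_ALTERING
}

#' Read copy-number segments
#'
#' Tab-separated with header `sample chrom start end gene copy_number`;
#' `start`/`end` are a 1-based inclusive span and `copy_number` is total
#' copy number, uncorrected for ploidy (real-valued; integer callers are a
#' special case, not an assumption).
#'
#' @param path CNA TSV path.
#' @return A tibble of segments.
#' @export
read_cna <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    sample = "c", chrom = "c", start = "i", end = "i",
    gene = "c", copy_number = "d"
  ))
  assert_cols(df, c("sample", "chrom", "start", "end", "gene", "copy_number"),
              "CNA TSV")
  if (any(df$start > df$end)) abort("CNA segment start > end")
  if (any(df$copy_number < 0)) abort("negative copy_number")
  df
}

#' Read structural-variant / fusion calls
#'
#' Tab-separated with header
#' `sample chrom1 pos1 chrom2 pos2 genes effect fusion5 fusion3`; `genes`
#' is semicolon-joined, `effect` is one of `loss_of_function`,
#' `viable_fusion`, `intra_intron_fusion`, `other`, and the fusion columns
#' name the 5' and 3' partners for viable fusions.
#'
#' @param path SV TSV path.
#' @return A tibble of structural variants.
#' @export
read_sv <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    sample = "c", chrom1 = "c", pos1 = "i", chrom2 = "c", pos2 = "i",
    genes = "c", effect = "c", fusion5 = "c", fusion3 = "c"
  ))
  assert_cols(df, sv_cols, "SV TSV")
  bad <- !df$effect %in% c("loss_of_function", "viable_fusion",
                           "intra_intron_fusion", "other")
  if (any(bad)) {
    abort(sprintf("unknown SV effect: %s", paste(unique(df$effect[bad]), collapse = ", ")))
  }
  incomplete <- df$effect == "viable_fusion" &
    (is.na(df$fusion5) | is.na(df$fusion3))
  if (any(incomplete)) abort("viable_fusion entries must carry fusion5 and fusion3")
  df
}

sv_cols <- c("sample", "chrom1", "pos1", "chrom2", "pos2",
             "genes", "effect", "fusion5", "fusion3")

#' @rdname read_cna
#' @param cna A CNA tibble.
#' @export
write_cna <- function(cna, path) {
  readr::write_tsv(cna[, c("sample", "chrom", "start", "end", "gene", "copy_number")], path)
  invisible(path)
}

#' @rdname read_sv
#' @param sv An SV tibble.
#' @export
write_sv <- function(sv, path) {
  readr::write_tsv(sv[, sv_cols], path)
  invisible(path)
}
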