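#' Reference span of a variant in 0-based half-open coordinates
#'
#' VCF-style calls are 1-based with the position at the first REF base; BED
#' footprints are 0-based half-open. All conversion between the two systems
#' in this package happens here, in one place, so overlap semantics cannot
#' drift between modules.
#'
#' @param pos 1-based reference position (first REF base).
#' @param ref Reference allele string; its length sets the span width. A
#'   missing value is treated as a 1 bp span.
#' @return A tibble with columns `start` and `end` (0-based half-open).
#' @examples
#' variant_span(11, "A")      # SNV: [10, 11)
#' variant_span(100, "ACGTA") # 5 bp deletion span: [99, 104)
#' @export
variant_span <- function(pos, ref) {
  width <- ifelse(is.na(ref) | !nzchar(ref), 1L, nchar(ref))
  tibble(start = as.integer(pos) - 1L, end = as.integer(pos) - 1L + width)
}

# Derive a stage seed from the pipeline's top-level seed, keeping the result
# a valid 32-bit R integer.  All stochastic stages draw their seed here so a
# single --seed reproduces the whole run.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

# Split a semicolon-joined field into a character vector, dropping blanks.
split_semi <- function(x) {
  out <- strsplit(as.character(x), ";", fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}
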