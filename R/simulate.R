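#' Build the toy reference world
#'
#' Constructs a small reference genome (5 contigs of 2 Mb), a gene table
#' mixing actionable genes with background genes, three nested platform
#' footprints and a microsatellite locus list, so every pipeline stage can
#' run end to end without external data. Nesting is by construction: the
#' hotspot-panel windows sit inside the comprehensive-panel gene spans,
#' which sit inside the exome footprint — mirroring how real capture
#' designs relate — and the exact footprint sizes are recorded so toy-world
#' TMB denominators are exact.
#'
#' @param seed Integer seed (layout is deterministic; the seed is recorded
#'   and reserved for downstream stages).
#' @param dir Optional directory; when given, writes `genes.tsv`,
#'   `wes.bed`, `cpanel.bed`, `hgp.bed` and `msi_loci.bed` there.
#' @return A list with `genome` (contig tibble), `genome_mb`, `genes`,
#'   `regions` (named list of [region_set()]s for WES/CPANEL/HGP),
#'   `msi_loci` and `seed`.
#' @export
make_toy_reference <- function(seed = 1, dir = NULL) {
  contigs <- tibble(chrom = paste0("chr", 1:5), length = 2000000L)

  kb_genes <- c("BRAF", "KRAS", "ERBB2", "BRCA1", "NTRK1", "TSC2", "TP53",
                "KIT", "EGFR", "NRAS", "FGFR2", "MLL2", "NF1", "PTEN")
  bg_genes <- sprintf("BG%02d", 1:16)
  all_genes <- c(kb_genes, bg_genes)
  n <- length(all_genes)
  idx <- seq_len(n) - 1L
  genes <- tibble(
    gene = all_genes,
    chrom = paste0("chr", (idx %% 5L) + 1L),
    start = 100000L + (idx %/% 5L) * 300000L,
    end = 100000L + (idx %/% 5L) * 300000L + 10000L,
    hotspot_pos = 100000L + (idx %/% 5L) * 300000L + 5000L,  # 1-based
    # comprehensive panels mix actionable genes with genes lacking any
    # biomarker rule; hotspot panels tile a few recurrent positions
    in_cpanel = all_genes %in% c(kb_genes, sprintf("BG%02d", 1:4)),
    in_hgp = all_genes %in% c("BRAF", "KRAS", "EGFR", "NRAS", "KIT", "TP53",
                              "BG01", "BG02")
  )

  wes <- region_set(genes[, c("chrom", "start", "end")])
  cpanel <- region_set(genes[genes$in_cpanel, c("chrom", "start", "end")])
  # amplicon-scale windows (1 kb) tiled around each panel hotspot
  hgp <- region_set(tibble(
    chrom = genes$chrom[genes$in_hgp],
    start = genes$hotspot_pos[genes$in_hgp] - 501L,
    end = genes$hotspot_pos[genes$in_hgp] + 499L
  ))

  # 60 genic loci (inside the exome footprint) + 60 intergenic loci
  genic_idx <- rep(seq_len(n), length.out = 60)
  genic <- tibble(
    chrom = genes$chrom[genic_idx],
    start = genes$start[genic_idx] + 8000L + (seq_len(60) %/% n) * 60L,
    end = genes$start[genic_idx] + 8000L + (seq_len(60) %/% n) * 60L + 30L
  )
  inter <- tibble(
    chrom = paste0("chr", (seq_len(60) %% 5L) + 1L),
    start = 1800000L + (seq_len(60) %/% 5L) * 500L,
    end = 1800000L + (seq_len(60) %/% 5L) * 500L + 30L
  )
  msi_loci <- bind_rows(genic, inter) |>
    mutate(unit = "A", locus_id = sprintf("MS%03d", row_number())) |>
    arrange(.data$chrom, .data$start)

  ref <- list(
    genome = contigs,
    genome_mb = sum(contigs$length) / 1e6,
    genes = genes,
    regions = list(WES = wes, CPANEL = cpanel, HGP = hgp),
    msi_loci = msi_loci,
    seed = as.integer(seed)
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(genes, file.path(dir, "genes.tsv"))
    write_bed(wes, file.path(dir, "wes.bed"))
    write_bed(cpanel, file.path(dir, "cpanel.bed"))
    write_bed(hgp, file.path(dir, "hgp.bed"))
    readr::write_tsv(msi_loci[, c("chrom", "start", "end", "unit")],
                     file.path(dir, "msi_loci.bed"), col_names = FALSE)
  }
  ref
}

#' Platform set for the toy reference
#'
#' Builds the four standard platforms over the toy footprints with
#' denominators equal to the exact toy footprint sizes (whole-genome uses
#' the toy genome size), so sampling properties of toy-world TMB are exact.
#'
#' @param reference Output of [make_toy_reference()].
#' @return Named list of [platform()] objects (`WGS`, `WES`, `CPANEL`,
#'   `HGP`).
#' @export
toy_platforms <- function(reference) {
  list(
    WGS = platform("WGS", footprint_mb = reference$genome_mb),
    WES = platform("WES", regions = reference$regions$WES,
                   footprint_mb = total_bases(reference$regions$WES) / 1e6),
    CPANEL = platform("CPANEL", regions = reference$regions$CPANEL,
                      footprint_mb = total_bases(reference$regions$CPANEL) / 1e6),
    HGP = platform("HGP", regions = reference$regions$HGP,
                   footprint_mb = total_bases(reference$regions$HGP) / 1e6)
  )
}

#' Build the toy biomarker knowledge base
#'
#' A small knowledge base populated with one rule per recurring archetype:
#' hotspot sensitivity under FDA guidelines (BRAF V600E in cutaneous
#' melanoma), codon-wildcard and trials-tier rules, amplification
#' (ERBB2/trastuzumab), gene-level resistance (KRAS versus anti-EGFR
#' antibodies), loss-of-function sensitivity (BRCA1/PARP inhibition),
#' a tumour-agnostic fusion approval (NTRK1), off-label-only rules
#' (TSC2/everolimus in renal angiomyolipoma, KIT/imatinib in GIST),
#' a trials-only rule (TP53), and case-report/pre-clinical rules that must
#' stay out of headline counts.
#'
#' @param seed Integer seed, recorded for provenance (the KB itself is a
#'   fixed catalogue).
#' @return A `biomarker_kb`.
#' @export
make_toy_kb <- function(seed = 1) {
  rules <- tibble::tribble(
    ~rule_id, ~gene, ~alteration_class, ~variant_pattern, ~fusion_partner,
    ~tumour_types, ~drug, ~association, ~evidence, ~driver,
    "R001", "BRAF", "MUT", "V600E", "", "melanoma_cutaneous",
    "dabrafenib", "sensitivity", "FDA_GUIDELINES", TRUE,
    "R002", "BRAF", "MUT", "V600.", "", "melanoma_cutaneous;colorectal_adenocarcinoma",
    "vemurafenib+cetuximab", "sensitivity", "LATE_TRIALS", TRUE,
    "R003", "ERBB2", "AMP", "", "", "breast_adenocarcinoma;oesophageal_adenocarcinoma",
    "trastuzumab", "sensitivity", "FDA_GUIDELINES", TRUE,
    "R004", "KRAS", "MUT", "any", "", "colorectal_adenocarcinoma",
    "cetuximab", "resistance", "FDA_GUIDELINES", TRUE,
    "R005", "BRCA1", "MUT", "LOF", "", "ovarian_adenocarcinoma",
    "olaparib", "sensitivity", "FDA_GUIDELINES", TRUE,
    "R006", "NTRK1", "FUS", "", "any", "solid_tumour",
    "entrectinib", "sensitivity", "FDA_GUIDELINES", TRUE,
    "R007", "TSC2", "MUT", "any", "", "renal_angiomyolipoma",
    "everolimus", "sensitivity", "FDA_GUIDELINES", TRUE,
    "R008", "KIT", "MUT", "any", "", "gist",
    "imatinib", "sensitivity", "FDA_GUIDELINES", TRUE,
    "R009", "TP53", "MUT", "any", "", "ovarian_adenocarcinoma",
    "adavosertib", "sensitivity", "EARLY_TRIALS", TRUE,
    "R010", "MLL2", "MUT", "LOF", "", "melanoma_cutaneous",
    "tankyrase-inhibitor", "sensitivity", "PRE_CLINICAL", TRUE,
    "R011", "EGFR", "MUT", "L858R", "", "lung_adenocarcinoma",
    "gefitinib", "sensitivity", "FDA_GUIDELINES", TRUE,
    "R012", "NRAS", "MUT", "Q61.", "", "melanoma_cutaneous;melanoma_mucosal",
    "binimetinib", "resistance", "LATE_TRIALS", TRUE,
    "R013", "FGFR2", "FUS", "", "any", "cholangiocarcinoma;bladder_carcinoma",
    "pemigatinib", "sensitivity", "FDA_GUIDELINES", TRUE,
    "R014", "PTEN", "DEL", "", "", "breast_adenocarcinoma",
    "capivasertib", "sensitivity", "EARLY_TRIALS", TRUE,
    "R015", "KIT", "MUT", "D816V", "", "mastocytosis",
    "avapritinib", "sensitivity", "CASE_REPORT", TRUE
  )
  ontology <- tibble::tribble(
    ~dataset_label, ~kb_label, ~parent,
    "melanoma_like", "melanoma_cutaneous", "solid_tumour",
    "mucosal_melanoma_like", "melanoma_mucosal", "solid_tumour",
    "breast_like", "breast_adenocarcinoma", "solid_tumour",
    "familial_breast_like", "breast_adenocarcinoma", "solid_tumour",
    "ovarian_like", "ovarian_adenocarcinoma", "solid_tumour",
    "pdac_like", "pancreatic_adenocarcinoma", "solid_tumour",
    "pnet_like", "pnet", "solid_tumour",
    "oesophageal_like", "oesophageal_adenocarcinoma", "solid_tumour",
    "mesothelioma_like", "mesothelioma", "solid_tumour",
    "lung_like", "lung_adenocarcinoma", "solid_tumour",
    "colorectal_like", "colorectal_adenocarcinoma", "solid_tumour",
    "gist", "gist", "solid_tumour",
    "renal_angiomyolipoma", "renal_angiomyolipoma", "solid_tumour",
    "cholangiocarcinoma", "cholangiocarcinoma", "solid_tumour",
    "bladder_carcinoma", "bladder_carcinoma", "solid_tumour",
    "mastocytosis", "mastocytosis", "solid_tumour"
  )
  kb <- biomarker_kb(rules, ontology)
  kb$seed <- as.integer(seed)
  kb
}

#' Define a simulated cohort
#'
#' A cohort profile sets the study conditions for one simulated dataset:
#' the genome-wide passenger mutation rate (high for melanoma-like
#' cohorts, low for mesothelioma-like), prevalences of planted actionable
#' events, and the MSI-high fraction. Planted hotspot keys take the form
#' `"GENE:SPEC"` where `SPEC` is an exact protein change (`"V600E"`) or
#' `"LOF"`; fusion keys are `"GENE5:GENE3"`.
#'
#' @param cohort_name Cohort identifier.
#' @param n_samples Number of tumours to simulate.
#' @param mutation_rate_per_mb Expected passenger mutations per Mb
#'   (Poisson; default 2).
#' @param rate_dispersion Between-sample spread of the passenger rate: each
#'   sample's rate is the cohort rate times a mean-preserving lognormal
#'   factor with this `sdlog` (default 0.5, emulating the several-fold
#'   within-cohort TMB spread of real tumours; 0 gives a homogeneous
#'   Poisson cohort).
#' @param tumour Dataset tumour label for every sample (defaults to
#'   `cohort_name`); must resolve in the KB ontology when matches are
#'   classified.
#' @param hotspot_prevalences Named numeric vector of per-sample planting
#'   probabilities for SNV/indel events, e.g. `c("BRAF:V600E" = 0.3)`.
#' @param cna_events Tibble with columns `gene`, `prob`, `cn` for planted
#'   copy-number events.
#' @param fusion_events Named numeric vector, e.g. `c("NTRK1:BG01" = 0.02)`.
#' @param lof_sv_events Named numeric vector of genes receiving
#'   loss-of-function structural variants.
#' @param msi_h_fraction Probability a sample is MSI-high.
#' @param msi_unstable_fraction Fraction of loci shifted in an MSI-high
#'   tumour (default 0.3).
#' @param msi_read_depth Reads per microsatellite locus (default 200).
#' @param generate_msi Set `FALSE` to skip microsatellite read-count
#'   generation (useful for large mutation-burden-only simulations).
#' @param nonsyn_fraction Fraction of coding passengers that are
#'   protein-altering; default 2.5/3.5, a fixed toy-world convention (2.5
#'   non-synonymous per synonymous) chosen so the non-synonymous TMB
#'   filter has a designed, testable effect.
#' @param mutually_exclusive When `TRUE`, at most one hotspot event is
#'   planted per sample (prevalences then are exact designed category
#'   prevalences rather than independent Bernoulli rates).
#' @param seed Integer seed for the cohort.
#' @return A `cohort_profile` list.
#' @export
cohort_profile <- function(cohort_name, n_samples,
                           mutation_rate_per_mb = 2,
                           rate_dispersion = 0.5,
                           tumour = cohort_name,
                           hotspot_prevalences = numeric(0),
                           cna_events = NULL,
                           fusion_events = numeric(0),
                           lof_sv_events = numeric(0),
                           msi_h_fraction = 0,
                           msi_unstable_fraction = 0.3,
                           msi_read_depth = 200,
                           generate_msi = TRUE,
                           nonsyn_fraction = 2.5 / 3.5,
                           mutually_exclusive = FALSE,
                           seed = 1) {
  probs <- c(hotspot_prevalences, fusion_events, lof_sv_events,
             msi_h_fraction, msi_unstable_fraction, nonsyn_fraction)
  if (length(probs) > 0 && (any(probs < 0) || any(probs > 1))) {
    abort("all probabilities must lie in [0, 1]")
  }
  if (mutation_rate_per_mb <= 0) abort("mutation_rate_per_mb must be > 0")
  if (rate_dispersion < 0) abort("rate_dispersion must be >= 0")
  if (is.null(cna_events)) {
    cna_events <- tibble(gene = character(0), prob = double(0), cn = double(0))
  }
  if (mutually_exclusive && sum(hotspot_prevalences) > 1) {
    abort("mutually exclusive hotspot prevalences must sum to <= 1")
  }
  structure(
    list(
      cohort_name = cohort_name, n_samples = as.integer(n_samples),
      mutation_rate_per_mb = mutation_rate_per_mb,
      rate_dispersion = rate_dispersion, tumour = tumour,
      hotspot_prevalences = hotspot_prevalences,
      cna_events = as_tibble(cna_events),
      fusion_events = fusion_events,
      lof_sv_events = lof_sv_events,
      msi_h_fraction = msi_h_fraction,
      msi_unstable_fraction = msi_unstable_fraction,
      msi_read_depth = as.integer(msi_read_depth),
      generate_msi = isTRUE(generate_msi),
      nonsyn_fraction = nonsyn_fraction,
      mutually_exclusive = isTRUE(mutually_exclusive),
      seed = as.integer(seed)
    ),
    class = "cohort_profile"
  )
}

# Parse "GENE:SPEC" keys into a tibble(gene, spec, prob).
parse_event_keys <- function(x) {
  if (length(x) == 0) {
    return(tibble(gene = character(0), spec = character(0), prob = double(0)))
  }
  parts <- strsplit(names(x), ":", fixed = TRUE)
  tibble(
    gene = vapply(parts, `[`, character(1), 1),
    spec = vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_, character(1)),
    prob = unname(x)
  )
}

random_base <- function(n, exclude = NULL) {
  bases <- c("A", "C", "G", "T")
  out <- sample(bases, n, replace = TRUE)
  if (!is.null(exclude)) {
    clash <- out == exclude
    while (any(clash)) {
      out[clash] <- sample(bases, sum(clash), replace = TRUE)
      clash <- out == exclude
    }
  }
  out
}

#' Simulate a cohort with ground-truth labels
#'
#' Draws, per sample: a Poisson number of passenger mutations placed
#' uniformly on the toy genome, with the per-sample rate spread by
#' `rate_dispersion`; planted hotspot SNVs/indels, copy-number events and
#' fusions by Bernoulli draws at the designed prevalences; and
#' tumour/normal repeat-length read counts at every microsatellite locus,
#' with a designed fraction of loci shifted in MSI-high samples.
#' Passengers are non-actionable by construction: those landing inside a
#' gene that carries biomarker rules are forced synonymous (synonymous
#' variants never match), passengers in background genes are
#' protein-altering with probability `nonsyn_fraction`, and the rest are
#' intergenic. Everything is deterministic given the profile's seed.
#'
#' @param profile A [cohort_profile()].
#' @param reference A [make_toy_reference()] world.
#' @param kb The `biomarker_kb` the planted events refer to; planting a
#'   gene absent from the reference is an error.
#' @param dir Optional output directory: writes per-sample VCFs plus
#'   combined `cna.tsv`, `sv.tsv`, `msi_sites.tsv`, `samples.tsv` and
#'   `ground_truth.tsv`.
#' @return A list with tibbles `variants`, `cna`, `sv`, `msi_sites`,
#'   `samples` (`sample`, `cohort`, `tumour`), `ground_truth` (per-sample
#'   planted events, genome-wide mutation count, MSI class) and the
#'   `profile`.
#' @export
simulate_cohort <- function(profile, reference, kb, dir = NULL) {
  stopifnot(inherits(profile, "cohort_profile"))
  genes <- reference$genes
  hot <- parse_event_keys(profile$hotspot_prevalences)
  fus <- parse_event_keys(profile$fusion_events)
  lof <- parse_event_keys(profile$lof_sv_events)
  referenced <- c(hot$gene, fus$gene, fus$spec, lof$gene, profile$cna_events$gene)
  unknown <- setdiff(referenced, genes$gene)
  if (length(unknown) > 0) {
    abort(sprintf("profile references unknown gene(s): %s",
                  paste(unique(unknown), collapse = ", ")))
  }

  set.seed(derive_seed(profile$seed, paste0("cohort_", profile$cohort_name)))

  kb_gene_rows <- genes[genes$gene %in% unique(kb$rules$gene), ]
  ggr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end)
  )
  contigs <- reference$genome
  sample_ids <- sprintf("%s_%03d", profile$cohort_name,
                        seq_len(profile$n_samples))

  variants <- list(); cnas <- list(); svs <- list(); msis <- list()
  gt <- list()

  normal_probs <- c(`14` = 0.15, `15` = 0.70, `16` = 0.15)
  shifted_probs <- c(`12` = 0.20, `13` = 0.60, `14` = 0.20)

  for (s in sample_ids) {
    ## --- passengers ---------------------------------------------------
    # mean-preserving lognormal spread of the per-sample rate
    s_rate <- profile$mutation_rate_per_mb * if (profile$rate_dispersion > 0) {
      exp(stats::rnorm(1, -profile$rate_dispersion^2 / 2,
                       profile$rate_dispersion))
    } else {
      1
    }
    n_pass <- rpois(1, s_rate * reference$genome_mb)
    if (n_pass > 0) {
      chrom <- sample(contigs$chrom, n_pass, replace = TRUE,
                      prob = contigs$length)
      pos <- floor(runif(n_pass) * contigs$length[match(chrom, contigs$chrom)]) + 1L
      # gene / consequence by position; passengers landing inside a gene
      # carrying biomarker rules are forced synonymous so they can never
      # fire a rule and ground truth stays exact under uniform placement
      vgr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
      hit <- GenomicRanges::findOverlaps(vgr, ggr, select = "first")
      gene <- ifelse(is.na(hit), NA_character_, genes$gene[hit])
      coding <- !is.na(gene)
      in_kb_gene <- coding & gene %in% kb_gene_rows$gene
      nonsyn <- coding & !in_kb_gene &
        (runif(n_pass) < profile$nonsyn_fraction)
      consequence <- dplyr::case_when(
        nonsyn ~ "missense_variant",
        coding ~ "synonymous_variant",
        TRUE ~ "intergenic_variant"
      )
      codon <- ifelse(coding, pmax(1L, (pos - genes$start[hit]) %/% 3L), NA_integer_)
      ref <- random_base(n_pass)
      alt <- random_base(n_pass, exclude = NULL)
      clash <- alt == ref
      while (any(clash)) {
        alt[clash] <- random_base(sum(clash))
        clash <- alt == ref
      }
      pc <- ifelse(nonsyn, paste0("A", codon, "V"), NA_character_)
      pass <- tibble(
        sample = s, chrom = chrom, pos = as.integer(pos), ref = ref,
        alt = alt, gene = gene, consequence = consequence,
        protein_change = pc
      )
    } else {
      pass <- empty_variants()
    }

    ## --- planted hotspot events ---------------------------------------
    planted_hot <- character(0)
    if (nrow(hot) > 0) {
      if (profile$mutually_exclusive) {
        u <- runif(1)
        cum <- cumsum(hot$prob)
        pick <- which(u < cum)[1]
        planted_idx <- if (!is.na(pick)) pick else integer(0)
      } else {
        planted_idx <- which(runif(nrow(hot)) < hot$prob)
      }
      planted_hot <- paste0(hot$gene[planted_idx], ":", hot$spec[planted_idx])
      if (length(planted_idx) > 0) {
        g <- genes[match(hot$gene[planted_idx], genes$gene), ]
        spec <- hot$spec[planted_idx]
        is_lof <- spec == "LOF"
        pass <- bind_rows(pass, tibble(
          sample = s, chrom = g$chrom, pos = g$hotspot_pos,
          ref = ifelse(is_lof, "CA", "T"),
          alt = ifelse(is_lof, "C", "G"),
          gene = g$gene,
          consequence = ifelse(is_lof, "frameshift_variant", "missense_variant"),
          protein_change = ifelse(is_lof, paste0("K", 100 + seq_along(spec), "fs"), spec)
        ))
      }
    }

    ## --- CNAs ----------------------------------------------------------
    planted_cna <- character(0)
    cn_rows <- empty_cna()
    if (nrow(profile$cna_events) > 0) {
      drawn <- runif(nrow(profile$cna_events)) < profile$cna_events$prob
      if (any(drawn)) {
        ev <- profile$cna_events[drawn, ]
        g <- genes[match(ev$gene, genes$gene), ]
        cn_rows <- tibble(
          sample = s, chrom = g$chrom, start = g$start + 1L, end = g$end,
          gene = g$gene, copy_number = ev$cn
        )
        planted_cna <- sprintf("%s:CN%g", ev$gene, ev$cn)
      }
    }
    # neutral background segments (never actionable)
    bg <- genes[match(c("BG01", "BG05"), genes$gene), ]
    cn_rows <- bind_rows(cn_rows, tibble(
      sample = s, chrom = bg$chrom, start = bg$start + 1L, end = bg$end,
      gene = bg$gene, copy_number = 2
    ))

    ## --- SVs ------------------------------------------------------------
    planted_fus <- character(0)
    sv_rows <- empty_sv()
    if (nrow(fus) > 0) {
      drawn <- which(runif(nrow(fus)) < fus$prob)
      if (length(drawn) > 0) {
        g5 <- genes[match(fus$gene[drawn], genes$gene), ]
        g3 <- genes[match(fus$spec[drawn], genes$gene), ]
        sv_rows <- bind_rows(sv_rows, tibble(
          sample = s, chrom1 = g5$chrom, pos1 = g5$start + 500L,
          chrom2 = g3$chrom, pos2 = g3$start + 500L,
          genes = paste(g5$gene, g3$gene, sep = ";"),
          effect = "viable_fusion", fusion5 = g5$gene, fusion3 = g3$gene
        ))
        planted_fus <- paste0(fus$gene[drawn], ":", fus$spec[drawn])
      }
    }
    planted_lof <- character(0)
    if (nrow(lof) > 0) {
      drawn <- which(runif(nrow(lof)) < lof$prob)
      if (length(drawn) > 0) {
        g <- genes[match(lof$gene[drawn], genes$gene), ]
        sv_rows <- bind_rows(sv_rows, tibble(
          sample = s, chrom1 = g$chrom, pos1 = g$start + 200L,
          chrom2 = g$chrom, pos2 = g$end - 200L,
          genes = g$gene, effect = "loss_of_function",
          fusion5 = NA_character_, fusion3 = NA_character_
        ))
        planted_lof <- paste0(lof$gene[drawn], ":LOF_SV")
      }
    }

    ## --- MSI ------------------------------------------------------------
    is_msi_h <- runif(1) < profile$msi_h_fraction
    if (profile$generate_msi) {
      loci <- reference$msi_loci
      unstable_locus <- is_msi_h &
        (runif(nrow(loci)) < profile$msi_unstable_fraction)
      depth <- profile$msi_read_depth
      draw_counts <- function(probs) {
        k <- rmultinom(1, depth, probs)[, 1]
        setNames(as.numeric(k), names(probs))
      }
      msi_rows <- loci |>
        mutate(
          sample = s,
          normal_counts = purrr::map_chr(row_number(), function(i) {
            encode_len_counts(draw_counts(normal_probs))
          }),
          tumour_counts = purrr::map_chr(row_number(), function(i) {
            encode_len_counts(draw_counts(
              if (unstable_locus[i]) shifted_probs else normal_probs
            ))
          })
        ) |>
        select("chrom", "start", "end", "unit", "sample",
               "normal_counts", "tumour_counts")
    } else {
      msi_rows <- tibble(
        chrom = character(0), start = integer(0), end = integer(0),
        unit = character(0), sample = character(0),
        normal_counts = character(0), tumour_counts = character(0)
      )
    }

    variants[[s]] <- pass
    cnas[[s]] <- cn_rows
    svs[[s]] <- sv_rows
    msis[[s]] <- msi_rows
    gt[[s]] <- tibble(
      sample = s, cohort = profile$cohort_name, tumour = profile$tumour,
      true_rate_per_mb = s_rate,
      true_mutation_count = nrow(pass),
      msi_class = if (is_msi_h) "MSI_H" else "MSS",
      planted_hotspots = paste(planted_hot, collapse = ","),
      planted_cna = paste(planted_cna, collapse = ","),
      planted_fusions = paste(planted_fus, collapse = ","),
      planted_lof_sv = paste(planted_lof, collapse = ",")
    )
  }

  out <- list(
    variants = bind_rows(variants),
    cna = bind_rows(cnas),
    sv = bind_rows(svs),
    msi_sites = bind_rows(msis),
    samples = tibble(sample = sample_ids, cohort = profile$cohort_name,
                     tumour = profile$tumour),
    ground_truth = bind_rows(gt),
    profile = profile
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (s in sample_ids) {
      write_variants_vcf(out$variants[out$variants$sample == s, ],
                         file.path(dir, paste0(s, ".vcf")))
    }
    write_cna(out$cna, file.path(dir, "cna.tsv"))
    write_sv(out$sv, file.path(dir, "sv.tsv"))
    write_msi_sites(out$msi_sites, file.path(dir, "msi_sites.tsv"))
    readr::write_tsv(out$samples, file.path(dir, "samples.tsv"))
    readr::write_tsv(out$ground_truth, file.path(dir, "ground_truth.tsv"))
  }
  out
}
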