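# Fixture generators: everything tests and demos need, with no downloads.
# The base KB transcribes the printed worked examples (the CYP2C9*3 tag-SNP
# axiom and warfarin rule 9, plus the 58-gene panel list); synthetic padding
# markers use an obviously fake rsid namespace (rs99...) so they can never be
# mistaken for real dbSNP identifiers.

PANEL_GENES_58 <- c(
  "ABCB1", "ABCC2", "ABCG2", "ACE", "ADRB1", "ADRB2", "AHR", "ALOX5",
  "BRCA1", "COMT", "CYP1A1", "CYP1A2", "CYP2A6", "CYP2B6", "CYP2C19",
  "CYP2C8", "CYP2C9", "CYP2D6", "CYP2J2", "CYP3A4", "CYP3A5", "DPYD",
  "DRD2", "F5", "G6PD", "GSTM1", "GSTP1", "HLA-B*1502", "HLA-B*5701",
  "HMGCR", "IL28B", "KCNH2", "KCNJ11", "MTHFR", "NAT1", "NAT2", "NQO1",
  "NR1I2", "P2RY1", "P2RY12", "PTGIS", "PTGS2", "SCN5A", "SLC15A2",
  "SLC19A1", "SLC22A1", "SLC22A2", "SLC22A6", "SLCO1B1", "SLCO1B3",
  "SLCO2B1", "SULT1A1", "TPMT", "TYMS", "UGT1A1", "UGT2B15", "UGT2B7",
  "VKORC1")

WARFARIN_RULE9_MESSAGE <- paste0(
  "0.5–2 mg warfarin per day should be considered as a starting dose ",
  "range for a patient with this genotype according to the warfarin drug ",
  "label.")

#' Build the worked-example knowledge base
#'
#' A small KB carrying the printed worked examples: the five CYP2C9/VKORC1
#' markers, the CYP2C9*3 haplotype (tag atom `rs1057910_C`; necessary atoms
#' `rs1057910_C`, `rs1057911_A`, `rs1799853_C`, `rs2256871_A`), a CYP2C9*1
#' reference-allele definition (no published axiom exists for *1, so it is
#' defined as the reference nucleotides at the *2/*3-defining positions and
#' marked `invented` in its metadata), the warfarin starting-dose rule
#' (`rule9`: CYP2C9*1 and CYP2C9*3 present plus two copies of
#' `rs9923231_T`), and the 58-gene panel list as metadata. Marker coordinates
#' are GRCh37 forward-strand dbSNP records.
#'
#' @return A `pgx_kb` that passes [check_consistency()] with zero findings.
#' @examples
#' kb <- build_fixture_kb()
#' kb$haplotypes[["CYP2C9*3"]]$sufficient
#' @export
build_fixture_kb <- function() {
  markers <- list(
    list(rsid = "rs1057910", chromosome = "10", position = 96741053L,
         reference = "A", allowed = c("A", "C")),
    list(rsid = "rs1057911", chromosome = "10", position = 96741058L,
         reference = "A", allowed = c("A", "T")),
    list(rsid = "rs1799853", chromosome = "10", position = 96702047L,
         reference = "C", allowed = c("C", "T")),
    list(rsid = "rs2256871", chromosome = "10", position = 96709038L,
         reference = "A", allowed = c("A", "G")),
    list(rsid = "rs9923231", chromosome = "16", position = 31107689L,
         reference = "C", allowed = c("C", "T"))
  )
  haplotypes <- list(
    list(gene = "CYP2C9", label = "*1",
         sufficient = list(variant_atom("rs1057910", "A"),
                           variant_atom("rs1799853", "C")),
         necessary = list(variant_atom("rs1057910", "A"),
                          variant_atom("rs1799853", "C")),
         meta = list(invented = TRUE,
                     note = paste("reference-allele definition: reference",
                                  "nucleotides at the *2/*3-defining positions;",
                                  "no published axiom"))),
    list(gene = "CYP2C9", label = "*3",
         sufficient = list(variant_atom("rs1057910", "C")),
         necessary = list(variant_atom("rs1057910", "C"),
                          variant_atom("rs1057911", "A"),
                          variant_atom("rs1799853", "C"),
                          variant_atom("rs2256871", "A")),
         meta = NULL)
  )
  rules <- list(
    list(rule_id = "rule9",
         condition = cds_and(has_haplotype("CYP2C9", "*1"),
                             has_haplotype("CYP2C9", "*3"),
                             has_exactly(2L, variant_atom("rs9923231", "T"))),
         message = WARFARIN_RULE9_MESSAGE,
         source = "FDA drug label (Coumadin, Bristol-Myers Squibb)")
  )
  new_kb(markers = markers, haplotypes = haplotypes, rules = rules,
         version = "0.2", build = "GRCh37", panel_genes = PANEL_GENES_58)
}

#' Fixture generation parameters
#'
#' @param n_markers Target panel size (default 385, the deployed panel size;
#'   must be at least the worked-example marker count).
#' @param seed Random seed; every generator output is a pure function of it.
#' @param missing_rate Probability a marker is masked to unknown in a sampled
#'   profile (default 0.02, a typical array no-call rate).
#' @param alt_freq Per-marker alternate-allele frequency for sampling
#'   (default 0.2).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_markers = 385L, seed = 1L, missing_rate = 0.02,
                         alt_freq = 0.2) {
  if (missing_rate < 0 || missing_rate > 1 || alt_freq < 0 || alt_freq > 1) {
    stop_sc("missing_rate and alt_freq must lie in [0, 1]",
            "safetycode_fixture_error")
  }
  structure(list(n_markers = as.integer(n_markers), seed = as.integer(seed),
                 missing_rate = missing_rate, alt_freq = alt_freq),
            class = "fixture_spec")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic knowledge base of a given panel size
#'
#' Extends the worked-example KB with deterministic synthetic biallelic
#' markers (rsid namespace `rs99...`, one synthetic gene per marker with a
#' *1/*2 allele definition pair) up to `n_markers` panel slots. A pure
#' function of the spec: the same spec yields a byte-identical KB.
#'
#' @param spec A [fixture_spec()].
#' @return A `pgx_kb` with exactly `spec$n_markers` panel markers.
#' @examples
#' kb <- generate_synthetic_kb(fixture_spec(n_markers = 10, seed = 42))
#' length(kb$markers)
#' @export
generate_synthetic_kb <- function(spec = fixture_spec()) {
  base <- build_fixture_kb()
  n_base <- length(base$markers)
  if (spec$n_markers < n_base) {
    stop_sc(sprintf("n_markers (%d) below the worked-example marker count (%d)",
                    spec$n_markers, n_base), "safetycode_fixture_error")
  }
  n_extra <- spec$n_markers - n_base
  if (n_extra == 0L) return(base)
  markers <- list(); haplotypes <- list()
  with_seed(spec$seed, {
    for (i in seq_len(n_extra)) {
      rsid <- sprintf("rs99%05d", i)
      alleles <- sample(NUCLEOTIDES, 2L)
      gene <- sprintf("SYNG%03d", i)
      markers[[i]] <- list(rsid = rsid, chromosome = as.character(1L + (i %% 22L)),
                           position = 1000L + i * 1000L,
                           reference = alleles[1], allowed = alleles)
      haplotypes[[2L * i - 1L]] <- list(
        gene = gene, label = "*1",
        sufficient = list(variant_atom(rsid, alleles[1])),
        necessary = list(variant_atom(rsid, alleles[1])),
        meta = list(synthetic = TRUE))
      haplotypes[[2L * i]] <- list(
        gene = gene, label = "*2",
        sufficient = list(variant_atom(rsid, alleles[2])),
        necessary = list(variant_atom(rsid, alleles[2])),
        meta = list(synthetic = TRUE))
    }
  })
  kb_markers <- c(lapply(unname(base$markers), identity), markers)
  kb_haps <- c(lapply(names(base$haplotypes), function(k) base$haplotypes[[k]]),
               haplotypes)
  new_kb(markers = kb_markers, haplotypes = kb_haps,
         rules = lapply(names(base$rules), function(k) base$rules[[k]]),
         version = base$version, build = base$build,
         panel_genes = base$panel_genes)
}

#' Sample a random genotype profile over a KB panel
#'
#' Per marker, two nucleotides are drawn independently (alternate allele with
#' probability `alt_freq`, uniformly among the non-reference alleles;
#' reference otherwise), then the call is masked to unknown with probability
#' `missing_rate`. Deterministic per seed.
#'
#' @param kb A `pgx_kb`.
#' @param spec A [fixture_spec()] (only `seed`, `missing_rate`, `alt_freq`
#'   are used).
#' @return A panel-complete [genotype_profile()].
#' @export
sample_profile <- function(kb, spec = fixture_spec()) {
  with_seed(spec$seed, {
    calls <- lapply(kb$markers, function(m) {
      if (stats::runif(1) < spec$missing_rate) return(NA_character_)
      alts <- setdiff(m$allowed, m$reference)
      vapply(1:2, function(i) {
        if (stats::runif(1) < spec$alt_freq) sample(alts, 1L) else m$reference
      }, "")
    })
    names(calls) <- names(kb$markers)
    genotype_profile(calls, source_format = "manual", build = kb$build)
  })
}

#' Write a profile as 23andMe and VCF fixture files
#'
#' Emits a 23andMe-dialect TSV (`profile.23andme.txt`) covering every panel
#' marker (unknowns as `--`) and a variant-only single-sample VCF
#' (`profile.vcf`): homozygous-reference markers are omitted so that the
#' missing-means-reference convention reconstructs them, heterozygous and
#' homozygous-alternate markers get `0/1`-style records, and unknown markers
#' get explicit `./.` records. Both files re-parse to the original profile.
#'
#' @param profile A panel-complete [genotype_profile()] over `kb`'s panel.
#' @param kb A `pgx_kb`.
#' @param dir Output directory (created if absent).
#' @return Named character vector with paths `twentythree` and `vcf`.
#' @export
write_profile_files <- function(profile, kb, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p23 <- file.path(dir, "profile.23andme.txt")
  pvcf <- file.path(dir, "profile.vcf")

  lines <- c("# Synthetic genotype fixture in 23andMe raw-data dialect",
             "# rsid\tchromosome\tposition\tgenotype")
  for (m in kb$markers) {
    g <- profile$calls[[m$rsid]]
    gt <- if (is.null(g) || is_unknown_call(g)) "--" else paste(g, collapse = "")
    lines <- c(lines, paste(m$rsid, m$chromosome, m$position, gt, sep = "\t"))
  }
  writeLines(lines, p23, useBytes = TRUE)

  vcf <- c("##fileformat=VCFv4.2",
           sprintf("##reference=%s", kb$build),
           "##source=safetycode synthetic fixture writer",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "SAMPLE1"), collapse = "\t"))
  for (m in kb$markers) {
    g <- profile$calls[[m$rsid]]
    if (is.null(g)) next
    if (is_unknown_call(g)) {
      rec <- c(m$chromosome, m$position, m$rsid, m$reference, ".", ".", ".",
               ".", "GT", "./.")
    } else if (all(g == m$reference)) {
      next  # variant-only convention: homozygous reference is implicit
    } else {
      alts <- sort(unique(g[g != m$reference]))
      gt_idx <- match(g, c(m$reference, alts)) - 1L
      rec <- c(m$chromosome, m$position, m$rsid, m$reference,
               paste(alts, collapse = ","), ".", ".", ".", "GT",
               paste(sort(gt_idx), collapse = "/"))
    }
    vcf <- c(vcf, paste(rec, collapse = "\t"))
  }
  writeLines(vcf, pvcf, useBytes = TRUE)
  c(twentythree = p23, vcf = pvcf)
}
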