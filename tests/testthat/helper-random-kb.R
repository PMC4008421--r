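# Random-KB generator for the property suites. Conditions are built to be
# satisfiable by construction: a witness genotype is drawn first and every
# emitted atom holds under it, so haplotypes/rules are never contradictory
# (contradictions are injected separately, and deliberately, below).

random_kb <- function(seed) {
  set.seed(seed)
  n_markers <- sample(2:6, 1L)
  markers <- lapply(seq_len(n_markers), function(i) {
    allowed <- sample(NUCLEOTIDES, sample(2:3, 1L))
    list(rsid = sprintf("rs10%d", i), chromosome = as.character(i),
         position = i * 100L, reference = allowed[1], allowed = allowed)
  })
  rsids <- vapply(markers, `[[`, "", "rsid")
  witness <- lapply(markers, function(m) sample(m$allowed, 2L, replace = TRUE))
  names(witness) <- rsids

  witness_atom <- function(rsid) {
    variant_atom(rsid, sample(witness[[rsid]], 1L))
  }
  haplotypes <- list()
  n_genes <- sample(1:3, 1L)
  for (g in seq_len(n_genes)) {
    gene <- sprintf("GENE%d", g)
    for (h in seq_len(sample(1:2, 1L))) {
      suff <- lapply(sample(rsids, sample(1:2, 1L)), witness_atom)
      extra <- if (stats::runif(1) < 0.5) list(witness_atom(sample(rsids, 1L))) else list()
      haplotypes[[length(haplotypes) + 1L]] <-
        list(gene = gene, label = paste0("*", h),
             sufficient = suff, necessary = c(suff, extra), meta = NULL)
    }
  }
  hap_keys <- vapply(haplotypes, function(h) paste0(h$gene, h$label), "")

  rules <- lapply(seq_len(sample(1:3, 1L)), function(r) {
    parts <- lapply(seq_len(sample(1:3, 1L)), function(i) {
      kind <- sample(c("some", "exactly", "hap"), 1L)
      if (kind == "hap") {
        return(has_haplotype(sample(hap_keys, 1L)))
      }
      rsid <- sample(rsids, 1L)
      nuc <- sample(c(witness[[rsid]],
                      sample(kb_marker_allowed(markers, rsid), 1L)), 1L)
      if (kind == "some" && sum(witness[[rsid]] == nuc) >= 1L) {
        has_some(variant_atom(rsid, nuc))
      } else {
        has_exactly(sum(witness[[rsid]] == nuc), variant_atom(rsid, nuc))
      }
    })
    list(rule_id = sprintf("rule%d", r), condition = cds_and(parts),
         message = sprintf("recommendation %d", r), source = "synthetic")
  })

  suppressWarnings(new_kb(markers = markers, haplotypes = haplotypes,
                          rules = rules, version = "0.0", build = "GRCh37"))
}

kb_marker_allowed <- function(markers, rsid) {
  for (m in markers) if (m$rsid == rsid) return(m$allowed)
  stop("unknown rsid")
}

# --- seeded defect injections ----------------------------------------------

# A marker with three allowed nucleotides, appended to the KB (injections
# need three distinct nucleotides at one locus to be unsatisfiable while
# still passing load-time atom validation).
inject_triallelic_marker <- function(kb_parts) {
  m <- list(rsid = "rs700001", chromosome = "7", position = 700001L,
            reference = "A", allowed = c("A", "C", "G"))
  kb_parts$markers <- c(kb_parts$markers, list(m))
  kb_parts
}

kb_parts <- function(kb) {
  list(markers = lapply(unname(kb$markers), identity),
       haplotypes = lapply(names(kb$haplotypes), function(k) kb$haplotypes[[k]]),
       rules = lapply(names(kb$rules), function(k) kb$rules[[k]]))
}

rebuild_kb <- function(parts) {
  suppressWarnings(new_kb(markers = parts$markers,
                          haplotypes = parts$haplotypes, rules = parts$rules,
                          version = "0.0", build = "GRCh37"))
}

# Rule requiring 2 copies of each of two different nucleotides at one marker.
inject_unsatisfiable_rule <- function(kb) {
  parts <- kb_parts(kb)
  m <- parts$markers[[1]]
  parts$rules <- c(parts$rules, list(list(
    rule_id = "zz_injected_rule",
    condition = cds_and(has_exactly(2L, variant_atom(m$rsid, m$allowed[1])),
                        has_exactly(2L, variant_atom(m$rsid, m$allowed[2]))),
    message = "injected unsatisfiable rule", source = "injected")))
  rebuild_kb(parts)
}

# Haplotype whose tag set is satisfiable but whose necessary atoms demand a
# third distinct nucleotide at the same diploid locus.
inject_non_entailing_tag <- function(kb) {
  parts <- inject_triallelic_marker(kb_parts(kb))
  a <- function(n) variant_atom("rs700001", n)
  parts$haplotypes <- c(parts$haplotypes, list(list(
    gene = "INJGENE", label = "*9",
    sufficient = list(a("A")),
    necessary = list(a("A"), a("C"), a("G")), meta = NULL)))
  rebuild_kb(parts)
}

# Haplotype whose tag set itself demands three distinct nucleotides.
inject_unsatisfiable_haplotype <- function(kb) {
  parts <- inject_triallelic_marker(kb_parts(kb))
  a <- function(n) variant_atom("rs700001", n)
  parts$haplotypes <- c(parts$haplotypes, list(list(
    gene = "INJGENE", label = "*8",
    sufficient = list(a("A"), a("C"), a("G")),
    necessary = list(a("A"), a("C"), a("G")), meta = NULL)))
  rebuild_kb(parts)
}

inject_duplicate_definition <- function(kb) {
  parts <- kb_parts(kb)
  h <- parts$haplotypes[[1]]
  parts$haplotypes <- c(parts$haplotypes, list(list(
    gene = h$gene, label = "*77", sufficient = h$sufficient,
    necessary = h$necessary, meta = NULL)))
  rebuild_kb(parts)
}
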