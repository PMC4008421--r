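# Independent brute-force oracles used by the property tests. Everything here
# re-derives semantics from first principles (plain loops over explicitly
# enumerated genotypes) and deliberately shares no code with the package's
# own evaluators or enumerator.

# Boolean evaluation of a condition on one complete genotype (named list of
# nucleotide pairs).
oracle_eval <- function(cond, geno, kb) {
  if (cond$type == "and") {
    return(all(vapply(cond$children, oracle_eval, NA, geno = geno, kb = kb)))
  }
  if (cond$type == "has_haplotype") {
    hap <- kb$haplotypes[[paste0(cond$gene, cond$label)]]
    return(all(vapply(hap$sufficient, function(a) {
      sum(geno[[a$rsid]] == a$nucleotide) >= 1L
    }, NA)))
  }
  count <- sum(geno[[cond$atom$rsid]] == cond$atom$nucleotide)
  if (cond$type == "has_some") count >= 1L else count == cond$n
}

oracle_condition_rsids <- function(cond, kb) {
  if (cond$type == "and") {
    return(unique(unlist(lapply(cond$children, oracle_condition_rsids, kb = kb))))
  }
  if (cond$type == "has_haplotype") {
    hap <- kb$haplotypes[[paste0(cond$gene, cond$label)]]
    return(unique(vapply(hap$sufficient, `[[`, "", "rsid")))
  }
  cond$atom$rsid
}

# All complete genotypes over the given markers, as a list of named lists.
oracle_genotype_space <- function(kb, rsids) {
  spaces <- lapply(rsids, function(r) {
    a <- sort(kb$markers[[r]]$allowed)
    out <- list()
    for (i in seq_along(a)) for (j in i:length(a)) {
      out[[length(out) + 1L]] <- c(a[i], a[j])
    }
    out
  })
  names(spaces) <- rsids
  genos <- list(stats::setNames(list(), character()))
  for (r in rsids) {
    genos <- unlist(lapply(genos, function(g) {
      lapply(spaces[[r]], function(pair) c(g, stats::setNames(list(pair), r)))
    }), recursive = FALSE)
  }
  genos
}

oracle_satisfiable <- function(cond, kb) {
  rsids <- sort(oracle_condition_rsids(cond, kb))
  for (g in oracle_genotype_space(kb, rsids)) {
    if (oracle_eval(cond, g, kb)) return(TRUE)
  }
  FALSE
}

# Sufficient-and-necessary conjunction of a haplotype as a plain condition.
oracle_hap_condition <- function(hap, include_necessary) {
  atoms <- hap$sufficient
  if (include_necessary) atoms <- c(atoms, hap$necessary)
  structure(list(type = "and", children = lapply(atoms, function(a) {
    structure(list(type = "has_some", atom = a), class = "condition_expr")
  })), class = "condition_expr")
}

# Re-derivation of the four consistency finding categories.
oracle_findings <- function(kb) {
  rows <- list()
  add <- function(category, entity) {
    rows[[length(rows) + 1L]] <<- data.frame(category = category,
                                             entity = entity,
                                             stringsAsFactors = FALSE)
  }
  for (key in names(kb$haplotypes)) {
    hap <- kb$haplotypes[[key]]
    if (!oracle_satisfiable(oracle_hap_condition(hap, FALSE), kb)) {
      add("UNSATISFIABLE_HAPLOTYPE", key)
    } else if (!oracle_satisfiable(oracle_hap_condition(hap, TRUE), kb)) {
      add("TAG_NOT_ENTAILING", key)
    }
  }
  sigs <- vapply(kb$haplotypes, function(h) {
    paste(h$gene, paste(sort(vapply(h$sufficient, format_atom, "")),
                        collapse = ","), sep = "|")
  }, "")
  for (sig in unique(sigs[duplicated(sigs)])) {
    add("DUPLICATE_DEFINITION",
        paste(sort(names(kb$haplotypes)[sigs == sig]), collapse = "|"))
  }
  for (rid in names(kb$rules)) {
    if (!oracle_satisfiable(kb$rules[[rid]]$condition, kb)) {
      add("UNSATISFIABLE_RULE", rid)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(category = character(), entity = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$category, out$entity), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Three-valued rule status by exhaustive completion enumeration: TRUE iff the
# condition holds under every completion of the unknown referenced markers,
# FALSE iff under none, UNKNOWN otherwise.
oracle_rule_status <- function(cond, profile, kb) {
  rsids <- sort(oracle_condition_rsids(cond, kb))
  unknown <- rsids[vapply(rsids, function(r) {
    g <- profile$calls[[r]]
    length(g) == 1L && is.na(g)
  }, NA)]
  known <- lapply(setdiff(rsids, unknown), function(r) profile$calls[[r]])
  names(known) <- setdiff(rsids, unknown)
  completions <- if (length(unknown) == 0L) list(known) else {
    lapply(oracle_genotype_space(kb, unknown), function(g) c(known, g))
  }
  vals <- vapply(completions, function(g) oracle_eval(cond, g, kb), NA)
  if (all(vals)) "TRUE" else if (!any(vals)) "FALSE" else "UNKNOWN"
}
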