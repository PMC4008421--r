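# Knowledge base: marker panel, star-allele (haplotype) definitions, and
# clinical decision-support rules. The KB is the formal stand-in for an
# OWL pharmacogenomics ontology; consistency checking is done by exhaustive
# finite-domain satisfiability over complete diploid genotypes.

CHROMOSOMES <- c(as.character(1:22), "X", "Y", "MT")

#' Construct a pharmacogenomic knowledge base
#'
#' Assembles and validates a knowledge base from its components. Most users
#' will call [load_kb()] on a JSON file instead; this constructor is the
#' programmatic route used by the fixture generators.
#'
#' @param markers List of marker records, each with fields `rsid`,
#'   `chromosome`, `position`, `reference`, `allowed` (character vector of
#'   nucleotides, first element = reference). List order defines the panel
#'   order used by the code layout.
#' @param haplotypes List of haplotype records with fields `gene`, `label`,
#'   `sufficient` (list of [variant_atom()], the tag-SNP set), `necessary`
#'   (list of atoms, all variants known on the allele) and optional `meta`.
#' @param rules List of rule records with fields `rule_id`, `condition`
#'   (a `condition_expr`), `message`, `source`.
#' @param version KB version string.
#' @param build Reference genome label, e.g. `"GRCh37"`.
#' @param panel_genes Optional character vector of gene symbols represented
#'   in the panel (metadata; not cross-validated against haplotypes).
#' @return A `pgx_kb` object.
#' @seealso [load_kb()], [write_kb()], [check_consistency()]
#' @export
new_kb <- function(markers = list(), haplotypes = list(), rules = list(),
                   version = "0.1", build = "GRCh37",
                   panel_genes = character()) {
  kb <- structure(list(version = version, build = build,
                       markers = list(), haplotypes = list(), rules = list(),
                       panel_genes = panel_genes),
                  class = "pgx_kb")

  for (i in seq_along(markers)) {
    m <- markers[[i]]
    ctx <- sprintf("marker record %d (%s)", i,
                   if (is.null(m$rsid)) "<no rsid>" else m$rsid)
    if (is.null(m$rsid) || !grepl("^rs[0-9]+$", m$rsid)) {
      stop_sc(paste0(ctx, ": invalid rsid"), "safetycode_load_error")
    }
    if (!is.null(kb$markers[[m$rsid]])) {
      stop_sc(paste0(ctx, ": duplicate rsid in panel"), "safetycode_load_error")
    }
    if (is.null(m$chromosome) || !as.character(m$chromosome) %in% CHROMOSOMES) {
      stop_sc(paste0(ctx, ": invalid chromosome"), "safetycode_load_error")
    }
    pos <- suppressWarnings(as.integer(m$position))
    if (is.na(pos) || pos < 1L) {
      stop_sc(paste0(ctx, ": position must be a positive integer"),
              "safetycode_load_error")
    }
    allowed <- toupper(unlist(m$allowed))
    if (length(allowed) < 2L || anyDuplicated(allowed) ||
        !all(allowed %in% NUCLEOTIDES)) {
      stop_sc(paste0(ctx, ": allowed nucleotides must be >=2 distinct A/C/G/T values"),
              "safetycode_load_error")
    }
    ref <- toupper(m$reference)
    if (!identical(ref, allowed[1])) {
      stop_sc(paste0(ctx, ": reference nucleotide must be first in allowed list"),
              "safetycode_load_error")
    }
    kb$markers[[m$rsid]] <- list(rsid = m$rsid,
                                 chromosome = as.character(m$chromosome),
                                 position = pos, reference = ref,
                                 allowed = allowed)
  }

  for (i in seq_along(haplotypes)) {
    h <- haplotypes[[i]]
    key <- haplotype_key(h$gene, h$label)
    ctx <- sprintf("haplotype %s", key)
    if (!is.null(kb$haplotypes[[key]])) {
      stop_sc(paste0(ctx, ": duplicate (gene, label)"), "safetycode_load_error")
    }
    if (length(h$sufficient) < 1L) {
      stop_sc(paste0(ctx, ": sufficient atom set must be non-empty"),
              "safetycode_load_error")
    }
    suff <- lapply(h$sufficient, as_atom)
    nec <- lapply(if (is.null(h$necessary)) list() else h$necessary, as_atom)
    for (a in c(suff, nec)) {
      validate_condition(has_some(a), kb, ctx)
    }
    suff_str <- vapply(suff, format_atom, "")
    nec_str <- vapply(nec, format_atom, "")
    extra <- setdiff(suff_str, nec_str)
    if (length(extra) > 0L) {
      # equivalent-class atoms are implicitly necessary: auto-repair by union
      warning(sprintf("%s: sufficient atoms %s missing from necessary set; repaired by union",
                      ctx, paste(extra, collapse = ", ")),
              call. = FALSE)
      nec <- c(nec, suff[suff_str %in% extra])
      nec_str <- c(nec_str, extra)
    }
    ord <- order(suff_str)
    suff <- suff[ord]
    nec <- nec[order(nec_str)]
    kb$haplotypes[[key]] <- list(gene = h$gene, label = h$label,
                                 sufficient = suff, necessary = nec,
                                 meta = h$meta)
  }

  for (i in seq_along(rules)) {
    r <- rules[[i]]
    ctx <- sprintf("rule %s", if (is.null(r$rule_id)) i else r$rule_id)
    if (is.null(r$rule_id) || !nzchar(r$rule_id)) {
      stop_sc(paste0(ctx, ": rule_id required"), "safetycode_load_error")
    }
    if (!is.null(kb$rules[[r$rule_id]])) {
      stop_sc(paste0(ctx, ": duplicate rule_id"), "safetycode_load_error")
    }
    if (is.null(r$message) || !nzchar(r$message)) {
      stop_sc(paste0(ctx, ": message must be non-empty"), "safetycode_load_error")
    }
    validate_condition(r$condition, kb, ctx)
    kb$rules[[r$rule_id]] <- list(rule_id = r$rule_id, condition = r$condition,
                                  message = r$message,
                                  source = if (is.null(r$source)) "" else r$source)
  }

  kb
}

as_atom <- function(x) {
  if (inherits(x, "variant_atom")) x else parse_atom(x)
}

#' @export
print.pgx_kb <- function(x, ...) {
  cat(sprintf("<pgx_kb v%s, build %s: %d markers, %d haplotypes, %d rules, %d panel genes>\n",
              x$version, x$build, length(x$markers), length(x$haplotypes),
              length(x$rules), length(x$panel_genes)))
  invisible(x)
}

#' Load a knowledge base from a JSON file
#'
#' Reads and validates a KB file. Top-level keys are `version`, `build`,
#' `markers`, `haplotypes`, `rules` and optionally `panel_genes`; conditions
#' are nested objects (`{"and": [...]}`, `{"has_some": "rs1057910_C"}`,
#' `{"has_exactly": {"n": 2, "atom": "rs9923231_T"}}`,
#' `{"has_haplotype": "CYP2C9*3"}`) and atoms are `"<rsid>_<nucleotide>"`
#' strings. A machine-readable schema ships at
#' `system.file("extdata", "kb-schema.json", package = "safetycode")`.
#'
#' Marker order in the file is the panel order and is preserved; it drives the
#' bit layout of the safety code. A haplotype whose sufficient (tag) atoms are
#' not contained in its necessary set is repaired by uniting the sets, with a
#' warning. Any dangling marker or haplotype reference is a reference error
#' naming the offender; unsupported condition constructs are load errors.
#'
#' @param path Path to a KB JSON file (or a connection).
#' @return A validated `pgx_kb` object.
#' @examples
#' kb <- build_fixture_kb()
#' f <- tempfile(fileext = ".json")
#' write_kb(kb, f)
#' kb2 <- load_kb(f)
#' @export
load_kb <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop_sc(sprintf("cannot parse KB file: %s", conditionMessage(e)),
                            "safetycode_load_error")
                  })
  for (key in c("version", "build", "markers", "haplotypes", "rules")) {
    if (is.null(obj[[key]])) {
      stop_sc(sprintf("KB file missing top-level key '%s'", key),
              "safetycode_load_error")
    }
  }
  haplotypes <- lapply(obj$haplotypes, function(h) {
    list(gene = h$gene, label = h$label,
         sufficient = lapply(unlist(h$sufficient), parse_atom),
         necessary = lapply(unlist(h$necessary), parse_atom),
         meta = h$meta)
  })
  rules <- lapply(obj$rules, function(r) {
    list(rule_id = r$rule_id,
         condition = condition_from_json(r$condition,
                                         context = sprintf("rule %s", r$rule_id)),
         message = r$message, source = r$source)
  })
  new_kb(markers = obj$markers, haplotypes = haplotypes, rules = rules,
         version = obj$version, build = obj$build,
         panel_genes = as.character(unlist(obj$panel_genes)))
}

#' Write a knowledge base to a JSON file
#'
#' Deterministic serialization: the same KB always produces byte-identical
#' output, so fixture generation is reproducible.
#'
#' @param kb A `pgx_kb` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_kb <- function(kb, path) {
  obj <- list(
    version = kb$version,
    build = kb$build,
    markers = lapply(unname(kb$markers), function(m) {
      list(rsid = m$rsid, chromosome = m$chromosome, position = m$position,
           reference = m$reference, allowed = as.list(m$allowed))
    }),
    haplotypes = lapply(unname(kb$haplotypes), function(h) {
      out <- list(gene = h$gene, label = h$label,
                  sufficient = as.list(vapply(h$sufficient, format_atom, "")),
                  necessary = as.list(vapply(h$necessary, format_atom, "")))
      if (!is.null(h$meta)) out$meta <- h$meta
      out
    }),
    rules = lapply(unname(kb$rules), function(r) {
      list(rule_id = r$rule_id, condition = condition_to_json(r$condition),
           message = r$message, source = r$source)
    }),
    panel_genes = as.list(kb$panel_genes)
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = 2L, digits = NA)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

# --- genotype-space enumeration --------------------------------------------

# All unordered nucleotide pairs over an allowed set, in lexicographic order
# of (min, max): a 2-column character matrix. Also the genotype index order
# used by the code layout (index 0 there is reserved for UNKNOWN).
genotype_pairs <- function(allowed) {
  allowed <- sort(allowed)
  k <- length(allowed)
  out <- matrix("", nrow = k * (k + 1L) / 2L, ncol = 2L)
  row <- 1L
  for (i in seq_len(k)) {
    for (j in i:k) {
      out[row, ] <- c(allowed[i], allowed[j])
      row <- row + 1L
    }
  }
  out
}

# Evaluate flattened count constraints over the full genotype space of the
# referenced markers. Returns list(any = <logical>, witness = <list of pairs>
# for the first satisfying genotype in enumeration order, or NULL).
enumerate_satisfying <- function(constraints, kb, max_markers) {
  rsids <- sort(unique(vapply(constraints, `[[`, "", "rsid")))
  if (length(rsids) > max_markers) {
    stop_sc(sprintf("condition references %d markers, above the per-check cap of %d",
                    length(rsids), max_markers),
            "safetycode_capacity_error")
  }
  pairs <- lapply(rsids, function(r) genotype_pairs(kb$markers[[r]]$allowed))
  names(pairs) <- rsids
  grid <- do.call(expand.grid,
                  c(lapply(rev(rsids), function(r) seq_len(nrow(pairs[[r]]))),
                    KEEP.OUT.ATTRS = FALSE))
  # reversed so the FIRST marker varies slowest: deterministic, readable order
  grid <- grid[, rev(seq_along(rsids)), drop = FALSE]
  names(grid) <- rsids

  ok <- rep(TRUE, nrow(grid))
  for (con in constraints) {
    p <- pairs[[con$rsid]]
    counts <- (p[, 1] == con$nucleotide) + (p[, 2] == con$nucleotide)
    cnt <- counts[grid[[con$rsid]]]
    ok <- ok & if (con$op == "some") cnt >= 1L else cnt == con$n
    if (!any(ok)) break
  }
  hit <- which(ok)
  if (length(hit) == 0L) return(list(any = FALSE, witness = NULL))
  first <- hit[1]
  witness <- lapply(rsids, function(r) unname(pairs[[r]][grid[[r]][first], ]))
  names(witness) <- rsids
  list(any = TRUE, witness = witness)
}

#' Decide satisfiability of a condition over complete diploid genotypes
#'
#' Exhaustively enumerates the genotype space of the markers the condition
#' references (the product, over markers, of all unordered nucleotide pairs
#' drawn from each marker's allowed set) and reports whether any complete
#' genotype evaluates the condition TRUE. `has_haplotype` atoms are expanded
#' into the haplotype's sufficient (tag) atoms.
#'
#' @param condition A `condition_expr`.
#' @param kb A `pgx_kb`.
#' @param max_markers_per_check Cap on distinct markers a single condition may
#'   reference before enumeration is refused with a capacity error. The
#'   default 12 keeps the worst biallelic space at 3^12 (~5e5) genotypes.
#' @return A list with `satisfiable` (logical) and, when satisfiable,
#'   `witness`: a [genotype_profile()] over the referenced markers (first
#'   satisfying genotype in deterministic enumeration order).
#' @examples
#' kb <- build_fixture_kb()
#' satisfiable(has_exactly(2, "rs9923231_T"), kb)$witness$calls
#' @export
satisfiable <- function(condition, kb, max_markers_per_check = 12L) {
  validate_condition(condition, kb, "condition")
  res <- enumerate_satisfying(flatten_condition(condition, kb), kb,
                              max_markers_per_check)
  if (!res$any) return(list(satisfiable = FALSE, witness = NULL))
  list(satisfiable = TRUE,
       witness = genotype_profile(res$witness, source_format = "manual",
                                  build = kb$build))
}

#' Consistency-check a knowledge base
#'
#' Brute-force finite-domain analogue of ontology consistency checking: every
#' haplotype definition and rule condition is tested by exhaustive enumeration
#' of complete diploid genotypes over its referenced markers. Findings fall in
#' four categories:
#'
#' * `UNSATISFIABLE_HAPLOTYPE` — no complete genotype satisfies the
#'   haplotype's sufficient (tag) conjunction.
#' * `TAG_NOT_ENTAILING` — the tag conjunction is satisfiable, but no complete
#'   genotype satisfies the tag conjunction together with all necessary atoms
#'   (the equivalent-class and subclass axioms are jointly unsatisfiable, so
#'   the tags can never identify a genotype consistent with the allele's full
#'   variant set).
#' * `DUPLICATE_DEFINITION` — two haplotypes of one gene with identical
#'   sufficient atom sets.
#' * `UNSATISFIABLE_RULE` — no complete genotype satisfies a rule condition.
#'
#' @param kb A `pgx_kb`.
#' @param max_markers_per_check As in [satisfiable()]. A condition exceeding
#'   the cap raises a capacity error naming the entity; it is never skipped.
#' @return A data frame with columns `category`, `entity`, `detail`, sorted by
#'   category then entity (byte-identical for identical inputs); zero rows iff
#'   no finding applies.
#' @examples
#' check_consistency(build_fixture_kb())
#' @export
check_consistency <- function(kb, max_markers_per_check = 12L) {
  findings <- list()
  add <- function(category, entity, detail) {
    findings[[length(findings) + 1L]] <<- data.frame(
      category = category, entity = entity, detail = detail,
      stringsAsFactors = FALSE)
  }
  with_entity_cap <- function(entity, expr) {
    tryCatch(expr, safetycode_capacity_error = function(e) {
      stop_sc(sprintf("%s: %s", entity, conditionMessage(e)),
              "safetycode_capacity_error")
    })
  }

  for (key in names(kb$haplotypes)) {
    hap <- kb$haplotypes[[key]]
    suff_con <- lapply(hap$sufficient, function(a) {
      list(op = "some", n = 1L, rsid = a$rsid, nucleotide = a$nucleotide)
    })
    nec_con <- lapply(hap$necessary, function(a) {
      list(op = "some", n = 1L, rsid = a$rsid, nucleotide = a$nucleotide)
    })
    n_mark <- length(unique(vapply(c(suff_con, nec_con), `[[`, "", "rsid")))
    if (n_mark > max_markers_per_check) {
      stop_sc(sprintf("haplotype %s references %d markers, above the per-check cap of %d",
                      key, n_mark, max_markers_per_check),
              "safetycode_capacity_error")
    }
    tag_sat <- enumerate_satisfying(suff_con, kb, max_markers_per_check)$any
    if (!tag_sat) {
      add("UNSATISFIABLE_HAPLOTYPE", key,
          "no complete diploid genotype satisfies the sufficient (tag) conjunction")
      next
    }
    joint_sat <- enumerate_satisfying(c(suff_con, nec_con), kb,
                                      max_markers_per_check)$any
    if (!joint_sat) {
      bad <- vapply(seq_along(nec_con), function(i) {
        !enumerate_satisfying(c(suff_con, nec_con[i]), kb,
                              max_markers_per_check)$any
      }, NA)
      detail <- if (any(bad)) {
        sprintf("necessary atom(s) %s cannot hold on any genotype matching the tag set",
                paste(vapply(hap$necessary[bad], format_atom, ""), collapse = ", "))
      } else {
        "necessary atoms are jointly incompatible with the tag set"
      }
      add("TAG_NOT_ENTAILING", key, detail)
    }
  }

  keys <- names(kb$haplotypes)
  if (length(keys) >= 2L) {
    sigs <- vapply(kb$haplotypes, function(h) {
      paste(h$gene, paste(sort(vapply(h$sufficient, format_atom, "")),
                          collapse = ","), sep = "|")
    }, "")
    for (sig in unique(sigs[duplicated(sigs)])) {
      dup <- sort(keys[sigs == sig])
      add("DUPLICATE_DEFINITION", paste(dup, collapse = "|"),
          "haplotypes of the same gene share an identical sufficient atom set")
    }
  }

  for (rid in names(kb$rules)) {
    rule <- kb$rules[[rid]]
    sat <- with_entity_cap(sprintf("rule %s", rid),
      enumerate_satisfying(flatten_condition(rule$condition, kb), kb,
                           max_markers_per_check))
    if (!sat$any) {
      add("UNSATISFIABLE_RULE", rid,
          "no complete diploid genotype satisfies the rule condition")
    }
  }

  if (length(findings) == 0L) {
    return(data.frame(category = character(), entity = character(),
                      detail = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, findings)
  out <- out[order(out$category, out$entity), , drop = FALSE]
  rownames(out) <- NULL
  out
}
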