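# Condition language for haplotype definitions and CDS rules: conjunctions of
# has-some / has-exactly / has-haplotype atoms. Or/Not are deliberately not
# part of the language; their presence in a KB file is a load error.

NUCLEOTIDES <- c("A", "C", "G", "T")

stop_sc <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "safetycode_error", "error")))
}

#' Variant atom
#'
#' A single SNP-variant symbol: a dbSNP identifier plus one nucleotide, the
#' `rsNNN_X` pattern used throughout haplotype definitions and decision rules.
#'
#' @param rsid dbSNP identifier (`"rs"` + digits).
#' @param nucleotide One of `"A"`, `"C"`, `"G"`, `"T"`.
#' @return A `variant_atom` object.
#' @examples
#' variant_atom("rs1057910", "C")
#' parse_atom("rs9923231_T")
#' @export
variant_atom <- function(rsid, nucleotide) {
  if (!grepl("^rs[0-9]+$", rsid)) {
    stop_sc(sprintf("invalid rsid '%s' (expected 'rs' + digits)", rsid),
            "safetycode_load_error")
  }
  nucleotide <- toupper(nucleotide)
  if (!nucleotide %in% NUCLEOTIDES) {
    stop_sc(sprintf("invalid nucleotide '%s' in atom for %s", nucleotide, rsid),
            "safetycode_load_error")
  }
  structure(list(rsid = rsid, nucleotide = nucleotide), class = "variant_atom")
}

#' @rdname variant_atom
#' @param x For `parse_atom`, a string `"<rsid>_<nucleotide>"`; for
#'   `format_atom`, a `variant_atom`.
#' @export
parse_atom <- function(x) {
  m <- regmatches(x, regexec("^(rs[0-9]+)_([ACGTacgt])$", x))[[1]]
  if (length(m) != 3) {
    stop_sc(sprintf("cannot parse variant atom '%s' (expected rsNNN_X)", x),
            "safetycode_load_error")
  }
  variant_atom(m[2], m[3])
}

#' @rdname variant_atom
#' @export
format_atom <- function(x) paste0(x$rsid, "_", x$nucleotide)

#' Condition expression constructors
#'
#' Build the condition AST used by haplotype definitions and CDS rules:
#' existential presence (`has_some`), diploid copy-count (`has_exactly`,
#' n in 0..2), named allele presence (`has_haplotype`), and conjunction
#' (`cds_and`). This conjunctive/cardinality fragment is the whole language.
#'
#' @param atom A `variant_atom` or an `"rsNNN_X"` string.
#' @param n Copy count, an integer in `0:2` (diploid).
#' @param gene Gene symbol, e.g. `"CYP2C9"`; alternatively pass the combined
#'   `"GENE*label"` form and omit `label`.
#' @param label Allele name, e.g. `"*3"`.
#' @param ... Child conditions for `cds_and` (at least one).
#' @return A `condition_expr` object.
#' @examples
#' cds_and(
#'   has_haplotype("CYP2C9*1"),
#'   has_haplotype("CYP2C9*3"),
#'   has_exactly(2, "rs9923231_T")
#' )
#' @export
has_some <- function(atom) {
  if (is.character(atom)) atom <- parse_atom(atom)
  structure(list(type = "has_some", atom = atom), class = "condition_expr")
}

#' @rdname has_some
#' @export
has_exactly <- function(n, atom) {
  if (is.character(atom)) atom <- parse_atom(atom)
  n <- as.integer(n)
  if (is.na(n) || n < 0L || n > 2L) {
    stop_sc("has_exactly count must be 0, 1 or 2 (diploid)",
            "safetycode_load_error")
  }
  structure(list(type = "has_exactly", n = n, atom = atom),
            class = "condition_expr")
}

#' @rdname has_some
#' @export
has_haplotype <- function(gene, label = NULL) {
  if (is.null(label)) {
    m <- regmatches(gene, regexec("^([^*]+)(\\*.+)$", gene))[[1]]
    if (length(m) != 3) {
      stop_sc(sprintf("cannot parse haplotype reference '%s' (expected GENE*label)",
                      gene), "safetycode_load_error")
    }
    gene <- m[2]
    label <- m[3]
  }
  structure(list(type = "has_haplotype", gene = gene, label = label),
            class = "condition_expr")
}

#' @rdname has_some
#' @export
cds_and <- function(...) {
  children <- list(...)
  if (length(children) == 1L && is.list(children[[1]]) &&
      !inherits(children[[1]], "condition_expr")) {
    children <- children[[1]]
  }
  if (length(children) < 1L) {
    stop_sc("conjunction needs at least one child", "safetycode_load_error")
  }
  for (ch in children) {
    if (!inherits(ch, "condition_expr")) {
      stop_sc("cds_and children must be condition expressions",
              "safetycode_load_error")
    }
  }
  structure(list(type = "and", children = children), class = "condition_expr")
}

haplotype_key <- function(gene, label) paste0(gene, label)

# --- JSON (de)serialization -------------------------------------------------

condition_from_json <- function(obj, context = "condition") {
  if (!is.list(obj) || length(obj) != 1L || is.null(names(obj))) {
    stop_sc(sprintf("%s: malformed condition object", context),
            "safetycode_load_error")
  }
  key <- names(obj)
  val <- obj[[1]]
  switch(key,
    "and" = {
      if (!is.list(val) || length(val) < 1L) {
        stop_sc(sprintf("%s: 'and' needs a non-empty array", context),
                "safetycode_load_error")
      }
      cds_and(lapply(val, condition_from_json, context = context))
    },
    "has_some" = has_some(parse_atom(val)),
    "has_exactly" = {
      if (is.null(val$n) || is.null(val$atom)) {
        stop_sc(sprintf("%s: 'has_exactly' needs fields n and atom", context),
                "safetycode_load_error")
      }
      has_exactly(val$n, parse_atom(val$atom))
    },
    "has_haplotype" = has_haplotype(val),
    stop_sc(sprintf(
      "%s: unsupported condition construct '%s' (only and/has_some/has_exactly/has_haplotype)",
      context, key), "safetycode_load_error")
  )
}

condition_to_json <- function(cond) {
  switch(cond$type,
    "and" = list(and = lapply(cond$children, condition_to_json)),
    "has_some" = list(has_some = format_atom(cond$atom)),
    "has_exactly" = list(has_exactly = list(n = cond$n,
                                            atom = format_atom(cond$atom))),
    "has_haplotype" = list(has_haplotype = haplotype_key(cond$gene, cond$label))
  )
}

#' @export
format.condition_expr <- function(x, ...) {
  switch(x$type,
    "and" = paste0("(", paste(vapply(x$children, format, ""), collapse = " and "), ")"),
    "has_some" = paste0("has some ", format_atom(x$atom)),
    "has_exactly" = paste0("has exactly ", x$n, " ", format_atom(x$atom)),
    "has_haplotype" = paste0("has some '", haplotype_key(x$gene, x$label), "'")
  )
}

#' @export
print.condition_expr <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# Flatten a condition into atom-level count constraints, expanding
# has_haplotype into the haplotype's sufficient atoms (each an existential).
# Returns a list of list(op = "some"|"exactly", n, rsid, nucleotide).
flatten_condition <- function(cond, kb) {
  switch(cond$type,
    "and" = do.call(c, lapply(cond$children, flatten_condition, kb = kb)),
    "has_some" = list(list(op = "some", n = 1L, rsid = cond$atom$rsid,
                           nucleotide = cond$atom$nucleotide)),
    "has_exactly" = list(list(op = "exactly", n = cond$n, rsid = cond$atom$rsid,
                              nucleotide = cond$atom$nucleotide)),
    "has_haplotype" = {
      key <- haplotype_key(cond$gene, cond$label)
      hap <- kb$haplotypes[[key]]
      if (is.null(hap)) {
        stop_sc(sprintf("condition references undefined haplotype '%s'", key),
                "safetycode_reference_error")
      }
      lapply(hap$sufficient, function(a) {
        list(op = "some", n = 1L, rsid = a$rsid, nucleotide = a$nucleotide)
      })
    }
  )
}

# Distinct rsids a condition touches (through haplotype expansion).
condition_markers <- function(cond, kb) {
  unique(vapply(flatten_condition(cond, kb), `[[`, "", "rsid"))
}

# Validate every cross-reference a condition makes against the KB.
validate_condition <- function(cond, kb, context) {
  if (cond$type == "and") {
    for (ch in cond$children) validate_condition(ch, kb, context)
    return(invisible(TRUE))
  }
  if (cond$type == "has_haplotype") {
    key <- haplotype_key(cond$gene, cond$label)
    if (is.null(kb$haplotypes[[key]])) {
      stop_sc(sprintf("%s references undefined haplotype '%s'", context, key),
              "safetycode_reference_error")
    }
    return(invisible(TRUE))
  }
  atom <- cond$atom
  marker <- kb$markers[[atom$rsid]]
  if (is.null(marker)) {
    stop_sc(sprintf("%s references undefined marker '%s'", context, atom$rsid),
            "safetycode_reference_error")
  }
  if (!atom$nucleotide %in% marker$allowed) {
    stop_sc(sprintf("%s: nucleotide %s not allowed for marker %s (allowed: %s)",
                    context, atom$nucleotide, atom$rsid,
                    paste(marker$allowed, collapse = "/")),
            "safetycode_reference_error")
  }
  invisible(TRUE)
}
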