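# Rule evaluation over a diploid profile with three-valued (Kleene) logic.
# The third value keeps "this rule does not apply" distinct from "not enough
# genotype data to tell" — the safety-relevant distinction an open-world
# reasoner preserves and a plain boolean evaluation would erase.

TV_TRUE <- "TRUE"; TV_FALSE <- "FALSE"; TV_UNKNOWN <- "UNKNOWN"

# Strong Kleene conjunction over a character vector of truth values:
# FALSE dominates, all-TRUE gives TRUE, anything else is UNKNOWN.
kleene_and <- function(values) {
  if (any(values == TV_FALSE)) return(TV_FALSE)
  if (all(values == TV_TRUE)) return(TV_TRUE)
  TV_UNKNOWN
}

#' Evaluate a variant atom against a profile
#'
#' `has_some` is TRUE iff at least one of the two observed nucleotides equals
#' the atom's nucleotide, FALSE if the genotype is known and neither matches,
#' and UNKNOWN if the genotype is unknown. `has_exactly(n)` compares the
#' multiset count (0, 1 or 2 copies) to `n` under the same unknown rule. A
#' bare [variant_atom()] is treated as `has_some`.
#'
#' @param profile A [genotype_profile()] whose call set covers the atom's
#'   marker (an absent marker is an evaluation error, not UNKNOWN).
#' @param atom A `variant_atom`, or a `condition_expr` of type `has_some` or
#'   `has_exactly`.
#' @return `"TRUE"`, `"FALSE"` or `"UNKNOWN"`.
#' @examples
#' p <- genotype_profile(list(rs1057910 = c("A", "C")))
#' evaluate_atom(p, has_some("rs1057910_C"))
#' evaluate_atom(p, has_exactly(2, "rs1057910_C"))
#' @export
evaluate_atom <- function(profile, atom) {
  if (inherits(atom, "variant_atom")) atom <- has_some(atom)
  if (!atom$type %in% c("has_some", "has_exactly")) {
    stop_sc("evaluate_atom expects a has_some or has_exactly condition",
            "safetycode_eval_error")
  }
  rsid <- atom$atom$rsid
  if (!rsid %in% names(profile$calls)) {
    stop_sc(sprintf("marker %s is not in the profile's panel", rsid),
            "safetycode_eval_error")
  }
  g <- profile$calls[[rsid]]
  if (is_unknown_call(g)) return(TV_UNKNOWN)
  count <- sum(g == atom$atom$nucleotide)
  hit <- if (atom$type == "has_some") count >= 1L else count == atom$n
  if (hit) TV_TRUE else TV_FALSE
}

# Evaluate a full condition; has_haplotype atoms are looked up in the named
# status vector produced by call_haplotypes.
eval_condition_tv <- function(cond, profile, hap_status) {
  switch(cond$type,
    "and" = kleene_and(vapply(cond$children, eval_condition_tv, "",
                              profile = profile, hap_status = hap_status)),
    "has_haplotype" = {
      key <- haplotype_key(cond$gene, cond$label)
      if (!key %in% names(hap_status)) {
        stop_sc(sprintf("no allele call available for %s", key),
                "safetycode_eval_error")
      }
      hap_status[[key]]
    },
    evaluate_atom(profile, cond)
  )
}

#' Call star alleles for a profile
#'
#' For every haplotype definition in the KB, the allele's status is the
#' Kleene conjunction of its sufficient (tag) atoms, each read existentially
#' over the unphased pair. On unphased data two alleles of one gene can both
#' be TRUE (compound presence); no diplotype phasing is attempted. An allele
#' is flagged `conflict` when its tag set holds but some necessary atom is
#' observed FALSE — the genotype contradicts the allele's full variant set.
#'
#' @param profile A panel-restricted [genotype_profile()].
#' @param kb A `pgx_kb`.
#' @return A data frame with one row per haplotype: `gene`, `label`, `status`,
#'   `conflict`, `supporting_atoms` (comma-joined tag atoms), ordered by gene
#'   then label.
#' @export
call_haplotypes <- function(profile, kb) {
  rows <- lapply(kb$haplotypes, function(h) {
    suff_tv <- vapply(h$sufficient, function(a) evaluate_atom(profile, a), "")
    status <- kleene_and(suff_tv)
    nec_tv <- vapply(h$necessary, function(a) evaluate_atom(profile, a), "")
    data.frame(gene = h$gene, label = h$label, status = status,
               conflict = status == TV_TRUE && any(nec_tv == TV_FALSE),
               supporting_atoms = paste(vapply(h$sufficient, format_atom, ""),
                                        collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), label = character(), status = character(),
               conflict = logical(), supporting_atoms = character(),
               stringsAsFactors = FALSE)
  out <- out[order(out$gene, out$label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match decision-support rules against a profile
#'
#' Evaluates each rule's condition with `has_haplotype` atoms substituted by
#' the corresponding allele-call status. A TRUE rule is triggered and carries
#' its recommendation message; an UNKNOWN rule reports every unknown marker
#' reachable from its condition (through haplotype expansion) so the caller
#' knows which genotypes would resolve it; a FALSE rule is not triggered.
#'
#' @param profile A panel-restricted [genotype_profile()].
#' @param calls Allele calls from [call_haplotypes()] on the same profile/KB.
#' @param kb A `pgx_kb`.
#' @return A data frame with one row per rule: `rule_id`, `status`, `message`,
#'   `source`, `missing_markers` (comma-joined, empty unless UNKNOWN),
#'   ordered by `rule_id`.
#' @export
match_rules <- function(profile, calls, kb) {
  hap_status <- if (nrow(calls)) {
    stats::setNames(calls$status, paste0(calls$gene, calls$label))
  } else {
    character()
  }
  rows <- lapply(kb$rules, function(r) {
    status <- eval_condition_tv(r$condition, profile, hap_status)
    missing <- ""
    if (status == TV_UNKNOWN) {
      rsids <- condition_markers(r$condition, kb)
      unk <- rsids[vapply(rsids, function(x) {
        is_unknown_call(profile$calls[[x]])
      }, NA)]
      missing <- paste(sort(unk), collapse = ",")
    }
    data.frame(rule_id = r$rule_id, status = status, message = r$message,
               source = r$source, missing_markers = missing,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(rule_id = character(), status = character(),
               message = character(), source = character(),
               missing_markers = character(), stringsAsFactors = FALSE)
  out <- out[order(out$rule_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Interpret a genotype profile against a knowledge base
#'
#' The full realization step: restrict the profile to the KB panel, call star
#' alleles, match decision rules, and assemble a deterministic report (genes
#' alphabetically, rules by id). Identical inputs give byte-identical
#' reports.
#'
#' @param profile A [genotype_profile()] (any marker set; it is
#'   panel-restricted internally).
#' @param kb A `pgx_kb`.
#' @return An `interpretation_report`: list with `allele_calls`,
#'   `rule_matches` (data frames as documented in [call_haplotypes()] and
#'   [match_rules()]), `profile_summary` (known/unknown/total marker counts)
#'   and `kb_version`.
#' @examples
#' kb <- build_fixture_kb()
#' p <- genotype_profile(list(rs1057910 = c("A", "C"), rs9923231 = c("T", "T")))
#' rep <- interpret(p, kb)
#' subset(rep$rule_matches, status == "TRUE")$rule_id
#' @export
interpret <- function(profile, kb) {
  profile <- restrict_to_panel(profile, kb)
  calls <- call_haplotypes(profile, kb)
  matches <- match_rules(profile, calls, kb)
  unknown <- sum(vapply(profile$calls, is_unknown_call, NA))
  structure(list(
    allele_calls = calls,
    rule_matches = matches,
    profile_summary = list(known = length(profile$calls) - unknown,
                           unknown = unknown,
                           total = length(profile$calls)),
    kb_version = kb$version
  ), class = "interpretation_report")
}

#' Serialize an interpretation report
#'
#' `report_to_json()` writes the report in a stable JSON shape (schema at
#' `system.file("extdata", "report-schema.json", package = "safetycode")`);
#' `format()`/`print()` give a plain-text rendering.
#'
#' @param report An `interpretation_report`.
#' @param path Optional output file; when `NULL` the JSON string is returned.
#' @return JSON string (or `path` invisibly).
#' @export
report_to_json <- function(report, path = NULL) {
  obj <- list(
    kb_version = report$kb_version,
    profile_summary = report$profile_summary,
    allele_calls = report$allele_calls,
    rule_matches = report$rule_matches
  )
  json <- jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE,
                           pretty = 2L, digits = NA)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' @export
format.interpretation_report <- function(x, ...) {
  lines <- c(
    sprintf("Interpretation report (KB version %s)", x$kb_version),
    sprintf("Markers: %d known / %d unknown of %d",
            x$profile_summary$known, x$profile_summary$unknown,
            x$profile_summary$total),
    "", "Allele calls:")
  if (nrow(x$allele_calls)) {
    lines <- c(lines, sprintf("  %s%s: %s%s", x$allele_calls$gene,
                              x$allele_calls$label, x$allele_calls$status,
                              ifelse(x$allele_calls$conflict,
                                     " [CONFLICT: necessary variant absent]", "")))
  } else lines <- c(lines, "  (none defined)")
  lines <- c(lines, "", "Decision-support rules:")
  if (nrow(x$rule_matches)) {
    for (i in seq_len(nrow(x$rule_matches))) {
      r <- x$rule_matches[i, ]
      lines <- c(lines, sprintf("  %s: %s", r$rule_id, r$status))
      if (r$status == TV_TRUE) {
        lines <- c(lines, sprintf("    message: %s", r$message),
                   if (nzchar(r$source)) sprintf("    source: %s", r$source))
      } else if (r$status == TV_UNKNOWN && nzchar(r$missing_markers)) {
        lines <- c(lines, sprintf("    insufficient data; missing markers: %s",
                                  r$missing_markers))
      }
    }
  } else lines <- c(lines, "  (none defined)")
  paste(lines, collapse = "\n")
}

#' @export
print.interpretation_report <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}
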