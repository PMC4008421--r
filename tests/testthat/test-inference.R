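# Profile carrying one *1- and one *3-defining CYP2C9 haplotype plus
# homozygous rs9923231 T: the genotype the warfarin starting-dose rule
# describes.
rule9_profile <- function(rs9923231 = c("T", "T")) {
  genotype_profile(list(
    rs1057910 = c("A", "C"),
    rs1057911 = c("A", "A"),
    rs1799853 = c("C", "C"),
    rs2256871 = c("A", "A"),
    rs9923231 = rs9923231))
}

test_that("atom evaluation implements existential and count semantics", {
  p <- genotype_profile(list(rs1057910 = c("A", "C"), rs9923231 = c("C", "T"),
                             rs2256871 = NA))
  expect_identical(evaluate_atom(p, has_some("rs1057910_C")), "TRUE")
  expect_identical(evaluate_atom(p, has_some("rs1057910_G")), "FALSE")
  expect_identical(evaluate_atom(p, has_exactly(2, "rs9923231_T")), "FALSE")
  expect_identical(evaluate_atom(p, has_exactly(1, "rs9923231_T")), "TRUE")
  expect_identical(evaluate_atom(p, has_exactly(0, "rs9923231_T")), "FALSE")
  expect_identical(evaluate_atom(p, has_some("rs2256871_A")), "UNKNOWN")
  expect_identical(evaluate_atom(p, has_exactly(2, "rs2256871_A")), "UNKNOWN")
  expect_error(evaluate_atom(p, has_some("rs424242_A")),
               class = "safetycode_eval_error")
})

test_that("unphased compound presence calls both CYP2C9 alleles TRUE", {
  kb <- build_fixture_kb()
  calls <- call_haplotypes(restrict_to_panel(rule9_profile(), kb), kb)
  expect_identical(calls$status[calls$label == "*1"], "TRUE")
  expect_identical(calls$status[calls$label == "*3"], "TRUE")
  expect_false(any(calls$conflict))

  p0 <- restrict_to_panel(genotype_profile(list(
    rs1057910 = c("A", "A"), rs1799853 = c("C", "C"))), kb)
  calls0 <- call_haplotypes(p0, kb)
  expect_identical(calls0$status[calls0$label == "*3"], "FALSE")
})

test_that("a tag that holds while a necessary variant is absent is a conflict", {
  kb <- build_fixture_kb()
  p <- restrict_to_panel(genotype_profile(list(
    rs1057910 = c("C", "C"), rs1057911 = c("A", "A"),
    rs1799853 = c("T", "T"), rs2256871 = c("A", "A"))), kb)
  calls <- call_haplotypes(p, kb)
  star3 <- calls[calls$label == "*3", ]
  expect_identical(star3$status, "TRUE")
  expect_true(star3$conflict)
})

test_that("the warfarin rule triggers, un-triggers, and reports missing data", {
  kb <- build_fixture_kb()
  rep <- interpret(rule9_profile(), kb)
  triggered <- rep$rule_matches[rep$rule_matches$status == "TRUE", ]
  expect_identical(nrow(triggered), 1L)
  expect_match(triggered$message, "0.5–2 mg warfarin per day", fixed = TRUE)

  rep2 <- interpret(rule9_profile(rs9923231 = c("C", "T")), kb)
  expect_identical(rep2$rule_matches$status, "FALSE")

  rep3 <- interpret(rule9_profile(rs9923231 = NA), kb)
  expect_identical(rep3$rule_matches$status, "UNKNOWN")
  expect_identical(rep3$rule_matches$missing_markers, "rs9923231")
})

test_that("an all-unknown profile leaves every rule indeterminate", {
  kb <- build_fixture_kb()
  rep <- interpret(genotype_profile(list()), kb)
  expect_identical(rep$rule_matches$status, "UNKNOWN")
  expect_identical(rep$profile_summary$unknown, 5L)
  expect_true(all(rep$allele_calls$status == "UNKNOWN"))
})

test_that("a reference-filled VCF profile calls *1 TRUE and triggers nothing", {
  kb <- build_fixture_kb()
  f <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", "S1"), collapse = "\t")), f)
  rep <- interpret(parse_vcf(f, kb), kb)
  expect_identical(rep$allele_calls$status[rep$allele_calls$label == "*1"], "TRUE")
  expect_identical(rep$allele_calls$status[rep$allele_calls$label == "*3"], "FALSE")
  expect_identical(rep$rule_matches$status, "FALSE")
})

test_that("interpretation is pure and survives the code round trip", {
  kb <- build_fixture_kb()
  layout <- build_layout(kb)
  p <- restrict_to_panel(rule9_profile(rs9923231 = NA), kb)
  r1 <- report_to_json(interpret(p, kb))
  r2 <- report_to_json(interpret(p, kb))
  expect_identical(r1, r2)
  decoded <- decode_code(encode_profile(p, layout), layout)
  expect_identical(report_to_json(interpret(decoded, kb)), r1)
})

test_that("monotone refinement: fixing an unknown marker never flips TRUE/FALSE", {
  for (seed in 1:20) {
    kb <- random_kb(seed)
    set.seed(seed + 1000)
    spec <- fixture_spec(n_markers = length(kb$markers), seed = seed + 2000,
                         missing_rate = 0.5, alt_freq = 0.4)
    p <- sample_profile(kb, spec)
    before <- match_rules(p, call_haplotypes(p, kb), kb)
    unknowns <- names(p$calls)[vapply(p$calls, function(g) {
      length(g) == 1L && is.na(g)
    }, NA)]
    if (length(unknowns) == 0L) next
    refined <- p
    r <- unknowns[1]
    refined$calls[[r]] <- sort(sample(kb$markers[[r]]$allowed, 2L, replace = TRUE))
    after <- match_rules(refined, call_haplotypes(refined, kb), kb)
    for (i in seq_len(nrow(before))) {
      if (before$status[i] != "UNKNOWN") {
        expect_identical(after$status[i], before$status[i])
      }
    }
  }
})

test_that("three-valued status equals the completion-enumeration oracle", {
  for (seed in 1:30) {
    kb <- random_kb(seed)
    p <- sample_profile(kb, fixture_spec(n_markers = length(kb$markers),
                                         seed = seed + 500,
                                         missing_rate = 0.4, alt_freq = 0.4))
    matches <- match_rules(p, call_haplotypes(p, kb), kb)
    for (i in seq_len(nrow(matches))) {
      rid <- matches$rule_id[i]
      expect_identical(
        matches$status[i],
        oracle_rule_status(kb$rules[[rid]]$condition, p, kb),
        info = sprintf("seed %d rule %s", seed, rid))
    }
  }
})
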