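fixture_kb_path <- function(dir = tempdir()) {
  path <- file.path(dir, "fixture-kb.json")
  write_kb(build_fixture_kb(), path)
  path
}

test_that("fixture KB loads with its haplotypes and rule intact", {
  kb <- load_kb(fixture_kb_path())
  expect_s3_class(kb, "pgx_kb")
  expect_setequal(names(kb$haplotypes), c("CYP2C9*1", "CYP2C9*3"))
  expect_named(kb$rules, "rule9")
  expect_identical(vapply(kb$haplotypes[["CYP2C9*3"]]$sufficient, format_atom, ""),
                   "rs1057910_C")
})

test_that("an empty-panel KB is valid and a dangling reference is an error", {
  f <- tempfile(fileext = ".json")
  writeLines('{"version":"0.1","build":"GRCh37","markers":[],"haplotypes":[],"rules":[]}', f)
  kb <- load_kb(f)
  expect_length(kb$markers, 0)
  expect_length(kb$rules, 0)

  bad <- tempfile(fileext = ".json")
  writeLines(paste0(
    '{"version":"0.1","build":"GRCh37","markers":[],"haplotypes":[],',
    '"rules":[{"rule_id":"r1","condition":{"has_some":"rs999_A"},"message":"m"}]}'), bad)
  err <- tryCatch(load_kb(bad), error = identity)
  expect_s3_class(err, "safetycode_reference_error")
  expect_match(conditionMessage(err), "rs999")
})

test_that("load rejects unsupported condition constructs and bad records", {
  f <- tempfile(fileext = ".json")
  writeLines(paste0(
    '{"version":"0.1","build":"GRCh37",',
    '"markers":[{"rsid":"rs1","chromosome":"1","position":10,"reference":"A","allowed":["A","C"]}],',
    '"haplotypes":[],',
    '"rules":[{"rule_id":"r1","condition":{"or":[{"has_some":"rs1_A"}]},"message":"m"}]}'), f)
  expect_error(load_kb(f), class = "safetycode_load_error")

  g <- tempfile(fileext = ".json")
  writeLines(paste0(
    '{"version":"0.1","build":"GRCh37",',
    '"markers":[{"rsid":"rs1","chromosome":"1","position":10,"reference":"C","allowed":["A","C"]}],',
    '"haplotypes":[],"rules":[]}'), g)
  err <- tryCatch(load_kb(g), error = identity)
  expect_s3_class(err, "safetycode_load_error")
  expect_match(conditionMessage(err), "rs1")
})

test_that("a tag set missing from the necessary set is repaired by union", {
  markers <- list(list(rsid = "rs1", chromosome = "1", position = 10L,
                       reference = "A", allowed = c("A", "C")),
                  list(rsid = "rs2", chromosome = "1", position = 20L,
                       reference = "G", allowed = c("G", "T")))
  expect_warning(
    kb <- new_kb(markers, haplotypes = list(list(
      gene = "G1", label = "*2",
      sufficient = list(variant_atom("rs1", "C")),
      necessary = list(variant_atom("rs2", "T"))))),
    "repaired by union")
  expect_setequal(vapply(kb$haplotypes[["G1*2"]]$necessary, format_atom, ""),
                  c("rs1_C", "rs2_T"))
})

test_that("satisfiable finds witnesses that actually satisfy the condition", {
  kb <- build_fixture_kb()
  res <- satisfiable(has_some("rs1057910_C"), kb)
  expect_true(res$satisfiable)
  expect_identical(res$witness$calls[["rs1057910"]], c("A", "C"))

  res2 <- satisfiable(has_exactly(2, "rs9923231_T"), kb)
  expect_true(res2$satisfiable)
  expect_identical(res2$witness$calls[["rs9923231"]], c("T", "T"))

  res3 <- satisfiable(cds_and(has_exactly(0, "rs1057910_C"),
                              has_some("rs1057910_C")), kb)
  expect_false(res3$satisfiable)
  expect_null(res3$witness)
})

test_that("check_consistency flags each defect category and nothing else", {
  kb <- build_fixture_kb()
  expect_identical(nrow(check_consistency(kb)), 0L)

  f1 <- check_consistency(inject_unsatisfiable_rule(kb))
  expect_identical(f1$category, "UNSATISFIABLE_RULE")
  expect_identical(f1$entity, "zz_injected_rule")

  f2 <- check_consistency(inject_non_entailing_tag(kb))
  expect_identical(f2$category, "TAG_NOT_ENTAILING")
  expect_identical(f2$entity, "INJGENE*9")

  f3 <- check_consistency(inject_unsatisfiable_haplotype(kb))
  expect_identical(f3$category, "UNSATISFIABLE_HAPLOTYPE")

  f4 <- check_consistency(inject_duplicate_definition(kb))
  expect_identical(f4$category, "DUPLICATE_DEFINITION")
  expect_match(f4$entity, "CYP2C9\\*77")
})

test_that("conditions over too many markers raise a capacity error, not a skip", {
  markers <- lapply(1:4, function(i) {
    list(rsid = sprintf("rs%d", i), chromosome = "1", position = i * 10L,
         reference = "A", allowed = c("A", "C"))
  })
  rule <- list(rule_id = "wide", message = "m",
               condition = cds_and(lapply(1:4, function(i) {
                 has_some(variant_atom(sprintf("rs%d", i), "C"))
               })))
  kb <- new_kb(markers, rules = list(rule))
  err <- tryCatch(check_consistency(kb, max_markers_per_check = 3L),
                  error = identity)
  expect_s3_class(err, "safetycode_capacity_error")
  expect_match(conditionMessage(err), "wide")
  expect_identical(nrow(check_consistency(kb, max_markers_per_check = 4L)), 0L)
})

test_that("findings are deterministic and ordered by category then entity", {
  kb <- inject_duplicate_definition(inject_unsatisfiable_rule(random_kb(99)))
  f1 <- check_consistency(kb)
  f2 <- check_consistency(kb)
  expect_identical(f1, f2)
  expect_identical(f1$category, sort(f1$category))
})

test_that("KB serialization round-trips byte-identically", {
  kb <- generate_synthetic_kb(fixture_spec(n_markers = 12, seed = 3))
  f1 <- tempfile(); f2 <- tempfile()
  write_kb(kb, f1)
  write_kb(load_kb(f1), f2)
  expect_identical(readLines(f1), readLines(f2))
})
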