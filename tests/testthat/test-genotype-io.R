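mini_23andme <- function(lines) {
  f <- tempfile(fileext = ".txt")
  writeLines(lines, f)
  f
}

test_that("detect_format recognizes VCF magic, 23andMe shape, and neither", {
  expect_identical(detect_format(mini_23andme("##fileformat=VCFv4.2")), "vcf")
  expect_identical(detect_format(mini_23andme(c(
    "# This data file generated by 23andMe",
    "rs1057910\t10\t96741053\tAC"))), "23andme")
  expect_identical(detect_format(mini_23andme("hello world")), "unknown")
  expect_error(detect_format(mini_23andme(character())),
               class = "safetycode_format_error")
})

test_that("23andMe parsing handles calls, no-calls, indels and orientation", {
  f <- mini_23andme(c(
    "# comment",
    "rs1057910\t10\t96741053\tAC",
    "rs12345\t1\t100\t--",
    "rs22222\t2\t200\tDI",
    "rs33333\tX\t300\tT",
    "i4000690\t1\t400\tGG"))
  p <- suppressMessages(parse_23andme(f))
  expect_identical(p$calls[["rs1057910"]], c("A", "C"))
  expect_true(is.na(p$calls[["rs12345"]]))
  expect_true(is.na(p$calls[["rs22222"]]))
  expect_identical(p$calls[["rs33333"]], c("T", "T"))  # hemizygous chrX
  expect_false("i4000690" %in% names(p$calls))

  rev <- suppressMessages(parse_23andme(f, orientation = "reverse"))
  expect_identical(rev$calls[["rs1057910"]], c("G", "T"))

  expect_error(suppressMessages(parse_23andme(mini_23andme("rs1\t1\t2"))),
               class = "safetycode_parse_error")
  expect_warning(parse_23andme(mini_23andme("rs5\t7\t100\tA")),
                 "single-base")
})

test_that("strand flip is an involution", {
  spec <- fixture_spec(n_markers = 30, seed = 5, missing_rate = 0.1)
  kb <- generate_synthetic_kb(spec)
  paths <- write_profile_files(sample_profile(kb, spec), kb, tempfile())
  fwd <- parse_23andme(paths[["twentythree"]])
  rev <- parse_23andme(paths[["twentythree"]], orientation = "reverse")
  flip_again <- genotype_profile(lapply(rev$calls, function(g) {
    if (length(g) == 1L && is.na(g)) NA_character_
    else unname(c(A = "T", C = "G", G = "C", T = "A")[g])
  }), source_format = "23andme")
  expect_identical(format(flip_again), format(fwd))
})

vcf_stream <- function(records, header_samples = "SAMPLE1") {
  f <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", header_samples), collapse = "\t"),
               records), f)
  f
}

test_that("VCF GT semantics resolve diploid pairs against REF/ALT", {
  kb <- build_fixture_kb()
  p <- parse_vcf(vcf_stream(
    "10\t96741053\trs1057910\tA\tC\t.\t.\t.\tGT\t0/1"), kb)
  expect_identical(p$calls[["rs1057910"]], c("A", "C"))

  p2 <- parse_vcf(vcf_stream(
    "10\t96741053\trs1057910\tA\tC\t.\t.\t.\tGT\t1|1"), kb)
  expect_identical(p2$calls[["rs1057910"]], c("C", "C"))

  # position fallback when the ID column is "."
  p3 <- parse_vcf(vcf_stream(
    "16\t31107689\t.\tC\tT\t.\t.\t.\tGT\t1/1"), kb)
  expect_identical(p3$calls[["rs9923231"]], c("T", "T"))

  p4 <- parse_vcf(vcf_stream(
    "10\t96741053\trs1057910\tA\tC\t.\t.\t.\tGT\t./."), kb)
  expect_true(is.na(p4$calls[["rs1057910"]]))
  expect_warning(
    p5 <- parse_vcf(vcf_stream(
      "10\t96741053\trs1057910\tA\tC\t.\t.\t.\tGT\t0/."), kb),
    "half-call")
  expect_true(is.na(p5$calls[["rs1057910"]]))
})

test_that("missing-means-reference fills the whole panel on an empty VCF", {
  kb <- build_fixture_kb()
  p <- parse_vcf(vcf_stream(character()), kb)
  expect_identical(unname(format(p)), c("AA", "AA", "CC", "AA", "CC"))
  expect_false(any(vapply(p$calls, function(g) length(g) == 1L && is.na(g), NA)))
})

test_that("multi-sample VCFs and off-allowed ALT alleles are handled", {
  kb <- build_fixture_kb()
  expect_error(parse_vcf(vcf_stream("10\t1\t.\tA\tC\t.\t.\t.\tGT\t0/1\t0/0",
                                    header_samples = "S1\tS2"), kb),
               class = "safetycode_parse_error")
  expect_warning(
    p <- parse_vcf(vcf_stream("10\t96741053\trs1057910\tA\tG\t.\t.\t.\tGT\t1/1"), kb),
    "allowed")
  expect_true(is.na(p$calls[["rs1057910"]]))
  expect_warning(
    p2 <- parse_vcf(vcf_stream("10\t96741053\trs1057910\tA\tAT\t.\t.\t.\tGT\t0/1"), kb),
    "indel")
  expect_identical(p2$calls[["rs1057910"]], c("A", "A"))
})

test_that("restrict_to_panel is idempotent and exactly matches the panel", {
  kb <- build_fixture_kb()
  p <- genotype_profile(list(rs1057910 = c("A", "C"), rs55555 = c("G", "G")))
  r1 <- suppressMessages(restrict_to_panel(p, kb))
  expect_identical(names(r1$calls), names(kb$markers))
  expect_true(is.na(r1$calls[["rs9923231"]]))
  r2 <- restrict_to_panel(r1, kb)
  expect_identical(format(r2), format(r1))

  empty <- restrict_to_panel(genotype_profile(list()), kb)
  expect_true(all(vapply(empty$calls, function(g) length(g) == 1L && is.na(g), NA)))
})

test_that("both fixture writers round-trip through their parsers", {
  spec <- fixture_spec(n_markers = 40, seed = 17, missing_rate = 0.15,
                       alt_freq = 0.35)
  kb <- generate_synthetic_kb(spec)
  profile <- sample_profile(kb, spec)
  paths <- write_profile_files(profile, kb, tempfile())
  p23 <- restrict_to_panel(parse_23andme(paths[["twentythree"]]), kb)
  pv <- parse_vcf(paths[["vcf"]], kb)
  expect_identical(format(p23), format(profile))
  expect_identical(format(pv), format(profile))
})
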