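test_that("layout widths follow the ceil-log2 genotype-count formula", {
  kb <- build_fixture_kb()
  layout <- build_layout(kb)
  expect_identical(layout$slots$rsid, names(kb$markers))   # panel order
  expect_true(all(layout$slots$bit_width == 2L))           # biallelic: G=3
  expect_identical(layout$total_bits, 10L)
  expect_identical(layout$slots$bit_offset,
                   cumsum(c(0L, head(layout$slots$bit_width, -1L))))

  # a 3-allele marker has G = 6 pairs -> 3 bits
  kb3 <- new_kb(list(list(rsid = "rs1", chromosome = "1", position = 1L,
                          reference = "A", allowed = c("A", "C", "G"))))
  expect_identical(build_layout(kb3)$slots$bit_width, 3L)

  empty <- new_kb()
  expect_identical(build_layout(empty)$total_bits, 0L)
  expect_identical(encode_profile(genotype_profile(list()),
                                  build_layout(empty))$payload, "")
})

three_marker_kb <- function() {
  new_kb(lapply(1:3, function(i) {
    list(rsid = sprintf("rs%d", i), chromosome = "1", position = i * 10L,
         reference = "A", allowed = c("A", "C"))
  }), version = "0.2")
}

test_that("the hand-computed 3-marker example encodes to payload 'Y'", {
  # indices {A,A}=1, {A,C}=2, UNKNOWN=0 -> bits 01 10 00 -> 011000 = 24 -> "Y"
  kb <- three_marker_kb()
  layout <- build_layout(kb)
  p <- genotype_profile(list(rs1 = c("A", "A"), rs2 = c("A", "C"), rs3 = NA))
  code <- encode_profile(p, layout)
  expect_identical(code$payload, "Y")
  expect_identical(code_url(code), "http://safety-code.org/v0.2/Y")
  back <- decode_code(code, layout)
  expect_identical(unname(format(back)), c("AA", "AC", "??"))
})

test_that("an all-unknown profile yields an all-'A' payload", {
  kb <- generate_synthetic_kb(fixture_spec(n_markers = 50, seed = 2))
  layout <- build_layout(kb)
  p <- restrict_to_panel(genotype_profile(list()), kb)
  code <- encode_profile(p, layout)
  expect_identical(code$payload,
                   paste(rep("A", ceiling(layout$total_bits / 6)), collapse = ""))
})

test_that("decode distinguishes alphabet, length and version errors", {
  layout <- build_layout(three_marker_kb())
  expect_error(decode_code(safety_code("AA"), layout), "length",
               class = "safetycode_decode_error")
  expect_error(safety_code("Y+"), "alphabet",
               class = "safetycode_decode_error")
  expect_error(decode_code(safety_code("Y", version = "v9.9"), layout),
               "version", class = "safetycode_decode_error")

  # slot index beyond the genotype table: a 3-allele marker has 6 pairs in a
  # 3-bit slot, so bits 111 (index 7) cannot decode
  kb3 <- new_kb(list(list(rsid = "rs1", chromosome = "1", position = 1L,
                          reference = "A", allowed = c("A", "C", "G"))),
                version = "0.2")
  expect_error(decode_code(safety_code("4"), build_layout(kb3)),  # 111000
               "exceeds", class = "safetycode_decode_error")
  # non-zero padding bits past total_bits are corruption, not silence
  expect_error(decode_code(safety_code("B"), build_layout(kb3)),  # 000001
               "padding", class = "safetycode_decode_error")
})

test_that("URL parsing splits base, version and payload", {
  sc <- parse_url("http://safety-code.org/v0.2/QXGqrLF2h8xuqzIyCGJE2hz")
  expect_identical(sc$version, "v0.2")
  expect_identical(sc$base_url, "http://safety-code.org/")
  expect_true(startsWith(sc$payload, "QXGqrLF2h8xu"))
  sc2 <- parse_url("http://host/v9.9/AAAA")
  expect_identical(sc2$version, "v9.9")
  expect_identical(sc2$payload, "AAAA")
  expect_error(parse_url("http://host/AAAA"), class = "safetycode_parse_error")
})

test_that("decode(encode(p)) is the identity on random panel profiles", {
  spec <- fixture_spec(n_markers = 60, seed = 21, missing_rate = 0.2,
                       alt_freq = 0.4)
  kb <- generate_synthetic_kb(spec)
  layout <- build_layout(kb)
  for (s in 1:25) {
    p <- sample_profile(kb, fixture_spec(n_markers = 60, seed = s,
                                         missing_rate = 0.2, alt_freq = 0.4))
    expect_identical(format(decode_code(encode_profile(p, layout), layout)),
                     format(p))
  }
})

test_that("two loads of the same KB give bit-identical layouts and codes", {
  f <- tempfile()
  write_kb(generate_synthetic_kb(fixture_spec(n_markers = 30, seed = 9)), f)
  kb1 <- load_kb(f); kb2 <- load_kb(f)
  p <- sample_profile(kb1, fixture_spec(n_markers = 30, seed = 4))
  c1 <- encode_profile(p, build_layout(kb1))
  c2 <- encode_profile(p, build_layout(kb2))
  expect_identical(code_url(c1), code_url(c2))
})

test_that("profiles with out-of-set nucleotides refuse to encode", {
  kb <- three_marker_kb()
  layout <- build_layout(kb)
  p <- genotype_profile(list(rs1 = c("G", "G"), rs2 = NA, rs3 = NA))
  err <- tryCatch(encode_profile(p, layout), error = identity)
  expect_s3_class(err, "safetycode_encode_error")
  expect_match(conditionMessage(err), "rs1")
})
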