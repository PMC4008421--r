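Package: safetycode
Title: Encode, Decode and Interpret Pharmacogenomic Medicine Safety Codes
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for representing a patient's pharmacogenomic marker
    genotypes as a compact, versioned Medicine Safety Code: a bit-packed,
    base64url-encoded URL rendered as a QR code. Parses 23andMe and VCF
    genotype files into a normalized diploid profile (applying the
    missing-means-reference convention for variant-only VCFs), encodes and
    decodes profiles against a deterministic per-marker bit layout, and
    interprets profiles against a formal knowledge base of star-allele
    (tag-SNP) definitions and clinical decision-support rules using
    three-valued logic, so that "rule does not apply" and "insufficient
    data" stay distinct. Includes a brute-force finite-domain consistency
    checker for the knowledge base, a self-contained QR symbol encoder with
    the full symbol capacity table, fixture generators for fully offline
    testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
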