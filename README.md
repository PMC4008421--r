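# safetycode

Pharmacogenomic test results are only useful at the point of care if they can
travel with the patient in a compact, machine-readable form and be turned back
into concrete dosing guidance on the spot. `safetycode` implements a complete
desk-scale version of that pipeline — the *Medicine Safety Code* idea — for
clinical-pharmacogenomics researchers and tool builders:

* **Genotype input.** Parsers for the two common consumer/clinical formats:
  23andMe raw-data files (with selectable strand orientation) and
  single-sample VCF, where a panel marker absent from a variant-only VCF is
  taken as homozygous reference (*missing-means-reference*).
* **The code itself.** A deterministic bit layout over the marker panel: a
  marker with G unordered diploid genotypes gets a ⌈log₂(G+1)⌉-bit slot
  (index 0 ≡ unknown, genotype pairs in lexicographic order), slots
  concatenated in panel order, zero-padded to 6-bit groups, base64url-encoded
  and embedded in a versioned URL
  (`http://safety-code.org/v0.2/<payload>`), rendered as a QR symbol by a
  self-contained ISO/IEC 18004 byte-mode encoder (Reed–Solomon error
  correction over GF(2⁸), penalty-scored mask selection).
* **Interpretation.** A knowledge base of star-allele definitions
  (tag-SNP *sufficient* atoms and full *necessary* variant sets, the
  equivalent-class/subclass pattern of ontology-based pharmacogenomics) and
  clinical decision-support rules — conjunctions of `has some rsNNN_X`,
  `has exactly n rsNNN_X` and `has haplotype GENE*k` atoms. Rules are
  evaluated with strong-Kleene three-valued logic so that *"rule does not
  apply"* and *"not enough genotype data"* stay distinct.
* **Knowledge-base quality control.** `check_consistency()` decides, by
  exhaustive enumeration of the diploid genotype space, whether any
  haplotype or rule is unsatisfiable, any tag set cannot entail its
  necessary variants, or two alleles are duplicates — a finite-domain
  replacement for description-logic consistency checking.

Everything needed for testing is generated offline: a worked-example KB
(CYP2C9*1/*3, the warfarin starting-dose rule over rs9923231, a 58-gene panel
list) plus synthetic panel padding up to the deployed 385-marker size.

## Worked example

Encode a genotype carrying one CYP2C9\*3-defining variant copy
(rs1057910 A/C), reference nucleotides at the other \*3-necessary positions,
and the homozygous VKORC1 promoter variant (rs9923231 T/T), then decode and
interpret it:

```r
library(safetycode)

kb      <- build_fixture_kb()
layout  <- build_layout(kb)
profile <- restrict_to_panel(genotype_profile(list(
  rs1057910 = c("A", "C"), rs1057911 = c("A", "A"), rs1799853 = c("C", "C"),
  rs2256871 = c("A", "A"), rs9923231 = c("T", "T"))), kb)

(code <- encode_profile(profile, layout))
#> http://safety-code.org/v0.2/lc

render_qr(code, "msc.png", ec_level = "M")$version
#> [1] 3

interpret(decode_code(code, layout), kb)
#> Interpretation report (KB version 0.2)
#> Markers: 5 known / 0 unknown of 5
#>
#> Allele calls:
#>   CYP2C9*1: TRUE
#>   CYP2C9*3: TRUE
#>
#> Decision-support rules:
#>   rule9: TRUE
#>     message: 0.5–2 mg warfarin per day should be considered as a starting
#>     dose range for a patient with this genotype according to the warfarin
#>     drug label.
#>     source: FDA drug label (Coumadin, Bristol-Myers Squibb)
```

The five-marker panel packs into 10 bits → a 2-character payload; both
CYP2C9 alleles are called present (unphased data cannot distinguish cis from
trans, so presence of a *1-defining and a *3-defining chromosome is reported
as a compound), and the warfarin starting-dose rule triggers. Flipping
rs9923231 to C/T un-triggers it; masking rs9923231 to unknown instead yields
status `UNKNOWN` with `missing_markers = rs9923231`.

The same pipeline is scriptable via the CLI wrapper at `inst/cli/msc`
(subcommands `encode`, `decode`, `interpret`, `validate-kb`,
`gen-fixtures`).

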