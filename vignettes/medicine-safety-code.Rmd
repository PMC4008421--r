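---
title: "Medicine Safety Codes: model, semantics, and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Medicine Safety Codes: model, semantics, and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(safetycode)
```

## The problem

Genotype-guided prescribing needs three things in one loop: a patient's
pharmacogenomic marker genotypes in a portable, anonymous form; a formal
knowledge base mapping genotypes to named star alleles and to guideline
recommendations; and an evaluation step that is honest about missing data.
`safetycode` implements that loop end to end: genotype file → normalized
diploid profile → bit-packed, base64url-encoded, versioned URL rendered as a
QR symbol → decoded profile → allele calls and triggered recommendations.

The data model is deliberately anonymous by construction: a profile is a map
from dbSNP identifiers to unordered nucleotide pairs and nothing else; no
identity field exists anywhere in the package.

## The knowledge base

A knowledge base (KB) holds three layers.

**Markers** form the panel: each has an rsid, chromosome, 1-based position
on a named reference build, and an ordered allowed-nucleotide set whose
first element is the reference nucleotide. All nucleotides are expressed on
the forward strand of the reference build; panel order is total and drives
the code layout.

**Haplotypes (star alleles)** follow the tag-SNP pattern used by
ontology-based pharmacogenomics resources: a *sufficient* atom set (the tags
whose joint presence identifies the allele — the equivalent-class side) and
a *necessary* atom set (every variant known to lie on the allele — the
subclass side). An atom `rsNNN_X` is read existentially over the unphased
pair: "at least one of the two observed nucleotides at rsNNN is X".
Reference alleles such as CYP2C9\*1 have no published tag axiom, so the
bundled KB defines \*1 as the reference nucleotides at the \*2/\*3-defining
positions and marks the definition `invented` in its metadata; this is a
documented convention, not a transcribed fact.

**Decision rules** attach a free-text recommendation and a source citation
to a condition. The condition language is exactly the fragment the printed
axioms use: conjunction over `has_some(atom)`, `has_exactly(n, atom)` with
n ∈ {0, 1, 2} (diploid copy counts), and `has_haplotype(GENE*k)`.
Disjunction and negation are intentionally absent, and their appearance in a
KB file is a load error rather than a silent extension.

A haplotype whose tag set is not contained in its necessary set is repaired
at load by uniting the sets (with a warning): a tag that identifies the
allele is by definition also on it.

## Consistency checking as finite-domain satisfiability

Description-logic systems detect modeling errors by reasoning over the
ontology. Here the genotype domain is finite — each marker takes one of
G = k(k+1)/2 unordered pairs over its k allowed nucleotides — so
satisfiability of any condition can be decided exactly by enumerating the
product space over the markers it references. `check_consistency()` reports:

* **UNSATISFIABLE_HAPLOTYPE** — no complete diploid genotype satisfies the
  tag conjunction (e.g. three distinct required nucleotides at one locus);
* **TAG_NOT_ENTAILING** — the tag conjunction is satisfiable, but no
  genotype satisfies tags *and* all necessary atoms jointly, so the tags can
  never identify a genotype consistent with the allele's full variant set;
* **DUPLICATE_DEFINITION** — two alleles of one gene with identical tag sets;
* **UNSATISFIABLE_RULE** — a rule no genotype can trigger.

The definition of TAG_NOT_ENTAILING deserves a note, because the design was
genuinely open. A stricter reading — "some genotype satisfies the tags while
some necessary atom is false" — sounds natural but is vacuous in practice:
any allele whose necessary set mentions a second marker would be flagged,
including the textbook CYP2C9\*3 definition (a genotype can carry the
rs1057910 C tag while being homozygous variant at rs1799853). The joint-
satisfiability reading flags exactly the definitions that are *internally*
broken, keeps the textbook definition clean, and still catches every
impossible necessary atom; conflicts between an individual's genotype and a
called allele's necessary set are reported per patient instead, as the
`conflict` flag on the allele call.

`max_markers_per_check` (default 12) caps the number of distinct markers a
single condition may reference before enumeration is refused with an error —
never skipped silently. At 12 biallelic markers the space is 3¹² ≈ 5·10⁵
genotypes, enumerable in seconds; real tag sets reference far fewer.

Findings are sorted by category name, then entity id, so reports are
byte-identical across runs.

## Three-valued evaluation

Consumer files contain no-calls, and a decoded code can carry unknown slots.
Evaluation therefore uses strong-Kleene three-valued logic: an atom over an
unknown genotype is UNKNOWN; conjunction is FALSE if any conjunct is FALSE,
TRUE if all are TRUE, else UNKNOWN. A rule reported UNKNOWN lists every
unknown marker reachable from its condition, so the caller knows which
genotyping would resolve it. Whether partially-matched rules should be shown
at all was an open question; reporting them with an explicit UNKNOWN status
is this package's answer, because hiding "cannot tell" behind "not
triggered" is the unsafe direction.

The semantics has a precise correctness property. Say a rule's *completion
status* is TRUE if its condition holds under **every** completion of the
unknown referenced markers, FALSE if under none, else UNKNOWN. For any rule
whose flattened atom conjunction is satisfiable, Kleene status equals
completion status:

* Kleene TRUE/FALSE always agree with all completions (monotonicity).
* If Kleene says UNKNOWN (no conjunct FALSE, some UNKNOWN), then (i) some
  completion falsifies the condition — every atom kind has a falsifying
  pair because each marker allows ≥ 2 nucleotides — and (ii) some completion
  satisfies it: take a witness of the conjunction and restrict it to the
  unknown markers; atoms are per-marker, so it composes with the known calls.

The proviso matters: for a *contradictory* condition (e.g.
`has_exactly(0, rs1_A) and has_some(rs1_A)`) every completion is FALSE while
Kleene can only reach UNKNOWN. Those conditions are exactly what
`check_consistency()` flags as unsatisfiable, so the package's position is:
run the checker on the KB; on a KB with no unsatisfiability findings,
three-valued evaluation is exact. The test suite verifies the equivalence
against exhaustive completion enumeration on 200 randomly generated KBs
(≤ 6 markers, ≤ 3 alleles per marker, conditions made satisfiable by
construction: a witness genotype is drawn first and atoms are emitted
consistent with it), and separately verifies that the checker detects 100%
of seeded contradictions and non-entailing tag sets.

Allele calling is presence calling, not diplotype assignment: on unphased
data, a genotype carrying one \*1-defining and one \*3-defining chromosome
makes both `CYP2C9*1` and `CYP2C9*3` TRUE. This over-calls compound
diplotypes in the cis/trans-ambiguous cases — a faithful consequence of the
existential atom semantics, stated rather than patched.

## The code layout

The deployed system's v0.2 bit layout was never published; the layout here
is a fully specified dialect of the same construction, documented so that
any implementation can reproduce it:

* one slot per panel marker, in panel order;
* slot width ⌈log₂(G+1)⌉ bits, where G is the marker's unordered-pair count
  (biallelic → 3 pairs → 2 bits; 385 biallelic markers → 770 bits);
* genotype index 0 is always "unknown"; pairs are indexed from 1 in
  lexicographic (min, max) order;
* indices are written MSB-first, the bit string is zero-padded to a multiple
  of 6, and 6-bit groups map through the base64url alphabet (chosen because
  published example payloads contain `-` and `_`);
* the payload is served as `<base_url>v<version>/<payload>`; the version is
  checked at decode and a mismatch is an error, not a fallback.

Consequently a historical v0.2 URL parses (`parse_url()`) but does not
decode against this dialect's layout — decoding requires the KB the code
was built from. Alphabet, length and version violations are distinguished in
decode errors; non-zero padding bits and out-of-table slot indices are
treated as corruption.

## QR rendering

No QR encoder exists in the dependency stack, so the package carries a
complete byte-mode ISO/IEC 18004 implementation: the 40 × 4 capacity/block
table, Reed–Solomon error correction over GF(2⁸) (polynomial 0x11D),
block interleaving, zigzag placement, the eight data masks scored by the
four penalty rules, and BCH-protected format/version fields. Design
choices: byte mode (URLs are not alphanumeric-mode safe), default
error-correction level M as a print-robustness/size balance (overridable),
smallest sufficient version selected automatically. The embedded block
table is cross-checked in the test suite against codeword totals derived
independently from symbol geometry for all 160 version/level combinations,
and format/version fields reproduce published BCH test vectors. Structural
correctness is verified by a built-in symbol reader (unmask → de-interleave
→ syndrome check → byte-stream re-parse) rather than an external scanner,
since no decoding utility is available in the dependency stack; scanning
the rendered PNGs with a phone is the recommended manual spot check.

## Genotype input conventions

* 23andMe: tab-separated rsid/chromosome/position/genotype; `--`, `I`, `D`
  become unknown; internal non-rs ids are skipped; a single-base call is
  hemizygous (stored as a homozygous pair) on X/Y/MT and a warned unknown on
  autosomes. The orientation flag (default `forward`) is the caller's
  assertion about the file's strand; `reverse` complements every base. The
  per-marker orientation tables some arrays would need are out of scope.
* VCF: single-sample v4.x with a GT subfield; `/` and `|` both accepted,
  phase ignored; records matched by rsid with a (chromosome, position)
  fallback; `./.` unknown, half-calls warned unknown, indel/structural
  records skipped with a warning; multi-sample files are refused with an
  instruction to subset. Every unmatched panel marker becomes homozygous
  reference — the variant-only convention — so an empty VCF yields a total,
  reference-homozygous panel profile.

## Fixtures: what they emulate and what they do not

The worked-example KB transcribes the published CYP2C9\*3 axiom (tag
`rs1057910_C`; necessary `rs1057910_C`, `rs1057911_A`, `rs1799853_C`,
`rs2256871_A`), the warfarin starting-dose rule
(\*1 present ∧ \*3 present ∧ exactly 2 × `rs9923231_T`) with its verbatim
message, and the 58-gene panel list. Marker coordinates are GRCh37
forward-strand dbSNP records. The full deployed 385-marker list was never
published, so `generate_synthetic_kb()` pads the panel with deterministic
biallelic markers in an obviously fake rsid namespace (`rs99…`), each with a
\*1/\*2 allele pair on a synthetic gene.

`sample_profile()` draws each nucleotide independently with alternate-allele
frequency `alt_freq` (default 0.2) and masks calls to unknown with
probability `missing_rate` (default 0.02, a typical array no-call rate).
This emulates panel-scale data volume and missingness only: there is no
linkage structure, no population allele-frequency spectrum, no genotyping
error model. Passing tests therefore demonstrate correctness of encoding,
evaluation and bookkeeping — not clinical validity of calls on real arrays,
which additionally depends on per-marker strand curation and KB curation
quality.

Default fixture sizes mirror the deployed scale (385 markers, 58 genes);
property suites use 200 random KBs of ≤ 6 markers (where exhaustive oracles
are cheap) and 500 random panel-scale profiles for the codec round trip.
All generators are pure functions of their seed; RNG state is saved and
restored around them.

## Degenerate inputs and tie-breaks

Empty-panel KBs are valid (zero-bit layout, empty payload); empty profiles
restrict to all-unknown panels; an all-unknown profile encodes to an
all-`A` payload. `satisfiable()` returns the first witness in deterministic
enumeration order (first marker varies slowest). QR mask selection breaks
penalty ties toward the lower mask number. Reports order genes
alphabetically and rules by id, making `interpret()` a pure function:
identical inputs yield byte-identical JSON.

## Known limitations

* No diplotype phasing, no phenotype (metabolizer-status) layer, no
  drug–drug(–gene) interactions, no indel/repeat polymorphisms, no genome
  build liftover, no imputation beyond the VCF reference rule.
* The condition language is purely conjunctive; guidelines needing
  disjunction must be split into multiple rules.
* Allele-level (rather than raw-genotype) payload encoding would shrink
  codes further; it is a possible second dialect, not implemented.
* The KB ships as a worked example plus synthetic padding; it is a formal
  stand-in, not a curated clinical knowledge base, and nothing here is
  medical advice or a certified medical device.
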