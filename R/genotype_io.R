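# Patient genotype input: 23andMe raw-data files and single-sample VCF,
# normalized into a diploid profile with explicit unknowns.

#' Diploid genotype profile
#'
#' A normalized per-marker genotype map: each call is an unordered pair of
#' nucleotides (stored sorted), or `NA` for an unknown/no-call. Calls are
#' unphased; the pair carries multiplicity (a homozygote is `c("A","A")`).
#'
#' @param calls Named list (names = rsids); each element a character vector of
#'   2 nucleotides, a single nucleotide (stored as a homozygous pair — the
#'   convention for hemizygous chrX/chrY/MT calls), or `NA` for unknown.
#' @param source_format One of `"23andme"`, `"vcf"`, `"code"`, `"manual"`.
#' @param build Reference-genome label, or `""` when unknown.
#' @return A `genotype_profile` object.
#' @examples
#' genotype_profile(list(rs1057910 = c("A", "C"), rs9923231 = NA))
#' @export
genotype_profile <- function(calls = list(), source_format = "manual",
                             build = "") {
  source_format <- match.arg(source_format, c("23andme", "vcf", "code", "manual"))
  if (length(calls) > 0L && is.null(names(calls))) {
    stop_sc("profile calls must be a named list keyed by rsid",
            "safetycode_profile_error")
  }
  calls <- lapply(calls, normalize_call)
  structure(list(calls = calls, source_format = source_format, build = build),
            class = "genotype_profile")
}

normalize_call <- function(x) {
  if (length(x) == 1L && is.na(x)) return(NA_character_)
  x <- toupper(as.character(x))
  if (length(x) == 1L) x <- c(x, x)   # hemizygous -> homozygous pair
  if (length(x) != 2L || !all(x %in% NUCLEOTIDES)) {
    stop_sc(sprintf("invalid genotype call '%s'", paste(x, collapse = "")),
            "safetycode_profile_error")
  }
  sort(x)
}

is_unknown_call <- function(x) length(x) == 1L && is.na(x)

#' @export
print.genotype_profile <- function(x, ...) {
  n_unk <- sum(vapply(x$calls, is_unknown_call, NA))
  cat(sprintf("<genotype_profile: %d markers (%d unknown), source %s%s>\n",
              length(x$calls), n_unk, x$source_format,
              if (nzchar(x$build)) paste0(", build ", x$build) else ""))
  invisible(x)
}

#' @export
format.genotype_profile <- function(x, ...) {
  vapply(x$calls, function(g) {
    if (is_unknown_call(g)) "??" else paste(g, collapse = "")
  }, "")
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

read_text_lines <- function(stream) {
  if (inherits(stream, "connection")) readLines(stream, warn = FALSE)
  else readLines(stream, warn = FALSE)
}

#' Detect a genotype file format
#'
#' Inspects the content, not the file name: a `##fileformat=VCF` magic line
#' means VCF; 4-column tab-separated lines whose first column is an rs
#' identifier (after skipping `#` comments) mean 23andMe; anything else is
#' `"unknown"`.
#'
#' @param stream File path or text connection.
#' @return `"vcf"`, `"23andme"` or `"unknown"`.
#' @export
detect_format <- function(stream) {
  lines <- read_text_lines(stream)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop_sc("empty input: cannot detect genotype format", "safetycode_format_error")
  }
  if (startsWith(lines[1], "##fileformat=VCF")) return("vcf")
  data_lines <- lines[!startsWith(lines, "#")]
  if (length(data_lines) > 0L) {
    fields <- strsplit(data_lines[1], "\t", fixed = TRUE)[[1]]
    if (length(fields) == 4L && grepl("^rs[0-9]+$", fields[1])) return("23andme")
  }
  "unknown"
}

#' Parse a 23andMe raw-data file
#'
#' Each data line is `rsid<TAB>chromosome<TAB>position<TAB>genotype` with the
#' genotype given as 1–2 characters from `A/C/G/T/-/I/D`. No-calls (`--`) and
#' indel calls (`I`/`D`) become unknown; a single-base genotype on an
#' autosome is recorded as unknown with a warning, while on X/Y/MT it is
#' stored as a homozygous pair. Non-rs identifiers (internal `i` ids) are
#' skipped. With `orientation = "reverse"` every nucleotide is complemented
#' before storage — the caller's assertion that the file reports the opposite
#' strand from the knowledge base's forward-strand convention.
#'
#' @param stream File path or text connection.
#' @param orientation `"forward"` (default) or `"reverse"`.
#' @return A [genotype_profile()] with `source_format = "23andme"`.
#' @export
parse_23andme <- function(stream, orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  lines <- read_text_lines(stream)
  calls <- list()
  skipped <- 0L
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(trimws(line)) || startsWith(line, "#")) next
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) != 4L) {
      stop_sc(sprintf("line %d: expected 4 tab-separated columns, got %d",
                      i, length(fields)), "safetycode_parse_error")
    }
    rsid <- fields[1]
    if (!grepl("^rs[0-9]+$", rsid)) {
      skipped <- skipped + 1L
      next
    }
    chrom <- fields[2]
    gt <- toupper(fields[4])
    chars <- strsplit(gt, "")[[1]]
    if (length(chars) < 1L || length(chars) > 2L ||
        any(!chars %in% c(NUCLEOTIDES, "-", "I", "D"))) {
      stop_sc(sprintf("line %d: malformed genotype '%s'", i, gt),
              "safetycode_parse_error")
    }
    if (any(chars %in% c("-", "I", "D"))) {
      calls[[rsid]] <- NA_character_
      next
    }
    if (orientation == "reverse") chars <- unname(COMPLEMENT[chars])
    if (length(chars) == 1L) {
      if (chrom %in% c("X", "Y", "MT", "M")) {
        calls[[rsid]] <- c(chars, chars)
      } else {
        warning(sprintf("line %d: single-base genotype for autosomal %s; recorded as unknown",
                        i, rsid), call. = FALSE)
        calls[[rsid]] <- NA_character_
      }
      next
    }
    calls[[rsid]] <- chars
  }
  if (skipped > 0L) {
    message(sprintf("parse_23andme: skipped %d non-rs identifier line(s)", skipped))
  }
  genotype_profile(calls, source_format = "23andme")
}

#' Parse a single-sample VCF into a panel profile
#'
#' Reads a VCF v4.x stream and resolves, for every marker in the KB panel, a
#' diploid genotype via the record's `GT` subfield and `REF`/`ALT` columns.
#' Records are matched to panel markers by the `ID` column (rsid), falling
#' back to (chromosome, position). Both `/` and `|` genotype separators are
#' accepted; phase is ignored.
#'
#' Variant-only VCFs are the norm, so every panel marker with no matching
#' record is assumed homozygous for the marker's reference nucleotide
#' (the missing-means-reference convention). `./.` yields unknown; half calls
#' (`0/.`) yield unknown with a warning; an ALT allele outside the marker's
#' allowed set yields unknown with a warning. Indel and structural-variant
#' records are skipped with a warning.
#'
#' @param stream File path or text connection.
#' @param kb A `pgx_kb` supplying the marker panel and reference nucleotides.
#' @return A panel-complete [genotype_profile()] with `source_format = "vcf"`.
#' @export
parse_vcf <- function(stream, kb) {
  lines <- read_text_lines(stream)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L || !startsWith(lines[1], "##fileformat=VCF")) {
    stop_sc("not a VCF stream (missing ##fileformat meta-information)",
            "safetycode_parse_error")
  }
  header_i <- which(startsWith(lines, "#CHROM"))
  if (length(header_i) != 1L) {
    stop_sc("VCF header line (#CHROM ...) missing", "safetycode_parse_error")
  }
  header <- strsplit(lines[header_i], "\t", fixed = TRUE)[[1]]
  if (length(header) < 10L) {
    stop_sc("VCF has no sample column (FORMAT + one sample required)",
            "safetycode_parse_error")
  }
  if (length(header) > 10L) {
    stop_sc(sprintf(
      "multi-sample VCF (%d samples); extract one sample first (e.g. bcftools view -s NAME)",
      length(header) - 9L), "safetycode_parse_error")
  }

  by_pos <- list()
  for (m in kb$markers) {
    by_pos[[paste(sub("^chr", "", m$chromosome), m$position)]] <- m$rsid
  }

  calls <- list()
  for (m in kb$markers) calls[[m$rsid]] <- c(m$reference, m$reference)

  for (line in lines[-seq_len(header_i)]) {
    if (startsWith(line, "#")) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) < 10L) {
      stop_sc(sprintf("VCF record with %d fields (need 10): %s",
                      length(f), substr(line, 1, 60)), "safetycode_parse_error")
    }
    chrom <- sub("^chr", "", f[1]); pos <- f[2]; id <- f[3]
    ref <- toupper(f[4]); alt <- toupper(f[5])
    rsid <- if (grepl("^rs[0-9]+$", id) && !is.null(kb$markers[[id]])) {
      id
    } else {
      key <- paste(chrom, pos)
      if (!is.null(by_pos[[key]])) by_pos[[key]] else NA_character_
    }
    if (is.na(rsid)) next   # off-panel record
    alleles <- c(ref, strsplit(alt, ",", fixed = TRUE)[[1]])
    alleles <- alleles[alleles != "."]
    if (any(nchar(alleles) != 1L) || any(!alleles %in% NUCLEOTIDES)) {
      warning(sprintf("skipping non-SNP (indel/structural) record at %s:%s (%s)",
                      chrom, pos, rsid), call. = FALSE)
      next
    }
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    gt_i <- match("GT", fmt)
    if (is.na(gt_i)) {
      stop_sc(sprintf("record %s:%s lacks GT subfield", chrom, pos),
              "safetycode_parse_error")
    }
    gt <- strsplit(f[10], ":", fixed = TRUE)[[1]][gt_i]
    idx <- strsplit(gt, "[/|]")[[1]]
    if (length(idx) == 1L) idx <- c(idx, idx)   # hemizygous record
    if (length(idx) != 2L) {
      stop_sc(sprintf("record %s:%s: cannot parse GT '%s'", chrom, pos, gt),
              "safetycode_parse_error")
    }
    if (all(idx == ".")) {
      calls[[rsid]] <- NA_character_
      next
    }
    if (any(idx == ".")) {
      warning(sprintf("half-call GT '%s' at %s (%s:%s); recorded as unknown",
                      gt, rsid, chrom, pos), call. = FALSE)
      calls[[rsid]] <- NA_character_
      next
    }
    ai <- suppressWarnings(as.integer(idx)) + 1L
    if (anyNA(ai) || any(ai < 1L) || any(ai > length(alleles))) {
      stop_sc(sprintf("record %s:%s: GT '%s' indexes outside REF/ALT", chrom, pos, gt),
              "safetycode_parse_error")
    }
    pair <- alleles[ai]
    marker <- kb$markers[[rsid]]
    if (!all(pair %in% marker$allowed)) {
      warning(sprintf("allele(s) %s at %s outside allowed set %s; recorded as unknown",
                      paste(setdiff(pair, marker$allowed), collapse = "/"),
                      rsid, paste(marker$allowed, collapse = "/")),
              call. = FALSE)
      calls[[rsid]] <- NA_character_
      next
    }
    calls[[rsid]] <- pair
  }
  genotype_profile(calls, source_format = "vcf", build = kb$build)
}

#' Restrict a profile to the knowledge-base panel
#'
#' Returns a profile whose call set is exactly the KB panel, in panel order.
#' Panel markers missing from the input become unknown (VCF-derived profiles
#' arrive already reference-filled, so nothing is lost there); off-panel
#' calls are dropped, with their count reported as a message. Idempotent.
#'
#' @param profile A [genotype_profile()].
#' @param kb A `pgx_kb`.
#' @return A panel-ordered [genotype_profile()].
#' @export
restrict_to_panel <- function(profile, kb) {
  panel <- names(kb$markers)
  dropped <- setdiff(names(profile$calls), panel)
  if (length(dropped) > 0L) {
    message(sprintf("restrict_to_panel: dropped %d off-panel call(s)",
                    length(dropped)))
  }
  calls <- lapply(panel, function(r) {
    g <- profile$calls[[r]]
    if (is.null(g)) NA_character_ else g
  })
  names(calls) <- panel
  genotype_profile(calls, source_format = profile$source_format,
                   build = if (nzchar(profile$build)) profile$build else kb$build)
}
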