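# The Medicine Safety Code itself: a deterministic bit layout over the marker
# panel, packed MSB-first, base64url-encoded, and carried as the path of a
# versioned URL. The layout is a pure function of the knowledge base.

BASE64URL <- c(LETTERS, letters, as.character(0:9), "-", "_")

#' Build the code layout for a knowledge base
#'
#' One slot per panel marker, in panel order. A marker with k allowed
#' nucleotides has G = k(k+1)/2 unordered genotype pairs; its slot is
#' `ceiling(log2(G + 1))` bits wide, indexing the pairs in lexicographic
#' (min, max) order starting at 1, with index 0 always meaning unknown.
#' Slot offsets are contiguous, so the same KB always yields a bit-identical
#' layout and therefore bit-identical codes.
#'
#' @param kb A `pgx_kb`.
#' @return A `code_layout` with `slots` (data frame: `rsid`, `bit_offset`,
#'   `bit_width`), per-slot genotype tables, `total_bits`, and the code
#'   `version` string derived from the KB version.
#' @examples
#' layout <- build_layout(build_fixture_kb())
#' layout$total_bits
#' @export
build_layout <- function(kb) {
  offset <- 0L
  slots <- vector("list", length(kb$markers))
  tables <- vector("list", length(kb$markers))
  for (i in seq_along(kb$markers)) {
    m <- kb$markers[[i]]
    if (length(m$allowed) > 4L) {
      stop_sc(sprintf("marker %s has >4 allowed nucleotides", m$rsid),
              "safetycode_layout_error")
    }
    pairs <- genotype_pairs(m$allowed)
    width <- as.integer(ceiling(log2(nrow(pairs) + 1L)))
    slots[[i]] <- data.frame(rsid = m$rsid, bit_offset = offset,
                             bit_width = width, stringsAsFactors = FALSE)
    tables[[i]] <- pairs
    offset <- offset + width
  }
  slots <- if (length(slots)) do.call(rbind, slots) else
    data.frame(rsid = character(), bit_offset = integer(),
               bit_width = integer(), stringsAsFactors = FALSE)
  names(tables) <- slots$rsid
  structure(list(slots = slots, tables = tables, total_bits = offset,
                 version = paste0("v", kb$version)),
            class = "code_layout")
}

#' @export
print.code_layout <- function(x, ...) {
  cat(sprintf("<code_layout %s: %d slots, %d bits, payload %d chars>\n",
              x$version, nrow(x$slots), x$total_bits,
              ceiling(x$total_bits / 6)))
  invisible(x)
}

#' Medicine Safety Code object
#'
#' @param payload base64url payload text (alphabet `A-Z a-z 0-9 - _`).
#' @param version Code version string, e.g. `"v0.2"`.
#' @param base_url URL prefix the payload is served under (a trailing `/` is
#'   added if missing).
#' @return A `safety_code` object; `code_url()` renders the full URL.
#' @export
safety_code <- function(payload, version = "v0.2",
                        base_url = "http://safety-code.org/") {
  if (!grepl("^[A-Za-z0-9_-]*$", payload)) {
    stop_sc("payload contains characters outside the base64url alphabet",
            "safetycode_decode_error")
  }
  if (!grepl("^v[0-9]+\\.[0-9]+$", version)) {
    stop_sc(sprintf("invalid version string '%s'", version),
            "safetycode_decode_error")
  }
  if (!endsWith(base_url, "/")) base_url <- paste0(base_url, "/")
  structure(list(version = version, payload = payload, base_url = base_url),
            class = "safety_code")
}

#' @rdname safety_code
#' @param code A `safety_code`.
#' @export
code_url <- function(code) paste0(code$base_url, code$version, "/", code$payload)

#' @export
print.safety_code <- function(x, ...) {
  cat(code_url(x), "\n")
  invisible(x)
}

slot_index <- function(call, pairs) {
  if (is_unknown_call(call)) return(0L)
  hit <- which(pairs[, 1] == call[1] & pairs[, 2] == call[2])
  if (length(hit) != 1L) return(NA_integer_)
  hit
}

int_to_bits_msb <- function(x, width) {
  if (width == 0L) return(integer(0))
  as.integer(bitwAnd(bitwShiftR(x, (width - 1L):0L), 1L))
}

bits_to_int_msb <- function(bits) {
  out <- 0L
  for (b in bits) out <- out * 2L + b
  out
}

#' Encode a genotype profile as a Medicine Safety Code
#'
#' Writes each marker's genotype index at its slot offset (most-significant
#' bit first within the slot), zero-pads the bit string to a multiple of 6,
#' and maps 6-bit groups through the base64url alphabet. Unknown calls encode
#' as index 0, so an all-unknown profile is an all-`"A"` payload.
#'
#' @param profile A [genotype_profile()] restricted to the layout's panel
#'   (same rsid set; see [restrict_to_panel()]).
#' @param layout A [build_layout()] result.
#' @param base_url URL prefix for the rendered code.
#' @return A [safety_code()].
#' @examples
#' kb <- build_fixture_kb()
#' layout <- build_layout(kb)
#' p <- restrict_to_panel(genotype_profile(list(rs1057910 = c("A", "C"))), kb)
#' code_url(encode_profile(p, layout))
#' @export
encode_profile <- function(profile, layout,
                           base_url = "http://safety-code.org/") {
  if (!setequal(names(profile$calls), layout$slots$rsid)) {
    stop_sc("profile is not restricted to the layout panel (run restrict_to_panel first)",
            "safetycode_encode_error")
  }
  bits <- integer(layout$total_bits)
  for (i in seq_len(nrow(layout$slots))) {
    rsid <- layout$slots$rsid[i]
    idx <- slot_index(profile$calls[[rsid]], layout$tables[[rsid]])
    if (is.na(idx)) {
      stop_sc(sprintf("genotype %s at marker %s is outside the allowed nucleotide set",
                      paste(profile$calls[[rsid]], collapse = "/"), rsid),
              "safetycode_encode_error")
    }
    w <- layout$slots$bit_width[i]
    if (w > 0L) {
      bits[(layout$slots$bit_offset[i] + 1L):(layout$slots$bit_offset[i] + w)] <-
        int_to_bits_msb(idx, w)
    }
  }
  n_char <- ceiling(layout$total_bits / 6)
  padded <- c(bits, integer(n_char * 6L - layout$total_bits))
  if (n_char > 0L) {
    groups <- matrix(padded, nrow = 6L)
    vals <- colSums(groups * 2L^(5:0))
    payload <- paste(BASE64URL[vals + 1L], collapse = "")
  } else {
    payload <- ""
  }
  safety_code(payload, version = layout$version, base_url = base_url)
}

#' Decode a Medicine Safety Code back into a genotype profile
#'
#' Exact inverse of [encode_profile()] over the panel. The payload alphabet,
#' payload length (which must equal `ceiling(total_bits / 6)`), and version
#' are each checked with a distinct error message; a slot index beyond the
#' marker's genotype table, or non-zero padding bits, is a decode error.
#'
#' @param code A [safety_code()] (or a string accepted by [parse_url()]).
#' @param layout The [build_layout()] of the KB the code was made against.
#' @return A [genotype_profile()] with `source_format = "code"`.
#' @export
decode_code <- function(code, layout) {
  if (is.character(code)) code <- parse_url(code)
  if (!grepl("^[A-Za-z0-9_-]*$", code$payload)) {
    stop_sc("payload contains characters outside the base64url alphabet",
            "safetycode_decode_error")
  }
  if (!identical(code$version, layout$version)) {
    stop_sc(sprintf("code version %s does not match layout version %s",
                    code$version, layout$version), "safetycode_decode_error")
  }
  n_char <- ceiling(layout$total_bits / 6)
  if (nchar(code$payload) != n_char) {
    stop_sc(sprintf("payload length %d does not match layout (expected %d characters)",
                    nchar(code$payload), n_char), "safetycode_decode_error")
  }
  if (n_char == 0L) {
    return(genotype_profile(list(), source_format = "code"))
  }
  vals <- match(strsplit(code$payload, "")[[1]], BASE64URL) - 1L
  bits <- as.integer(vapply(vals, int_to_bits_msb, integer(6L), width = 6L))
  if (any(bits[seq_len(n_char * 6L)][-seq_len(layout$total_bits)] != 0L)) {
    stop_sc("non-zero padding bits in payload", "safetycode_decode_error")
  }
  calls <- vector("list", nrow(layout$slots))
  names(calls) <- layout$slots$rsid
  for (i in seq_len(nrow(layout$slots))) {
    w <- layout$slots$bit_width[i]
    off <- layout$slots$bit_offset[i]
    idx <- if (w > 0L) bits_to_int_msb(bits[(off + 1L):(off + w)]) else 0L
    pairs <- layout$tables[[i]]
    if (idx > nrow(pairs)) {
      stop_sc(sprintf("slot %s: genotype index %d exceeds table size %d",
                      layout$slots$rsid[i], idx, nrow(pairs)),
              "safetycode_decode_error")
    }
    calls[[i]] <- if (idx == 0L) NA_character_ else pairs[idx, ]
  }
  genotype_profile(calls, source_format = "code")
}

#' Parse a Medicine Safety Code URL
#'
#' Splits a URL of the form `<base_url>v<major>.<minor>/<payload>` into its
#' parts and validates the payload alphabet.
#'
#' @param url Full code URL (or bare `v0.2/<payload>` tail).
#' @return A [safety_code()].
#' @examples
#' parse_url("http://safety-code.org/v0.2/QXGqrLF2h8xu")$version
#' @export
parse_url <- function(url) {
  m <- regmatches(url, regexec("^(.*?)(v[0-9]+\\.[0-9]+)/([^/]*)$", url))[[1]]
  if (length(m) != 4L) {
    stop_sc(sprintf("URL '%s' has no /v<digits>.<digits>/<payload> segment", url),
            "safetycode_parse_error")
  }
  base_url <- if (nzchar(m[2])) m[2] else "http://safety-code.org/"
  safety_code(m[4], version = m[3], base_url = base_url)
}
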