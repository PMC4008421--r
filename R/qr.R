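# Self-contained QR symbol encoder (ISO/IEC 18004): byte mode, Reed-Solomon
# error correction over GF(2^8), data masking chosen by penalty score, and
# format/version information with BCH check bits. Includes a symbol reader
# (qr_read_symbol) that reverses the construction; it doubles as an
# independent structural check in the test suite.

# Error-correction block structure per (version, level L/M/Q/H = 1..4):
# columns: version, level, ec codewords per block, group-1 block count,
# group-1 data codewords, group-2 block count, group-2 data codewords.
QR_BLOCKS <- matrix(c(
  1,1,7,1,19,0,0,    1,2,10,1,16,0,0,   1,3,13,1,13,0,0,   1,4,17,1,9,0,0,
  2,1,10,1,34,0,0,   2,2,16,1,28,0,0,   2,3,22,1,22,0,0,   2,4,28,1,16,0,0,
  3,1,15,1,55,0,0,   3,2,26,1,44,0,0,   3,3,18,2,17,0,0,   3,4,22,2,13,0,0,
  4,1,20,1,80,0,0,   4,2,18,2,32,0,0,   4,3,26,2,24,0,0,   4,4,16,4,9,0,0,
  5,1,26,1,108,0,0,  5,2,24,2,43,0,0,   5,3,18,2,15,2,16,  5,4,22,2,11,2,12,
  6,1,18,2,68,0,0,   6,2,16,4,27,0,0,   6,3,24,4,19,0,0,   6,4,28,4,15,0,0,
  7,1,20,2,78,0,0,   7,2,18,4,31,0,0,   7,3,18,2,14,4,15,  7,4,26,4,13,1,14,
  8,1,24,2,97,0,0,   8,2,22,2,38,2,39,  8,3,22,4,18,2,19,  8,4,26,4,14,2,15,
  9,1,30,2,116,0,0,  9,2,22,3,36,2,37,  9,3,20,4,16,4,17,  9,4,24,4,12,4,13,
  10,1,18,2,68,2,69, 10,2,26,4,43,1,44, 10,3,24,6,19,2,20, 10,4,28,6,15,2,16,
  11,1,20,4,81,0,0,  11,2,30,1,50,4,51, 11,3,28,4,22,4,23, 11,4,24,3,12,8,13,
  12,1,24,2,92,2,93, 12,2,22,6,36,2,37, 12,3,26,4,20,6,21, 12,4,28,7,14,4,15,
  13,1,26,4,107,0,0, 13,2,22,8,37,1,38, 13,3,24,8,20,4,21, 13,4,22,12,11,4,12,
  14,1,30,3,115,1,116, 14,2,24,4,40,5,41, 14,3,20,11,16,5,17, 14,4,24,11,12,5,13,
  15,1,22,5,87,1,88, 15,2,24,5,41,5,42, 15,3,30,5,24,7,25, 15,4,24,11,12,7,13,
  16,1,24,5,98,1,99, 16,2,28,7,45,3,46, 16,3,24,15,19,2,20, 16,4,30,3,15,13,16,
  17,1,28,1,107,5,108, 17,2,28,10,46,1,47, 17,3,28,1,22,15,23, 17,4,28,2,14,17,15,
  18,1,30,5,120,1,121, 18,2,26,9,43,4,44, 18,3,28,17,22,1,23, 18,4,28,2,14,19,15,
  19,1,28,3,113,4,114, 19,2,26,3,44,11,45, 19,3,26,17,21,4,22, 19,4,26,9,13,16,14,
  20,1,28,3,107,5,108, 20,2,26,3,41,13,42, 20,3,30,15,24,5,25, 20,4,28,15,15,10,16,
  21,1,28,4,116,4,117, 21,2,26,17,42,0,0, 21,3,28,17,22,6,23, 21,4,30,19,16,6,17,
  22,1,28,2,111,7,112, 22,2,28,17,46,0,0, 22,3,30,7,24,16,25, 22,4,24,34,13,0,0,
  23,1,30,4,121,5,122, 23,2,28,4,47,14,48, 23,3,30,11,24,14,25, 23,4,30,16,15,14,16,
  24,1,30,6,117,4,118, 24,2,28,6,45,14,46, 24,3,30,11,24,16,25, 24,4,30,30,16,2,17,
  25,1,26,8,106,4,107, 25,2,28,8,47,13,48, 25,3,30,7,24,22,25, 25,4,30,22,15,13,16,
  26,1,28,10,114,2,115, 26,2,28,19,46,4,47, 26,3,28,28,22,6,23, 26,4,30,33,16,4,17,
  27,1,30,8,122,4,123, 27,2,28,22,45,3,46, 27,3,30,8,23,26,24, 27,4,30,12,15,28,16,
  28,1,30,3,117,10,118, 28,2,28,3,45,23,46, 28,3,30,4,24,31,25, 28,4,30,11,15,31,16,
  29,1,30,7,116,7,117, 29,2,28,21,45,7,46, 29,3,30,1,23,37,24, 29,4,30,19,15,26,16,
  30,1,30,5,115,10,116, 30,2,28,19,47,10,48, 30,3,30,15,24,25,25, 30,4,30,23,15,25,16,
  31,1,30,13,115,3,116, 31,2,28,2,46,29,47, 31,3,30,42,24,1,25, 31,4,30,23,15,28,16,
  32,1,30,17,115,0,0, 32,2,28,10,46,23,47, 32,3,30,10,24,35,25, 32,4,30,19,15,35,16,
  33,1,30,17,115,1,116, 33,2,28,14,46,21,47, 33,3,30,29,24,19,25, 33,4,30,11,15,46,16,
  34,1,30,13,115,6,116, 34,2,28,14,46,23,47, 34,3,30,44,24,7,25, 34,4,30,59,16,1,17,
  35,1,30,12,121,7,122, 35,2,28,12,47,26,48, 35,3,30,39,24,14,25, 35,4,30,22,15,41,16,
  36,1,30,6,121,14,122, 36,2,28,6,47,34,48, 36,3,30,46,24,10,25, 36,4,30,2,15,64,16,
  37,1,30,17,122,4,123, 37,2,28,29,46,14,47, 37,3,30,49,24,10,25, 37,4,30,24,15,46,16,
  38,1,30,4,122,18,123, 38,2,28,13,46,32,47, 38,3,30,48,24,14,25, 38,4,30,42,15,32,16,
  39,1,30,20,117,4,118, 39,2,28,40,47,7,48, 39,3,30,43,24,22,25, 39,4,30,10,15,67,16,
  40,1,30,19,118,6,119, 40,2,28,18,47,31,48, 40,3,30,34,24,34,25, 40,4,30,20,15,61,16
), ncol = 7, byrow = TRUE)
colnames(QR_BLOCKS) <- c("version", "level", "ec", "b1", "d1", "b2", "d2")

EC_LEVELS <- c(L = 1L, M = 2L, Q = 3L, H = 4L)
EC_LEVEL_BITS <- c(L = 1L, M = 0L, Q = 3L, H = 2L)  # format-info level field

qr_block_row <- function(version, level) {
  QR_BLOCKS[QR_BLOCKS[, "version"] == version & QR_BLOCKS[, "level"] == level, ]
}

qr_data_codewords <- function(version, level) {
  r <- qr_block_row(version, level)
  as.integer(r["b1"] * r["d1"] + r["b2"] * r["d2"])
}

qr_total_codewords_table <- function(version, level) {
  r <- qr_block_row(version, level)
  as.integer(r["b1"] * (r["d1"] + r["ec"]) + r["b2"] * (r["d2"] + r["ec"]))
}

# Total codeword capacity derived from symbol geometry alone (finder,
# separator, timing, alignment, format/version areas); independent check on
# the block table.
qr_total_codewords_geometry <- function(version) {
  n <- 4L * version + 17L
  modules <- n^2 - 3L * 64L - 31L - 2L * (n - 16L)
  if (version >= 7L) modules <- modules - 36L
  if (version > 1L) {
    p <- length(qr_alignment_centers(version))
    modules <- modules - 25L * (p^2 - 3L) + 10L * (p - 2L)
  }
  as.integer(modules %/% 8L)
}

QR_ALIGNMENT <- list(
  NULL, c(6,18), c(6,22), c(6,26), c(6,30), c(6,34),
  c(6,22,38), c(6,24,42), c(6,26,46), c(6,28,50), c(6,30,54), c(6,32,58),
  c(6,34,62), c(6,26,46,66), c(6,26,48,70), c(6,26,50,74), c(6,30,54,78),
  c(6,30,56,82), c(6,30,58,86), c(6,34,62,90), c(6,28,50,72,94),
  c(6,26,50,74,98), c(6,30,54,78,102), c(6,28,54,80,106), c(6,32,58,84,110),
  c(6,30,58,86,114), c(6,34,62,90,118), c(6,26,50,74,98,122),
  c(6,30,54,78,102,126), c(6,26,52,78,104,130), c(6,30,56,82,108,134),
  c(6,34,60,86,112,138), c(6,30,58,86,114,142), c(6,34,62,90,118,146),
  c(6,30,54,78,102,126,150), c(6,24,50,76,102,128,154),
  c(6,28,54,80,106,132,158), c(6,32,58,84,110,136,162),
  c(6,26,54,82,110,138,166), c(6,30,58,86,114,142,170)
)

qr_alignment_centers <- function(version) QR_ALIGNMENT[[version]]

#' QR symbol data capacity in bits
#'
#' Data capacity (data codewords times 8) of a QR symbol at a given version
#' and error-correction level, from the embedded ISO/IEC 18004 capacity
#' table. At version 40, level L, a single symbol carries 23,648 data bits.
#'
#' @param version Symbol version, an integer in 1–40.
#' @param ec_level Error-correction level: `"L"`, `"M"`, `"Q"` or `"H"`.
#' @return Number of data bits.
#' @examples
#' qr_capacity(40, "L")  # 23648
#' @export
qr_capacity <- function(version, ec_level = c("L", "M", "Q", "H")) {
  ec_level <- match.arg(ec_level)
  version <- as.integer(version)
  if (is.na(version) || version < 1L || version > 40L) {
    stop_sc("QR version must be an integer in 1..40", "safetycode_capacity_error")
  }
  8L * qr_data_codewords(version, EC_LEVELS[[ec_level]])
}

# --- GF(2^8) arithmetic and Reed-Solomon -----------------------------------

gf_tables <- local({
  exp <- integer(510)
  log <- integer(256)
  x <- 1L
  for (i in 0:254) {
    exp[i + 1L] <- x
    log[x + 1L] <- i
    x <- bitwShiftL(x, 1L)
    if (x >= 256L) x <- bitwAnd(bitwXor(x, 0x11DL), 0xFFL)
  }
  exp[256:510] <- exp[1:255]
  list(exp = exp, log = log)
})

gf_mul <- function(a, b) {
  if (a == 0L || b == 0L) return(0L)
  gf_tables$exp[((gf_tables$log[a + 1L] + gf_tables$log[b + 1L]) %% 255L) + 1L]
}

rs_generator <- function(n_ec) {
  g <- 1L
  for (i in 0:(n_ec - 1L)) {
    # multiply g by (x - alpha^i)
    a <- gf_tables$exp[i + 1L]
    g_new <- integer(length(g) + 1L)
    for (j in seq_along(g)) {
      g_new[j] <- bitwXor(g_new[j], gf_mul(g[j], a))
      g_new[j + 1L] <- bitwXor(g_new[j + 1L], g[j])
    }
    g <- g_new
  }
  rev(g)  # descending powers, leading coefficient first (== 1)
}

rs_encode <- function(data, n_ec) {
  gen <- rs_generator(n_ec)[-1L]  # drop leading 1
  rem <- integer(n_ec)
  for (d in data) {
    factor <- bitwXor(d, rem[1L])
    rem <- c(rem[-1L], 0L)
    if (factor != 0L) {
      lf <- gf_tables$log[factor + 1L]
      for (j in seq_len(n_ec)) {
        if (gen[j] != 0L) {
          rem[j] <- bitwXor(rem[j],
                            gf_tables$exp[((lf + gf_tables$log[gen[j] + 1L]) %% 255L) + 1L])
        }
      }
    }
  }
  rem
}

# Syndromes of a full codeword block (data ++ ec); all zero iff valid.
rs_syndromes <- function(block, n_ec) {
  vapply(0:(n_ec - 1L), function(i) {
    a <- gf_tables$exp[i + 1L]
    s <- 0L
    for (b in block) s <- bitwXor(gf_mul(s, a), b)
    s
  }, 0L)
}

# --- BCH codes for format and version information ---------------------------

bch_remainder <- function(value, value_bits, gen, gen_bits) {
  v <- bitwShiftL(value, gen_bits - 1L)
  for (i in (value_bits + gen_bits - 2L):(gen_bits - 1L)) {
    if (bitwAnd(v, bitwShiftL(1L, i)) != 0L) {
      v <- bitwXor(v, bitwShiftL(gen, i - gen_bits + 1L))
    }
  }
  v
}

qr_format_bits <- function(level, mask) {
  data <- bitwOr(bitwShiftL(EC_LEVEL_BITS[[level]], 3L), mask)
  code <- bitwOr(bitwShiftL(data, 10L), bch_remainder(data, 5L, 0x537L, 11L))
  bitwXor(code, 0x5412L)
}

qr_version_bits <- function(version) {
  bitwOr(bitwShiftL(version, 12L), bch_remainder(version, 6L, 0x1F25L, 13L))
}

# --- symbol construction ----------------------------------------------------

# Function-module template: list(mod = matrix of 0/1 (dark), fun = logical
# matrix marking function/reserved modules). 0-based coordinates throughout,
# mat[r + 1, c + 1].
qr_template <- function(version) {
  n <- 4L * version + 17L
  mod <- matrix(0L, n, n)
  fun <- matrix(FALSE, n, n)
  put <- function(r, c, v) {
    mod[r + 1L, c + 1L] <<- v
    fun[r + 1L, c + 1L] <<- TRUE
  }
  finder <- function(r0, c0) {
    for (r in -1:7) for (c in -1:7) {
      rr <- r0 + r; cc <- c0 + c
      if (rr < 0L || cc < 0L || rr >= n || cc >= n) next
      dark <- (r >= 0 && r <= 6 && (c == 0 || c == 6)) ||
              (c >= 0 && c <= 6 && (r == 0 || r == 6)) ||
              (r >= 2 && r <= 4 && c >= 2 && c <= 4)
      put(rr, cc, as.integer(dark))
    }
  }
  finder(0L, 0L); finder(0L, n - 7L); finder(n - 7L, 0L)
  for (i in 8:(n - 9L)) {           # timing patterns
    v <- as.integer(i %% 2L == 0L)
    if (!fun[7L, i + 1L]) put(6L, i, v)
    if (!fun[i + 1L, 7L]) put(i, 6L, v)
  }
  centers <- qr_alignment_centers(version)
  if (!is.null(centers)) {
    for (rc in centers) for (cc in centers) {
      if (fun[rc + 1L, cc + 1L]) next   # overlaps a finder corner
      for (r in -2:2) for (c in -2:2) {
        dark <- max(abs(r), abs(c)) != 1L
        put(rc + r, cc + c, as.integer(dark))
      }
    }
  }
  # reserve format info areas (filled later) and the dark module
  for (i in 0:8) {
    if (i != 6L) { put(8L, i, 0L); put(i, 8L, 0L) }
  }
  put(8L, 8L, 0L)
  for (i in 0:7) { put(8L, n - 1L - i, 0L); put(n - 1L - i, 8L, 0L) }
  put(n - 8L, 8L, 1L)               # dark module
  if (version >= 7L) {
    vb <- qr_version_bits(version)
    for (j in 0:17) {
      bit <- bitwAnd(bitwShiftR(vb, j), 1L)
      put(n - 11L + j %% 3L, j %/% 3L, bit)
      put(j %/% 3L, n - 11L + j %% 3L, bit)
    }
  }
  list(mod = mod, fun = fun, n = n)
}

# Zigzag placement order of data modules: matrix with columns (row, col),
# 0-based, in writing order.
qr_placement_order <- function(fun) {
  n <- nrow(fun)
  ord <- matrix(0L, sum(!fun), 2L)
  k <- 0L
  col <- n - 1L
  upward <- TRUE
  while (col > 0L) {
    if (col == 6L) col <- col - 1L   # skip the vertical timing column
    rows <- if (upward) (n - 1L):0L else 0L:(n - 1L)
    for (r in rows) {
      for (c in c(col, col - 1L)) {
        if (!fun[r + 1L, c + 1L]) {
          k <- k + 1L
          ord[k, ] <- c(r, c)
        }
      }
    }
    upward <- !upward
    col <- col - 2L
  }
  ord
}

qr_mask_bit <- function(mask, r, c) {
  v <- switch(mask + 1L,
    (r + c) %% 2L,
    r %% 2L,
    c %% 3L,
    (r + c) %% 3L,
    (r %/% 2L + c %/% 3L) %% 2L,
    (r * c) %% 2L + (r * c) %% 3L,
    ((r * c) %% 2L + (r * c) %% 3L) %% 2L,
    ((r + c) %% 2L + (r * c) %% 3L) %% 2L)
  as.integer(v == 0L)
}

qr_place_format <- function(mod, level, mask) {
  n <- nrow(mod)
  fb <- qr_format_bits(level, mask)
  bit <- function(i) bitwAnd(bitwShiftR(fb, i), 1L)
  coords1 <- rbind(  # copy around the top-left finder, bits 0..14
    cbind(8L, 0:5), c(8L, 7L), c(8L, 8L), c(7L, 8L), cbind(5:0, 8L))
  for (i in 0:14) {
    mod[coords1[i + 1L, 1L] + 1L, coords1[i + 1L, 2L] + 1L] <- bit(i)
  }
  for (i in 0:6) mod[n - i, 9L] <- bit(i)              # col 8, rows n-1..n-7
  for (i in 7:14) mod[9L, n - 15L + i + 1L] <- bit(i)  # row 8, cols n-8..n-1
  mod
}

qr_penalty <- function(mod) {
  n <- nrow(mod)
  total <- 0L
  run_penalty <- function(v) {
    p <- 0L
    r <- rle(v)
    p + sum(ifelse(r$lengths >= 5L, 3L + r$lengths - 5L, 0L))
  }
  pat1 <- c(1L, 0L, 1L, 1L, 1L, 0L, 1L, 0L, 0L, 0L, 0L)
  pat2 <- rev(pat1)
  count_pattern <- function(v) {
    if (length(v) < 11L) return(0L)
    hits <- 0L
    for (s in 1:(length(v) - 10L)) {
      w <- v[s:(s + 10L)]
      if (all(w == pat1) || all(w == pat2)) hits <- hits + 1L
    }
    hits
  }
  for (i in seq_len(n)) {
    total <- total + run_penalty(mod[i, ]) + run_penalty(mod[, i])
    total <- total + 40L * (count_pattern(mod[i, ]) + count_pattern(mod[, i]))
  }
  blocks <- mod[-n, -n] + mod[-1, -n] + mod[-n, -1] + mod[-1, -1]
  total <- total + 3L * sum(blocks == 0L | blocks == 4L)
  dark_pct <- 100 * sum(mod) / n^2
  total + 10L * (abs(trunc(dark_pct) - 50L) %/% 5L)
}

# Build the byte-mode bit stream (with terminator and pad codewords) and the
# interleaved final codeword sequence for one symbol.
qr_codewords <- function(bytes, version, level) {
  n_data <- qr_data_codewords(version, level)
  cci_bits <- if (version <= 9L) 8L else 16L
  need <- 4L + cci_bits + 8L * length(bytes)
  if (need > 8L * n_data) {
    stop_sc(sprintf("payload of %d bytes does not fit QR version %d",
                    length(bytes), version), "safetycode_capacity_error")
  }
  bits <- c(int_to_bits_msb(4L, 4L),                 # byte-mode indicator 0100
            int_to_bits_msb(length(bytes), cci_bits),
            unlist(lapply(bytes, int_to_bits_msb, width = 8L)))
  bits <- c(bits, integer(min(4L, 8L * n_data - length(bits))))  # terminator
  if (length(bits) %% 8L != 0L) bits <- c(bits, integer(8L - length(bits) %% 8L))
  data <- vapply(seq_len(length(bits) %/% 8L), function(i) {
    bits_to_int_msb(bits[(8L * i - 7L):(8L * i)])
  }, 0L)
  pad <- c(0xECL, 0x11L)
  i <- 1L
  while (length(data) < n_data) {
    data <- c(data, pad[i])
    i <- 3L - i
  }
  r <- qr_block_row(version, level)
  sizes <- c(rep(r[["d1"]], r[["b1"]]), rep(r[["d2"]], r[["b2"]]))
  blocks <- vector("list", length(sizes))
  at <- 1L
  for (b in seq_along(sizes)) {
    blocks[[b]] <- data[at:(at + sizes[b] - 1L)]
    at <- at + sizes[b]
  }
  ec_blocks <- lapply(blocks, rs_encode, n_ec = r[["ec"]])
  interleave <- function(lst) {
    out <- integer(0)
    for (i in seq_len(max(lengths(lst)))) {
      for (b in lst) if (length(b) >= i) out <- c(out, b[i])
    }
    out
  }
  list(final = c(interleave(blocks), interleave(ec_blocks)),
       data = data, blocks = blocks, ec_blocks = ec_blocks)
}

# Smallest version whose byte-mode capacity holds n_bytes at the given level.
qr_min_version <- function(n_bytes, level) {
  for (v in 1:40) {
    cci <- if (v <= 9L) 8L else 16L
    if (4L + cci + 8L * n_bytes <= 8L * qr_data_codewords(v, level)) return(v)
  }
  stop_sc(sprintf(
    "payload of %d bytes exceeds the %d-bit version-40 capacity at this level",
    n_bytes, qr_capacity(40L, names(EC_LEVELS)[level])),
    "safetycode_capacity_error")
}

# Full symbol matrix for a byte payload. Returns list(mod, version, mask).
qr_build_matrix <- function(bytes, ec_level = "M", version = NULL) {
  level <- EC_LEVELS[[match.arg(ec_level, names(EC_LEVELS))]]
  if (is.null(version)) version <- qr_min_version(length(bytes), level)
  cw <- qr_codewords(bytes, version, level)
  tpl <- qr_template(version)
  ord <- qr_placement_order(tpl$fun)
  bits <- unlist(lapply(cw$final, int_to_bits_msb, width = 8L))
  bits <- c(bits, integer(nrow(ord) - length(bits)))  # remainder bits
  best <- NULL
  for (mask in 0:7) {
    mod <- tpl$mod
    for (k in seq_len(nrow(ord))) {
      r <- ord[k, 1L]; c <- ord[k, 2L]
      mod[r + 1L, c + 1L] <- bitwXor(bits[k], qr_mask_bit(mask, r, c))
    }
    mod <- qr_place_format(mod, names(EC_LEVELS)[level], mask)
    pen <- qr_penalty(mod)
    if (is.null(best) || pen < best$penalty) {
      best <- list(mod = mod, version = version, mask = mask, penalty = pen)
    }
  }
  best
}

#' Render a Medicine Safety Code as a QR image
#'
#' Encodes the full code URL in QR byte mode at the smallest symbol version
#' whose data capacity holds it, applies Reed-Solomon error correction and
#' the lowest-penalty data mask, and writes a PNG (dark modules black, 8
#' pixels per module, 4-module quiet zone).
#'
#' @param code A [safety_code()] (or a full URL string).
#' @param out_path Output PNG path.
#' @param ec_level Error-correction level `"L"`, `"M"`, `"Q"`, `"H"`
#'   (default `"M"`).
#' @param scale Pixels per module.
#' @return The chosen symbol version, invisibly as part of a list with
#'   `version`, `mask`, `path`.
#' @examples
#' \donttest{
#' kb <- build_fixture_kb()
#' layout <- build_layout(kb)
#' p <- restrict_to_panel(genotype_profile(list()), kb)
#' res <- render_qr(encode_profile(p, layout), tempfile(fileext = ".png"))
#' res$version
#' }
#' @export
render_qr <- function(code, out_path, ec_level = "M", scale = 8L) {
  url <- if (is.character(code)) code else code_url(code)
  bytes <- as.integer(charToRaw(url))
  sym <- qr_build_matrix(bytes, ec_level = ec_level)
  quiet <- 4L
  n <- nrow(sym$mod)
  img <- matrix(1, n + 2L * quiet, n + 2L * quiet)
  img[(quiet + 1L):(quiet + n), (quiet + 1L):(quiet + n)] <- 1 - sym$mod
  img <- img[rep(seq_len(nrow(img)), each = scale),
             rep(seq_len(ncol(img)), each = scale)]
  png::writePNG(img, out_path)
  invisible(list(version = sym$version, mask = sym$mask, path = out_path))
}

# --- symbol reading (structural oracle) -------------------------------------

# Read back the byte-mode payload of a symbol matrix produced by
# qr_build_matrix: recover format info, unmask, de-interleave, verify every
# Reed-Solomon block's syndromes are zero, and re-parse the byte stream.
qr_read_symbol <- function(mod) {
  n <- nrow(mod)
  version <- (n - 17L) %/% 4L
  fmt <- 0L
  coords1 <- rbind(cbind(8L, 0:5), c(8L, 7L), c(8L, 8L), c(7L, 8L), cbind(5:0, 8L))
  for (i in 14:0) {
    fmt <- bitwOr(bitwShiftL(fmt, 1L),
                  mod[coords1[i + 1L, 1L] + 1L, coords1[i + 1L, 2L] + 1L])
  }
  # brute-force match against all 32 valid format codes
  best <- NULL
  for (lv in names(EC_LEVELS)) for (mk in 0:7) {
    cand <- qr_format_bits(lv, mk)
    d <- sum(int_to_bits_msb(bitwXor(cand, fmt), 15L))
    if (is.null(best) || d < best$dist) best <- list(level = lv, mask = mk, dist = d)
  }
  if (best$dist > 3L) stop("unreadable format information")
  level <- EC_LEVELS[[best$level]]
  tpl <- qr_template(version)
  ord <- qr_placement_order(tpl$fun)
  bits <- integer(nrow(ord))
  for (k in seq_len(nrow(ord))) {
    r <- ord[k, 1L]; c <- ord[k, 2L]
    bits[k] <- bitwXor(mod[r + 1L, c + 1L], qr_mask_bit(best$mask, r, c))
  }
  total_cw <- qr_total_codewords_table(version, level)
  cw <- vapply(seq_len(total_cw), function(i) {
    bits_to_int_msb(bits[(8L * i - 7L):(8L * i)])
  }, 0L)
  r <- qr_block_row(version, level)
  sizes <- c(rep(r[["d1"]], r[["b1"]]), rep(r[["d2"]], r[["b2"]]))
  nb <- length(sizes)
  blocks <- lapply(sizes, function(s) integer(s))
  k <- 1L
  for (i in seq_len(max(sizes))) {
    for (b in seq_len(nb)) {
      if (sizes[b] >= i) { blocks[[b]][i] <- cw[k]; k <- k + 1L }
    }
  }
  ec_blocks <- lapply(seq_len(nb), function(b) integer(r[["ec"]]))
  for (i in seq_len(r[["ec"]])) {
    for (b in seq_len(nb)) { ec_blocks[[b]][i] <- cw[k]; k <- k + 1L }
  }
  for (b in seq_len(nb)) {
    if (any(rs_syndromes(c(blocks[[b]], ec_blocks[[b]]), r[["ec"]]) != 0L)) {
      stop(sprintf("Reed-Solomon syndrome check failed in block %d", b))
    }
  }
  data_bits <- unlist(lapply(unlist(blocks), int_to_bits_msb, width = 8L))
  mode <- bits_to_int_msb(data_bits[1:4])
  if (mode != 4L) stop(sprintf("unexpected mode indicator %d", mode))
  cci_bits <- if (version <= 9L) 8L else 16L
  len <- bits_to_int_msb(data_bits[5:(4L + cci_bits)])
  at <- 4L + cci_bits
  bytes <- vapply(seq_len(len), function(i) {
    bits_to_int_msb(data_bits[(at + 8L * i - 7L):(at + 8L * i)])
  }, 0L)
  rawToChar(as.raw(bytes))
}
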