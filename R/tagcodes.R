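#' @title JSATS-style 31-bit tag codes: layout, CRC-8, and mimic analysis
#'
#' @description
#' A JSATS-style acoustic tag transmits a uniquely coded 31-bit message.
#' This module fixes a concrete bit layout (7 sync bits, a 16-bit tag
#' identifier, and an 8-bit cyclic redundancy check over the identifier),
#' provides encoding, CRC validation of received codewords, and enumeration
#' of "mimic" tag codes: distinct identifiers reachable from a real codeword
#' by a small number of bit inversions that still carry a matching CRC.
#'
#' The true commercial bit layout and CRC parameters are proprietary; the
#' layout here satisfies the published envelope (31 bits total, 8 CRC bits,
#' an identifier space above 65,000 codes) and uses the standard CRC-8
#' polynomial x^8 + x^2 + x + 1 (0x07), zero initial value, MSB-first, no
#' reflection and no final XOR. Interoperability with real hardware is not
#' a goal.
#'
#' @name tagcodes
NULL

# 7-bit sync preamble (Barker-7 sequence); not covered by the CRC and not
# checked during validation -- a real decoder locates the message by
# correlating on it before any bits are available.
.SYNC_BITS <- c(1L, 1L, 1L, 0L, 0L, 1L, 0L)

#' Message layout for 31-bit coded tag transmissions
#'
#' @param sync_bits integer, width of the sync preamble (default 7)
#' @param id_bits integer, width of the tag-identifier field (default 16)
#' @param crc_bits integer, width of the CRC field (default 8)
#' @param poly CRC generator polynomial, low 8 bits (default 0x07)
#' @return an object of class `message_layout`
#' @examples
#' layout <- message_layout()
#' layout$total_bits  # 31
#' @export
message_layout <- function(sync_bits = 7L, id_bits = 16L, crc_bits = 8L,
                           poly = 0x07) {
  total <- sync_bits + id_bits + crc_bits
  if (total != 31L)
    stop("sync, id and crc widths must sum to 31 bits, got ", total)
  if (2^id_bits < 65000)
    stop("identifier space must hold at least 65,000 codes")
  structure(
    list(sync_bits = as.integer(sync_bits), id_bits = as.integer(id_bits),
         crc_bits = as.integer(crc_bits), total_bits = as.integer(total),
         poly = as.integer(poly)),
    class = "message_layout"
  )
}

.default_layout <- message_layout()

# 256-entry byte table for the chosen polynomial; memoised per polynomial.
.crc_table_env <- new.env(parent = emptyenv())

.crc8_byte_table <- function(poly = 0x07) {
  key <- as.character(poly)
  tab <- .crc_table_env[[key]]
  if (!is.null(tab)) return(tab)
  tab <- integer(256L)
  for (b in 0:255) {
    crc <- b
    for (k in 1:8) {
      crc <- if (bitwAnd(crc, 0x80L) != 0L)
        bitwAnd(bitwXor(bitwShiftL(crc, 1L), poly), 0xFFL)
      else
        bitwAnd(bitwShiftL(crc, 1L), 0xFFL)
    }
    tab[b + 1L] <- crc
  }
  .crc_table_env[[key]] <- tab
  tab
}

#' CRC-8 checksum of a bit sequence
#'
#' Computes the 8-bit CRC of `bits` (a vector of 0/1, most significant bit
#' first) by long division with the generator polynomial, zero initial
#' value, no reflection and no final XOR. The payload length must be a
#' positive multiple of one bit; the tag encoder always supplies the 16
#' identifier bits, but any length is accepted so that the implementation
#' can be checked against published test vectors (the ASCII string
#' "123456789" as a 72-bit payload yields 0xF4 for polynomial 0x07).
#'
#' The chosen configuration is linear over bitwise XOR:
#' `crc8(xor(a, b)) == bitwXor(crc8(a), crc8(b))` for equal-length payloads.
#'
#' @param bits integer vector of 0s and 1s, MSB first
#' @param layout a [message_layout()]; only the polynomial is used
#' @return integer in \[0, 255\]
#' @export
crc8 <- function(bits, layout = .default_layout) {
  bits <- as.integer(bits)
  if (length(bits) == 0L || any(is.na(bits)) || any(bits < 0L | bits > 1L))
    stop("payload must be a non-empty vector of 0/1 bits")
  poly <- layout$poly
  crc <- 0L
  for (b in bits) {
    fb <- bitwXor(bitwShiftR(crc, 7L), b)    # bit shifted out XOR input bit
    crc <- bitwAnd(bitwShiftL(crc, 1L), 0xFFL)
    if (fb != 0L) crc <- bitwXor(crc, poly)
  }
  crc
}

# CRC-8 of a 16-bit identifier via the byte table (vectorised, used for
# bulk validation).
.crc8_id <- function(id, layout = .default_layout) {
  tab <- .crc8_byte_table(layout$poly)
  hi <- id %/% 256L
  lo <- id %% 256L
  tab[bitwXor(tab[hi + 1L], lo) + 1L]
}

.int_to_bits <- function(x, width) {
  vapply(seq_len(width), function(i)
    as.integer(bitwAnd(bitwShiftR(x, width - i), 1L)), integer(1L))
}

.bits_to_int <- function(bits) {
  out <- 0L
  for (b in bits) out <- bitwOr(bitwShiftL(out, 1L), as.integer(b))
  out
}

#' Encode a tag identifier as a 31-bit codeword
#'
#' @param id integer tag identifier in \[0, 65535\]
#' @param layout a [message_layout()]
#' @return integer vector of 31 bits (sync, id, CRC), MSB first
#' @export
encode_tag <- function(id, layout = .default_layout) {
  id <- as.integer(id)
  if (is.na(id) || id < 0L || id >= 2^layout$id_bits)
    stop("tag id must lie in [0, ", 2^layout$id_bits - 1L, "]")
  id_bits <- .int_to_bits(id, layout$id_bits)
  crc_bits <- .int_to_bits(crc8(id_bits, layout), layout$crc_bits)
  c(.SYNC_BITS, id_bits, crc_bits)
}

#' Validate a received 31-bit codeword
#'
#' Recomputes the CRC over the identifier field and compares it with the
#' embedded CRC field. The sync preamble is carried but not compared: the
#' receiver has already synchronised on it before any payload bits exist,
#' so CRC agreement is the sole validity criterion. A uniformly random
#' word therefore validates with probability 1/256.
#'
#' @param codeword integer vector of 31 bits, or an integer holding the
#'   31-bit word
#' @param layout a [message_layout()]
#' @return list with elements `id` (integer) and `valid` (logical)
#' @export
validate_decode <- function(codeword, layout = .default_layout) {
  if (length(codeword) == 1L)   # an integer-held 31-bit word
    codeword <- .int_to_bits(as.integer(codeword), layout$total_bits)
  codeword <- as.integer(codeword)
  if (length(codeword) != layout$total_bits)
    stop("codeword must be ", layout$total_bits, " bits")
  s <- layout$sync_bits
  id_bits <- codeword[(s + 1L):(s + layout$id_bits)]
  crc_bits <- codeword[(s + layout$id_bits + 1L):layout$total_bits]
  id <- .bits_to_int(id_bits)
  list(id = id, valid = crc8(id_bits, layout) == .bits_to_int(crc_bits))
}

#' Bulk-validate 31-bit words held as integers
#'
#' Vectorised equivalent of [validate_decode()] for Monte-Carlo work:
#' extracts the identifier and CRC fields of each word by integer
#' arithmetic and compares the embedded CRC with a table-driven
#' recomputation.
#'
#' @param words numeric/integer vector of 31-bit words
#' @param layout a [message_layout()]
#' @return logical vector, one element per word
#' @export
validate_words <- function(words, layout = .default_layout) {
  id <- as.integer((words %/% 2^layout$crc_bits) %% 2^layout$id_bits)
  emb <- as.integer(words %% 2^layout$crc_bits)
  .crc8_id(id, layout) == emb
}

#' Tag-code serialisation helpers
#'
#' Codewords travel as 31-character "0"/"1" strings; tag identifiers are
#' rendered as 4-hex-digit uppercase strings in CSV output.
#'
#' @param bits integer bit vector (for `codeword_to_string`)
#' @param s character string of 0s and 1s (for `string_to_codeword`)
#' @param id integer tag id (for `format_tag_id`)
#' @param x hex string (for `parse_tag_id`)
#' @return the converted representation
#' @export
codeword_to_string <- function(bits) paste(as.integer(bits), collapse = "")

#' @rdname codeword_to_string
#' @export
string_to_codeword <- function(s) {
  as.integer(strsplit(s, "")[[1L]])
}

#' @rdname codeword_to_string
#' @export
format_tag_id <- function(id) sprintf("%04X", as.integer(id))

#' @rdname codeword_to_string
#' @export
parse_tag_id <- function(x) strtoi(x, base = 16L)

#' Enumerate mimic tag codes reachable within a corruption weight
#'
#' Bit corruption of a real transmission can produce a different
#' identifier whose corrupted CRC field still matches -- a "mimic" code.
#' Because the CRC is linear over XOR, a corruption pattern `e` applied to
#' the 24 identifier + CRC bits yields a valid word if and only if the CRC
#' of the pattern's identifier part equals the pattern's CRC part (zero
#' syndrome), independent of the source identifier. This function
#' enumerates every zero-syndrome pattern of Hamming weight at most
#' `max_weight` that alters the identifier, and applies each to `id`.
#'
#' The relation is symmetric (XOR with the same pattern maps the mimic
#' back to the source) and irreflexive. The CRC detects all corruptions of
#' weight 1 and 2 at this length, so mimics first appear at higher
#' weights.
#'
#' @param id source tag identifier
#' @param max_weight maximum number of flipped bits considered (>= 0)
#' @param layout a [message_layout()]
#' @return data.frame with columns `source_id`, `mimic_id`, `weight`, and
#'   `error_pattern` (flipped bit positions, 1-based within the 24
#'   id + CRC bits, as a comma-separated string)
#' @export
mimic_candidates <- function(id, max_weight, layout = .default_layout) {
  if (max_weight < 0) stop("max_weight must be >= 0")
  pats <- .zero_syndrome_patterns(max_weight, layout)
  if (nrow(pats) == 0L)
    return(data.frame(source_id = integer(), mimic_id = integer(),
                      weight = integer(), error_pattern = character(),
                      stringsAsFactors = FALSE))
  mimic_id <- bitwXor(as.integer(id), pats$id_xor)
  data.frame(source_id = as.integer(id), mimic_id = mimic_id,
             weight = pats$weight, error_pattern = pats$pattern,
             stringsAsFactors = FALSE)
}

# Zero-syndrome corruption patterns over the id+crc field, by exhaustive
# combination enumeration; memoised on (max_weight, poly).
.syndrome_env <- new.env(parent = emptyenv())

.zero_syndrome_patterns <- function(max_weight, layout = .default_layout) {
  key <- paste(max_weight, layout$poly, sep = "_")
  cached <- .syndrome_env[[key]]
  if (!is.null(cached)) return(cached)
  n <- layout$id_bits + layout$crc_bits
  # syndrome contribution of flipping bit j alone (j = 1..n, MSB first)
  single <- vapply(seq_len(n), function(j) {
    bits <- integer(n)
    bits[j] <- 1L
    idp <- bits[seq_len(layout$id_bits)]
    crcp <- .bits_to_int(bits[(layout$id_bits + 1L):n])
    bitwXor(crc8(idp, layout), crcp)
  }, integer(1L))
  id_xor_single <- vapply(seq_len(n), function(j) {
    if (j <= layout$id_bits) bitwShiftL(1L, layout$id_bits - j) else 0L
  }, integer(1L))
  rows <- list()
  w <- 1L
  while (w <= max_weight) {
    if (w <= n) {
      combs <- utils::combn(n, w)
      syn <- apply(combs, 2L, function(ix) Reduce(bitwXor, single[ix], 0L))
      keep <- which(syn == 0L)
      for (k in keep) {
        ix <- combs[, k]
        id_xor <- Reduce(bitwXor, id_xor_single[ix], 0L)
        if (id_xor != 0L)   # pattern must change the identifier
          rows[[length(rows) + 1L]] <- data.frame(
            id_xor = id_xor, weight = w,
            pattern = paste(ix, collapse = ","),
            stringsAsFactors = FALSE)
      }
    }
    w <- w + 1L
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id_xor = integer(), weight = integer(), pattern = character(),
               stringsAsFactors = FALSE)
  .syndrome_env[[key]] <- out
  out
}

#' Build a mimic lookup table for a set of deployed tags
#'
#' @param ids integer vector of deployed tag identifiers
#' @param max_weight corruption weight to search (default 4, the smallest
#'   weight at which mimics exist for this code)
#' @param layout a [message_layout()]
#' @return data.frame of source/mimic pairs restricted to `ids` as sources
#' @export
mimic_table <- function(ids, max_weight = 4L, layout = .default_layout) {
  out <- do.call(rbind, lapply(ids, mimic_candidates,
                               max_weight = max_weight, layout = layout))
  if (is.null(out))
    out <- data.frame(source_id = integer(), mimic_id = integer(),
                      weight = integer(), error_pattern = character())
  out
}
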