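#' Bit-vector helpers
#'
#' Sequences on genes and binding sites are fixed-length bit vectors of
#' length `B`. Internally they are stored as integer masks (bit 1 of the
#' string is the lowest-order bit); these helpers convert between the mask,
#' a 0/1 integer vector, and the character form used by the genome text
#' format.
#'
#' @param bits a 0/1 integer vector, or a character string such as `"10010"`.
#' @param mask an integer mask.
#' @param B bit-vector length.
#' @return `bits_to_mask()` an integer mask; `mask_to_bits()` a 0/1 integer
#'   vector of length `B`; `mask_to_string()` a character string.
#' @examples
#' bits_to_mask("101")
#' mask_to_string(5, 3)
#' @export
bits_to_mask <- function(bits) {
  if (is.character(bits)) {
    stopifnot(length(bits) == 1L)
    bits <- as.integer(strsplit(bits, "", fixed = TRUE)[[1]])
  }
  if (any(is.na(bits)) || !all(bits %in% c(0L, 1L)))
    stop("bits must be 0/1", call. = FALSE)
  if (length(bits) > 30L) stop("at most 30 bits supported", call. = FALSE)
  as.integer(sum(bits * 2^(seq_along(bits) - 1L)))
}

#' @rdname bits_to_mask
#' @export
mask_to_bits <- function(mask, B) {
  as.integer(bitwAnd(bitwShiftR(mask, seq_len(B) - 1L), 1L))
}

#' @rdname bits_to_mask
#' @export
mask_to_string <- function(mask, B) {
  paste(mask_to_bits(mask, B), collapse = "")
}

#' Hamming distance between bit masks
#'
#' @param a,b integer masks (recycled to a common length).
#' @return integer vector of distances.
#' @examples
#' hamming(bits_to_mask("1010"), bits_to_mask("1001"))
#' @export
hamming <- function(a, b) .hamming_mask(as.integer(a), as.integer(b))

# uniform random mask of B bits
random_mask <- function(B) {
  bits_to_mask(as.integer(stats::runif(B) < 0.5))
}

# mask at exact Hamming distance d from `mask` (first d bits flipped after
# shuffling is overkill for fixture construction; flip the d lowest bits of
# a chosen set). Used only to wire fixtures.
mask_at_distance <- function(mask, d, B, positions = seq_len(d)) {
  stopifnot(d <= B, length(positions) == d)
  flip <- sum(2^(positions - 1L))
  bitwXor(as.integer(mask), as.integer(flip))
}
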