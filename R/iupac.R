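# IUPAC nucleotide algebra on a 4-bit set encoding (A = 1, C = 2, G = 4,
# T = 8).  Every ambiguity code is the bitwise OR of its base set, so subset
# tests, unions and complements are single integer operations.  The gap
# character "-" encodes to 0 (the empty set).

.IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
  M = 3L, R = 5L, W = 9L, S = 6L, Y = 10L, K = 12L,
  V = 7L, H = 11L, D = 13L, B = 14L, N = 15L, "-" = 0L
)

# canonical code for each bit pattern (index = bits + 1); U normalises to T
.BITS_CODE <- c("-", "A", "C", "M", "G", "R", "S", "V",
                "T", "W", "Y", "H", "K", "D", "B", "N")

.POPCOUNT <- c(0L, 1L, 1L, 2L, 1L, 2L, 2L, 3L,
               1L, 2L, 2L, 3L, 2L, 3L, 3L, 4L)

.COMP_BITS <- vapply(0:15, function(b) {
  out <- 0L
  if (bitwAnd(b, 1L) > 0L) out <- bitwOr(out, 8L)  # A -> T
  if (bitwAnd(b, 8L) > 0L) out <- bitwOr(out, 1L)  # T -> A
  if (bitwAnd(b, 2L) > 0L) out <- bitwOr(out, 4L)  # C -> G
  if (bitwAnd(b, 4L) > 0L) out <- bitwOr(out, 2L)  # G -> C
  out
}, integer(1))

.BASE_CHARS <- c("A", "C", "G", "T")
.BASE_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L)

# split a string into uppercase single characters
.chars <- function(x) strsplit(toupper(as.character(x)), "", fixed = TRUE)[[1]]

# encode one string as an integer bits vector; errors name the 1-based
# position of the first invalid character
.seq_bits <- function(x, allow_gap = TRUE, what = "sequence") {
  ch <- .chars(x)
  b <- unname(.IUPAC_BITS[ch])
  bad <- which(is.na(b) | (!allow_gap & b == 0L))
  if (length(bad) > 0L) {
    stop(sprintf("invalid character '%s' at position %d in %s",
                 ch[bad[1L]], bad[1L], what), call. = FALSE)
  }
  b
}

.bits_string <- function(bits) paste(.BITS_CODE[bits + 1L], collapse = "")

# concrete base characters represented by one bits value
.bits_set <- function(bits) .BASE_CHARS[bitwAnd(bits, .BASE_BITS) > 0L]

#' Degeneracy of an IUPAC sequence
#'
#' The degeneracy (degree of degeneration, D) of a degenerate oligonucleotide
#' is the number of concrete A/C/G/T sequences it represents: the product of
#' the per-position IUPAC set sizes.
#'
#' @param x a character string of IUPAC nucleotide codes (no gaps), or a
#'   [degenerate_primer()] object.
#' @return a single number (can exceed integer range for long, highly
#'   degenerate sequences).
#' @examples
#' iupac_degeneracy("ACGT")  # 1
#' iupac_degeneracy("ANRT")  # 4 * 2 = 8
#' @export
iupac_degeneracy <- function(x) {
  if (inherits(x, "degenerate_primer")) x <- x$sequence
  bits <- .seq_bits(x, allow_gap = FALSE, what = "primer")
  prod(as.numeric(.POPCOUNT[bits + 1L]))
}

#' Enumerate the concrete sequences of a degenerate primer
#'
#' Expands every IUPAC ambiguity code so that the result is the full set of
#' concrete A/C/G/T sequences the primer represents.  The set size equals
#' [iupac_degeneracy()].
#'
#' @inheritParams iupac_degeneracy
#' @return a character vector of concrete sequences, sorted.
#' @examples
#' expand_degeneracies("AN")  # "AA" "AC" "AG" "AT"
#' @export
expand_degeneracies <- function(x) {
  if (inherits(x, "degenerate_primer")) x <- x$sequence
  bits <- .seq_bits(x, allow_gap = FALSE, what = "primer")
  sets <- lapply(bits, .bits_set)
  grid <- expand.grid(rev(sets), stringsAsFactors = FALSE)
  out <- do.call(paste0, rev(grid))
  sort(out)
}

#' Reverse complement of an IUPAC string
#'
#' Ambiguity codes map to the code of the complementary base set
#' (R <-> Y, K <-> M, W and S are self-complementary, B <-> V, D <-> H,
#' N <-> N); gaps are preserved.  Applying the function twice returns the
#' input (involution).
#'
#' @param x a character string of IUPAC codes (gaps allowed).
#' @return the reverse-complemented string.
#' @examples
#' reverse_complement("CYT")  # "ARG"
#' @export
reverse_complement <- function(x) {
  bits <- .seq_bits(x, allow_gap = TRUE)
  .bits_string(rev(.COMP_BITS[bits + 1L]))
}

#' Does a template base satisfy a degenerate primer position?
#'
#' Subset semantics: a template code matches a primer code if and only if the
#' template's base set is contained in the primer's base set.  A concrete
#' template base therefore matches iff it is one of the bases the primer
#' position can pair as written; an ambiguous template base matches only when
#' every base it could be is covered.  A gap in the template never matches.
#'
#' @param primer_code,template_code single IUPAC characters (vectorised,
#'   recycled).  The template may contain "-"; the primer may not.
#' @return logical vector.
#' @examples
#' base_matches("H", "T")  # TRUE:  T is in {A,C,T}
#' base_matches("Y", "G")  # FALSE
#' base_matches("W", "N")  # FALSE: {A,C,G,T} is not a subset of {A,T}
#' @export
base_matches <- function(primer_code, template_code) {
  p <- unname(.IUPAC_BITS[toupper(primer_code)])
  t <- unname(.IUPAC_BITS[toupper(template_code)])
  if (anyNA(p) || any(p == 0L)) {
    stop("primer positions must be non-gap IUPAC codes", call. = FALSE)
  }
  if (anyNA(t)) stop("invalid IUPAC code in template", call. = FALSE)
  n <- max(length(p), length(t))
  p <- rep_len(p, n)
  t <- rep_len(t, n)
  t != 0L & bitwAnd(p, t) == t
}

# vectorised subset-match on bits vectors; template gap (0) never matches
.bits_match <- function(p_bits, t_bits) {
  t_bits != 0L & bitwAnd(p_bits, t_bits) == t_bits
}
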