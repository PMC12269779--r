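#' Construct a degenerate PCR primer
#'
#' A primer is a 5'-to-3' string of IUPAC nucleotide codes together with its
#' orientation relative to the plus strand of the alignment it will be tested
#' against.  Reverse primers are written, as in the lab, 5'-to-3' on the
#' minus strand; all binding and scoring functions place them on the plus
#' strand internally.
#'
#' @param name short identifier.
#' @param sequence IUPAC string, 5'-to-3'.  Case-insensitive; U is read as T.
#' @param orientation `"forward"` or `"reverse"`.
#' @return an object of class `degenerate_primer` with fields `name`,
#'   `sequence`, `orientation`, `length` and `degeneracy`.
#' @examples
#' degenerate_primer("AscCOI2_F", "CCDGATATAGCHTTYCCWCG", "forward")
#' @export
degenerate_primer <- function(name, sequence,
                              orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  seq <- gsub("U", "T", toupper(as.character(sequence)), fixed = TRUE)
  bits <- .seq_bits(seq, allow_gap = FALSE, what = sprintf("primer '%s'", name))
  if (length(bits) < 1L) stop("primer sequence is empty", call. = FALSE)
  structure(
    list(name = name,
         sequence = .bits_string(bits),
         orientation = orientation,
         length = length(bits),
         degeneracy = prod(as.numeric(.POPCOUNT[bits + 1L]))),
    class = "degenerate_primer"
  )
}

#' @export
print.degenerate_primer <- function(x, ...) {
  cat(sprintf("<degenerate_primer> %s (%s)\n  5'-%s-3'  length %d, degeneracy %g\n",
              x$name, x$orientation, x$sequence, x$length, x$degeneracy))
  invisible(x)
}

#' Pair a forward and a reverse primer
#'
#' Optionally carries the primers' binding sites as 1-based inclusive
#' alignment-column intervals on the plus strand, and the expected amplicon
#' size.  When both sites are given the forward site must precede the
#' reverse site without overlap.  A supplied `expected_amplicon` is stored as
#' given (published amplicon sizes are treated as metadata, not recomputed);
#' when omitted and both sites are set it defaults to
#' `reverse_site[2] - forward_site[1] + 1`.
#'
#' @param forward,reverse [degenerate_primer()] objects with the matching
#'   orientations.
#' @param forward_site,reverse_site integer length-2 vectors `c(start, end)`
#'   or `NULL`.
#' @param expected_amplicon integer bp or `NULL`.
#' @return an object of class `primer_pair`.
#' @export
primer_pair <- function(forward, reverse, forward_site = NULL,
                        reverse_site = NULL, expected_amplicon = NULL) {
  stopifnot(inherits(forward, "degenerate_primer"),
            inherits(reverse, "degenerate_primer"))
  if (forward$orientation != "forward" || reverse$orientation != "reverse") {
    stop("pair needs one forward and one reverse primer", call. = FALSE)
  }
  chk_site <- function(s, primer, label) {
    if (is.null(s)) return(NULL)
    s <- as.integer(s)
    if (length(s) != 2L || anyNA(s) || s[1] < 1L || s[2] < s[1]) {
      stop(sprintf("%s must be c(start, end) with 1 <= start <= end", label),
           call. = FALSE)
    }
    if (s[2] - s[1] + 1L != primer$length) {
      stop(sprintf("%s width %d does not equal primer length %d",
                   label, s[2] - s[1] + 1L, primer$length), call. = FALSE)
    }
    s
  }
  forward_site <- chk_site(forward_site, forward, "forward_site")
  reverse_site <- chk_site(reverse_site, reverse, "reverse_site")
  if (!is.null(forward_site) && !is.null(reverse_site) &&
      reverse_site[1] <= forward_site[2]) {
    stop("forward_site must precede reverse_site with no overlap",
         call. = FALSE)
  }
  if (is.null(expected_amplicon) && !is.null(forward_site) &&
      !is.null(reverse_site)) {
    expected_amplicon <- reverse_site[2] - forward_site[1] + 1L
  }
  structure(
    list(forward = forward, reverse = reverse,
         forward_site = forward_site, reverse_site = reverse_site,
         expected_amplicon = if (is.null(expected_amplicon)) NULL
                             else as.integer(expected_amplicon)),
    class = "primer_pair"
  )
}

#' @export
print.primer_pair <- function(x, ...) {
  fmt_site <- function(s) if (is.null(s)) "unset" else sprintf("%d-%d", s[1], s[2])
  cat(sprintf("<primer_pair> %s / %s\n", x$forward$name, x$reverse$name))
  cat(sprintf("  F 5'-%s-3'  site %s\n", x$forward$sequence,
              fmt_site(x$forward_site)))
  cat(sprintf("  R 5'-%s-3'  site %s\n", x$reverse$sequence,
              fmt_site(x$reverse_site)))
  if (!is.null(x$expected_amplicon)) {
    cat(sprintf("  expected amplicon %d bp\n", x$expected_amplicon))
  }
  invisible(x)
}

#' Read primer definitions from a TSV file
#'
#' Expects a tab-separated file with header columns `name`, `sequence` and
#' `orientation`.
#'
#' @param path file path.
#' @return a named list of [degenerate_primer()] objects.
#' @export
read_primers <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "sequence", "orientation")
  if (!all(need %in% names(tab))) {
    stop("primer TSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(seq_len(nrow(tab)), function(i) {
    degenerate_primer(tab$name[i], tab$sequence[i], tab$orientation[i])
  })
  names(out) <- tab$name
  out
}

#' Published ascidian COI mini-barcode primer pairs
#'
#' Returns the original ascidian-specific COI primer pair (AscCOI) and its
#' redesigned successor (AscCOI2), with their binding sites on the reference
#' COI alignment coordinate system (1-based columns) and published amplicon
#' sizes.  The AscCOI2 reverse site sits 21 bp 3' of the AscCOI reverse site;
#' forward sites coincide.
#'
#' @return a named list with `primer_pair` elements `AscCOI` and `AscCOI2`.
#' @examples
#' ascidian_coi_primers()$AscCOI2
#' @export
ascidian_coi_primers <- function() {
  path <- system.file("extdata", "ascidian_coi_primers.tsv",
                      package = "primerscreen", mustWork = TRUE)
  p <- read_primers(path)
  list(
    AscCOI = primer_pair(p$AscCOI_F, p$AscCOI_R,
                         forward_site = c(361L, 380L),
                         reverse_site = c(532L, 554L),
                         expected_amplicon = 197L),
    AscCOI2 = primer_pair(p$AscCOI2_F, p$AscCOI2_R,
                          forward_site = c(361L, 380L),
                          reverse_site = c(553L, 575L),
                          expected_amplicon = 216L)
  )
}
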