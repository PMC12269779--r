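# Kimura two-parameter (K80) pairwise distances and the barcoding gap:
# d = -1/2 * ln((1 - 2P - Q) * sqrt(1 - 2Q)), with P the transition and Q
# the transversion proportion over pairwise-complete sites.

#' K80 distance between two aligned sequences
#'
#' Comparison is restricted to columns where both sequences carry a concrete
#' A/C/G/T base (pairwise deletion of gaps and ambiguity codes).  The
#' estimate is invalid — `distance` is `NA` — when the log arguments leave
#' the model's domain (saturation) or fewer than `min_overlap` sites were
#' compared.
#'
#' @param seq_a,seq_b gapped IUPAC strings of equal length.
#' @param min_overlap minimum number of compared sites (default 100,
#'   suitable for short mini-barcode alignments).
#' @return list with `P`, `Q`, `distance`, `valid` and `sites` (number of
#'   compared sites).
#' @examples
#' # 10 transitions and 5 transversions over 100 sites:
#' # d = -0.5 * log(0.75 * sqrt(0.90)) = 0.17018
#' @export
k80_distance <- function(seq_a, seq_b, min_overlap = 100L) {
  a <- .seq_bits(seq_a, allow_gap = TRUE, what = "sequence a")
  b <- .seq_bits(seq_b, allow_gap = TRUE, what = "sequence b")
  if (length(a) != length(b)) {
    stop("sequences have different lengths", call. = FALSE)
  }
  .k80_bits(a, b, min_overlap)
}

# purine/pyrimidine group of a concrete bits value: A(1),G(4) -> 1; C(2),T(8) -> 2
.TS_GROUP <- c(NA, 1L, 2L, NA, 1L, NA, NA, NA, 2L, rep(NA, 7L))

.k80_bits <- function(a, b, min_overlap) {
  concrete <- .POPCOUNT[a + 1L] == 1L & .POPCOUNT[b + 1L] == 1L
  n <- sum(concrete)
  if (n == 0L) {
    return(list(P = NA_real_, Q = NA_real_, distance = NA_real_,
                valid = FALSE, sites = 0L))
  }
  a <- a[concrete]
  b <- b[concrete]
  diff <- a != b
  ga <- .TS_GROUP[a + 1L]
  gb <- .TS_GROUP[b + 1L]
  ts <- sum(diff & ga == gb)
  tv <- sum(diff & ga != gb)
  P <- ts / n
  Q <- tv / n
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0 || n < min_overlap) {
    return(list(P = P, Q = Q, distance = NA_real_, valid = FALSE, sites = n))
  }
  list(P = P, Q = Q, distance = -0.5 * log(arg1 * sqrt(arg2)),
       valid = TRUE, sites = n)
}

#' All pairwise K80 distances of an alignment
#'
#' Computes every unordered pair, labels it `intra` when the two records
#' share a species label and `inter` otherwise, and retains invalid
#' (saturated or under-covered) pairs with `valid = FALSE`.
#'
#' @param aln an [aligned_set()] with at least 2 records.
#' @param min_overlap see [k80_distance()].
#' @return an object of class `pairwise_distances`: data frame with columns
#'   `id_a`, `id_b`, `comparison`, `P`, `Q`, `distance`, `valid`, `sites`.
#' @export
distance_matrix <- function(aln, min_overlap = 100L) {
  stopifnot(inherits(aln, "aligned_set"))
  if (aln$n < 2L) stop("need at least 2 records", call. = FALSE)
  m <- .aln_bits(aln)
  pairs <- utils::combn(aln$n, 2L)
  res <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]
    j <- pairs[2L, k]
    d <- .k80_bits(m[i, ], m[j, ], min_overlap)
    res[[k]] <- data.frame(
      id_a = aln$ids[i], id_b = aln$ids[j],
      comparison = if (aln$species[i] == aln$species[j]) "intra" else "inter",
      P = d$P, Q = d$Q, distance = d$distance, valid = d$valid,
      sites = d$sites, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  class(out) <- c("pairwise_distances", "data.frame")
  out
}

#' @export
print.pairwise_distances <- function(x, ...) {
  cat(sprintf(
    "<pairwise_distances> %d pairs (%d intra, %d inter; %d invalid/saturated)\n",
    nrow(x), sum(x$comparison == "intra"), sum(x$comparison == "inter"),
    sum(!x$valid)))
  invisible(x)
}

#' Barcoding-gap statistics
#'
#' The barcoding gap is the separation between the largest valid
#' intraspecific and the smallest valid interspecific distance
#' (`gap = min_inter - max_intra`; negative when the classes overlap — no
#' clamping).  Histograms of both classes are binned at `bin_width`.
#'
#' @param dists a [distance_matrix()] result.
#' @param bin_width histogram bin width in substitutions/site (default 0.01).
#' @return an object of class `barcoding_gap`: list with `max_intra`,
#'   `min_inter`, `gap`, `intra_histogram`, `inter_histogram` (data frames
#'   with `bin_start`, `count`), `bin_width` and the retained distances.
#' @export
gap_statistics <- function(dists, bin_width = 0.01) {
  stopifnot(inherits(dists, "pairwise_distances"))
  intra <- dists$distance[dists$comparison == "intra" & dists$valid]
  inter <- dists$distance[dists$comparison == "inter" & dists$valid]
  if (length(intra) == 0L) {
    stop("no valid intraspecific pair (single-species input?)", call. = FALSE)
  }
  if (length(inter) == 0L) {
    stop("no valid interspecific pair", call. = FALSE)
  }
  hist_of <- function(v) {
    breaks <- seq(0, (max(v) %/% bin_width + 1) * bin_width, by = bin_width)
    h <- graphics::hist(v, breaks = breaks, plot = FALSE, right = FALSE)
    data.frame(bin_start = h$breaks[-length(h$breaks)], count = h$counts)
  }
  structure(
    list(max_intra = max(intra), min_inter = min(inter),
         gap = min(inter) - max(intra),
         intra_histogram = hist_of(intra),
         inter_histogram = hist_of(inter),
         bin_width = bin_width,
         intra = intra, inter = inter,
         n_saturated = sum(!dists$valid)),
    class = "barcoding_gap"
  )
}

#' @export
print.barcoding_gap <- function(x, ...) {
  cat("<barcoding_gap>\n")
  cat(sprintf("  max intraspecific distance %.4f (%d pairs)\n",
              x$max_intra, length(x$intra)))
  cat(sprintf("  min interspecific distance %.4f (%d pairs)\n",
              x$min_inter, length(x$inter)))
  cat(sprintf("  gap %.4f%s\n", x$gap,
              if (x$gap <= 0) "  [classes overlap]" else ""))
  if (x$n_saturated > 0L) {
    cat(sprintf("  %d saturated/invalid pairs excluded\n", x$n_saturated))
  }
  invisible(x)
}

#' Plot intra- vs interspecific distance distributions
#'
#' @param x a [gap_statistics()] result.
#' @param ... passed to [graphics::barplot()].
#' @return `x`, invisibly.
#' @export
plot.barcoding_gap <- function(x, ...) {
  all_bins <- seq(0, max(x$intra_histogram$bin_start,
                         x$inter_histogram$bin_start), by = x$bin_width)
  cnt <- function(h) {
    out <- numeric(length(all_bins))
    out[match(round(h$bin_start, 10), round(all_bins, 10))] <- h$count
    out
  }
  mat <- rbind(intra = cnt(x$intra_histogram), inter = cnt(x$inter_histogram))
  graphics::barplot(mat, beside = TRUE, names.arg = round(all_bins, 3),
                    col = c("firebrick", "steelblue"), border = NA,
                    xlab = "K80 distance", ylab = "pairs", las = 2, ...)
  graphics::legend("topright", bty = "n", fill = c("firebrick", "steelblue"),
                   legend = c("intraspecific", "interspecific"))
  invisible(x)
}
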