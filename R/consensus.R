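# Conservation profiling: IUPAC consensus of an alignment and the
# sliding-window similarity index 1/D, where D is the product of per-column
# IUPAC set sizes ("degree of degeneration") over the window.

#' Build an IUPAC consensus sequence
#'
#' Each alignment column is summarised by the minimal IUPAC code covering
#' every base whose frequency among non-gap residues reaches
#' `inclusion_threshold`, and always covering the most frequent base(s).
#' Ambiguous residues in the data contribute fractionally (1/k to each of
#' their k bases).  All-gap columns are called N with a non-gap proportion of
#' 0.  The per-column fraction of records with a non-gap character is
#' returned alongside the codes, matching the "proportion of sequences
#' present at each position" track displayed with conservation profiles.
#'
#' @param aln an [aligned_set()].
#' @param inclusion_threshold fraction in `[0, 1)`; bases rarer than this are
#'   excluded from the consensus code.  The default 0.05 suppresses rare
#'   variants and sequencing noise while retaining genuinely variable sites.
#' @return an object of class `consensus_seq` with fields `codes` (per-column
#'   IUPAC characters), `nongap_proportion`, `inclusion_threshold` and
#'   `length`.
#' @export
build_consensus <- function(aln, inclusion_threshold = 0.05) {
  stopifnot(inherits(aln, "aligned_set"))
  if (!is.numeric(inclusion_threshold) || inclusion_threshold < 0 ||
      inclusion_threshold >= 1) {
    stop("inclusion_threshold must be in [0, 1)", call. = FALSE)
  }
  m <- .aln_bits(aln)
  ncol_a <- ncol(m)
  codes <- character(ncol_a)
  prop <- numeric(ncol_a)
  # per-residue fractional weight of each base: weight 1/popcount to each
  # member of the residue's base set
  w <- matrix(1 / .POPCOUNT[m + 1L], nrow = nrow(m))  # Inf where gap
  w[m == 0L] <- 0
  for (j in seq_len(ncol_a)) {
    b <- m[, j]
    nongap <- b != 0L
    prop[j] <- mean(nongap)
    if (!any(nongap)) {
      codes[j] <- "N"
      next
    }
    cnt <- c(A = 0, C = 0, G = 0, T = 0)
    for (k in seq_along(.BASE_BITS)) {
      cnt[k] <- sum(w[, j][bitwAnd(b, .BASE_BITS[k]) > 0L])
    }
    freq <- cnt / sum(cnt)
    keep <- cnt > 0 & freq >= inclusion_threshold  # only observed bases
    keep[freq == max(freq)] <- TRUE   # always cover the most frequent base(s)
    codes[j] <- .BITS_CODE[sum(.BASE_BITS[keep]) + 1L]
  }
  structure(
    list(codes = codes, nongap_proportion = prop,
         inclusion_threshold = inclusion_threshold, length = ncol_a),
    class = "consensus_seq"
  )
}

#' @export
print.consensus_seq <- function(x, ...) {
  d <- .POPCOUNT[unname(.IUPAC_BITS[x$codes]) + 1L]
  cat(sprintf(
    "<consensus_seq> %d columns (inclusion threshold %.2f)\n  %d degenerate columns; mean non-gap proportion %.3f\n",
    x$length, x$inclusion_threshold, sum(d > 1L),
    mean(x$nongap_proportion)))
  invisible(x)
}

#' Sliding-window similarity profile (1/D)
#'
#' For each window of `window_size` consensus columns, computes the degree of
#' degeneration D (the product of per-column IUPAC set sizes), the
#' similarity index 1/D, and the mean non-gap proportion.  High index values
#' flag conserved, low-degeneracy regions suitable for primer binding.
#'
#' @param cons a [build_consensus()] result.
#' @param window_size window width in columns (default 20, a typical primer
#'   length).
#' @param step step between window starts in columns (default 1).
#' @return an object of class `similarity_profile`: a data frame with columns
#'   `window_start`, `degeneration`, `index` and `proportion`, plus
#'   attributes `window_size` and `step`.
#' @export
similarity_profile <- function(cons, window_size = 20L, step = 1L) {
  stopifnot(inherits(cons, "consensus_seq"))
  window_size <- as.integer(window_size)
  step <- as.integer(step)
  if (step < 1L) stop("step must be >= 1", call. = FALSE)
  if (window_size < 1L || window_size > cons$length) {
    stop(sprintf("window_size %d exceeds alignment length %d",
                 window_size, cons$length), call. = FALSE)
  }
  sizes <- as.numeric(.POPCOUNT[unname(.IUPAC_BITS[cons$codes]) + 1L])
  starts <- seq.int(1L, cons$length - window_size + 1L, by = step)
  degeneration <- vapply(starts, function(s) {
    prod(sizes[s:(s + window_size - 1L)])
  }, numeric(1))
  proportion <- vapply(starts, function(s) {
    mean(cons$nongap_proportion[s:(s + window_size - 1L)])
  }, numeric(1))
  out <- data.frame(window_start = starts,
                    degeneration = degeneration,
                    index = 1 / degeneration,
                    proportion = proportion)
  structure(out, class = c("similarity_profile", "data.frame"),
            window_size = window_size, step = step)
}

#' @export
print.similarity_profile <- function(x, ...) {
  cat(sprintf(
    "<similarity_profile> %d windows (size %d, step %d)\n  index range %.4g-%.4g\n",
    nrow(x), attr(x, "window_size"), attr(x, "step"),
    min(x$index), max(x$index)))
  invisible(x)
}

#' Plot a similarity profile
#'
#' Two-track display: the similarity index 1/D as a filled profile and the
#' mean non-gap sequence proportion as a grey overlay, against window start
#' column.  Optional vertical lines mark primer sites.
#'
#' @param x a [similarity_profile()].
#' @param sites optional list of `c(start, end)` intervals to mark.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.similarity_profile <- function(x, sites = NULL, ...) {
  graphics::plot(x$window_start, x$index, type = "h", col = "darkgreen",
                 xlab = "window start (alignment column)",
                 ylab = "similarity index (1/D)", ylim = c(0, 1), ...)
  graphics::lines(x$window_start, x$proportion, col = "grey50", lwd = 1.5)
  if (!is.null(sites)) {
    for (s in sites) graphics::abline(v = s, lty = 2, col = "red")
  }
  graphics::legend("topright", bty = "n", lwd = c(1, 1.5),
                   col = c("darkgreen", "grey50"),
                   legend = c("1/D", "non-gap proportion"))
  invisible(x)
}

#' Summarise a profile over an alignment interval
#'
#' Summarises the windows overlapping a 1-based inclusive column interval,
#' e.g. a primer binding site.
#'
#' @param profile a [similarity_profile()].
#' @param interval integer `c(start, end)` in alignment columns.
#' @return a list with `min_index`, `max_index` and `mean_proportion` over
#'   the overlapping windows.
#' @export
profile_over_interval <- function(profile, interval) {
  stopifnot(inherits(profile, "similarity_profile"))
  interval <- as.integer(interval)
  w <- attr(profile, "window_size")
  keep <- profile$window_start <= interval[2L] &
    (profile$window_start + w - 1L) >= interval[1L]
  if (!any(keep)) stop("no window overlaps the interval", call. = FALSE)
  list(min_index = min(profile$index[keep]),
       max_index = max(profile$index[keep]),
       mean_proportion = mean(profile$proportion[keep]))
}
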