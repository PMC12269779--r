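# Position- and type-weighted mismatch penalty scoring.  Each primer
# position contributes position_factor(distance from the 3' terminus) times
# a type-dependent pair penalty; forward and reverse scores are summed and a
# template is classified Working when the combined score falls below the
# threshold (default 150, the midpoint of the empirical 100-200 transition
# zone between amplification success and failure).

#' Penalty weight matrices
#'
#' @param position_factor numeric vector of multipliers indexed by distance
#'   from the primer's 3' terminus (element 1 = terminal base).  Must be
#'   non-increasing: 3'-proximal mismatches are penalised at least as hard as
#'   distal ones.  Primers longer than the vector reuse its last value.
#' @param type_factor 4 x 6 numeric matrix of mismatch-type multipliers:
#'   rows = primer base (A, C, G, T), columns = compared template base
#'   (A, C, G, T, gap, N).  Matching concrete pairs (the diagonal) must be 0.
#' @param adjacency_factor extra multiplier applied to a mismatch whose
#'   neighbouring position also mismatches (default 1: no adjacency
#'   penalty).
#' @param gap_as_missing,n_as_missing when `TRUE`, a template gap / N makes
#'   the score missing instead of being scored through its matrix column
#'   (defaults `FALSE`: gaps and Ns receive penalties).
#' @return an object of class `penalty_matrices`.
#' @seealso [default_penalty_matrices()] for the packaged weights.
#' @export
penalty_matrices <- function(position_factor, type_factor,
                             adjacency_factor = 1,
                             gap_as_missing = FALSE, n_as_missing = FALSE) {
  position_factor <- as.numeric(position_factor)
  if (length(position_factor) < 1L || any(position_factor < 0)) {
    stop("position_factor must be a non-negative vector", call. = FALSE)
  }
  if (any(diff(position_factor) > 1e-12)) {
    stop("position_factor must be non-increasing with distance from the 3' end",
         call. = FALSE)
  }
  type_factor <- as.matrix(type_factor)
  if (!all(dim(type_factor) == c(4L, 6L))) {
    stop("type_factor must be 4 x 6 (primer A,C,G,T x template A,C,G,T,gap,N)",
         call. = FALSE)
  }
  dimnames(type_factor) <- list(c("A", "C", "G", "T"),
                                c("A", "C", "G", "T", "gap", "N"))
  if (any(type_factor < 0)) stop("type factors must be >= 0", call. = FALSE)
  if (any(diag(type_factor[, 1:4]) != 0)) {
    stop("type_factor must be 0 on matching concrete pairs", call. = FALSE)
  }
  out <- list(position_factor = position_factor,
              type_factor = type_factor,
              adjacency_factor = as.numeric(adjacency_factor),
              gap_as_missing = isTRUE(gap_as_missing),
              n_as_missing = isTRUE(n_as_missing))
  out$pair_table <- .pair_penalty_table(out)  # cached 16x16 lookup
  structure(out, class = "penalty_matrices")
}

#' Packaged default penalty weights
#'
#' Loads the versioned weight tables shipped under `inst/extdata`
#' (`position_weights_v1.tsv`, `mismatch_type_weights_v1.tsv`).  These are
#' package-calibrated defaults: position weights decay from 100 at the 3'
#' terminal base to 2 beyond position 19, and type weights penalise
#' destabilising duplex mismatches more than near-stable wobble pairings.
#'
#' @param adjacency_factor,gap_as_missing,n_as_missing see
#'   [penalty_matrices()]; defaults reproduce the standard evaluation
#'   setting (no adjacency penalty, gaps and Ns scored rather than treated
#'   as missing).
#' @return a `penalty_matrices` object.
#' @export
default_penalty_matrices <- function(adjacency_factor = 1,
                                     gap_as_missing = FALSE,
                                     n_as_missing = FALSE) {
  pos <- utils::read.delim(system.file("extdata", "position_weights_v1.tsv",
                                       package = "primerscreen",
                                       mustWork = TRUE))
  typ <- utils::read.delim(system.file("extdata",
                                       "mismatch_type_weights_v1.tsv",
                                       package = "primerscreen",
                                       mustWork = TRUE))
  penalty_matrices(pos$factor, as.matrix(typ[, -1L]),
                   adjacency_factor = adjacency_factor,
                   gap_as_missing = gap_as_missing,
                   n_as_missing = n_as_missing)
}

# 16 x 16 pair-penalty lookup (primer bits x template bits), averaging rule:
# mean over ordered concrete pairs, with template gap (bits 0) and N
# (bits 15) routed through their dedicated columns.
.pair_penalty_table <- function(matrices) {
  tf <- matrices$type_factor
  tab <- matrix(NA_real_, 16L, 16L)
  base_idx <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  for (p in 1:15) {
    px <- base_idx[.bits_set(p)]
    # template gap column
    tab[p + 1L, 1L] <- mean(tf[px, "gap"])
    for (t in 1:15) {
      if (t == 15L) {
        tab[p + 1L, t + 1L] <- mean(tf[px, "N"])
      } else {
        ty <- base_idx[.bits_set(t)]
        grid <- expand.grid(px, ty)
        vals <- ifelse(grid[[1L]] == grid[[2L]], 0,
                       tf[cbind(grid[[1L]], grid[[2L]])])
        tab[p + 1L, t + 1L] <- mean(vals)
      }
    }
  }
  tab
}

#' Penalty for one primer/template code pair
#'
#' Averaging rule over degeneracies: the mean over all ordered concrete
#' pairs (x in the primer code's set, y in the template code's set) of 0 for
#' x = y and `type_factor[x, y]` otherwise.  A partially matching wobble
#' template therefore earns a reduced penalty.  Template gap and N use their
#' dedicated weight columns (averaged over the primer code's set).
#'
#' @param primer_code,template_code single IUPAC characters (vectorised).
#' @param matrices a [penalty_matrices()].
#' @return non-negative numeric vector.
#' @examples
#' m <- default_penalty_matrices()
#' pair_penalty("A", "A", m)  # 0
#' pair_penalty("W", "A", m)  # half the T-vs-A factor
#' @export
pair_penalty <- function(primer_code, template_code,
                         matrices = default_penalty_matrices()) {
  stopifnot(inherits(matrices, "penalty_matrices"))
  p <- unname(.IUPAC_BITS[toupper(primer_code)])
  t <- unname(.IUPAC_BITS[toupper(template_code)])
  if (anyNA(p) || any(p == 0L)) {
    stop("primer positions must be non-gap IUPAC codes", call. = FALSE)
  }
  if (anyNA(t)) stop("invalid IUPAC code in template", call. = FALSE)
  tab <- matrices$pair_table
  n <- max(length(p), length(t))
  tab[cbind(rep_len(p, n) + 1L, rep_len(t, n) + 1L)]
}

#' Penalty score of a primer against a template site
#'
#' Sum over primer positions of
#' `position_factor(distance from 3') * pair_penalty * adjacency multiplier`,
#' where the adjacency multiplier applies to mismatches flanked by another
#' mismatching position.  Reverse primers are evaluated in their own
#' orientation against the reverse-complemented plus-strand site, so
#' distance 1 is always the biologically critical 3'-terminal base.
#'
#' @param primer a [degenerate_primer()].
#' @param template_site plus-strand IUPAC string, same length as the primer.
#' @param matrices a [penalty_matrices()].
#' @return list with `score` (non-negative, `NA` when missing) and `missing`
#'   (`TRUE` when a gap/N was encountered under `gap_as_missing` /
#'   `n_as_missing`).
#' @export
primer_penalty <- function(primer, template_site,
                           matrices = default_penalty_matrices()) {
  stopifnot(inherits(primer, "degenerate_primer"),
            inherits(matrices, "penalty_matrices"))
  t_bits <- .seq_bits(template_site, allow_gap = TRUE, what = "template site")
  if (length(t_bits) != primer$length) {
    stop(sprintf("template site length %d does not equal primer length %d",
                 length(t_bits), primer$length), call. = FALSE)
  }
  p_bits <- .seq_bits(primer$sequence)
  if (primer$orientation == "reverse") {
    t_bits <- rev(.COMP_BITS[t_bits + 1L])
  }
  if ((matrices$gap_as_missing && any(t_bits == 0L)) ||
      (matrices$n_as_missing && any(t_bits == 15L))) {
    return(list(score = NA_real_, missing = TRUE))
  }
  pen <- matrices$pair_table[cbind(p_bits + 1L, t_bits + 1L)]
  L <- primer$length
  dist3 <- L - seq_len(L) + 1L
  pf <- matrices$position_factor
  pos <- pf[pmin(dist3, length(pf))]
  mm <- pen > 0
  adj <- c(FALSE, mm[-L]) | c(mm[-1L], FALSE)
  mult <- ifelse(mm & adj, matrices$adjacency_factor, 1)
  list(score = sum(pos * pen * mult), missing = FALSE)
}

#' Penalty scores of a primer pair over an alignment
#'
#' Computes per-record forward and reverse penalty scores at the pair's
#' binding sites (located against the consensus when unset, as in
#' [evaluate_pair()]).  A record is missing when either site could not be
#' scored under the matrices' missing flags.
#'
#' @inheritParams evaluate_pair
#' @param matrices a [penalty_matrices()].
#' @return data frame with columns `sequence_id`, `species`, `taxon`,
#'   `forward_score`, `reverse_score`.
#' @export
penalty_scores <- function(aln, pair, matrices = default_penalty_matrices(),
                           consensus = NULL) {
  stopifnot(inherits(aln, "aligned_set"), inherits(pair, "primer_pair"))
  fwd_site <- pair$forward_site
  rev_site <- pair$reverse_site
  if (is.null(fwd_site) || is.null(rev_site)) {
    if (is.null(consensus)) consensus <- build_consensus(aln)
    if (is.null(fwd_site)) fwd_site <- .locate_site(pair$forward, consensus)
    if (is.null(rev_site)) rev_site <- .locate_site(pair$reverse, consensus)
  }
  if (fwd_site[2L] > aln$width || rev_site[2L] > aln$width) {
    stop("primer site extends beyond the alignment", call. = FALSE)
  }
  score_one <- function(primer, site) {
    sub <- substr(aln$sequences, site[1L], site[2L])
    vapply(sub, function(s) primer_penalty(primer, s, matrices)$score,
           numeric(1), USE.NAMES = FALSE)
  }
  data.frame(
    sequence_id = aln$ids, species = aln$species, taxon = aln$taxon,
    forward_score = score_one(pair$forward, fwd_site),
    reverse_score = score_one(pair$reverse, rev_site),
    stringsAsFactors = FALSE)
}

#' Classify combined penalty scores
#'
#' Sums forward and reverse scores and classifies each record: `Working`
#' when the combined score is strictly below the threshold, `Failed` at or
#' above it, `Missing` when either score could not be computed.
#'
#' @param scores data frame from [penalty_scores()] (columns
#'   `forward_score`, `reverse_score`, optionally `sequence_id`, `species`,
#'   `taxon`).
#' @param threshold combined-score cutoff (default 150).
#' @return an object of class `penalty_classification`: list with
#'   `per_sequence` (scores plus `combined` and `classification`),
#'   `summary` (per-taxon Working/Failed/Missing counts and percentages)
#'   and `threshold`.
#' @export
classify <- function(scores, threshold = 150) {
  scores <- as.data.frame(scores)
  if (nrow(scores) == 0L) stop("no scores to classify", call. = FALSE)
  if (!all(c("forward_score", "reverse_score") %in% names(scores))) {
    stop("scores need forward_score and reverse_score columns", call. = FALSE)
  }
  if (is.null(scores$taxon)) scores$taxon <- NA_character_
  combined <- scores$forward_score + scores$reverse_score
  cls <- ifelse(is.na(combined), "Missing",
                ifelse(combined < threshold, "Working", "Failed"))
  per_sequence <- cbind(scores,
                        data.frame(combined = combined, classification = cls,
                                   stringsAsFactors = FALSE))
  grp <- ifelse(is.na(per_sequence$taxon), "(all)", per_sequence$taxon)
  summary <- do.call(rbind, lapply(unique(grp), function(g) {
    cg <- cls[grp == g]
    n <- length(cg)
    data.frame(taxon = g, total = n,
               working = sum(cg == "Working"),
               failed = sum(cg == "Failed"),
               missing = sum(cg == "Missing"),
               working_pct = 100 * sum(cg == "Working") / n,
               failed_pct = 100 * sum(cg == "Failed") / n,
               missing_pct = 100 * sum(cg == "Missing") / n,
               stringsAsFactors = FALSE)
  }))
  structure(list(per_sequence = per_sequence, summary = summary,
                 threshold = threshold),
            class = "penalty_classification")
}

#' @export
print.penalty_classification <- function(x, ...) {
  cat(sprintf("<penalty_classification> threshold %g\n", x$threshold))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-15s %6d (100)  working %d (%.2f)  failed %d (%.2f)  missing %d (%.2f)\n",
                s$taxon[i], s$total[i], s$working[i], s$working_pct[i],
                s$failed[i], s$failed_pct[i], s$missing[i], s$missing_pct[i]))
  }
  invisible(x)
}

#' Per-group score distribution summaries
#'
#' Median and quartiles of the forward and reverse penalty scores per taxon
#' group — the data behind the usual per-direction box plots.
#'
#' @param scores data frame from [penalty_scores()].
#' @param group_by column name used for grouping (default `"taxon"`).
#' @return data frame with columns `group`, `direction`, `n`, `q1`,
#'   `median`, `q3`.
#' @export
score_distribution <- function(scores, group_by = "taxon") {
  scores <- as.data.frame(scores)
  grp <- scores[[group_by]]
  grp <- ifelse(is.na(grp), "(all)", as.character(grp))
  out <- list()
  for (g in unique(grp)) {
    for (dir in c("forward", "reverse")) {
      v <- scores[[paste0(dir, "_score")]][grp == g]
      v <- v[!is.na(v)]
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        group = g, direction = dir, n = length(v),
        q1 = q[1L], median = q[2L], q3 = q[3L], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Box plot of penalty scores by group and direction
#'
#' @param x a [penalty_classification()].
#' @param ... passed to [graphics::boxplot()].
#' @return `x`, invisibly.
#' @export
plot.penalty_classification <- function(x, ...) {
  ps <- x$per_sequence
  grp <- ifelse(is.na(ps$taxon), "(all)", ps$taxon)
  long <- data.frame(
    score = c(ps$forward_score, ps$reverse_score),
    label = c(paste0(grp, "_F"), paste0(grp, "_R")))
  long <- long[!is.na(long$score), ]
  graphics::boxplot(score ~ label, data = long, las = 2,
                    ylab = "penalty score", ...)
  graphics::abline(h = x$threshold, lty = 2, col = "red")
  invisible(x)
}
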