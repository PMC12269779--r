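# Mismatch-rule binding test: a primer binds a template site when the total
# number of mismatching positions (subset semantics on IUPAC codes) does not
# exceed max_total_mismatch and the 3'-terminal window carries no more than
# max_three_prime_mismatch mismatches.

#' Binding-rule parameters
#'
#' @param max_total_mismatch maximum mismatches over the whole binding region
#'   (default 3).
#' @param three_prime_window number of bases at the primer's 3' end subject
#'   to the stricter terminal rule (default 2).
#' @param max_three_prime_mismatch mismatches allowed inside the terminal
#'   window (default 0: no mismatch within two bases of the 3' end).
#' @param missing_policy how to treat sites containing gaps or N:
#'   `"missing_if_gap_or_incomplete"` (default) makes the record neither
#'   bound nor unbound — it is excluded from the bound numerator but kept in
#'   the denominator; `"score_as_mismatch"` counts such positions as plain
#'   mismatches.
#' @return an object of class `binding_params`.
#' @export
binding_params <- function(max_total_mismatch = 3L,
                           three_prime_window = 2L,
                           max_three_prime_mismatch = 0L,
                           missing_policy = c("missing_if_gap_or_incomplete",
                                              "score_as_mismatch")) {
  missing_policy <- match.arg(missing_policy)
  vals <- c(max_total_mismatch, three_prime_window, max_three_prime_mismatch)
  if (any(vals < 0L)) stop("binding parameters must be >= 0", call. = FALSE)
  structure(list(max_total_mismatch = as.integer(max_total_mismatch),
                 three_prime_window = as.integer(three_prime_window),
                 max_three_prime_mismatch = as.integer(max_three_prime_mismatch),
                 missing_policy = missing_policy),
            class = "binding_params")
}

#' Per-position mismatch report of a primer against a template site
#'
#' The template site is given on the plus strand at the primer's binding
#' interval.  Reverse primers are compared after reverse-complementing the
#' primer onto the plus strand; the returned flags are indexed from the
#' primer's own 5' end, so the 3'-terminal window is always the tail of
#' `per_position`.
#'
#' @param primer a [degenerate_primer()].
#' @param template_site IUPAC string (gaps allowed) of the same length as the
#'   primer, plus-strand orientation.
#' @param params a [binding_params()].
#' @return an object of class `mismatch_report`: list with `per_position`
#'   (logical, 5'→3' on the primer), `total`, `three_prime_count` and
#'   `missing`.
#' @export
mismatch_report <- function(primer, template_site, params = binding_params()) {
  stopifnot(inherits(primer, "degenerate_primer"),
            inherits(params, "binding_params"))
  t_bits <- .seq_bits(template_site, allow_gap = TRUE, what = "template site")
  if (length(t_bits) != primer$length) {
    stop(sprintf("template site length %d does not equal primer length %d",
                 length(t_bits), primer$length), call. = FALSE)
  }
  p_bits <- .seq_bits(primer$sequence, allow_gap = FALSE)
  if (params$three_prime_window > primer$length) {
    stop("three_prime_window exceeds primer length", call. = FALSE)
  }
  # primer-orientation template: reverse primers read the site 3'->5' on the
  # plus strand, i.e. the reverse complement
  t_primer <- if (primer$orientation == "reverse") {
    rev(.COMP_BITS[t_bits + 1L])
  } else {
    t_bits
  }
  flags <- !.bits_match(p_bits, t_primer)
  incomplete <- t_primer == 0L | t_primer == 15L   # gap or N
  missing <- FALSE
  if (any(incomplete)) {
    if (params$missing_policy == "missing_if_gap_or_incomplete") {
      missing <- TRUE
    }
    # under score_as_mismatch the subset rule already flags gaps and
    # (unless the primer base is N) Ns as mismatches
  }
  L <- primer$length
  tail_idx <- if (params$three_prime_window > 0L) {
    (L - params$three_prime_window + 1L):L
  } else integer(0)
  structure(
    list(per_position = flags,
         total = sum(flags),
         three_prime_count = sum(flags[tail_idx]),
         missing = missing),
    class = "mismatch_report"
  )
}

#' @export
print.mismatch_report <- function(x, ...) {
  cat(sprintf(
    "<mismatch_report> %d mismatches (%d in 3' window)%s\n",
    x$total, x$three_prime_count, if (x$missing) ", site missing/gapped" else ""))
  invisible(x)
}

#' Classify a mismatch report as bound, unbound or missing
#'
#' Bound iff the site is not missing, the total mismatch count does not
#' exceed `max_total_mismatch`, and the 3'-terminal window count does not
#' exceed `max_three_prime_mismatch` (both bounds inclusive).
#'
#' @param report a [mismatch_report()].
#' @param params a [binding_params()].
#' @return one of `"bound"`, `"unbound"`, `"missing"`.
#' @export
test_binding <- function(report, params = binding_params()) {
  stopifnot(inherits(report, "mismatch_report"),
            inherits(params, "binding_params"))
  if (report$missing) return("missing")
  if (report$total <= params$max_total_mismatch &&
      report$three_prime_count <= params$max_three_prime_mismatch) {
    "bound"
  } else {
    "unbound"
  }
}

# locate the window of the consensus minimising total mismatches for a
# primer; ties broken toward the 5'-most (smallest start) window
.locate_site <- function(primer, cons) {
  c_bits <- unname(.IUPAC_BITS[cons$codes])
  L <- primer$length
  p_bits <- .seq_bits(primer$sequence)
  if (primer$orientation == "reverse") {
    p_plus <- rev(.COMP_BITS[p_bits + 1L])
  } else {
    p_plus <- p_bits
  }
  n_win <- cons$length - L + 1L
  if (n_win < 1L) stop("primer longer than alignment", call. = FALSE)
  mism <- vapply(seq_len(n_win), function(s) {
    sum(!.bits_match(p_plus, c_bits[s:(s + L - 1L)]))
  }, numeric(1))
  s <- which.min(mism)
  c(s, s + L - 1L)
}

#' Binding analysis of a primer pair over an alignment
#'
#' Tests both primers of a pair against every record and aggregates binding
#' at the sequence and species level (a species counts as bound when at
#' least one of its sequences is bound by both primers).  Sites come from
#' the pair's stored intervals; when unset, each primer is placed at the
#' consensus window minimising its mismatch count (ties resolved 5'-most).
#' Totals always include missing records, so fractions are over the full
#' dataset.
#'
#' @param aln an [aligned_set()].
#' @param pair a [primer_pair()].
#' @param params a [binding_params()].
#' @param consensus optional [build_consensus()] result reused for site
#'   placement.
#' @return an object of class `binding_summary`: list with `per_sequence`
#'   (data frame: id, species, mismatch counts and status per primer, pair
#'   status), `summary` (counts/fractions per level and primer), `sites`,
#'   `pair_name` and `params`.
#' @export
evaluate_pair <- function(aln, pair, params = binding_params(),
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
  status_one <- function(primer, site) {
    sub <- substr(aln$sequences, site[1L], site[2L])
    reps <- lapply(sub, function(s) mismatch_report(primer, s, params))
    data.frame(
      total = vapply(reps, `[[`, 0L, "total"),
      three_prime = vapply(reps, `[[`, 0L, "three_prime_count"),
      status = vapply(reps, test_binding, "", params = params),
      stringsAsFactors = FALSE)
  }
  f <- status_one(pair$forward, fwd_site)
  r <- status_one(pair$reverse, rev_site)
  pair_status <- ifelse(
    f$status == "unbound" | r$status == "unbound", "unbound",
    ifelse(f$status == "missing" | r$status == "missing", "missing", "bound"))
  per_sequence <- data.frame(
    sequence_id = aln$ids, species = aln$species, taxon = aln$taxon,
    fwd_total = f$total, fwd_3p = f$three_prime, fwd_status = f$status,
    rev_total = r$total, rev_3p = r$three_prime, rev_status = r$status,
    status = pair_status, stringsAsFactors = FALSE)

  n_seq <- aln$n
  sp <- unique(aln$species)
  n_sp <- length(sp)
  seq_bound <- function(st) sum(st == "bound")
  sp_bound <- function(st) {
    sum(vapply(sp, function(s) any(st[aln$species == s] == "bound"), TRUE))
  }
  summary <- data.frame(
    level = rep(c("species", "sequence"), each = 3L),
    primer = rep(c("forward", "reverse", "pair"), 2L),
    total = rep(c(n_sp, n_seq), each = 3L),
    bound = c(sp_bound(f$status), sp_bound(r$status), sp_bound(pair_status),
              seq_bound(f$status), seq_bound(r$status), seq_bound(pair_status)),
    stringsAsFactors = FALSE)
  summary$fraction <- summary$bound / summary$total

  structure(
    list(per_sequence = per_sequence, summary = summary,
         sites = list(forward = fwd_site, reverse = rev_site),
         pair_name = paste(pair$forward$name, pair$reverse$name, sep = "/"),
         params = params),
    class = "binding_summary"
  )
}

#' @export
print.binding_summary <- function(x, ...) {
  cat(sprintf("<binding_summary> %s (max %d mismatches, %d allowed in %d-base 3' window)\n",
              x$pair_name, x$params$max_total_mismatch,
              x$params$max_three_prime_mismatch, x$params$three_prime_window))
  s <- x$summary
  for (lev in c("species", "sequence")) {
    row <- s[s$level == lev, ]
    cat(sprintf("  %-9s (%d)  F %d (%.2f%%)  R %d (%.2f%%)  pair %d (%.2f%%)\n",
                lev, row$total[1L],
                row$bound[row$primer == "forward"],
                100 * row$fraction[row$primer == "forward"],
                row$bound[row$primer == "reverse"],
                100 * row$fraction[row$primer == "reverse"],
                row$bound[row$primer == "pair"],
                100 * row$fraction[row$primer == "pair"]))
  }
  invisible(x)
}

#' @export
as.data.frame.binding_summary <- function(x, ...) x$per_sequence
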