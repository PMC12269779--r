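# Seeded synthetic-alignment generator with known ground truth.  Species
# ancestors diverge from a common root under a K80 substitution process;
# sequences diverge from their species ancestor at a lower rate; primer
# binding sites are seeded into the root and, for one designated pair,
# overwritten per sequence to carry exactly the designed mismatch counts.

#' Describe a synthetic dataset
#'
#' Collects every parameter of the generator into a single truth record.
#' Defaults are a desk-scale analogue of a curated COI mini-barcode
#' alignment: a 700-column alignment carrying both packaged primer pairs at
#' their reference coordinates, 25 species of 4 sequences, ~1% expected
#' intraspecific and ~20% interspecific divergence under a
#' transition/transversion rate ratio of 2.
#'
#' @param seed integer; every draw of the generator is a pure function of
#'   it.
#' @param n_species,seqs_per_species species partition (`seqs_per_species`
#'   may be a per-species vector).
#' @param alignment_length columns.
#' @param pairs list of [primer_pair()] objects (with sites) seeded into the
#'   root sequence so every primer has a plausible binding region; defaults
#'   to [ascidian_coi_primers()].
#' @param constrained_pair index into `pairs` of the pair whose sites are
#'   overwritten per sequence with exact designed mismatch counts, or `NULL`
#'   to skip constraint.
#' @param fwd_mismatch,rev_mismatch integer vectors (recycled over
#'   sequences) of designed total mismatch counts against the constrained
#'   pair's forward/reverse primer.
#' @param fwd_3p_mismatch,rev_3p_mismatch designed mismatches inside the
#'   terminal two bases of the 3' end (placed first); remaining designed
#'   mismatches are placed 5'-first.
#' @param ambiguity_rate,gap_rate per-cell injection rates of ambiguity
#'   codes and gaps, applied outside the primer-site columns.
#' @param intra_rate,inter_rate expected pairwise K80 distance within and
#'   between species (substitutions/site).
#' @param ts_tv_ratio transition/transversion rate ratio kappa.
#' @param true_effect,species_sd,baseline_logodds parameters of the logistic
#'   outcome model used by [generate_binding_outcomes()]: designed log-odds
#'   advantage of the improved primer set, species intercept SD, and
#'   reference-set baseline log-odds.
#' @param taxon taxon-group label stamped on every generated record.
#' @return an object of class `synthetic_truth` (a named list).
#' @export
synthetic_truth <- function(seed,
                            n_species = 25L,
                            seqs_per_species = 4L,
                            alignment_length = 700L,
                            pairs = ascidian_coi_primers(),
                            constrained_pair = NULL,
                            fwd_mismatch = 0L, rev_mismatch = 0L,
                            fwd_3p_mismatch = 0L, rev_3p_mismatch = 0L,
                            ambiguity_rate = 0.002, gap_rate = 0.01,
                            intra_rate = 0.01, inter_rate = 0.20,
                            ts_tv_ratio = 2,
                            true_effect = 2.0, species_sd = 1.0,
                            baseline_logodds = 0.5,
                            taxon = "target") {
  stopifnot(length(seed) == 1L, is.finite(seed))
  rates <- c(ambiguity_rate, gap_rate, intra_rate, inter_rate)
  if (any(rates < 0) || any(rates >= 1)) {
    stop("rates must lie in [0, 1)", call. = FALSE)
  }
  if (intra_rate >= inter_rate) {
    stop("intra_rate must be smaller than inter_rate", call. = FALSE)
  }
  seqs_per_species <- rep_len(as.integer(seqs_per_species),
                              as.integer(n_species))
  structure(
    list(seed = as.integer(seed), n_species = as.integer(n_species),
         seqs_per_species = seqs_per_species,
         alignment_length = as.integer(alignment_length),
         pairs = pairs, constrained_pair = constrained_pair,
         fwd_mismatch = as.integer(fwd_mismatch),
         rev_mismatch = as.integer(rev_mismatch),
         fwd_3p_mismatch = as.integer(fwd_3p_mismatch),
         rev_3p_mismatch = as.integer(rev_3p_mismatch),
         ambiguity_rate = ambiguity_rate, gap_rate = gap_rate,
         intra_rate = intra_rate, inter_rate = inter_rate,
         ts_tv_ratio = ts_tv_ratio,
         true_effect = true_effect, species_sd = species_sd,
         baseline_logodds = baseline_logodds, taxon = taxon),
    class = "synthetic_truth"
  )
}

# K80 per-site substitution sampling for a branch of expected length d
# (substitutions/site) and rate ratio kappa: alpha*t = kappa*d/(kappa+2),
# beta*t = d/(kappa+2); closed-form transition probabilities.
.k80_change_probs <- function(d, kappa) {
  at <- kappa * d / (kappa + 2)
  bt <- d / (kappa + 2)
  p_ts <- 0.25 + 0.25 * exp(-4 * bt) - 0.5 * exp(-2 * (at + bt))
  p_tv <- 0.25 - 0.25 * exp(-4 * bt)   # each of the two transversions
  c(ts = p_ts, tv = p_tv)
}

# transition partner and the two transversion partners, by bits value
.TS_PARTNER <- c(NA, 4L, 8L, NA, 1L, NA, NA, NA, 2L, rep(NA, 7L))
.TV_PARTNERS <- list(NULL, c(2L, 8L), c(1L, 4L), NULL, c(2L, 8L), NULL, NULL,
                     NULL, c(1L, 4L), NULL, NULL, NULL, NULL, NULL, NULL, NULL)

.evolve_k80 <- function(bits, d, kappa) {
  if (d <= 0) return(bits)
  p <- .k80_change_probs(d, kappa)
  u <- stats::runif(length(bits))
  out <- bits
  ts_idx <- which(u < p["ts"])
  tv1 <- which(u >= p["ts"] & u < p["ts"] + p["tv"])
  tv2 <- which(u >= p["ts"] + p["tv"] & u < p["ts"] + 2 * p["tv"])
  if (length(ts_idx)) out[ts_idx] <- .TS_PARTNER[bits[ts_idx] + 1L]
  for (i in tv1) out[i] <- .TV_PARTNERS[[bits[i] + 1L]][1L]
  for (i in tv2) out[i] <- .TV_PARTNERS[[bits[i] + 1L]][2L]
  out
}

# site columns covered by any primer of any pair in the truth
.site_columns <- function(truth) {
  cols <- integer(0)
  for (pp in truth$pairs) {
    for (s in list(pp$forward_site, pp$reverse_site)) {
      if (!is.null(s)) cols <- c(cols, s[1L]:s[2L])
    }
  }
  unique(cols)
}

# a random concrete realisation (bits) of a primer, on the plus strand
.realise_primer_plus <- function(primer) {
  p_bits <- .seq_bits(primer$sequence)
  if (primer$orientation == "reverse") p_bits <- rev(.COMP_BITS[p_bits + 1L])
  vapply(p_bits, function(b) {
    s <- .BASE_BITS[bitwAnd(b, .BASE_BITS) > 0L]
    unname(s[sample.int(length(s), 1L)])
  }, integer(1))
}

# inject exactly n_total designed mismatches (n_3p of them in the terminal
# two 3' bases) into a plus-strand site realisation; positions are chosen
# 5'-first in primer orientation, skipping positions where no mismatching
# base exists (primer code N)
.design_mismatches <- function(site_bits, primer, n_total, n_3p) {
  L <- primer$length
  p_bits <- .seq_bits(primer$sequence)  # primer orientation
  # primer-orientation view of the site
  view <- if (primer$orientation == "reverse") {
    rev(.COMP_BITS[site_bits + 1L])
  } else site_bits
  can_mm <- p_bits != 15L               # N admits every base
  three_p <- (L - 1L):L                 # terminal window, primer orientation
  pick <- integer(0)
  if (n_3p > 0L) {
    avail <- rev(three_p[can_mm[three_p]])   # terminal base first
    if (length(avail) < n_3p) {
      stop("cannot place the designed 3'-terminal mismatches", call. = FALSE)
    }
    pick <- avail[seq_len(n_3p)]
  }
  n_rest <- n_total - length(pick)
  if (n_rest < 0L) stop("3' mismatch count exceeds total", call. = FALSE)
  if (n_rest > 0L) {
    avail <- setdiff(which(can_mm), c(pick, if (n_3p == 0L) three_p else integer(0)))
    if (length(avail) < n_rest) {
      stop("designed mismatches exceed the usable site length", call. = FALSE)
    }
    pick <- c(pick, avail[seq_len(n_rest)])   # 5'-first
  }
  for (i in pick) {
    off <- .BASE_BITS[bitwAnd(p_bits[i], .BASE_BITS) == 0L]
    view[i] <- unname(off[1L])          # first non-covered base, deterministic
  }
  if (primer$orientation == "reverse") rev(.COMP_BITS[view + 1L]) else view
}

#' Generate a synthetic aligned dataset with known truth
#'
#' See [synthetic_truth()] for the generating model.  The same seed yields
#' byte-identical output.  Realised mismatch counts at the constrained
#' pair's sites are verified against the design before returning.
#'
#' @param truth a [synthetic_truth()].
#' @return list with `alignment` (an [aligned_set()]) and `truth`.
#' @export
generate_alignment <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(truth$seed)

  L <- truth$alignment_length
  kappa <- truth$ts_tv_ratio
  root <- unname(.BASE_BITS[sample.int(4L, L, replace = TRUE)])
  # seed every primer site into the root so all pairs have binding regions
  for (pp in truth$pairs) {
    for (side in c("forward", "reverse")) {
      s <- pp[[paste0(side, "_site")]]
      if (is.null(s)) next
      if (s[2L] > L) stop("primer site outside the alignment", call. = FALSE)
      root[s[1L]:s[2L]] <- .realise_primer_plus(pp[[side]])
    }
  }

  n_seq <- sum(truth$seqs_per_species)
  seqs <- matrix(0L, nrow = n_seq, ncol = L)
  species <- character(n_seq)
  row <- 1L
  for (sp in seq_len(truth$n_species)) {
    anc <- .evolve_k80(root, truth$inter_rate / 2, kappa)
    for (k in seq_len(truth$seqs_per_species[sp])) {
      seqs[row, ] <- .evolve_k80(anc, truth$intra_rate / 2, kappa)
      species[row] <- sprintf("Species_%02d", sp)
      row <- row + 1L
    }
  }

  # overwrite the constrained pair's sites with exact designed mismatches
  cp <- truth$constrained_pair
  design <- NULL
  if (!is.null(cp)) {
    pp <- truth$pairs[[cp]]
    if (is.null(pp$forward_site) || is.null(pp$reverse_site)) {
      stop("constrained pair needs both sites set", call. = FALSE)
    }
    design <- data.frame(
      fwd = rep_len(truth$fwd_mismatch, n_seq),
      rev = rep_len(truth$rev_mismatch, n_seq),
      fwd_3p = rep_len(truth$fwd_3p_mismatch, n_seq),
      rev_3p = rep_len(truth$rev_3p_mismatch, n_seq))
    for (i in seq_len(n_seq)) {
      fs <- pp$forward_site
      rs <- pp$reverse_site
      seqs[i, fs[1L]:fs[2L]] <- .design_mismatches(
        .realise_primer_plus(pp$forward), pp$forward,
        design$fwd[i], design$fwd_3p[i])
      seqs[i, rs[1L]:rs[2L]] <- .design_mismatches(
        .realise_primer_plus(pp$reverse), pp$reverse,
        design$rev[i], design$rev_3p[i])
    }
  }

  # gaps and ambiguity codes outside all primer-site columns
  free <- setdiff(seq_len(L), .site_columns(truth))
  if (length(free) > 0L && (truth$gap_rate > 0 || truth$ambiguity_rate > 0)) {
    for (i in seq_len(n_seq)) {
      u <- stats::runif(length(free))
      gap_idx <- free[u < truth$gap_rate]
      amb_idx <- free[u >= truth$gap_rate &
                        u < truth$gap_rate + truth$ambiguity_rate]
      seqs[i, gap_idx] <- 0L
      for (j in amb_idx) {
        b <- seqs[i, j]
        seqs[i, j] <- if (stats::runif(1) < 0.5) 15L else {
          other <- .BASE_BITS[.BASE_BITS != b]
          bitwOr(b, unname(other[sample.int(3L, 1L)]))
        }
      }
    }
  }

  chars <- apply(seqs, 1L, .bits_string)
  ids <- sprintf("SYN%04d", seq_len(n_seq))
  aln <- aligned_set(chars, species = species, taxon = truth$taxon, ids = ids)

  # generator self-check: realised counts at constrained sites equal design
  if (!is.null(cp)) {
    pp <- truth$pairs[[cp]]
    bp <- binding_params(missing_policy = "score_as_mismatch")
    for (i in seq_len(n_seq)) {
      fr <- mismatch_report(pp$forward, substr(chars[i], pp$forward_site[1L],
                                               pp$forward_site[2L]), bp)
      rr <- mismatch_report(pp$reverse, substr(chars[i], pp$reverse_site[1L],
                                               pp$reverse_site[2L]), bp)
      if (fr$total != design$fwd[i] || rr$total != design$rev[i]) {
        stop("internal error: realised mismatch counts differ from design",
             call. = FALSE)
      }
    }
  }
  list(alignment = aln, truth = truth)
}

#' Simulate binary amplification outcomes under the mixed logistic model
#'
#' Draws Bernoulli success outcomes for both primer sets of every sequence
#' from exactly the model [fit_glmm()] assumes:
#' `logit P = baseline + true_effect * [improved] + b_species`,
#' `b_species ~ N(0, species_sd^2)`.  Used for recovery and coverage tests.
#'
#' @param truth a [synthetic_truth()] (fields `n_species`,
#'   `seqs_per_species`, `true_effect`, `species_sd`, `baseline_logodds`,
#'   `seed`).
#' @return an `amplification_records` data frame (see [build_records()])
#'   with the generating parameters attached as attribute `truth`.
#' @export
generate_binding_outcomes <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (truth$n_species < 2L) {
    stop("at least two species are needed for the species random intercept",
         call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(truth$seed)

  b_sp <- stats::rnorm(truth$n_species, 0, truth$species_sd)
  rows <- list()
  idx <- 1L
  for (sp in seq_len(truth$n_species)) {
    n_k <- truth$seqs_per_species[sp]
    for (set in c("reference", "improved")) {
      eta <- truth$baseline_logodds + b_sp[sp] +
        if (set == "improved") truth$true_effect else 0
      rows[[length(rows) + 1L]] <- data.frame(
        sequence_id = sprintf("SYN%04d", idx:(idx + n_k - 1L)),
        species = sprintf("Species_%02d", sp),
        primer_set = set,
        outcome = stats::rbinom(n_k, 1L, stats::plogis(eta)),
        stringsAsFactors = FALSE)
    }
    idx <- idx + n_k
  }
  out <- do.call(rbind, rows)
  out$primer_set <- factor(out$primer_set, levels = c("reference", "improved"))
  class(out) <- c("amplification_records", "data.frame")
  attr(out, "truth") <- truth
  out
}
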