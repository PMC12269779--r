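# Orchestration of the full in-silico validation workflow:
# conservation profile -> binding analysis -> penalty classification ->
# (optional) mixed-model primer-set comparison -> barcoding gap.

#' Assemble a validation configuration
#'
#' @param target an [aligned_set()] or path to an aligned FASTA of the
#'   target group.
#' @param pairs list of one or two [primer_pair()] objects.  With two pairs
#'   the first is treated as the reference set and the second as the
#'   improved set for the mixed-model comparison.
#' @param nontargets named list of [aligned_set()]s (or FASTA paths) for
#'   non-target groups; names are used as taxon labels when the sets carry
#'   none.
#' @param binding a [binding_params()].
#' @param matrices a [penalty_matrices()].
#' @param threshold combined penalty-score classification cutoff.
#' @param outcome response used by the mixed model (see [build_records()]).
#' @param gap logical: run the barcoding-gap analysis on the target group.
#' @param bin_width gap-histogram bin width.
#' @param min_overlap minimum pairwise-complete sites for a K80 distance.
#' @param inclusion_threshold consensus inclusion threshold.
#' @param window_size,step similarity-profile window parameters.
#' @param out_dir optional directory; when set, [run_validation()] writes
#'   TSV/JSON outputs there.
#' @return an object of class `validation_config`.
#' @export
validation_config <- function(target, pairs, nontargets = list(),
                              binding = binding_params(),
                              matrices = default_penalty_matrices(),
                              threshold = 150,
                              outcome = c("binding", "penalty"),
                              gap = TRUE, bin_width = 0.01,
                              min_overlap = 100L,
                              inclusion_threshold = 0.05,
                              window_size = 20L, step = 1L,
                              out_dir = NULL) {
  outcome <- match.arg(outcome)
  if (inherits(pairs, "primer_pair")) pairs <- list(pairs)
  if (length(pairs) < 1L || length(pairs) > 2L) {
    stop("supply one or two primer pairs", call. = FALSE)
  }
  load_aln <- function(x) {
    if (inherits(x, "aligned_set")) x else read_aligned_fasta(x)
  }
  target <- load_aln(target)
  nontargets <- lapply(nontargets, load_aln)
  structure(
    list(target = target, pairs = pairs, nontargets = nontargets,
         binding = binding, matrices = matrices, threshold = threshold,
         outcome = outcome, gap = gap, bin_width = bin_width,
         min_overlap = as.integer(min_overlap),
         inclusion_threshold = inclusion_threshold,
         window_size = as.integer(window_size), step = as.integer(step),
         out_dir = out_dir),
    class = "validation_config"
  )
}

#' Read a validation configuration from a YAML file
#'
#' Expected keys: `target` (FASTA path), optional `nontargets` (name: path
#' map), `pairs` (list of entries with `forward`/`reverse` sub-entries
#' `name` and `sequence`, optional `forward_site`, `reverse_site`,
#' `amplicon`), and any scalar option of [validation_config()]
#' (`threshold`, `outcome`, `max_total_mismatch`, ...).
#'
#' @param path YAML file path.
#' @return a `validation_config`.
#' @export
read_validation_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$target) || is.null(y$pairs)) {
    stop("config needs 'target' and 'pairs'", call. = FALSE)
  }
  pairs <- lapply(y$pairs, function(p) {
    primer_pair(
      degenerate_primer(p$forward$name, p$forward$sequence, "forward"),
      degenerate_primer(p$reverse$name, p$reverse$sequence, "reverse"),
      forward_site = if (!is.null(p$forward_site)) unlist(p$forward_site),
      reverse_site = if (!is.null(p$reverse_site)) unlist(p$reverse_site),
      expected_amplicon = p$amplicon)
  })
  opt <- function(name, default) if (is.null(y[[name]])) default else y[[name]]
  validation_config(
    target = y$target, pairs = pairs,
    nontargets = as.list(opt("nontargets", list())),
    binding = binding_params(
      max_total_mismatch = opt("max_total_mismatch", 3L),
      three_prime_window = opt("three_prime_window", 2L),
      max_three_prime_mismatch = opt("max_three_prime_mismatch", 0L)),
    matrices = default_penalty_matrices(
      adjacency_factor = opt("adjacent", 1),
      gap_as_missing = opt("gap_na", FALSE),
      n_as_missing = opt("n_na", FALSE)),
    threshold = opt("threshold", 150),
    outcome = opt("outcome", "binding"),
    gap = opt("gap", TRUE),
    bin_width = opt("bin_width", 0.01),
    min_overlap = opt("min_overlap", 100L),
    inclusion_threshold = opt("inclusion_threshold", 0.05),
    window_size = opt("window_size", 20L),
    step = opt("step", 1L),
    out_dir = y$out_dir)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s': %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full primer validation workflow
#'
#' Stages, in order: consensus + similarity profile of the target
#' alignment; binding analysis of every pair on the target and each
#' non-target group; penalty scoring and threshold classification of the
#' same; mixed-model comparison of the two pairs on the target group (only
#' when two pairs are configured); barcoding-gap analysis of the target
#' group.  When `out_dir` is configured, per-sequence and summary tables
#' are written as TSV/JSON.  The pipeline is deterministic: rerunning the
#' same configuration on the same inputs reproduces every number.
#'
#' @param config a [validation_config()].
#' @return an object of class `validation_report`: list with `similarity`,
#'   `binding`, `penalty`, `score_distribution`, `glmm` (or `NULL`),
#'   `gap` (or `NULL`) and `config`.
#' @export
run_validation <- function(config) {
  stopifnot(inherits(config, "validation_config"))
  target <- config$target
  pair_names <- vapply(config$pairs, function(p)
    paste(p$forward$name, p$reverse$name, sep = "/"), "")

  cons <- .stage("consensus",
                 build_consensus(target, config$inclusion_threshold))
  profile <- .stage("similarity",
                    similarity_profile(cons, config$window_size, config$step))

  alns <- c(list(target = target), config$nontargets)
  binding <- list()
  penalty <- list()
  for (pn in seq_along(config$pairs)) {
    pp <- config$pairs[[pn]]
    for (an in names(alns)) {
      # with two pairs the reference (first) is evaluated on the target
      # group only; the improved pair runs on every group
      if (length(config$pairs) == 2L && pn == 1L && an != "target") next
      key <- paste(pair_names[pn], an, sep = " | ")
      binding[[key]] <- .stage(
        paste("binding", key),
        evaluate_pair(alns[[an]], pp, config$binding, consensus = cons))
      sc <- .stage(
        paste("penalty", key),
        penalty_scores(alns[[an]], pp, config$matrices, consensus = cons))
      if (an != "target" && all(is.na(sc$taxon))) sc$taxon <- an
      penalty[[key]] <- .stage(paste("classify", key),
                               classify(sc, config$threshold))
    }
  }
  # reference pair evaluated first in config order; improved pair = last
  glmm <- NULL
  if (length(config$pairs) == 2L) {
    key_ref <- paste(pair_names[1L], "target", sep = " | ")
    key_imp <- paste(pair_names[2L], "target", sep = " | ")
    src <- if (config$outcome == "binding") binding else penalty
    glmm <- .stage("glmm", fit_glmm(
      build_records(src[[key_ref]], src[[key_imp]], outcome = config$outcome)))
  }
  gap <- NULL
  if (isTRUE(config$gap)) {
    gap <- .stage("gap", gap_statistics(
      distance_matrix(target, config$min_overlap), config$bin_width))
  }
  sdist <- do.call(rbind, lapply(names(penalty), function(k) {
    cbind(evaluation = k,
          score_distribution(penalty[[k]]$per_sequence))
  }))
  report <- structure(
    list(similarity = profile, consensus = cons, binding = binding,
         penalty = penalty, score_distribution = sdist, glmm = glmm,
         gap = gap, config = config),
    class = "validation_report")
  if (!is.null(config$out_dir)) .write_report(report, config$out_dir)
  report
}

.write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(as.data.frame(report$similarity), "similarity_profile.tsv")
  for (k in names(report$binding)) {
    slug <- gsub("[^A-Za-z0-9]+", "_", k)
    wt(report$binding[[k]]$per_sequence,
       sprintf("binding_%s.tsv", slug))
    wt(report$binding[[k]]$summary, sprintf("binding_summary_%s.tsv", slug))
    wt(report$penalty[[k]]$per_sequence, sprintf("penalty_%s.tsv", slug))
    wt(report$penalty[[k]]$summary, sprintf("penalty_summary_%s.tsv", slug))
  }
  wt(report$score_distribution, "score_distribution.tsv")
  if (!is.null(report$glmm)) {
    jsonlite::write_json(glmm_report(report$glmm),
                         file.path(dir, "glmm.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  if (!is.null(report$gap)) {
    g <- report$gap
    jsonlite::write_json(
      list(max_intra = g$max_intra, min_inter = g$min_inter, gap = g$gap,
           n_intra = length(g$intra), n_inter = length(g$inter),
           n_saturated = g$n_saturated),
      file.path(dir, "gap_summary.json"), auto_unbox = TRUE, digits = NA)
    wt(g$intra_histogram, "gap_intra_histogram.tsv")
    wt(g$inter_histogram, "gap_inter_histogram.tsv")
  }
  invisible(dir)
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n\n-- similarity --\n")
  print(x$similarity)
  cat("\n-- binding --\n")
  for (k in names(x$binding)) {
    cat(k, "\n")
    print(x$binding[[k]])
  }
  cat("\n-- penalty classification --\n")
  for (k in names(x$penalty)) {
    cat(k, "\n")
    print(x$penalty[[k]])
  }
  if (!is.null(x$glmm)) {
    cat("\n-- primer-set comparison --\n")
    print(x$glmm)
  }
  if (!is.null(x$gap)) {
    cat("\n-- barcoding gap --\n")
    print(x$gap)
  }
  invisible(x)
}
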