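# Logistic mixed-model comparison of two primer sets: per-sequence binary
# success, primer set as the fixed effect, species as a random intercept.

#' Build amplification records from two primer-set evaluations
#'
#' Joins the per-sequence outcomes of a reference and an improved primer
#' pair into the long-format record set the mixed model consumes: one row
#' per sequence per primer set.  The outcome is binding success
#' (bound = 1, unbound = 0) or penalty classification (Working = 1,
#' Failed = 0).  Records whose outcome is missing under a given primer set
#' are excluded for that set only.
#'
#' @param reference,improved results for the two primer sets: either
#'   [evaluate_pair()] `binding_summary` objects (with
#'   `outcome = "binding"`) or [classify()] `penalty_classification`
#'   objects (with `outcome = "penalty"`), both computed on the same
#'   sequence set.
#' @param outcome which success definition to use.
#' @return a data frame of class `amplification_records` with columns
#'   `sequence_id`, `species`, `primer_set` (factor, reference first) and
#'   `outcome` (0/1).
#' @export
build_records <- function(reference, improved,
                          outcome = c("binding", "penalty")) {
  outcome <- match.arg(outcome)
  extract <- function(x, set_label) {
    if (outcome == "binding") {
      stopifnot(inherits(x, "binding_summary"))
      ps <- x$per_sequence
      keep <- ps$status != "missing"
      data.frame(sequence_id = ps$sequence_id[keep],
                 species = ps$species[keep],
                 primer_set = set_label,
                 outcome = as.integer(ps$status[keep] == "bound"),
                 stringsAsFactors = FALSE)
    } else {
      stopifnot(inherits(x, "penalty_classification"))
      ps <- x$per_sequence
      keep <- ps$classification != "Missing"
      data.frame(sequence_id = ps$sequence_id[keep],
                 species = ps$species[keep],
                 primer_set = set_label,
                 outcome = as.integer(ps$classification[keep] == "Working"),
                 stringsAsFactors = FALSE)
    }
  }
  ref <- extract(reference, "reference")
  imp <- extract(improved, "improved")
  if (length(intersect(ref$sequence_id, imp$sequence_id)) == 0L) {
    stop("the two primer sets share no sequences", call. = FALSE)
  }
  out <- rbind(ref, imp)
  out$primer_set <- factor(out$primer_set,
                           levels = c("reference", "improved"))
  class(out) <- c("amplification_records", "data.frame")
  out
}

#' Fit the logistic mixed model comparing two primer sets
#'
#' Fits `logit P(success) = intercept + effect * [improved] + b_species`
#' with `b_species ~ N(0, sd^2)` by maximum likelihood (Laplace
#' approximation, via `lme4::glmer`).  The fixed effect is the conditional
#' log-odds advantage of the improved primer set; `exp(effect)` is its odds
#' ratio.  Significance is assessed with the Wald z-test.
#'
#' @param records an [build_records()] result, or any data frame with
#'   columns `species`, `primer_set` (two levels, reference first) and
#'   binary `outcome`.
#' @param random_intercept set `FALSE` to drop the species random intercept
#'   and fit an ordinary logistic regression (then `random_sd` is 0); used
#'   for degenerate designs and as a reduction check.
#' @return an object of class `glmm_fit`: list with `intercept`, `effect`,
#'   `effect_se`, `wald_z`, `p_value`, `odds_ratio`, `random_sd`,
#'   `converged`, `n_obs`, `n_species` and the underlying `model`.
#' @export
fit_glmm <- function(records, random_intercept = TRUE) {
  records <- as.data.frame(records)
  need <- c("species", "primer_set", "outcome")
  if (!all(need %in% names(records))) {
    stop("records need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  records$primer_set <- droplevels(as.factor(records$primer_set))
  if (nlevels(records$primer_set) != 2L) {
    stop("records must contain exactly two primer_set levels", call. = FALSE)
  }
  if (random_intercept && length(unique(records$species)) < 2L) {
    stop("at least two species are needed for a species random intercept",
         call. = FALSE)
  }
  for (lev in levels(records$primer_set)) {
    y <- records$outcome[records$primer_set == lev]
    if (all(y == y[1L])) {
      stop(sprintf(
        "complete separation: every outcome under '%s' is %d; consider an exact or penalized fit",
        lev, y[1L]), call. = FALSE)
    }
  }
  if (random_intercept) {
    model <- lme4::glmer(outcome ~ primer_set + (1 | species),
                         data = records, family = stats::binomial())
    co <- summary(model)$coefficients
    vc <- lme4::VarCorr(model)
    random_sd <- attr(vc$species, "stddev")[[1L]]
    converged <- length(model@optinfo$conv$lme4$messages) == 0L &&
      model@optinfo$conv$opt == 0L
  } else {
    model <- stats::glm(outcome ~ primer_set, data = records,
                        family = stats::binomial())
    co <- summary(model)$coefficients
    random_sd <- 0
    converged <- model$converged
  }
  effect <- co[2L, 1L]
  se <- co[2L, 2L]
  z <- effect / se
  structure(
    list(intercept = co[1L, 1L], effect = effect, effect_se = se,
         wald_z = z, p_value = 2 * stats::pnorm(-abs(z)),
         odds_ratio = exp(effect), random_sd = random_sd,
         converged = converged,
         n_obs = nrow(records),
         n_species = length(unique(records$species)),
         model = model),
    class = "glmm_fit"
  )
}

#' @export
print.glmm_fit <- function(x, ...) {
  p_txt <- if (x$p_value < 1e-16) "< 1e-16" else sprintf("%.4g", x$p_value)
  cat("<glmm_fit> logistic mixed model, species random intercept\n")
  cat(sprintf("  effect (improved vs reference): %.4f  SE %.4f  z %.3f  p %s\n",
              x$effect, x$effect_se, x$wald_z, p_txt))
  cat(sprintf("  odds ratio %.3f; species intercept SD %.3f\n",
              x$odds_ratio, x$random_sd))
  cat(sprintf("  n = %d observations, %d species%s\n", x$n_obs, x$n_species,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' @export
coef.glmm_fit <- function(object, ...) {
  c(intercept = object$intercept, effect = object$effect)
}

#' Export the fit as a plain list (for JSON reports)
#'
#' @param x a [fit_glmm()] result.
#' @return a named list of the scalar fit statistics.
#' @export
glmm_report <- function(x) {
  stopifnot(inherits(x, "glmm_fit"))
  list(estimate = x$effect, se = x$effect_se, wald_z = x$wald_z,
       p_value = x$p_value, odds_ratio = x$odds_ratio,
       random_sd = x$random_sd, converged = x$converged,
       n_obs = x$n_obs, n_species = x$n_species)
}
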