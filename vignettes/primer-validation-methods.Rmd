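---
title: "Methods: in-silico validation of degenerate mini-barcode primers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in-silico validation of degenerate mini-barcode primers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(primerscreen)
```

This vignette documents the models and procedures the package implements,
the parameters that matter and why their defaults are what they are, what
the synthetic-data generator does and does not emulate, and the numerical
and design choices made where more than one reading was defensible.

## The problem

Group-specific degenerate PCR primers for eDNA metabarcoding must satisfy
two opposing constraints: bind broadly across a variable target group
(here, a COI mini-barcode for ascidians, a morphologically difficult and
frequently invasive group of marine invertebrates) and bind poorly in
co-occurring non-target groups. Before any wet-lab work, a candidate pair
is vetted *in silico* against curated alignments: where is the alignment
conserved enough to put a primer, how many templates does each primer
actually bind under a mismatch rule, how severe are the mismatches when
weighted by position and type, is the improvement over an older pair
statistically real, and does the amplicon retain a usable barcoding gap.
Each question is one stage of this package.

## IUPAC matching semantics

Every sequence position is a 4-bit base set (`A`=1, `C`=2, `G`=4, `T`=8;
ambiguity codes are unions, the gap is the empty set). A template code
*matches* a primer code when the template's set is a subset of the
primer's (`base_matches()`): a concrete template base matches iff the
primer can pair it as written, and an ambiguous template base (e.g. `N`)
matches only when every base it could stand for is covered. A gap never
matches. This crisp subset rule drives the binding decision; *partial*
overlap between degenerate codes earns credit only in penalty scoring,
where it belongs (see below). Input is case-insensitive and `U` is read as
`T`.

## Conservation profile (similarity index 1/D)

`build_consensus()` calls, per column, the minimal IUPAC code covering
every base whose frequency among non-gap residues reaches the
`inclusion_threshold`, always covering the most frequent base(s).
Ambiguous residues in the data contribute fractionally (1/k to each of
their k bases). The threshold defaults to 0.05: how the consensus behind
the published profile was called is not machine-specified anywhere, and 5%
suppresses singleton variants and sequencing noise while leaving genuinely
polymorphic columns degenerate; it is exposed for sensitivity analysis.
All-gap columns are called `N` with coverage 0; columns are never dropped,
because the coverage information lives in the separate per-position
non-gap proportion track, displayed alongside the index exactly so that
low-coverage regions can be judged on coverage rather than on a spuriously
confident consensus code.

`similarity_profile()` slides a window (default 20 columns — a typical
primer length — step 1) over the consensus and reports `1/D` per window,
`D` being the product of per-column IUPAC set sizes. `1/D` is at most 1 by
construction, so similarity values above 1 are arithmetically impossible
under this formula; the package implements plain `1/D` and makes no
attempt to reproduce published similarity values exceeding 1, which we
treat as a reporting artefact of the source analysis. Windows are indexed
by their start column, which is also the plot x-axis.

Alignment coordinates are 1-based inclusive columns throughout. The
packaged reverse-primer site starts at the published column 553; since the
primer is 23 nt, the stored interval is 553–575 (the published end column,
572, is not reachable with a 23-mer and is treated as a display
inconsistency). Published amplicon sizes (216/197 bp) are stored as
metadata and deliberately never recomputed from the sites, because the
published size and coordinate sets are mutually inconsistent; the sites,
not the amplicon field, drive all computation.

## Binding rule

`mismatch_report()` compares a primer to the plus-strand site (reverse
primers are reverse-complemented onto the plus strand; mismatch flags are
reported in primer orientation so the 3' terminus is always the tail).
`test_binding()` declares a template bound when the total mismatch count is
at most `max_total_mismatch` (default 3) *and* the terminal
`three_prime_window` (default 2) bases carry at most
`max_three_prime_mismatch` (default 0) mismatches. The published
description of the terminal rule appears in two forms ("two bp mismatch at
the 3' end" allowed vs. "no mismatch ... two bp from the 3' end"); the
default follows the stricter zero-mismatch reading, which is the form
stated alongside the published binding counts, and both counts are plain
parameters.

A site containing a gap or `N` is, under the default
`missing_if_gap_or_incomplete` policy, neither bound nor unbound: it is
excluded from the bound numerator but kept in the denominator, matching
summary tables whose totals are the full dataset. The alternative
`score_as_mismatch` policy counts such positions as mismatches; both are
provided because the original analysis does not state which reading it
used.

When a pair carries no stored sites, each primer is placed at the
consensus window minimising its mismatch count, ties resolved toward the
5'-most window — a deterministic placement, so reruns are identical.
Species-level success means at least one sequence of the species binds
both primers (detection-coverage semantics).

## Penalty scoring

`primer_penalty()` scores a primer against a site as

> sum over positions of `position_factor(d) * pair_penalty * adj`,

where `d` is the distance from the 3' terminus (`d = 1` is the terminal
base, for both orientations — the 3' end is the extension-critical end),
`pair_penalty` is the mismatch-type weight, and `adj` is an extra
multiplier applied when a neighbouring position also mismatches
(`adjacency_factor`, default 1 = no adjacency penalty, the standard
setting).

`pair_penalty()` averages over degeneracy: the mean over all ordered
concrete pairs (x in the primer code's set, y in the template code's set)
of 0 for x = y and `type_factor[x, y]` otherwise. A template base that
matches one of two primer expansions therefore earns half the full weight
— this is the "partial wobble match" credit, and it also means a
degenerate primer position retains a small background penalty even against
a perfectly compatible concrete base (the cost of degeneracy). Template
gaps and `N` have dedicated weight columns and are scored, not skipped,
under the default `gap_as_missing = FALSE`, `n_as_missing = FALSE`; the
*Missing* class then arises only from sites that cannot be evaluated at
all. Both flags are exposed because the treatment of gaps/`N` in the
source analysis is described in self-contradictory terms.

The shipped weight tables (`inst/extdata/position_weights_v1.tsv`,
`mismatch_type_weights_v1.tsv`) are package-calibrated defaults: position
weights decay monotonically from 100 at the 3'-terminal base to 2 beyond
position 19, and type weights range from 0.6 (near-stable wobble duplexes,
e.g. primer G over template A) to 1.6 (strongly destabilising
pyrimidine–pyrimidine duplexes), with 1.5 for template gaps and 1.0 for
`N`. The constructor enforces the two structural invariants every such
table must satisfy — position weights non-increasing with distance from
the 3' end, type weights zero exactly on matching pairs — and all scoring
functions take the matrices as an argument, so analyses and tests can
substitute flat or custom weights with hand-computable outcomes. Absolute
penalty values are therefore comparable only within one weight set;
conclusions should rest on the classification threshold and on contrasts
between primers, not on raw score magnitudes.

`classify()` sums forward and reverse scores and applies a strict
threshold: *Working* means combined score strictly below 150 (the midpoint
of the empirical 100–200 zone in which primer performance transitions from
success to failure); exactly 150 is *Failed*. Percentages are reported per
taxon over all sequences, so Working + Failed + Missing is always 100.

## Mixed-model primer-set comparison

`build_records()` joins two evaluations of the same sequences into
long-format records (one row per sequence per primer set; rows whose
outcome is missing under a given set are dropped for that set only). The
default outcome is *binding* success rather than penalty classification:
with the packaged pairs, penalty classification can be completely
separated (one set with zero Working sequences), under which no finite
odds ratio exists — binding outcomes are the response under which a
finite published-scale effect is estimable. `outcome = "penalty"`
preserves the alternative.

`fit_glmm()` fits `logit P(success) = b0 + b1*[improved] + u_species`,
`u_species ~ N(0, sigma^2)`, by maximum likelihood with the Laplace
approximation (`lme4::glmer`) — standard practice for a single random
intercept at this scale. It reports the Wald z-test and `exp(b1)` as the
odds ratio, flags non-convergence, refuses completely separated inputs
with a pointer toward exact/penalised alternatives, and prints p-values
below representable precision as `< 1e-16`. Setting
`random_intercept = FALSE` reduces the fit to ordinary logistic
regression, which the tests use as an oracle: on balanced data its effect
equals the marginal 2x2 log odds ratio exactly.

## Barcoding gap

`k80_distance()` restricts each pair to columns where both sequences carry
a concrete A/C/G/T (pairwise deletion) and evaluates
`d = -1/2 ln((1 - 2P - Q) sqrt(1 - 2Q))`. Pairwise rather than complete
deletion is the right default for short, ragged mini-barcode alignments,
where complete deletion would discard most of the signal; `min_overlap`
(default 100 sites) guards against distances estimated on a handful of
columns. Ambiguity codes are excluded from comparison rather than
fractionally counted, keeping P and Q integer ratios as in standard
distance software. Pairs outside the formula's domain (saturation) or
under `min_overlap` are kept with `valid = FALSE`, excluded from the gap
statistic, and counted in a saturation report — near-saturated pairs are a
property of deep interspecific divergence worth surfacing, not an error.

`gap_statistics()` reports `max(intra)`, `min(inter)` and their difference
(negative when the classes overlap; never clamped), plus histograms at
`bin_width = 0.01` (1%), the granularity at which such distributions are
customarily read. All valid pairs enter the statistics; no
one-sequence-per-species thinning is applied.

## Synthetic data: what it emulates, and what it does not

`generate_alignment()` draws a random root sequence, writes one concrete
realisation of every supplied primer into its sites (so each primer has a
plausible binding region), evolves species ancestors and then individual
sequences under a K80 process (closed-form substitution probabilities per
site; branch lengths `inter_rate/2` and `intra_rate/2`, so *pairwise*
expected divergences are `inter_rate` between and `intra_rate` within
species), and finally injects gaps and ambiguity codes outside the primer
sites. For one designated pair, sites are overwritten per sequence with
*exact* designed mismatch counts (3'-terminal counts placed terminal-first,
the rest 5'-first, always choosing a base outside the primer's set), and
the generator verifies the realised counts before returning. Defaults —
25 species x 4 sequences, 700 columns, 1% intra- and 20% interspecific
divergence, transition/transversion rate ratio 2, gap rate 1%, ambiguity
rate 0.2% — are desk-scale analogues of a curated COI dataset: divergences
sit inside the empirically observed intra (<= ~6.5%) and inter (~10–35%)
ranges, and kappa = 2 is the textbook mitochondrial default.

What the generator does *not* emulate: phylogenetic structure beyond a
two-level star (no coalescent, no rate heterogeneity across lineages or
sites), codon/amino-acid constraint, alignment error, or the strongly
non-uniform species abundances of real GenBank data. Passing tests on
synthetic data therefore demonstrate correctness of the computations and
recoverability of designed signals — not that real curated alignments will
show any particular binding fraction or gap.

`generate_binding_outcomes()` samples binary outcomes from exactly the
logistic species-intercept model the GLMM assumes, which makes coverage
testable: across 200 seeded replicates of 50 species x 20 sequences at a
designed log-odds effect of 2, the 95% Wald interval covers the truth in
at least 90% of fits (the test suite computes this; at this size a Laplace
fit takes ~0.3 s, which is why those replicate counts were chosen).

## Numerical and degenerate-input choices

* Window products `D` are computed in double precision (exact up to
  `4^26`, far beyond any primer-length window).
* The generator saves and restores the caller's RNG state; all its
  randomness is a pure function of the truth record's seed.
* Ties in primer placement go to the smallest start column; ties among
  most-frequent consensus bases include all tied bases in the code.
* Empty alignments, single-species gap analyses, one-level or separated
  model inputs, ragged/ill-alphabet FASTA records, and oversized designed
  mismatch counts all fail fast with errors naming the offending record,
  class or stage.
* `run_validation()` is deterministic end to end; the only randomness in
  the package lives in the seeded generator.

## Known limitations

* Penalty magnitudes depend on the shipped weight tables; they are
  relative scores, not physical binding energies, and no
  melting-temperature or nearest-neighbour thermodynamic model is
  provided.
* The binding rule is count-based, as in the source workflow; primers
  whose failures are thermodynamic rather than combinatorial will be
  misjudged.
* K80 is fixed as the distance model (no model selection), and the gap
  statistic uses all valid pairs, which over-weights densely sampled
  species.
* The mixed model supports exactly the two-set, species-intercept design;
  no additional covariates or model selection.
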