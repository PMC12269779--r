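fwd20 <- degenerate_primer("f20", "CCDGATATAGCHTTYCCWCG", "forward")

test_that("mismatch reports count and place mismatches correctly", {
  p <- degenerate_primer("p", "ACGTACGTAC", "forward")
  perfect <- mismatch_report(p, "ACGTACGTAC")
  expect_identical(perfect$total, 0L)
  expect_identical(perfect$three_prime_count, 0L)
  expect_false(perfect$missing)
  # mismatch at the 3'-terminal base
  r <- mismatch_report(p, "ACGTACGTAT")
  expect_identical(r$total, 1L)
  expect_identical(r$three_prime_count, 1L)
  # degenerate positions accept any covered base: T under D is a match
  r <- mismatch_report(fwd20, "CCTGATATAGCATTCCCACG")
  expect_identical(r$total, 0L)
  expect_error(mismatch_report(p, "ACGT"), "length")
})

test_that("reverse primers are tested on the plus strand with the 3' end tracked", {
  p <- degenerate_primer("r", "ACGTTT", "reverse")
  # plus-strand site = reverse complement of the primer -> perfect match
  expect_identical(mismatch_report(p, reverse_complement("ACGTTT"))$total, 0L)
  # a mismatch at the site's FIRST plus-strand base is the primer's 3' end
  site <- reverse_complement("ACGTTT")
  substr(site, 1, 1) <- "G"   # was A (complement of terminal T)
  r <- mismatch_report(p, site)
  expect_identical(r$total, 1L)
  expect_identical(r$three_prime_count, 1L)
  expect_true(r$per_position[6])  # flags are 5'->3' on the primer
})

test_that("the binding rule is inclusive on totals and strict at the 3' end", {
  p <- degenerate_primer("p", "AAAAAAAAAA", "forward")
  mk <- function(site) mismatch_report(p, site)
  expect_identical(test_binding(mk("CCCAAAAAAA")), "bound")    # 3 mismatches
  expect_identical(test_binding(mk("CCCCAAAAAA")), "unbound")  # 4 mismatches
  expect_identical(test_binding(mk("AAAAAAAAAC")), "unbound")  # one 3' mismatch
  relaxed <- binding_params(max_three_prime_mismatch = 2L)
  expect_identical(test_binding(mk("AAAAAAAAAC"), relaxed), "bound")
  # gap in the site: missing by default, mismatch under the other policy
  expect_identical(test_binding(mk("AAAA-AAAAA")), "missing")
  strict <- binding_params(missing_policy = "score_as_mismatch")
  expect_identical(test_binding(mismatch_report(p, "AAAA-AAAAA", strict),
                                strict), "bound")
})

test_that("bound status equals the expansion-enumeration oracle", {
  params <- binding_params()
  set.seed(202)
  for (i in 1:60) {
    pseq <- random_primer_seq(sample(6:10, 1), amb = 0.3)
    if (iupac_degeneracy(pseq) > 64) next
    primer <- degenerate_primer("p", pseq, "forward")
    tmpl <- random_concrete_seq(primer$length)
    # flip a few positions toward the primer so bound cases occur
    exp1 <- strsplit(expand_degeneracies(pseq)[1], "")[[1]]
    flip <- sample(primer$length, sample(0:primer$length, 1))
    tv <- strsplit(tmpl, "")[[1]]
    tv[flip] <- exp1[flip]
    tmpl <- paste(tv, collapse = "")

    got <- test_binding(mismatch_report(primer, tmpl, params), params)
    hams <- vapply(expand_degeneracies(pseq), function(e) {
      sum(strsplit(e, "")[[1]] != strsplit(tmpl, "")[[1]])
    }, numeric(1))
    tail_hams <- vapply(expand_degeneracies(pseq), function(e) {
      L <- nchar(e)
      sum(strsplit(e, "")[[1]][(L - 1):L] != strsplit(tmpl, "")[[1]][(L - 1):L])
    }, numeric(1))
    oracle <- any(hams <= params$max_total_mismatch &
                    tail_hams <= params$max_three_prime_mismatch)
    expect_identical(got == "bound", oracle, info = paste(pseq, tmpl))
  }
})

test_that("tightening binding parameters never increases bound counts", {
  g <- generate_alignment(synthetic_truth(9, n_species = 6,
                                          seqs_per_species = 3,
                                          constrained_pair = 2,
                                          rev_mismatch = c(0L, 1L, 2L, 3L, 4L, 5L)))
  pair <- ascidian_coi_primers()$AscCOI2
  bound_at <- function(mm) {
    s <- evaluate_pair(g$alignment, pair, binding_params(max_total_mismatch = mm))
    s$summary$bound[s$summary$level == "sequence" & s$summary$primer == "pair"]
  }
  counts <- vapply(0:5, bound_at, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("pair evaluation recovers engineered binding and species coverage", {
  # 4 of 10 sequences carry >= 4 reverse mismatches -> 6 bound
  tr <- synthetic_truth(77, n_species = 5, seqs_per_species = 2,
                        constrained_pair = 2,
                        rev_mismatch = c(4L, 0L, 0L, 0L, 4L,
                                         0L, 4L, 0L, 0L, 4L))
  g <- generate_alignment(tr)
  s <- evaluate_pair(g$alignment, ascidian_coi_primers()$AscCOI2)
  seq_row <- s$summary[s$summary$level == "sequence" & s$summary$primer == "pair", ]
  expect_equal(seq_row$bound, 6)
  # species bound iff >= 1 of its sequences is pair-bound (partition check)
  ps <- s$per_sequence
  expected_sp <- sum(vapply(unique(ps$species), function(x)
    any(ps$status[ps$species == x] == "bound"), TRUE))
  sp_row <- s$summary[s$summary$level == "species" & s$summary$primer == "pair", ]
  expect_equal(sp_row$bound, expected_sp)
  # pair bound count can never exceed either single-primer count
  seq_rows <- s$summary[s$summary$level == "sequence", ]
  expect_true(seq_row$bound <= min(seq_rows$bound))
})

test_that("an alignment made of primer expansions binds perfectly", {
  pair <- ascidian_coi_primers()$AscCOI2
  fseq <- expand_degeneracies(pair$forward)[1:5]
  rsite <- vapply(expand_degeneracies(pair$reverse)[1:5],
                  reverse_complement, "")
  spacer <- strrep("A", 10)
  aln <- tiny_aln(paste0(fseq, spacer, rsite), species = "sp1")
  pp <- primer_pair(pair$forward, pair$reverse,
                    forward_site = c(1, 20), reverse_site = c(31, 53))
  s <- evaluate_pair(aln, pp)
  expect_true(all(s$summary$fraction == 1))
})

test_that("unset sites are placed at the best consensus window, 5'-most on ties", {
  pair0 <- ascidian_coi_primers()$AscCOI2
  g <- generate_alignment(synthetic_truth(3))
  free <- primer_pair(pair0$forward, pair0$reverse)
  s <- evaluate_pair(g$alignment, free)
  expect_identical(s$sites$forward, c(361L, 380L))
  expect_identical(s$sites$reverse, c(553L, 575L))
})
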