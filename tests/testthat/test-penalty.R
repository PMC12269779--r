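test_that("pair penalties follow the averaging rule over degeneracies", {
  m <- default_penalty_matrices()
  tf <- m$type_factor
  expect_identical(pair_penalty("A", "A", m), 0)
  expect_identical(pair_penalty("A", "C", m), tf["A", "C"])
  # primer W vs template A: one of two expansions matches
  expect_equal(pair_penalty("W", "A", m), 0.5 * tf["T", "A"],
               ignore_attr = TRUE)
  # primer N vs a concrete base: 3 of 4 expansions mismatch
  expect_equal(pair_penalty("N", "A", m),
               0.75 * mean(c(tf["C", "A"], tf["G", "A"], tf["T", "A"])),
               ignore_attr = TRUE)
  # degenerate template: mean over both sets
  expect_equal(pair_penalty("R", "Y", m),
               mean(c(tf["A", "C"], tf["A", "T"], tf["G", "C"], tf["G", "T"])),
               ignore_attr = TRUE)
  # gap and N columns are dedicated rows
  expect_equal(pair_penalty("A", "-", m), tf["A", "gap"], ignore_attr = TRUE)
  expect_equal(pair_penalty("W", "N", m),
               mean(c(tf["A", "N"], tf["T", "N"])), ignore_attr = TRUE)
})

test_that("primer penalty equals the hand-computed position/type sum", {
  m <- default_penalty_matrices()
  p <- degenerate_primer("p", strrep("A", 20), "forward")
  # mismatches at the 5'-terminal (distance 20) and 3'-terminal (distance 1)
  site <- strrep("A", 20)
  substr(site, 1, 1) <- "C"
  substr(site, 20, 20) <- "G"
  got <- primer_penalty(p, site, m)
  expected <- m$position_factor[20] * m$type_factor["A", "C"] +
    m$position_factor[1] * m$type_factor["A", "G"]
  expect_equal(got$score, expected, ignore_attr = TRUE)
  expect_false(got$missing)
  # perfect match scores zero
  expect_identical(primer_penalty(p, strrep("A", 20), m)$score, 0)
})

test_that("a 3'-terminal mismatch outweighs the same mismatch at the 5' end", {
  m <- default_penalty_matrices()
  p <- degenerate_primer("p", strrep("A", 20), "forward")
  s3 <- strrep("A", 20); substr(s3, 20, 20) <- "C"
  s5 <- strrep("A", 20); substr(s5, 1, 1) <- "C"
  expect_gt(primer_penalty(p, s3, m)$score, primer_penalty(p, s5, m)$score)
  # and for a reverse primer, whose 3' end sits at the site's start
  r <- degenerate_primer("r", strrep("A", 20), "reverse")
  site3 <- reverse_complement(s3)   # mismatch at the primer 3' terminus
  site5 <- reverse_complement(s5)
  expect_gt(primer_penalty(r, site3, m)$score,
            primer_penalty(r, site5, m)$score)
})

test_that("scores are zero iff perfect and grow as matches become mismatches", {
  m <- default_penalty_matrices()
  set.seed(88)
  for (i in 1:25) {
    # concrete primers: score 0 exactly at the perfect match
    cseq <- random_concrete_seq(12)
    cp <- degenerate_primer("p", cseq, "forward")
    expect_identical(primer_penalty(cp, cseq, m)$score, 0)

    # degenerate primers keep a small partial-match background penalty at
    # ambiguous positions (averaging rule), and degrading matched positions
    # one by one never lowers the score
    pseq <- random_primer_seq(12, amb = 0.25)
    p <- degenerate_primer("p", pseq, "forward")
    match_site <- expand_degeneracies(pseq)[1]
    chars <- strsplit(match_site, "")[[1]]
    pchars <- strsplit(pseq, "")[[1]]
    last <- primer_penalty(p, match_site, m)$score
    if (pseq == match_site) expect_identical(last, 0)
    for (j in sample(12)) {
      off <- setdiff(c("A", "C", "G", "T"), IUPAC_SETS[[pchars[j]]])
      if (length(off) == 0) next
      chars[j] <- off[1]
      sc <- primer_penalty(p, paste(chars, collapse = ""), m)$score
      expect_gt(sc, last)
      last <- sc
    }
  }
})

test_that("with adjacency factor 1 the score ignores mismatch adjacency", {
  p <- degenerate_primer("p", strrep("A", 10), "forward")
  adjacent <- "CCAAAAAAAA"
  spread <- "CAAAACAAAA"   # same distances? no - compare same site both ways
  m1 <- flat_matrices(adjacency_factor = 1)
  m2 <- flat_matrices(adjacency_factor = 3)
  # under flat weights, two adjacent mismatches score 2 regardless of
  # position when adjacency_factor is 1
  expect_identical(primer_penalty(p, adjacent, m1)$score, 2)
  expect_identical(primer_penalty(p, spread, m1)$score, 2)
  # a non-unit adjacency factor separates the two layouts
  expect_identical(primer_penalty(p, adjacent, m2)$score, 6)
  expect_identical(primer_penalty(p, spread, m2)$score, 2)
})

test_that("gap/N missing flags produce Missing classifications", {
  p <- degenerate_primer("p", strrep("A", 6), "forward")
  m_scored <- flat_matrices()
  m_missing <- flat_matrices(gap_as_missing = TRUE, n_as_missing = TRUE)
  site <- "AA-AAA"
  expect_false(primer_penalty(p, site, m_scored)$missing)
  expect_identical(primer_penalty(p, site, m_scored)$score, 1)
  expect_true(primer_penalty(p, site, m_missing)$missing)
  expect_true(is.na(primer_penalty(p, "AANAAA", m_missing)$score))
})

test_that("classification splits Working/Failed/Missing at a strict threshold", {
  scores <- data.frame(
    sequence_id = paste0("s", 1:10),
    species = "sp", taxon = "target",
    forward_score = c(rep(50, 5), rep(100, 3), NA, 10),
    reverse_score = c(rep(50, 5), rep(100, 3), 5, NA))
  cl <- classify(scores, threshold = 150)
  expect_identical(cl$per_sequence$classification,
                   c(rep("Working", 5), rep("Failed", 3), "Missing", "Missing"))
  s <- cl$summary
  expect_equal(s$working_pct, 50)
  expect_equal(s$failed_pct, 30)
  expect_equal(s$missing_pct, 20)
  # combined exactly at the threshold is Failed, just below is Working
  boundary <- classify(data.frame(forward_score = c(75, 75),
                                  reverse_score = c(75, 74.999)), 150)
  expect_identical(boundary$per_sequence$classification,
                   c("Failed", "Working"))
  # forward 18.45 + reverse 120.4 = 138.85 < 150 -> Working
  med <- classify(data.frame(forward_score = 18.45, reverse_score = 120.4))
  expect_identical(med$per_sequence$classification, "Working")
  expect_error(classify(scores[0, ]), "no scores")
})

test_that("class percentages always sum to 100 within each taxon", {
  g <- generate_alignment(synthetic_truth(14, n_species = 6,
                                          seqs_per_species = 3,
                                          gap_rate = 0.05))
  aln <- g$alignment
  aln$taxon <- rep(c("grpA", "grpB", "grpC"), each = 6)
  sc <- penalty_scores(aln, ascidian_coi_primers()$AscCOI2,
                       default_penalty_matrices(gap_as_missing = TRUE))
  s <- classify(sc)$summary
  expect_equal(s$working_pct + s$failed_pct + s$missing_pct,
               rep(100, nrow(s)))
  expect_equal(s$working + s$failed + s$missing, s$total)
})

test_that("score distributions summarise per group and direction", {
  sc <- data.frame(taxon = rep(c("a", "b"), each = 4),
                   forward_score = c(rep(5, 4), 1:4),
                   reverse_score = c(rep(7, 4), 11:14))
  d <- score_distribution(sc)
  expect_identical(nrow(d), 4L)
  a_f <- d[d$group == "a" & d$direction == "forward", ]
  expect_equal(a_f$median, 5)
  expect_equal(a_f$q3 - a_f$q1, 0)
  b_r <- d[d$group == "b" & d$direction == "reverse", ]
  expect_equal(b_r$median, 12.5)
})

test_that("matrix validation rejects malformed weights", {
  tf <- matrix(1, 4, 6); diag(tf[, 1:4]) <- 0
  expect_error(penalty_matrices(c(1, 2, 3), tf), "non-increasing")
  bad <- tf; bad[1, 1] <- 0.5
  expect_error(penalty_matrices(rep(1, 5), bad), "matching")
  expect_error(penalty_matrices(rep(1, 5), tf[, 1:4]), "4 x 6")
})
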