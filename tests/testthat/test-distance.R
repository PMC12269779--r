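test_that("the K80 closed form matches hand-computed cases", {
  # identical sequences
  d0 <- k80_distance(strrep("ACGT", 30), strrep("ACGT", 30), min_overlap = 10)
  expect_identical(d0$P, 0)
  expect_identical(d0$Q, 0)
  expect_identical(d0$distance, 0)
  expect_true(d0$valid)

  # 100 sites, 10 transitions (A<->G), 5 transversions (A<->C)
  a <- rep("A", 100)
  b <- a
  b[1:10] <- "G"
  b[11:15] <- "C"
  d <- k80_distance(paste(a, collapse = ""), paste(b, collapse = ""))
  expect_equal(d$P, 0.10)
  expect_equal(d$Q, 0.05)
  expect_equal(d$distance, -0.5 * log(0.75 * sqrt(0.90)), tolerance = 1e-12)
  expect_equal(d$distance, 0.17018, tolerance = 1e-4)

  # saturation: P = 0.5, Q = 0 leaves the log domain
  b2 <- a
  b2[1:50] <- "G"
  dsat <- k80_distance(paste(a, collapse = ""), paste(b2, collapse = ""))
  expect_false(dsat$valid)
  expect_true(is.na(dsat$distance))

  expect_error(k80_distance("ACGT", "ACG"), "length")
})

test_that("pairwise deletion drops gaps and ambiguity codes from comparisons", {
  d <- k80_distance("ACGTAC-TRA", "ACGTACGTAA", min_overlap = 5)
  # compared sites exclude the gap and the R: 8 sites, all identical
  expect_identical(d$sites, 8L)
  expect_identical(d$distance, 0)
  # under-covered pairs are invalid
  d2 <- k80_distance("AC--------", "ACGTACGTAA", min_overlap = 5)
  expect_false(d2$valid)
})

test_that("K80 distance is symmetric and bounded below by P + Q", {
  set.seed(61)
  for (i in 1:50) {
    a <- random_concrete_seq(200)
    bv <- strsplit(a, "")[[1]]
    flip <- sample(200, sample(2:8, 1))
    for (j in flip) bv[j] <- sample(setdiff(c("A", "C", "G", "T"), bv[j]), 1)
    b <- paste(bv, collapse = "")
    d_ab <- k80_distance(a, b)
    d_ba <- k80_distance(b, a)
    expect_identical(d_ab, d_ba)
    if (d_ab$valid && d_ab$P + d_ab$Q <= 0.05) {
      # small-divergence first-order check: d >= p-distance, within 10%
      expect_gte(d_ab$distance, d_ab$P + d_ab$Q)
      expect_lt(d_ab$distance, 1.1 * (d_ab$P + d_ab$Q))
    }
  }
})

test_that("distance matrices agree with an independent K80 implementation", {
  skip_if_not_installed("ape")
  g <- generate_alignment(synthetic_truth(44, n_species = 6,
                                          seqs_per_species = 2,
                                          alignment_length = 700,
                                          gap_rate = 0, ambiguity_rate = 0))
  aln <- g$alignment
  dm <- distance_matrix(aln)
  bin <- ape::as.DNAbin(t(sapply(aln$sequences,
                                 function(s) strsplit(s, "")[[1]])))
  rownames(bin) <- aln$ids
  ref <- as.matrix(ape::dist.dna(bin, model = "K80",
                                 pairwise.deletion = TRUE))
  for (k in seq_len(nrow(dm))) {
    expect_equal(dm$distance[k], ref[dm$id_a[k], dm$id_b[k]],
                 tolerance = 1e-10)
  }
})

test_that("pair counting and intra/inter partition follow the species labels", {
  aln <- tiny_aln(rep(strrep("ACGT", 30), 4),
                  species = c("A", "A", "B", "B"))
  dm <- distance_matrix(aln, min_overlap = 10)
  expect_identical(nrow(dm), 6L)             # 4 choose 2
  expect_identical(sum(dm$comparison == "intra"), 2L)
  expect_identical(sum(dm$comparison == "inter"), 4L)
})

test_that("gap statistics report the intra/inter separation without clamping", {
  mk_dists <- function(intra, inter) {
    n <- length(intra) + length(inter)
    structure(data.frame(
      id_a = paste0("a", 1:n), id_b = paste0("b", 1:n),
      comparison = c(rep("intra", length(intra)), rep("inter", length(inter))),
      P = 0, Q = 0, distance = c(intra, inter), valid = TRUE, sites = 200L),
      class = c("pairwise_distances", "data.frame"))
  }
  g <- gap_statistics(mk_dists(c(0.01, 0.02), c(0.10, 0.30)))
  expect_equal(g$max_intra, 0.02)
  expect_equal(g$min_inter, 0.10)
  expect_equal(g$gap, 0.08)
  expect_identical(sum(g$intra_histogram$count), 2L)
  expect_identical(sum(g$inter_histogram$count), 2L)
  # overlapping classes: the gap goes negative
  g2 <- gap_statistics(mk_dists(c(0.05, 0.12), c(0.08, 0.30)))
  expect_equal(g2$gap, 0.08 - 0.12)
  # single-species input has no interspecific class
  solo <- mk_dists(c(0.01), numeric(0))
  expect_error(gap_statistics(solo), "interspecific")
})

test_that("two-level synthetic divergence produces a positive barcoding gap", {
  g <- generate_alignment(synthetic_truth(55, n_species = 10,
                                          seqs_per_species = 3,
                                          intra_rate = 0.01,
                                          inter_rate = 0.25))
  dm <- distance_matrix(g$alignment)
  gap <- gap_statistics(dm)
  expect_gt(mean(gap$inter), mean(gap$intra))
  expect_gt(gap$gap, 0)
})

test_that("the estimator is consistent on long simulated K80 sequences", {
  # pairs diverged by d = 0.1 expected substitutions/site over 10 kb
  truth <- synthetic_truth(66, n_species = 2, seqs_per_species = 1,
                           alignment_length = 10000, pairs = list(),
                           intra_rate = 0.001, inter_rate = 0.1,
                           gap_rate = 0, ambiguity_rate = 0)
  ests <- vapply(1:5, function(k) {
    t_k <- truth
    t_k$seed <- truth$seed + k
    g <- generate_alignment(t_k)
    k80_distance(g$alignment$sequences[1], g$alignment$sequences[2])$distance
  }, numeric(1))
  # the SE of one 10 kb estimate is about sqrt(d/L) ~ 0.003; the mean of 5
  # replicates must land within 3 of these
  expect_lt(abs(mean(ests) - 0.1), 3 * sqrt(0.1 / 10000))
})
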