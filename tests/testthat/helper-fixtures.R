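# Shared fixtures, all built in code.

# independent IUPAC definition table (typed from the nomenclature, not taken
# from package internals) for enumeration oracles
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# random degenerate primer as a string; ambiguity codes appear at rate amb
random_primer_seq <- function(len, amb = 0.2) {
  codes <- names(IUPAC_SETS)
  amb_codes <- codes[lengths(IUPAC_SETS) > 1L]
  paste(ifelse(runif(len) < amb,
               sample(amb_codes, len, replace = TRUE),
               sample(c("A", "C", "G", "T"), len, replace = TRUE)),
        collapse = "")
}

random_concrete_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# tiny alignment with explicit sequences
tiny_aln <- function(seqs, species = paste0("sp", seq_along(seqs)),
                     taxon = NA_character_) {
  aligned_set(seqs, species = species, taxon = taxon)
}

# a consensus_seq built directly from codes (for profile-level tests)
make_cons <- function(codes, prop = rep(1, length(codes))) {
  structure(list(codes = codes, nongap_proportion = prop,
                 inclusion_threshold = 0.05, length = length(codes)),
            class = "consensus_seq")
}

# uniform penalty weights with hand-computable outcomes: every mismatch
# factor 1, every position factor 1
flat_matrices <- function(adjacency_factor = 1, ...) {
  tf <- matrix(1, 4, 6)
  diag(tf[, 1:4]) <- 0
  penalty_matrices(rep(1, 30), tf, adjacency_factor = adjacency_factor, ...)
}

# write an aligned set to a temporary FASTA and return the path
temp_fasta <- function(aln) {
  path <- tempfile(fileext = ".fasta")
  write_aligned_fasta(aln, path)
  path
}
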