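#' Construct an aligned sequence set
#'
#' The container every pipeline stage consumes: equal-length gapped sequences
#' over the IUPAC alphabet plus "-", each labelled with a species and an
#' optional taxon group.
#'
#' @param sequences character vector of gapped sequences (identical lengths).
#' @param species character vector of species labels (non-empty), recycled.
#' @param taxon character vector of taxon-group labels, recycled; defaults to
#'   `NA`.
#' @param ids sequence identifiers; defaults to `names(sequences)` or
#'   `seq_1 ... seq_n`.
#' @return an object of class `aligned_set` with fields `ids`, `species`,
#'   `taxon`, `sequences`, `n` and `width` (the alignment length in columns).
#' @export
aligned_set <- function(sequences, species, taxon = NA_character_,
                        ids = names(sequences)) {
  sequences <- toupper(as.character(sequences))
  n <- length(sequences)
  if (n < 1L) stop("alignment is empty", call. = FALSE)
  if (is.null(ids)) ids <- paste0("seq_", seq_len(n))
  ids <- as.character(ids)
  species <- rep_len(as.character(species), n)
  taxon <- rep_len(as.character(taxon), n)
  if (any(is.na(species) | !nzchar(species))) {
    bad <- which(is.na(species) | !nzchar(species))[1L]
    stop(sprintf("record %d ('%s') has no species label", bad, ids[bad]),
         call. = FALSE)
  }
  widths <- nchar(sequences)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1L])[1L]
    stop(sprintf(
      "ragged alignment: record %d ('%s') has %d columns, expected %d",
      bad, ids[bad], widths[bad], widths[1L]), call. = FALSE)
  }
  for (i in seq_len(n)) {   # alphabet check, naming record and position
    .seq_bits(sequences[i], allow_gap = TRUE,
              what = sprintf("record %d ('%s')", i, ids[i]))
  }
  structure(
    list(ids = ids, species = species, taxon = taxon,
         sequences = gsub("U", "T", sequences, fixed = TRUE),
         n = n, width = widths[1L]),
    class = "aligned_set"
  )
}

#' @export
print.aligned_set <- function(x, ...) {
  cat(sprintf("<aligned_set> %d records x %d columns, %d species\n",
              x$n, x$width, length(unique(x$species))))
  if (!all(is.na(x$taxon))) {
    cat("  taxa:", paste(unique(x$taxon), collapse = ", "), "\n")
  }
  invisible(x)
}

# integer bits matrix (records x columns) for vectorised matching
.aln_bits <- function(aln) {
  m <- matrix(0L, nrow = aln$n, ncol = aln$width)
  for (i in seq_len(aln$n)) m[i, ] <- .seq_bits(aln$sequences[i])
  m
}

#' Sizes of the species partition
#'
#' @param aln an [aligned_set()].
#' @return a named integer vector of record counts per species.
#' @export
species_sizes <- function(aln) {
  stopifnot(inherits(aln, "aligned_set"))
  table(aln$species) |> c()
}

#' Read an aligned FASTA file
#'
#' Reads a gapped multiple-sequence alignment.  Species and taxon labels come
#' either from the headers, parsed as `>id|species` with an optional third
#' `|taxon` field, or from a tab-separated mapping file with header columns
#' `sequence_id`, `species_label`, `taxon_group` which overrides the headers.
#'
#' @param path FASTA file path.
#' @param species_map optional path to the TSV mapping file.
#' @return an [aligned_set()]; record order is preserved.
#' @export
read_aligned_fasta <- function(path, species_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  seqs <- as.character(set)
  headers <- names(set)
  fields <- strsplit(headers, "|", fixed = TRUE)
  ids <- vapply(fields, `[`, "", 1L)
  ids <- trimws(ids)
  species <- vapply(fields, function(f) if (length(f) >= 2L) trimws(f[2L]) else NA_character_, "")
  taxon <- vapply(fields, function(f) if (length(f) >= 3L) trimws(f[3L]) else NA_character_, "")
  taxon[!nzchar(taxon)] <- NA_character_
  if (!is.null(species_map)) {
    map <- utils::read.delim(species_map, stringsAsFactors = FALSE)
    need <- c("sequence_id", "species_label", "taxon_group")
    if (!all(need %in% names(map))) {
      stop("species map needs columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    idx <- match(ids, map$sequence_id)
    if (anyNA(idx)) {
      stop(sprintf("record '%s' is missing from the species map",
                   ids[which(is.na(idx))[1L]]), call. = FALSE)
    }
    species <- map$species_label[idx]
    taxon <- map$taxon_group[idx]
  } else if (any(is.na(species) | !nzchar(species))) {
    bad <- which(is.na(species) | !nzchar(species))[1L]
    stop(sprintf(
      "header '%s' has no '|species' field and no species_map was given",
      headers[bad]), call. = FALSE)
  }
  aligned_set(seqs, species = species, taxon = taxon, ids = ids)
}

#' Write an aligned set to FASTA
#'
#' Headers are written in the `>id|species|taxon` convention that
#' [read_aligned_fasta()] parses (the taxon field is dropped when `NA`).
#'
#' @param aln an [aligned_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_aligned_fasta <- function(aln, path) {
  stopifnot(inherits(aln, "aligned_set"))
  hdr <- ifelse(is.na(aln$taxon),
                paste(aln$ids, aln$species, sep = "|"),
                paste(aln$ids, aln$species, aln$taxon, sep = "|"))
  out <- Biostrings::BStringSet(aln$sequences)
  names(out) <- hdr
  Biostrings::writeXStringSet(out, path, width = 80L)
  invisible(path)
}

#' Write a species mapping table
#'
#' @param aln an [aligned_set()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_species_map <- function(aln, path) {
  stopifnot(inherits(aln, "aligned_set"))
  utils::write.table(
    data.frame(sequence_id = aln$ids, species_label = aln$species,
               taxon_group = aln$taxon, stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
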