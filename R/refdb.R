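# candidate reference database preparation: length filtering, IUPAC
# ambiguity resolution, pairwise identity, greedy centroid clustering

#' Load candidate 16S reference sequences and filter by length
#'
#' Reads a FASTA file of candidate reference sequences and keeps records
#' whose length lies within `[min_len, max_len]`, the usual filter for
#' near-full-length small-subunit rRNA genes.  Input order is preserved
#' and ambiguity codes are left untouched (see [resolve_ambiguities()]).
#'
#' @param fasta_path FASTA file of candidate sequences.
#' @param min_len,max_len inclusive length bounds in bases.
#' @return data.frame with columns `id`, `seq`, `length`.
#' @export
load_and_filter_references <- function(fasta_path, min_len = 1200, max_len = 1900) {
  stopifnot(min_len <= max_len)
  refs <- read_fasta_refs(fasta_path)
  bad <- grepl(paste0("[^", paste(names(IUPAC_DNA), collapse = ""), "]"), refs$seq)
  if (any(bad))
    stop("non-IUPAC nucleotide characters in record(s): ",
         paste(utils::head(refs$id[bad], 5), collapse = ", "))
  refs[refs$length >= min_len & refs$length <= max_len, , drop = FALSE]
}

#' Resolve IUPAC ambiguity codes to concrete bases
#'
#' Each ambiguous position is replaced by one of the bases its IUPAC code
#' permits, drawn uniformly at random from a single seeded generator
#' consumed in sequence order; unambiguous positions (and the output
#' length) are unchanged.
#'
#' @param sequence IUPAC nucleotide string (U is treated as T).
#' @param seed integer seed; fixed seed gives a deterministic result.
#' @return string over \{A,C,G,T\}.
#' @export
resolve_ambiguities <- function(sequence, seed) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  known <- chars %in% names(IUPAC_DNA)
  if (!all(known))
    stop("invalid nucleotide character '", chars[which(!known)[1]],
         "' at position ", which(!known)[1])
  amb <- which(!(chars %in% c("A", "C", "G", "T")))
  if (length(amb)) {
    with_seed(seed, {
      for (i in amb) {
        allowed <- IUPAC_DNA[[chars[i]]]
        chars[i] <- allowed[sample.int(length(allowed), 1L)]
      }
    })
  }
  paste(chars, collapse = "")
}

#' Pairwise sequence identity from a banded global alignment
#'
#' Global (end-to-end) alignment with lightly penalized terminal gaps:
#' match +1, mismatch -1, internal gap -2 per base, terminal gap -1 per
#' base.  Identity is matched columns divided by aligned columns, where
#' terminal-gap columns (the unaligned overhangs) are excluded from the
#' count.  The dynamic program is restricted to a diagonal band of
#' half-width `band * min(nchar)` plus the length difference, which is
#' ample for the near-identical full-length rRNA comparisons this metric
#' serves; strongly shifted optimal alignments outside the band are not
#' found.
#'
#' @param a,b nonempty nucleotide strings.
#' @param band band half-width as a fraction of the shorter length.
#' @return identity fraction in \[0, 1\]; symmetric in its arguments.
#' @export
pairwise_identity <- function(a, b, band = 0.05) {
  stopifnot(is.character(a), is.character(b), length(a) == 1L, length(b) == 1L)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  cpp_banded_identity(a, b, band)
}

#' Greedy centroid clustering of reference sequences
#'
#' Processes records in input order; a record founds a new centroid unless
#' its [pairwise_identity()] to some existing centroid is at or above the
#' threshold, in which case it is assigned to the first such centroid.
#'
#' @param records data.frame with `id` and `seq` columns.
#' @param identity_threshold clustering identity in (0, 1].
#' @return the centroid subset of `records`, with an attribute
#'   `"assignment"`: a named character vector mapping every input id to
#'   its centroid id.
#' @export
cluster_references <- function(records, identity_threshold = 0.97) {
  stopifnot(nrow(records) > 0, identity_threshold > 0, identity_threshold <= 1)
  centroid_rows <- integer(0)
  assignment <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    hit <- 0L
    for (cr in centroid_rows) {
      if (pairwise_identity(records$seq[i], records$seq[cr]) >= identity_threshold) {
        hit <- cr
        break
      }
    }
    if (hit == 0L) {
      centroid_rows <- c(centroid_rows, i)
      assignment[i] <- records$id[i]
    } else {
      assignment[i] <- records$id[hit]
    }
  }
  out <- records[centroid_rows, , drop = FALSE]
  attr(out, "assignment") <- setNames(assignment, records$id)
  out
}

#' Prepare a candidate reference database
#'
#' Convenience wrapper chaining [load_and_filter_references()],
#' [resolve_ambiguities()] (one seeded stream, consumed in record order)
#' and [cluster_references()].
#'
#' @inheritParams load_and_filter_references
#' @inheritParams cluster_references
#' @param seed integer seed for ambiguity resolution.
#' @param out optional path; when given, the clustered database is written
#'   there as FASTA.
#' @return centroid data.frame as from [cluster_references()].
#' @export
make_reference_db <- function(fasta_path, min_len = 1200, max_len = 1900,
                              identity_threshold = 0.97, seed = 1, out = NULL) {
  refs <- load_and_filter_references(fasta_path, min_len, max_len)
  message(sprintf("length filter [%d, %d]: %d records kept", min_len, max_len, nrow(refs)))
  if (nrow(refs) == 0) stop("no reference sequences pass the length filter")
  refs$seq <- vapply(seq_len(nrow(refs)), function(i)
    resolve_ambiguities(refs$seq[i], seed = stage_seed(seed, paste0("ambig", i))),
    character(1))
  db <- cluster_references(refs, identity_threshold)
  message(sprintf("clustering at %.2f identity: %d centroids", identity_threshold, nrow(db)))
  if (!is.null(out)) write_fasta_refs(db, out)
  db
}
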