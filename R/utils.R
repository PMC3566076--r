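# shared internal helpers: sequence ops, seeded RNG scoping, FASTA/FASTQ io

.datatable.aware <- TRUE

IUPAC_DNA <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Reverse complement
#'
#' @param x character vector of DNA sequences (A/C/G/T, case preserved;
#'   other characters become `N`).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  cpp_revcomp(x)
}

# run `expr` under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# derive a stage-specific 31-bit seed from a master seed so pipeline stages
# can be re-run independently and deterministically
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

phred_to_eps <- function(qchar, cap = 0.25) {
  q <- utf8ToInt(qchar) - 33L
  pmin(10^(-q / 10), cap)
}

eps_to_phred_char <- function(eps) {
  q <- as.integer(round(-10 * log10(pmax(eps, 1e-4))))
  intToUtf8(pmin(q, 41L) + 33L, multiple = FALSE)
}

#' Read a FASTA file into a reference table
#'
#' @param path FASTA file.
#' @return data.frame with columns `id` (first whitespace-delimited token of
#'   the header), `seq` (uppercased sequence) and `length`.
#' @export
read_fasta_refs <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  seqs <- toupper(as.character(x))
  data.frame(id = ids, seq = unname(seqs), length = nchar(seqs),
             stringsAsFactors = FALSE)
}

#' Write a reference table to FASTA
#'
#' @param refs data.frame with `id` and `seq` columns.
#' @param path output path.
#' @param headers optional full header lines (defaults to `refs$id`).
#' @return `path`, invisibly.
#' @export
write_fasta_refs <- function(refs, path, headers = refs$id) {
  x <- Biostrings::BStringSet(setNames(refs$seq, headers))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write a paired-end library to two FASTQ files
#'
#' @param reads data.frame with columns `id`, `seq1`, `qual1`, `seq2`,
#'   `qual2` (qualities Sanger Phred+33).
#' @param prefix output prefix; files are written to `<prefix>_R1.fastq`
#'   and `<prefix>_R2.fastq`.
#' @return character vector of the two paths, invisibly.
#' @export
write_paired_fastq <- function(reads, prefix) {
  paths <- paste0(prefix, c("_R1.fastq", "_R2.fastq"))
  for (m in 1:2) {
    s <- Biostrings::DNAStringSet(reads[[paste0("seq", m)]])
    q <- Biostrings::PhredQuality(reads[[paste0("qual", m)]])
    x <- Biostrings::QualityScaledDNAStringSet(s, q)
    names(x) <- reads$id
    Biostrings::writeQualityScaledXStringSet(x, paths[m])
  }
  invisible(paths)
}

#' Read a paired-end FASTQ library
#'
#' @param r1,r2 paths to the two mate files (Sanger Phred+33).
#' @return data.frame with columns `id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @export
read_paired_fastq <- function(r1, r2) {
  for (p in c(r1, r2)) if (!file.exists(p)) stop("cannot read FASTQ file: ", p)
  a <- Biostrings::readDNAStringSet(r1, format = "fastq", with.qualities = TRUE)
  b <- Biostrings::readDNAStringSet(r2, format = "fastq", with.qualities = TRUE)
  if (length(a) != length(b))
    stop("mate files differ in record count: ", length(a), " vs ", length(b))
  data.frame(id = sub("\\s.*$", "", names(a)),
             seq1 = as.character(a),
             qual1 = as.character(S4Vectors::mcols(a)$qualities),
             seq2 = as.character(b),
             qual2 = as.character(S4Vectors::mcols(b)$qualities),
             row.names = NULL, stringsAsFactors = FALSE)
}
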