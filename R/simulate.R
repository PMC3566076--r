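# synthetic sheared-amplicon paired-end library simulator with fragment
# end bias, plus the closed-form expected-coverage model

#' Simulation configuration for a sheared-amplicon library
#'
#' Defaults describe the library structure this simulator emulates:
#' ~1.5 kb amplicons bounded by the 27F/1492R primer pair, sheared to
#' inserts of mean 275 bp (sd 15), sequenced as 93-bp paired-end reads,
#' with fragment starts roughly 100-fold enriched at the two terminal
#' placements and a uniform 1% per-base substitution error rate with
#' matching Phred qualities.
#'
#' @param community named numeric vector of true relative abundances,
#'   names matching reference ids; must sum to 1 within 1e-9.
#' @param n_pairs number of read pairs to simulate.
#' @param read_len read length in bases.
#' @param insert_mean,insert_sd insert-length distribution (normal,
#'   truncated to `[read_len, amplicon length]`).
#' @param end_bias_weight relative sampling weight (>= 1) of the two
#'   terminal fragment placements versus one interior position.
#' @param error_rate per-base substitution probability.
#' @param fwd_primer,rev_primer amplification primers (reverse primer given
#'   5'->3' on the opposite strand, as conventionally written).
#' @param seed integer seed.
#' @return validated config list of class `emrec_sim_config`.
#' @export
sim_config <- function(community, n_pairs, read_len = 93, insert_mean = 275,
                       insert_sd = 15, end_bias_weight = 100, error_rate = 0.01,
                       fwd_primer = PRIMER_27F, rev_primer = PRIMER_1492R,
                       seed = 1) {
  if (is.null(names(community)) || any(!nzchar(names(community))))
    stop("community abundances must be named by reference id")
  if (abs(sum(community) - 1) > 1e-9)
    stop("community abundances must sum to 1 (got ", sum(community), ")")
  stopifnot(n_pairs > 0, read_len > 0, insert_mean >= read_len,
            insert_sd >= 0, end_bias_weight >= 1,
            error_rate >= 0, error_rate < 1)
  structure(list(community = community, n_pairs = as.integer(n_pairs),
                 read_len = as.integer(read_len), insert_mean = insert_mean,
                 insert_sd = insert_sd, end_bias_weight = end_bias_weight,
                 error_rate = error_rate, fwd_primer = fwd_primer,
                 rev_primer = rev_primer, seed = as.integer(seed)),
            class = "emrec_sim_config")
}

#' Excise the amplicon delimited by a primer pair
#'
#' Finds the forward-primer site as the window of minimal Hamming distance
#' (ties broken leftmost) and the reverse site as the minimal-distance
#' window of the reverse complement of the reverse primer (ties broken
#' rightmost); any number of primer mismatches is allowed.  Returns the
#' subsequence spanning both primer-binding regions inclusive.
#'
#' @param reference a sequence string, or a one-row data.frame with `seq`
#'   (and optionally `id`).
#' @param fwd_primer,rev_primer primer sequences, 5'->3'.
#' @return amplicon sequence string.
#' @export
generate_amplicon <- function(reference, fwd_primer = PRIMER_27F,
                              rev_primer = PRIMER_1492R) {
  id <- "<sequence>"
  if (is.data.frame(reference)) {
    if (!is.null(reference$id)) id <- reference$id[1]
    reference <- reference$seq[1]
  }
  stopifnot(is.character(reference), length(reference) == 1L)
  if (nchar(reference) <= nchar(fwd_primer) + nchar(rev_primer))
    stop("reference ", id, " shorter than the two primers combined")
  df <- cpp_hamming_windows(reference, toupper(fwd_primer))
  fs <- which.min(df)                                  # leftmost tie
  rcrev <- revcomp(toupper(rev_primer))
  dr <- cpp_hamming_windows(reference, rcrev)
  rs <- max(which(dr == min(dr)))                      # rightmost tie
  f_end <- fs + nchar(fwd_primer) - 1L
  r_end <- rs + nchar(rcrev) - 1L
  if (f_end >= rs)
    stop("best forward-primer site is not upstream of the best reverse site in ", id)
  substr(reference, fs, r_end)
}

#' Draw fragment start positions with terminal end bias
#'
#' Starts are drawn from the 0-based positions `0 .. amplicon_len -
#' insert_len`, where the two terminal placements (start 0 and the
#' right-flush start) each carry weight `end_bias_weight` and interior
#' positions weight 1.  Uses the current RNG stream.
#'
#' @param amplicon_len,insert_len lengths in bases (`insert_len <=
#'   amplicon_len`).
#' @param end_bias_weight terminal placement weight (>= 1).
#' @param n number of draws.
#' @return integer vector of 0-based start positions.
#' @export
draw_fragment <- function(amplicon_len, insert_len, end_bias_weight = 100, n = 1) {
  if (insert_len > amplicon_len)
    stop("insert length ", insert_len, " exceeds amplicon length ", amplicon_len)
  npos <- amplicon_len - insert_len + 1L
  if (npos == 1L) return(rep.int(0L, n))
  w <- rep.int(1, npos)
  w[c(1L, npos)] <- end_bias_weight
  sample.int(npos, n, replace = TRUE, prob = w) - 1L
}

#' Simulate a sheared-amplicon paired-end library
#'
#' Amplicons are excised from each reference with the configured primers;
#' read pairs are assigned to references by their true abundances, insert
#' lengths drawn from a truncated normal, fragment starts drawn with
#' terminal end bias, and substitution errors injected per base with
#' Phred qualities consistent with the error rate.  Read 1 is the first
#' `read_len` bases of the fragment; read 2 the reverse complement of its
#' last `read_len` bases.
#'
#' @param config an [sim_config()] object.
#' @param references data.frame with `id` and `seq` columns covering every
#'   community member.
#' @return list with `reads` (data.frame `id`, `seq1`, `qual1`, `seq2`,
#'   `qual2`), `truth` (data.frame `pair_id`, `ref_id`, `start`,
#'   `insert_len`, `n_errors`) and `amplicons` (named character vector).
#' @export
simulate_library <- function(config, references) {
  stopifnot(inherits(config, "emrec_sim_config"))
  ids <- names(config$community)
  missing_ids <- setdiff(ids, references$id)
  if (length(missing_ids))
    stop("community ids absent from references: ", paste(missing_ids, collapse = ", "))
  amplicons <- vapply(ids, function(i)
    generate_amplicon(references[references$id == i, , drop = FALSE],
                      config$fwd_primer, config$rev_primer), character(1))
  alen <- nchar(amplicons)
  rl <- config$read_len
  if (any(alen < rl)) stop("amplicon shorter than read length")
  n <- config$n_pairs

  with_seed(config$seed, {
    ref_idx <- sample.int(length(ids), n, replace = TRUE, prob = config$community)
    insert <- as.integer(round(rnorm(n, config$insert_mean, config$insert_sd)))
    insert <- pmax(rl, pmin(insert, alen[ref_idx]))
    # end-biased start draw, vectorized over pairs
    npos <- alen[ref_idx] - insert + 1L
    w <- config$end_bias_weight
    p_end <- ifelse(npos <= 2L, 1, 2 * w / (2 * w + (npos - 2L)))
    u <- stats::runif(n)
    terminal <- u < p_end
    start <- integer(n)
    right <- stats::runif(n) < 0.5
    start[terminal] <- ifelse(right[terminal], npos[terminal] - 1L, 0L)
    ni <- sum(!terminal)
    if (ni) {
      # uniform over interior positions 1 .. npos - 2
      start[!terminal] <- 1L + floor(stats::runif(ni) * (npos[!terminal] - 2L))
    }
    frag <- substr(amplicons[ref_idx], start + 1L, start + insert)
    seq1 <- substr(frag, 1L, rl)
    seq2 <- revcomp(substr(frag, insert - rl + 1L, insert))

    # uniform per-base substitution errors across both mates
    reads <- c(seq1, seq2)
    n_err <- integer(2L * n)
    if (config$error_rate > 0) {
      flags <- which(stats::runif(2L * n * rl) < config$error_rate)
      if (length(flags)) {
        rix <- (flags - 1L) %/% rl + 1L
        pos <- (flags - 1L) %% rl + 1L
        orig <- substr(reads[rix], pos, pos)
        alt <- matrix(c("C","G","T", "A","G","T", "A","C","T", "A","C","G"),
                      nrow = 3, dimnames = list(NULL, c("A","C","G","T")))
        pick <- alt[cbind(sample.int(3L, length(flags), replace = TRUE),
                          match(orig, colnames(alt)))]
        reads <- cpp_mutate_bases(reads, rix, pos, pick)
        tab <- tabulate(rix, nbins = 2L * n)
        n_err <- tab
      }
    }
    qchar <- if (config$error_rate > 0)
      intToUtf8(min(41L, as.integer(round(-10 * log10(config$error_rate)))) + 33L)
    else "I"  # Q40
    qual <- strrep(qchar, rl)
    pair_id <- sprintf("pair_%06d", seq_len(n))
    list(reads = data.frame(id = pair_id,
                            seq1 = reads[seq_len(n)], qual1 = qual,
                            seq2 = reads[n + seq_len(n)], qual2 = qual,
                            stringsAsFactors = FALSE),
         truth = data.frame(pair_id = pair_id, ref_id = ids[ref_idx],
                            start = start, insert_len = insert,
                            n_errors = n_err[seq_len(n)] + n_err[n + seq_len(n)],
                            stringsAsFactors = FALSE),
         amplicons = amplicons)
  })
}

#' Closed-form expected coverage under the end-biased library model
#'
#' A community member at relative abundance `rel_abundance` in a library of
#' `n_reads_total` read pairs receives `n_reads_total * rel_abundance`
#' pairs, i.e. twice that many reads of `read_len` bases.  The naive depth
#' (total read bases / amplicon length) is discounted by the fraction of
#' fragment-start weight mass falling on interior placements under the
#' end-bias scheme of [draw_fragment()]; per-base depth in interior
#' regions is then modeled as Poisson with that mean.
#'
#' @param n_reads_total library size in read pairs.
#' @param read_len read length in bases.
#' @param rel_abundance relative abundance fraction.
#' @param amplicon_len,insert_len amplicon and insert lengths in bases.
#' @param end_bias_weight terminal placement weight.
#' @param depth_threshold fold-coverage threshold for the Poisson tail.
#' @return list with `interior_mean_depth` (fold) and
#'   `fraction_at_or_above_threshold` (P(depth >= threshold)).
#' @export
expected_coverage <- function(n_reads_total, read_len, rel_abundance,
                              amplicon_len, insert_len, end_bias_weight = 100,
                              depth_threshold = 5) {
  stopifnot(n_reads_total > 0, read_len > 0, rel_abundance > 0,
            rel_abundance <= 1, amplicon_len > 0, insert_len > 0,
            insert_len <= amplicon_len, end_bias_weight >= 1,
            depth_threshold > 0)
  pairs <- n_reads_total * rel_abundance
  total_bases <- pairs * 2 * read_len
  naive_depth <- total_bases / amplicon_len
  npos <- amplicon_len - insert_len + 1
  interior_frac <- if (npos <= 2) 0 else
    (npos - 2) / (2 * end_bias_weight + (npos - 2))
  mu <- naive_depth * interior_frac
  list(interior_mean_depth = mu,
       fraction_at_or_above_threshold = ppois(depth_threshold - 1, mu,
                                              lower.tail = FALSE))
}

#' Generate synthetic primer-bounded 16S-like reference sequences
#'
#' Each reference begins with the forward primer site and ends with the
#' reverse complement of the reverse primer, bracketing an i.i.d. random
#' core, so the full sequence is its own amplicon.  Random cores make the
#' species mutually distant (~25% identity), a deliberately simple stand-in
#' for real rRNA phylogenetic structure.
#'
#' @param n number of references.
#' @param core_len core length in bases (default gives 1464-bp amplicons
#'   with the standard primers).
#' @param seed integer seed.
#' @param fwd_primer,rev_primer flanking primers.
#' @return data.frame with `id`, `seq`, `length`.
#' @export
make_synthetic_references <- function(n, core_len = 1425, seed = 1,
                                      fwd_primer = PRIMER_27F,
                                      rev_primer = PRIMER_1492R) {
  with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i)
      paste0(fwd_primer,
             paste(sample(c("A", "C", "G", "T"), core_len, replace = TRUE),
                   collapse = ""),
             revcomp(rev_primer)), character(1))
    data.frame(id = sprintf("ref_%03d", seq_len(n)), seq = seqs,
               length = nchar(seqs), stringsAsFactors = FALSE)
  })
}

#' Introduce random substitutions into a sequence
#'
#' Substitutes a fixed number (or fraction) of positions with a different
#' base, chosen uniformly; useful for building divergent database seeds
#' and planted cluster structure.
#'
#' @param sequence nucleotide string.
#' @param n_subs number of substituted positions; or give `rate`.
#' @param rate fraction of positions to substitute (ignored when `n_subs`
#'   is supplied).
#' @param seed integer seed.
#' @return mutated sequence string.
#' @export
mutate_sequence <- function(sequence, n_subs = NULL, rate = NULL, seed = 1) {
  L <- nchar(sequence)
  if (is.null(n_subs)) {
    stopifnot(!is.null(rate))
    n_subs <- round(rate * L)
  }
  stopifnot(n_subs >= 0, n_subs <= L)
  if (n_subs == 0) return(sequence)
  with_seed(seed, {
    pos <- sort(sample.int(L, n_subs))
    chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
    for (p in pos) {
      chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
    }
    paste(chars, collapse = "")
  })
}

#' Log-spaced community abundance vector
#'
#' Abundances log-spaced between `lo` and `hi` across the given ids,
#' normalized to sum to 1 (most-abundant first id).
#'
#' @param ids reference ids.
#' @param lo,hi unnormalized abundance range.
#' @return named numeric vector summing to 1.
#' @export
log_spaced_community <- function(ids, lo = 0.001, hi = 0.3) {
  n <- length(ids)
  raw <- exp(seq(log(hi), log(lo), length.out = n))
  setNames(raw / sum(raw), ids)
}

#' Write the truth table of a simulated library to TSV
#'
#' @param truth truth data.frame from [simulate_library()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
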