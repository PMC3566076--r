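# read trimming, subsampling, insert-size estimation and quality-aware
# ungapped paired-end mapping (seed-and-extend over a k-mer index)

# trimmed length of one quality string under the centred 10-base window
# rule: the read is cut just before the first position whose window
# (positions i-4 .. i+5, truncated at the read ends) has mean quality
# below the threshold
trim_length <- function(qual, q_threshold) {
  q <- utf8ToInt(qual) - 33L
  L <- length(q)
  cs <- c(0, cumsum(q))
  i <- seq_len(L)
  lo <- pmax(1L, i - 4L)
  hi <- pmin(L, i + 5L)
  wmean <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  bad <- which(wmean < q_threshold)
  if (length(bad) == 0) L else bad[1] - 1L
}

#' Quality-trim paired-end reads
#'
#' Trims 3' bases from each mate starting at the first position whose
#' centred 10-base window mean quality falls below `q_threshold`; a pair
#' is rejected when either mate is left shorter than `min_len`.
#'
#' @param pairs data.frame with `id`, `seq1`, `qual1`, `seq2`, `qual2`
#'   (Sanger Phred+33).
#' @param q_threshold Phred threshold for the window mean.
#' @param min_len minimum post-trim mate length.
#' @return list with `pairs` (trimmed, passing pairs) and `n_rejected`.
#' @export
quality_trim <- function(pairs, q_threshold = 20, min_len = 60) {
  stopifnot(all(nchar(pairs$seq1) == nchar(pairs$qual1)),
            all(nchar(pairs$seq2) == nchar(pairs$qual2)))
  keep_len <- function(quals) {
    uq <- unique(quals)
    lens <- vapply(uq, trim_length, integer(1), q_threshold = q_threshold)
    lens[match(quals, uq)]
  }
  l1 <- keep_len(pairs$qual1)
  l2 <- keep_len(pairs$qual2)
  ok <- l1 >= min_len & l2 >= min_len
  out <- pairs[ok, , drop = FALSE]
  out$seq1 <- substr(out$seq1, 1L, l1[ok])
  out$qual1 <- substr(out$qual1, 1L, l1[ok])
  out$seq2 <- substr(out$seq2, 1L, l2[ok])
  out$qual2 <- substr(out$qual2, 1L, l2[ok])
  rownames(out) <- NULL
  list(pairs = out, n_rejected = sum(!ok))
}

#' Subsample read pairs without replacement
#'
#' @param pairs data.frame of read pairs.
#' @param n number of pairs to draw.
#' @param seed integer seed.
#' @return data.frame of `n` distinct pairs (input order of the kept rows
#'   is randomized by the draw).
#' @export
subsample_reads <- function(pairs, n, seed) {
  if (n > nrow(pairs))
    stop("requested ", n, " pairs but only ", nrow(pairs), " available")
  idx <- with_seed(seed, sample.int(nrow(pairs), n))
  out <- pairs[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map read pairs to candidate sequences
#'
#' Gapless seed-and-extend mapping: 15-base exact seeds at three offsets
#' per mate locate candidate placements, which are verified end-to-end.
#' A placement is reported when both mates align in consistent orientation
#' with per-mate mismatches at most `max_mm_rate` times the mate length
#' and the implied insert lies within `insert_range`; per candidate only
#' the best-likelihood placement is kept (ties broken leftmost).  The
#' log-likelihood sums `log(1 - eps_b)` over matching bases and
#' `log(eps_b / 3)` over mismatches, with `eps_b` the Phred-implied error
#' probability capped at `eps_cap`.
#'
#' @param pairs data.frame of read pairs (`id`, `seq1`, `qual1`, `seq2`,
#'   `qual2`).
#' @param candidates data.frame with `id` and `seq`, or a named character
#'   vector of sequences.
#' @param max_mm_rate maximum per-mate mismatch fraction.
#' @param insert_range length-2 numeric, accepted insert interval in bases
#'   (typically mean +/- 3 sd from [estimate_insert_size()]).
#' @param seed_len exact-seed length.
#' @param eps_cap ceiling on the per-base error probability, so that no
#'   base is uninformative-negative.
#' @return data.frame of hits: `pair_id`, `candidate_id`, `start_fwd`,
#'   `start_rc` (0-based starts of the forward-mapping and
#'   reverse-complemented mate), `rc_mate` (which mate is reverse
#'   complemented; 2 = pair in forward orientation), `mismatches`,
#'   `insert`, `loglik`.
#' @export
map_reads <- function(pairs, candidates, max_mm_rate = 0.06,
                      insert_range = c(93, 500), seed_len = 15, eps_cap = 0.25) {
  if (is.data.frame(candidates)) {
    cand_ids <- candidates$id
    cand_seqs <- candidates$seq
  } else {
    cand_ids <- names(candidates)
    cand_seqs <- unname(candidates)
  }
  stopifnot(length(cand_seqs) > 0, length(insert_range) == 2)
  hits <- cpp_map_reads(cand_seqs, pairs$seq1, pairs$seq2,
                        pairs$qual1, pairs$qual2, max_mm_rate,
                        as.integer(insert_range[1]), as.integer(insert_range[2]),
                        as.integer(seed_len), eps_cap)
  data.frame(pair_id = pairs$id[hits$pair], candidate_id = cand_ids[hits$cand],
             pair = hits$pair, cand = hits$cand,
             start_fwd = hits$start_fwd, start_rc = hits$start_rc,
             rc_mate = hits$rc_mate, mismatches = hits$mismatches,
             insert = hits$insert, loglik = hits$loglik,
             stringsAsFactors = FALSE)
}

#' Map a single read pair, with mismatch coordinates
#'
#' Convenience wrapper around [map_reads()] for one pair; adds a
#' `mismatch_positions` list column of 0-based candidate coordinates.
#'
#' @param pair one-row data.frame (`id`, `seq1`, `qual1`, `seq2`, `qual2`).
#' @inheritParams map_reads
#' @return hit data.frame as from [map_reads()] plus `mismatch_positions`.
#' @export
map_read_pair <- function(pair, candidates, max_mm_rate = 0.06,
                          insert_range = c(93, 500), seed_len = 15,
                          eps_cap = 0.25) {
  hits <- map_reads(pair[1, , drop = FALSE], candidates, max_mm_rate,
                    insert_range, seed_len, eps_cap)
  if (is.data.frame(candidates)) cand_seqs <- setNames(candidates$seq, candidates$id)
  else cand_seqs <- candidates
  hits$mismatch_positions <- lapply(seq_len(nrow(hits)), function(h) {
    cs <- cand_seqs[[hits$candidate_id[h]]]
    fwd <- if (hits$rc_mate[h] == 2) pair$seq1[1] else pair$seq2[1]
    rcm <- revcomp(if (hits$rc_mate[h] == 2) pair$seq2[1] else pair$seq1[1])
    mmpos <- function(read, s) {
      win <- substr(cs, s + 1L, s + nchar(read))
      a <- strsplit(read, "")[[1]]; b <- strsplit(win, "")[[1]]
      s + which(a != b) - 1L
    }
    sort(c(mmpos(fwd, hits$start_fwd[h]), mmpos(rcm, hits$start_rc[h])))
  })
  hits
}

#' Estimate the insert-size distribution by an initial mapping
#'
#' Maps pairs to the reference database with a permissive insert window
#' and returns the mean and standard deviation of implied insert lengths
#' over pairs with a unique best placement.
#'
#' @param pairs data.frame of read pairs.
#' @param references candidate database (data.frame `id`, `seq`).
#' @param max_mm_rate per-mate mismatch ceiling for the initial mapping.
#' @param min_pairs minimum number of unique-best concordant pairs
#'   required.
#' @return list with `mean` and `sd` in bases, and `n` pairs used.
#' @export
estimate_insert_size <- function(pairs, references, max_mm_rate = 0.06,
                                 min_pairs = 100) {
  max_ins <- max(nchar(references$seq))
  hits <- map_reads(pairs, references, max_mm_rate,
                    insert_range = c(1, max_ins))
  if (nrow(hits) == 0)
    stop("no concordant pairs; check the reference database or specify the insert size manually")
  best <- do.call(rbind, lapply(split(hits, hits$pair), function(h) {
    top <- h[h$loglik >= max(h$loglik) - 1e-9, , drop = FALSE]
    if (nrow(top) == 1L) top else NULL
  }))
  if (is.null(best) || nrow(best) < min_pairs)
    stop("only ", if (is.null(best)) 0 else nrow(best),
         " unique-best concordant pairs (need ", min_pairs,
         "); specify the insert size manually")
  list(mean = mean(best$insert), sd = sd(best$insert), n = nrow(best))
}
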