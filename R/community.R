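# downstream community-table procedures: abundance-ordered OTU picking,
# adjusted expected-count tables, replicate-specificity screen, V3
# excision, rarefaction with clipping, end-bias diagnostics

#' Pick OTUs by greedy abundance-ordered clustering
#'
#' Sequences pooled across samples are processed in decreasing abundance
#' order (ties broken by lexicographic sequence id); each sequence joins
#' the first existing OTU whose representative (centroid) it matches at
#' `identity` or better, otherwise it founds a new OTU with itself as
#' representative.
#'
#' @param sequences data.frame with `id`, `seq`, `abundance`.
#' @param identity clustering identity threshold.
#' @return list with `assignment` (named character vector: sequence id ->
#'   OTU id) and `representatives` (data.frame `otu_id`, `id`, `seq`).
#' @export
pick_otus <- function(sequences, identity = 0.97) {
  stopifnot(nrow(sequences) > 0, !is.null(sequences$abundance))
  ord <- order(-sequences$abundance, sequences$id)
  s <- sequences[ord, , drop = FALSE]
  rep_seq <- character(0)
  rep_id <- character(0)
  assignment <- character(nrow(s))
  for (i in seq_len(nrow(s))) {
    hit <- 0L
    for (k in seq_along(rep_seq)) {
      if (pairwise_identity(s$seq[i], rep_seq[k]) >= identity) { hit <- k; break }
    }
    if (hit == 0L) {
      rep_seq <- c(rep_seq, s$seq[i])
      rep_id <- c(rep_id, s$id[i])
      hit <- length(rep_seq)
    }
    assignment[i] <- sprintf("OTU_%d", hit)
  }
  list(assignment = setNames(assignment, s$id),
       representatives = data.frame(otu_id = sprintf("OTU_%d", seq_along(rep_id)),
                                    id = rep_id, seq = rep_seq,
                                    stringsAsFactors = FALSE))
}

#' Build the adjusted OTU table of expected read counts
#'
#' `entry(o, s) = mapped_total(s) * sum of the estimated abundances of the
#' sample-s sequences assigned to OTU o`, i.e. the expected number of
#' reads per OTU per sample given the per-sample mapped totals and the
#' EM-estimated relative abundances.
#'
#' @param per_sample_results named list (one element per sample) of
#'   data.frames with `id`, `abundance` and `otu` (OTU id per sequence).
#' @param mapped_totals named numeric vector of mapped-pair totals per
#'   sample.
#' @return numeric matrix, OTUs x samples.
#' @export
build_adjusted_table <- function(per_sample_results, mapped_totals) {
  stopifnot(all(names(per_sample_results) %in% names(mapped_totals)))
  otus <- sort(unique(unlist(lapply(per_sample_results, `[[`, "otu"))))
  samples <- names(per_sample_results)
  tab <- matrix(0, nrow = length(otus), ncol = length(samples),
                dimnames = list(otus, samples))
  for (s in samples) {
    res <- per_sample_results[[s]]
    if (any(is.na(res$otu)))
      stop("sequence(s) without an OTU assignment in sample ", s)
    agg <- tapply(res$abundance, res$otu, sum)
    tab[names(agg), s] <- as.numeric(agg) * mapped_totals[[s]]
  }
  tab
}

#' High-specificity OTU screen across technical replicates
#'
#' An OTU is high-specificity when it is present in at least `min_present`
#' of the `group_size` replicate subsamples of at least one biological
#' sample.
#'
#' @param presence logical (or 0/1) matrix, OTUs x subsamples.
#' @param groups named list mapping each biological sample to its
#'   subsample column names.
#' @param min_present minimum replicate count.
#' @param group_size required replicates per group.
#' @return character vector of high-specificity OTU ids.
#' @export
high_specificity_otus <- function(presence, groups, min_present = 12,
                                  group_size = 16) {
  sizes <- lengths(groups)
  if (any(sizes != group_size))
    stop("group size mismatch: expected ", group_size, ", got ",
         paste(sizes[sizes != group_size], collapse = ", "))
  hit <- Reduce(`|`, lapply(groups, function(cols)
    rowSums(presence[, cols, drop = FALSE] > 0) >= min_present))
  rownames(presence)[hit]
}

#' Excise the V3 hypervariable region in silico
#'
#' The forward-primer site is the minimal-Hamming window (ties leftmost);
#' the reverse site is the minimal-Hamming window of the reverse
#' complement of the reverse primer, searched strictly downstream of the
#' forward site (ties leftmost).  Any number of primer mismatches is
#' allowed.  The excised region spans both primer sites inclusive and is
#' rejected when its length falls outside `[min_len, max_len]`.
#'
#' @param sequence sequence string.
#' @param fwd,rev V3 primer sequences.
#' @param min_len,max_len accepted region lengths in bases.
#' @return list with `region` (string or `NA`), `start` (0-based),
#'   `length`, and `rejected` (logical with a `reason` attribute when
#'   `TRUE`).
#' @export
extract_v3 <- function(sequence, fwd = PRIMER_341F, rev = PRIMER_518R,
                       min_len = 100, max_len = 225) {
  reject <- function(reason) list(region = NA_character_, start = NA_integer_,
                                  length = NA_integer_,
                                  rejected = structure(TRUE, reason = reason))
  if (nchar(sequence) <= nchar(fwd) + nchar(rev))
    return(reject("sequence shorter than the two primers"))
  df <- cpp_hamming_windows(sequence, toupper(fwd))
  fs <- which.min(df)
  rcrev <- revcomp(toupper(rev))
  dr <- cpp_hamming_windows(sequence, rcrev)
  valid <- seq_along(dr) > fs + nchar(fwd) - 1L
  if (!any(valid)) return(reject("no window downstream of the forward site"))
  drv <- ifelse(valid, dr, Inf)
  rs <- which.min(drv)
  region_len <- rs + nchar(rcrev) - fs
  if (region_len < min_len || region_len > max_len)
    return(reject(sprintf("region length %d outside [%d, %d]",
                          region_len, min_len, max_len)))
  list(region = substr(sequence, fs, rs + nchar(rcrev) - 1L),
       start = fs - 1L, length = region_len, rejected = FALSE)
}

# largest-remainder rounding of a non-negative vector to integers summing
# to round(sum(x))
largest_remainder_round <- function(x) {
  target <- round(sum(x))
  fl <- floor(x)
  rem <- as.integer(target - sum(fl))
  if (rem > 0) {
    extra <- order(x - fl, decreasing = TRUE)[seq_len(rem)]
    fl[extra] <- fl[extra] + 1
  }
  as.integer(fl)
}

#' Rarefy an expected-count OTU table with count clipping
#'
#' Expected (fractional) counts are first rounded to integers per sample
#' by largest-remainder rounding (which preserves column totals); each
#' replicate then draws `depth` reads per sample uniformly without
#' replacement (multivariate hypergeometric, the standard rarefaction
#' draw, so a full-depth draw returns the sample unchanged), and every
#' resulting count at or below `clip` is set to 0.
#'
#' @param table OTU x sample matrix of expected counts.
#' @param depth reads to draw per sample.
#' @param clip counts `<= clip` are zeroed after sampling.
#' @param replicates number of rarefaction replicates.
#' @param seed integer seed.
#' @return list of `replicates` integer matrices with the dimensions of
#'   `table`.
#' @export
rarefy_with_clipping <- function(table, depth, clip = 20, replicates = 10,
                                 seed = 1) {
  stopifnot(all(table >= 0))
  counts <- apply(table, 2, largest_remainder_round)
  dimnames(counts) <- dimnames(table)
  short <- colSums(counts) < depth
  if (any(short))
    stop("depth ", depth, " exceeds the total of sample(s): ",
         paste(colnames(table)[short], collapse = ", "))
  with_seed(seed, {
    lapply(seq_len(replicates), function(r) {
      out <- vapply(seq_len(ncol(counts)), function(s) {
        pool <- rep.int(seq_len(nrow(counts)), counts[, s])
        tabulate(pool[sample.int(length(pool), depth)], nbins = nrow(counts))
      }, integer(nrow(counts)))
      dimnames(out) <- dimnames(counts)
      out[out <= clip] <- 0L
      out
    })
  })
}

#' Fragment end-bias diagnostics
#'
#' For each mapped pair the fragment's distance to the nearest amplicon
#' end, `min(start, L - end)`, is recorded; the histogram is reported as
#' a fraction of fragments per distance.  The per-position enrichment
#' factor divides the rate at distance 0 (fragments at distance 0 over
#' positions that could yield distance 0) by the mean interior rate,
#' accounting for the two-fold degeneracy of interior distances.  A
#' binned per-position relative read-coverage curve is also returned.
#'
#' @param hits hit data.frame from [map_reads()] (uses `candidate_id`,
#'   `start_fwd`, `start_rc`, `rc_mate`, `insert`).
#' @param sequences named character vector (or data.frame `id`, `seq`) of
#'   the reconstructed sequences the hits refer to.
#' @param read_len read length used for the coverage curve.
#' @param n_bins bins for the relative coverage curve.
#' @return list with `histogram` (data.frame `distance`, `fraction`),
#'   `enrichment_factor`, and `coverage` (data.frame `rel_pos`,
#'   `rel_coverage`, normalized to mean 1).
#' @export
end_bias_profile <- function(hits, sequences, read_len = NULL, n_bins = 100) {
  if (is.data.frame(sequences)) sequences <- setNames(sequences$seq, sequences$id)
  L <- nchar(sequences)[hits$candidate_id]
  start <- hits$start_fwd
  end <- hits$start_fwd + hits$insert          # 0-based half-open fragment
  d <- pmin(start, L - end)
  # positions available at each distance, per fragment: 2 except at the
  # exact midpoint of an odd position count
  dmax_frag <- floor((L - hits$insert) / 2)
  maxd <- max(d)
  count <- tabulate(d + 1L, nbins = maxd + 1L)
  den <- vapply(0:maxd, function(k) {
    avail <- dmax_frag >= k
    mid <- (L - hits$insert) == 2L * k
    sum(2L * avail - (avail & mid))
  }, numeric(1))
  frac <- count / sum(count)
  rate <- ifelse(den > 0, count / den, NA_real_)
  interior <- sum(count[-1]) / sum(den[-1])
  enrichment <- rate[1] / interior

  if (is.null(read_len)) read_len <- 93L
  cov_bins <- numeric(n_bins)
  for (nm in unique(hits$candidate_id)) {
    h <- hits[hits$candidate_id == nm, , drop = FALSE]
    len <- nchar(sequences[[nm]])
    cov <- numeric(len)
    add <- function(s, l) {
      s1 <- max(1L, s + 1L); s2 <- min(len, s + l)
      if (s2 >= s1) cov[s1:s2] <<- cov[s1:s2] + 1
    }
    for (i in seq_len(nrow(h))) {
      add(h$start_fwd[i], read_len)
      add(h$start_rc[i], read_len)
    }
    bins <- pmin(n_bins, 1L + floor((seq_len(len) - 1) / len * n_bins))
    cov_bins <- cov_bins + vapply(seq_len(n_bins), function(b)
      mean(cov[bins == b]), numeric(1))
  }
  cov_rel <- cov_bins / mean(cov_bins)
  list(histogram = data.frame(distance = 0:maxd, fraction = frac),
       enrichment_factor = enrichment,
       coverage = data.frame(rel_pos = (seq_len(n_bins) - 0.5) / n_bins,
                             rel_coverage = cov_rel))
}
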