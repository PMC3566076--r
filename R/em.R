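# iterative expectation-maximization reconstruction of consensus sequences
# and relative abundances from probabilistic paired-read attribution

#' E-step: probabilistic read attribution
#'
#' Computes, for every mapped pair, the posterior probability of each
#' candidate placement: `post(j | i) = pi_j P(r_i | s_j) / sum_k pi_k
#' P(r_i | s_k)`, evaluated stably in log space.
#'
#' @param hits hit data.frame from [map_reads()] (`pair_id`,
#'   `candidate_id`, `loglik`, ...).
#' @param priors named abundance vector over candidates, summing to 1.
#' @return `hits` with an added `post` column; per-pair posteriors sum
#'   to 1.
#' @export
e_step <- function(hits, priors) {
  if (nrow(hits) == 0) return(cbind(hits, post = numeric(0)))
  lp <- log(priors[hits$candidate_id]) + hits$loglik
  dt <- data.table::data.table(pair_id = hits$pair_id, lp = lp)
  dt[, m := max(lp), by = pair_id]
  dt[, w := exp(lp - m)]
  dt[, post := w / sum(w), by = pair_id]
  if (any(!is.finite(dt$post)))
    stop("internal error: non-finite posterior in E-step")
  hits$post <- dt$post
  hits
}

#' M-step: abundance update
#'
#' `pi'_j = sum_i post(j | i) / n_mapped`; the returned vector sums to 1
#' over the candidates appearing in `posteriors`.
#'
#' @param posteriors hits with a `post` column, as from [e_step()].
#' @param n_mapped number of mapped pairs (defaults to the number of
#'   distinct pairs in `posteriors`).
#' @return named abundance vector.
#' @export
m_step_abundance <- function(posteriors, n_mapped = length(unique(posteriors$pair_id))) {
  if (n_mapped == 0) stop("no mapped pairs; cannot update abundances")
  s <- tapply(posteriors$post, posteriors$candidate_id, sum)
  setNames(as.numeric(s) / n_mapped, names(s))
}

# posterior-weighted 4 x L base-count matrix for one candidate
candidate_base_weights <- function(posteriors, pairs, candidate_id, cand_len,
                                   eps_cap = 0.25) {
  h <- posteriors[posteriors$candidate_id == candidate_id, , drop = FALSE]
  cpp_base_weights(cand_len, pairs$seq1, pairs$seq2, pairs$qual1, pairs$qual2,
                   h$pair, h$start_fwd, h$start_rc, h$rc_mate, h$post, eps_cap)
}

# consensus call from a 4 x L weight matrix: per-column argmax, ties
# preferring the current base then lexicographic; zero-coverage columns
# keep the current base
consensus_from_weights <- function(W, current) {
  bases <- c("A", "C", "G", "T")
  L <- ncol(W)
  cur <- match(strsplit(current, "", fixed = TRUE)[[1]], bases)
  W2 <- W
  covered <- colSums(W) > 0
  ok <- !is.na(cur)
  W2[cbind(cur[ok], which(ok))] <- W2[cbind(cur[ok], which(ok))] + 1e-7
  idx <- max.col(t(W2), ties.method = "first")
  out <- bases[idx]
  out[!covered & ok] <- bases[cur[!covered & ok]]
  paste(out, collapse = "")
}

#' M-step: consensus update for one candidate
#'
#' Accumulates posterior-weighted base evidence, `w = post(j|i) * (1 -
#' eps_base)`, over all reads covering each position, and calls the
#' per-position argmax base (ties prefer the current consensus base, then
#' alphabetical order); positions without coverage retain the current
#' base.
#'
#' @param posteriors hits with `post`, restricted or not (rows for other
#'   candidates are ignored).
#' @param pairs the read-pair data.frame the hits refer to.
#' @param candidate list with `id`, `consensus` (and optionally
#'   `prior_abundance`).
#' @param eps_cap per-base error probability ceiling.
#' @return the candidate with updated `consensus` and a `base_weights`
#'   4 x L matrix (rows A, C, G, T).
#' @export
m_step_consensus <- function(posteriors, pairs, candidate, eps_cap = 0.25) {
  L <- nchar(candidate$consensus)
  W <- candidate_base_weights(posteriors, pairs, candidate$id, L, eps_cap)
  rownames(W) <- c("A", "C", "G", "T")
  candidate$base_weights <- W
  candidate$consensus <- consensus_from_weights(W, candidate$consensus)
  candidate
}

# best ungapped offset of consensus b against consensus a (b placed at
# a-coordinate `offset`), maximizing matched bases; ties -> smallest |offset|
best_offset <- function(a, b, max_shift = NULL) {
  la <- nchar(a); lb <- nchar(b)
  if (is.null(max_shift)) max_shift <- abs(la - lb) + 10L
  offs <- seq.int(-max_shift, max_shift)
  offs <- offs[order(abs(offs), offs)]
  best <- 0L; best_m <- -1L
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  for (off in offs) {
    s_a <- max(1L, 1L + off); e_a <- min(la, lb + off)
    if (e_a < s_a) next
    m <- sum(av[s_a:e_a] == bv[(s_a - off):(e_a - off)])
    if (m > best_m) { best_m <- m; best <- off }
  }
  best
}

#' Merge near-identical candidate models
#'
#' Any two candidates whose consensus sequences share at least
#' `join_threshold` [pairwise_identity()] are merged, transitively within
#' one call (union-find over the identity graph).  The survivor of each
#' group is the member with the highest prior abundance (ties broken by
#' lexicographic id); it inherits the summed abundance, and base-weight
#' matrices are summed positionwise after an ungapped offset alignment of
#' the consensuses, with the consensus re-called from the pooled weights.
#'
#' @param candidates list of candidate models (`id`, `consensus`,
#'   `prior_abundance`, optional `base_weights`).
#' @param join_threshold merge identity threshold.
#' @return list of surviving candidate models, with an attribute
#'   `"merged_into"`: named character vector mapping absorbed ids to
#'   survivor ids.
#' @export
merge_candidates <- function(candidates, join_threshold = 0.97) {
  n <- length(candidates)
  if (n <= 1) {
    attr(candidates, "merged_into") <- character(0)
    return(candidates)
  }
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    if (find(i) == find(j)) next
    if (pairwise_identity(candidates[[i]]$consensus,
                          candidates[[j]]$consensus) >= join_threshold)
      parent[find(j)] <- find(i)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  out <- list()
  merged_into <- character(0)
  for (r in unique(roots)) {
    grp <- which(roots == r)
    ab <- vapply(grp, function(i) candidates[[i]]$prior_abundance, numeric(1))
    ids <- vapply(grp, function(i) candidates[[i]]$id, character(1))
    surv <- grp[order(-ab, ids)][1]
    model <- candidates[[surv]]
    if (length(grp) > 1) {
      model$prior_abundance <- sum(ab)
      for (i in setdiff(grp, surv)) {
        other <- candidates[[i]]
        merged_into[other$id] <- model$id
        if (!is.null(model$base_weights) && !is.null(other$base_weights)) {
          off <- best_offset(model$consensus, other$consensus)
          cols_o <- seq_len(ncol(other$base_weights))
          cols_s <- cols_o + off
          ok <- cols_s >= 1 & cols_s <= ncol(model$base_weights)
          model$base_weights[, cols_s[ok]] <-
            model$base_weights[, cols_s[ok]] + other$base_weights[, cols_o[ok]]
        }
      }
      if (!is.null(model$base_weights))
        model$consensus <- consensus_from_weights(model$base_weights, model$consensus)
    }
    out[[length(out) + 1]] <- model
  }
  attr(out, "merged_into") <- merged_into
  out
}

#' Run the full EM reconstruction
#'
#' Initializes priors uniformly over database candidates that attract at
#' least one mapped pair, then iterates: probabilistic read attribution
#' ([e_step()]), abundance update ([m_step_abundance()]), consensus update
#' ([m_step_consensus()]), merging of near-identical candidates
#' ([merge_candidates()]), and pruning of candidates whose expected read
#' count falls below `prune_expected_reads`.  Reads are re-mapped against
#' every candidate whose consensus changed (mapping results for unchanged
#' consensuses are cached, which is exact because the mapper is
#' deterministic).  After the final iteration, candidates at or above
#' `min_abundance` are returned in decreasing abundance order; abundances
#' are fractions of mapped pairs and are not renormalized after
#' filtering.
#'
#' @param pairs trimmed read pairs (`id`, `seq1`, `qual1`, `seq2`,
#'   `qual2`).
#' @param reference_db candidate database data.frame (`id`, `seq`; strict
#'   A/C/G/T).
#' @param n_iterations number of EM iterations.
#' @param join_threshold merge identity threshold.
#' @param min_abundance final reporting threshold (fraction of mapped
#'   pairs).
#' @param max_mm_rate per-mate mismatch ceiling for mapping.
#' @param insert_mean,insert_sd insert-size model; when `NULL`, estimated
#'   by [estimate_insert_size()] on up to 2000 pairs.  The accepted insert
#'   window is mean +/- 3 sd.
#' @param prune_expected_reads candidates expected to attract fewer reads
#'   than this are dropped each iteration.
#' @param eps_cap per-base error probability ceiling.
#' @param verbose print per-iteration progress.
#' @return list of class `emrec_result`: `results` (data.frame `id`,
#'   `sequence`, `abundance`, `expected_reads`, sorted by decreasing
#'   abundance), `mapped_fraction`, `n_mapped`, `n_pairs`, and `log`
#'   (per-iteration data.frame: candidate count, mapped fraction, total
#'   data log-likelihood, and whether consensus changes, merges or prunes
#'   occurred).
#' @export
run_emirge <- function(pairs, reference_db, n_iterations = 120,
                       join_threshold = 0.97, min_abundance = 1e-4,
                       max_mm_rate = 0.06, insert_mean = NULL, insert_sd = NULL,
                       prune_expected_reads = 0.05, eps_cap = 0.25,
                       verbose = FALSE) {
  stopifnot(nrow(pairs) > 0, nrow(reference_db) > 0, n_iterations >= 1)
  if (is.null(insert_mean)) {
    est <- estimate_insert_size(pairs[seq_len(min(2000L, nrow(pairs))), ],
                                reference_db, max_mm_rate)
    insert_mean <- est$mean
    insert_sd <- if (is.na(est$sd)) 0 else est$sd
  }
  if (is.null(insert_sd)) insert_sd <- 0
  insert_range <- c(max(1, floor(insert_mean - 3 * insert_sd - 1)),
                    ceiling(insert_mean + 3 * insert_sd + 1))

  models <- lapply(seq_len(nrow(reference_db)), function(i)
    list(id = reference_db$id[i], consensus = reference_db$seq[i],
         prior_abundance = NA_real_, base_weights = NULL))
  names(models) <- reference_db$id

  hits <- map_reads(pairs, reference_db, max_mm_rate, insert_range,
                    eps_cap = eps_cap)
  if (nrow(hits) == 0)
    stop("no read pair maps to any database candidate; check the reference database")
  active <- intersect(names(models), unique(hits$candidate_id))
  models <- models[active]
  hits <- hits[hits$candidate_id %in% active, , drop = FALSE]
  priors <- setNames(rep(1 / length(models), length(models)), names(models))

  remap_candidates <- function(hits, ids) {
    if (length(ids) == 0) return(hits)
    sub <- data.frame(id = ids,
                      seq = vapply(models[ids], `[[`, character(1), "consensus"),
                      stringsAsFactors = FALSE)
    nh <- map_reads(pairs, sub, max_mm_rate, insert_range, eps_cap = eps_cap)
    rbind(hits[!(hits$candidate_id %in% ids), , drop = FALSE], nh)
  }

  log_rows <- vector("list", n_iterations)
  for (iter in seq_len(n_iterations)) {
    post <- e_step(hits, priors)
    n_mapped <- length(unique(post$pair_id))
    pi_new <- m_step_abundance(post, n_mapped)
    pi_full <- setNames(rep(0, length(models)), names(models))
    pi_full[names(pi_new)] <- pi_new

    changed <- character(0)
    for (id in names(models)) {
      models[[id]]$prior_abundance <- pi_full[[id]]
      old <- models[[id]]$consensus
      models[[id]] <- m_step_consensus(post, pairs, models[[id]], eps_cap)
      if (!identical(models[[id]]$consensus, old)) changed <- c(changed, id)
    }

    # merging is deterministic in the consensus set, so it can only find new
    # pairs when some consensus changed this iteration
    if (iter == 1 || length(changed) > 0) {
      merged <- merge_candidates(models, join_threshold)
      merged_into <- attr(merged, "merged_into")
      models <- setNames(merged, vapply(merged, `[[`, character(1), "id"))
    } else {
      merged_into <- character(0)
    }
    if (length(merged_into)) {
      hits <- hits[!(hits$candidate_id %in% names(merged_into)), , drop = FALSE]
      changed <- union(setdiff(changed, names(merged_into)),
                       unique(unname(merged_into)))
    }

    pi_now <- vapply(models, `[[`, numeric(1), "prior_abundance")
    expected_reads <- n_mapped * pi_now
    drop_ids <- names(models)[expected_reads < prune_expected_reads]
    if (length(drop_ids)) {
      models <- models[setdiff(names(models), drop_ids)]
      hits <- hits[!(hits$candidate_id %in% drop_ids), , drop = FALSE]
      changed <- setdiff(changed, drop_ids)
      if (length(models) == 0) stop("all candidates pruned; check inputs")
    }

    hits <- remap_candidates(hits, intersect(changed, names(models)))
    pi_now <- vapply(models, `[[`, numeric(1), "prior_abundance")
    priors <- pi_now / sum(pi_now)

    # total data log-likelihood under current priors and placements
    lp <- log(priors[hits$candidate_id]) + hits$loglik
    dtl <- data.table::data.table(pair_id = hits$pair_id, lp = lp)
    ll <- dtl[, .(v = {m <- max(lp); m + log(sum(exp(lp - m)))}), by = pair_id]
    log_rows[[iter]] <- data.frame(
      iteration = iter, n_candidates = length(models), n_mapped = n_mapped,
      mapped_fraction = n_mapped / nrow(pairs), loglik = sum(ll$v),
      abundance_sum = sum(pi_full), consensus_changed = length(changed) > 0,
      merged = length(merged_into) > 0, pruned = length(drop_ids) > 0)
    if (verbose)
      message(sprintf("iter %3d: %d candidates, %.4f mapped, loglik %.2f",
                      iter, length(models), n_mapped / nrow(pairs), sum(ll$v)))
  }

  n_mapped_final <- length(unique(hits$pair_id))
  res <- data.frame(
    id = names(models),
    sequence = vapply(models, `[[`, character(1), "consensus"),
    abundance = vapply(models, `[[`, numeric(1), "prior_abundance"),
    stringsAsFactors = FALSE, row.names = NULL)
  res$abundance <- res$abundance / sum(res$abundance)
  res$expected_reads <- n_mapped_final * res$abundance
  res <- res[order(-res$abundance, res$id), , drop = FALSE]
  rownames(res) <- NULL
  out <- list(results = filter_by_abundance(res, min_abundance),
              all_results = res,
              mapped_fraction = n_mapped_final / nrow(pairs),
              n_mapped = n_mapped_final, n_pairs = nrow(pairs),
              insert_mean = insert_mean, insert_sd = insert_sd,
              final_hits = hits,
              log = do.call(rbind, log_rows))
  class(out) <- "emrec_result"
  out
}

#' Filter reconstruction results by abundance
#'
#' Retains entries with `abundance >= threshold`; retained abundances are
#' not renormalized, so they continue to report shares of the full mapped
#' library.
#'
#' @param results data.frame with an `abundance` column.
#' @param threshold abundance floor (inclusive).
#' @return the retained rows.
#' @export
filter_by_abundance <- function(results, threshold = 1e-4) {
  out <- results[results$abundance >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.emrec_result <- function(x, ...) {
  cat(sprintf("emrec reconstruction: %d sequence(s) reported (%d before the abundance filter)\n",
              nrow(x$results), nrow(x$all_results)))
  cat(sprintf("mapped pairs: %d / %d (%.1f%%)\n", x$n_mapped, x$n_pairs,
              100 * x$mapped_fraction))
  print(utils::head(transform(x$results,
                              sequence = paste0(substr(sequence, 1, 24), "...")), 10))
  invisible(x)
}

#' Write reconstruction results as FASTA and TSV
#'
#' FASTA headers carry the estimated abundance and expected read count
#' (`>id|abundance=...|reads=...`).
#'
#' @param result an `emrec_result` or a results data.frame.
#' @param prefix output prefix (`<prefix>.fasta`, `<prefix>.tsv`).
#' @return the two paths, invisibly.
#' @export
write_results <- function(result, prefix) {
  res <- if (inherits(result, "emrec_result")) result$results else result
  headers <- sprintf("%s|abundance=%.6f|reads=%.1f", res$id, res$abundance,
                     res$expected_reads)
  write_fasta_refs(data.frame(id = res$id, seq = res$sequence),
                   paste0(prefix, ".fasta"), headers = headers)
  write.table(res[, c("id", "abundance", "expected_reads")],
              paste0(prefix, ".tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paste0(prefix, c(".fasta", ".tsv")))
}
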