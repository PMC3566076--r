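# independent oracles used across the suite: an unbanded dynamic-programming
# identity, brute-force greedy clustering, an exhaustive all-positions
# paired-end mapper, a sliding-Hamming primer-site scan, and small
# sequence-generation helpers.  These deliberately share no code with the
# package internals.

BASES <- c("A", "C", "G", "T")

random_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# apply k substitutions (and optionally small indels) to a sequence
perturb_seq <- function(seq, n_subs = 0, n_indels = 0) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (n_subs > 0) {
    pos <- sample.int(length(chars), n_subs)
    for (p in pos) chars[p] <- sample(setdiff(BASES, chars[p]), 1)
  }
  for (k in seq_len(n_indels)) {
    p <- sample.int(length(chars) - 2, 1) + 1
    if (runif(1) < 0.5) chars <- append(chars, sample(BASES, 1), after = p)
    else chars <- chars[-p]
  }
  paste(chars, collapse = "")
}

# --- unbanded global-alignment identity oracle ------------------------------
# scoring identical to the package definition: match +1, mismatch -1,
# internal gap -2/base, terminal gap -1/base; identity = matches / aligned
# columns with terminal-gap columns excluded.  Move priority on score ties:
# diagonal, then up (consume a), then left (consume b).
dp_identity_oracle <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av); m <- length(bv)
  S <- matrix(-Inf, n + 1, m + 1)
  M <- matrix(0L, n + 1, m + 1)  # 1 diag, 2 up, 3 left
  S[1, 1] <- 0
  for (j in seq_len(m)) { S[1, j + 1] <- -j; M[1, j + 1] <- 3L }
  for (i in seq_len(n)) {
    for (j in 0:m) {
      best <- -Inf; how <- 0L
      if (j == 0) { best <- -i; how <- 2L }
      if (j > 0) {
        s <- S[i, j] + if (av[i] == bv[j]) 1 else -1
        if (s > best) { best <- s; how <- 1L }
        su <- S[i, j + 1] + if (j == m) -1 else -2
        if (su > best) { best <- su; how <- 2L }
        sl <- S[i + 1, j] + if (i == n || i == 0) -1 else -2
        if (sl > best) { best <- sl; how <- 3L }
      }
      S[i + 1, j + 1] <- best; M[i + 1, j + 1] <- how
    }
  }
  i <- n; j <- m; matches <- 0L; cols <- 0L; in_tail <- TRUE
  while (i > 0 || j > 0) {
    how <- M[i + 1, j + 1]
    if (how == 1L) {
      in_tail <- FALSE
      if (av[i] == bv[j]) matches <- matches + 1L
      cols <- cols + 1L; i <- i - 1; j <- j - 1
    } else if (how == 2L) {
      if (!((j == m && in_tail) || j == 0)) cols <- cols + 1L
      i <- i - 1
    } else if (how == 3L) {
      if (!((i == n && in_tail) || i == 0)) cols <- cols + 1L
      j <- j - 1
    } else break
  }
  if (cols == 0) 0 else matches / cols
}

# --- brute-force greedy clustering oracle -----------------------------------
greedy_cluster_oracle <- function(seqs, threshold, identity_fun = dp_identity_oracle) {
  centroids <- integer(0)
  for (i in seq_along(seqs)) {
    assigned <- FALSE
    for (c in centroids) {
      if (identity_fun(seqs[i], seqs[c]) >= threshold) { assigned <- TRUE; break }
    }
    if (!assigned) centroids <- c(centroids, i)
  }
  centroids
}

# --- exhaustive all-positions, both-orientations paired mapper --------------
revcomp_oracle <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

loglik_oracle <- function(read, qual, window, eps_cap = 0.25, qual_reversed = FALSE) {
  rv <- strsplit(read, "", fixed = TRUE)[[1]]
  wv <- strsplit(window, "", fixed = TRUE)[[1]]
  q <- utf8ToInt(qual) - 33
  if (qual_reversed) q <- rev(q)
  eps <- pmin(10^(-q / 10), eps_cap)
  sum(ifelse(rv == wv, log1p(-eps), log(eps / 3)))
}

# best placement per candidate by exhaustive scan; returns a data.frame
# comparable to map_reads() output (pair fields omitted)
exhaustive_map_oracle <- function(seq1, qual1, seq2, qual2, cand_seqs,
                                  max_mm_rate = 0.06, insert_range = c(1, 1e6),
                                  eps_cap = 0.25) {
  out <- NULL
  for (ci in seq_along(cand_seqs)) {
    cs <- cand_seqs[ci]; L <- nchar(cs)
    best <- NULL
    for (ori in 1:2) {
      Fr <- if (ori == 1) seq1 else seq2
      Fq <- if (ori == 1) qual1 else qual2
      Rr <- revcomp_oracle(if (ori == 1) seq2 else seq1)
      Rq <- if (ori == 1) qual2 else qual1
      lf <- nchar(Fr); lr <- nchar(Rr)
      for (sf in 0:(L - lf)) {
        wf <- substr(cs, sf + 1, sf + lf)
        mmf <- sum(strsplit(wf, "")[[1]] != strsplit(Fr, "")[[1]])
        if (mmf > floor(max_mm_rate * lf)) next
        for (sr in sf:(L - lr)) {
          ins <- sr + lr - sf
          if (ins < insert_range[1] || ins > insert_range[2]) next
          wr <- substr(cs, sr + 1, sr + lr)
          mmr <- sum(strsplit(wr, "")[[1]] != strsplit(Rr, "")[[1]])
          if (mmr > floor(max_mm_rate * lr)) next
          ll <- loglik_oracle(Fr, Fq, wf, eps_cap) +
            loglik_oracle(Rr, Rq, wr, eps_cap, qual_reversed = TRUE)
          if (is.null(best) || ll > best$loglik + 1e-12) {
            best <- data.frame(cand = ci, start_fwd = sf, start_rc = sr,
                               rc_mate = if (ori == 1) 2L else 1L,
                               mismatches = mmf + mmr, insert = ins, loglik = ll)
          }
        }
      }
    }
    if (!is.null(best)) out <- rbind(out, best)
  }
  out
}

# --- sliding-Hamming primer-site oracle -------------------------------------
hamming_scan_oracle <- function(seq, pattern) {
  sv <- strsplit(seq, "", fixed = TRUE)[[1]]
  pv <- strsplit(pattern, "", fixed = TRUE)[[1]]
  k <- length(pv)
  vapply(seq_len(length(sv) - k + 1), function(s)
    sum(sv[s:(s + k - 1)] != pv), integer(1))
}

# --- small fixture builders -------------------------------------------------
write_temp_fasta <- function(seqs, ids = sprintf("seq%d", seq_along(seqs))) {
  path <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", ids, "\n", seqs), path)
  path
}

# fabricate a hits-with-posteriors table for consensus-update tests
fake_hits <- function(pair, candidate_id, start_fwd, start_rc, rc_mate, post,
                      loglik = 0) {
  data.frame(pair_id = sprintf("p%d", pair), candidate_id = candidate_id,
             pair = pair, cand = 1L, start_fwd = start_fwd, start_rc = start_rc,
             rc_mate = rc_mate, mismatches = 0L,
             insert = start_rc - start_fwd + 1L, loglik = loglik, post = post,
             stringsAsFactors = FALSE)
}
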