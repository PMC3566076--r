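# community post-processing: OTU picking, adjusted tables, replicate
# screens, V3 excision, rarefaction with clipping, end-bias diagnostics

test_that("OTU picking clusters by abundance order at 97% identity", {
  set.seed(60)
  a <- random_seq(600)
  # identical sequences from three samples collapse
  s3 <- data.frame(id = c("s1", "s2", "s3"), seq = a, abundance = c(3, 2, 1))
  p <- pick_otus(s3)
  expect_equal(nrow(p$representatives), 1)
  expect_true(all(p$assignment == "OTU_1"))

  # 96% -> two OTUs, 98% -> one
  s96 <- data.frame(id = c("x", "y"), seq = c(a, perturb_seq(a, 24)),
                    abundance = c(2, 1))
  expect_equal(nrow(pick_otus(s96)$representatives), 2)
  s98 <- data.frame(id = c("x", "y"), seq = c(a, perturb_seq(a, 12)),
                    abundance = c(2, 1))
  expect_equal(nrow(pick_otus(s98)$representatives), 1)

  # the most abundant sequence, not the first, is the representative
  srep <- data.frame(id = c("low", "high"), seq = c(perturb_seq(a, 12), a),
                     abundance = c(1, 5))
  expect_equal(pick_otus(srep)$representatives$id, "high")
})

test_that("OTU picking matches a brute-force greedy oracle with planted clusters", {
  set.seed(61)
  base_seqs <- replicate(6, random_seq(300))
  seqs <- unlist(lapply(base_seqs, function(s)
    c(s, replicate(4, perturb_seq(s, n_subs = sample(0:8, 1))))))
  tab <- data.frame(id = sprintf("q%02d", seq_along(seqs)), seq = seqs,
                    abundance = runif(length(seqs)))
  p <- pick_otus(tab, 0.97)
  ord <- order(-tab$abundance, tab$id)
  oracle <- greedy_cluster_oracle(tab$seq[ord], 0.97)
  expect_equal(p$representatives$id, tab$id[ord][oracle])
  # completeness: every input sequence maps to exactly one OTU
  expect_setequal(names(p$assignment), tab$id)
  expect_false(any(is.na(p$assignment)))
})

test_that("adjusted table turns abundances into expected read counts", {
  res <- list(
    sampleA = data.frame(id = c("e1", "e2"), abundance = c(0.25, 0.25),
                         otu = c("OTU_1", "OTU_1")),
    sampleB = data.frame(id = "e3", abundance = 1.0, otu = "OTU_2"))
  tab <- build_adjusted_table(res, c(sampleA = 1e6, sampleB = 1e6))
  expect_equal(tab["OTU_1", "sampleA"], 5e5)
  expect_equal(tab["OTU_2", "sampleB"], 1e6)
  expect_equal(tab["OTU_2", "sampleA"], 0)  # absent OTU -> 0
  # conservation: column sum = mapped total x total reported abundance
  expect_equal(colSums(tab), c(sampleA = 1e6 * 0.5, sampleB = 1e6))
  res$sampleA$otu[2] <- NA
  expect_error(build_adjusted_table(res, c(sampleA = 1, sampleB = 1)), "sampleA")
})

test_that("high-specificity screen applies the >=12 of 16 rule per group", {
  subs <- paste0("s", 1:32)
  groups <- list(g1 = subs[1:16], g2 = subs[17:32])
  pres <- matrix(0, 3, 32, dimnames = list(c("o12", "o11", "o16"), subs))
  pres["o12", subs[1:12]] <- 1       # 12/16 in one group -> included
  pres["o11", subs[c(1:11, 17:27)]] <- 1  # 11/16 in both -> excluded
  pres["o16", subs[17:32]] <- 1      # 16/16 -> included
  expect_setequal(high_specificity_otus(pres, groups), c("o12", "o16"))
  expect_error(high_specificity_otus(pres, list(g = subs[1:5])), "mismatch")
})

test_that("V3 excision finds primer windows and applies the length filter", {
  set.seed(62)
  v3 <- paste0(PRIMER_341F, random_seq(130), revcomp(PRIMER_518R))
  s <- paste0(random_seq(300), v3, random_seq(400))
  r <- extract_v3(s)
  expect_false(isTRUE(r$rejected))
  expect_identical(r$region, v3)
  expect_equal(r$length, 130 + 34)

  # a 90-base region is rejected as a possible error
  short <- paste0(random_seq(200), PRIMER_341F, random_seq(56),
                  revcomp(PRIMER_518R), random_seq(200))
  expect_true(isTRUE(extract_v3(short)$rejected))

  # chosen windows equal an exhaustive Hamming scan on random sequences
  for (rep in 1:10) {
    x <- random_seq(1500)
    r <- extract_v3(x, min_len = 0, max_len = 1500)
    df <- hamming_scan_oracle(x, PRIMER_341F)
    fs <- which.min(df)
    dr <- hamming_scan_oracle(x, revcomp(PRIMER_518R))
    dr[seq_along(dr) <= fs + nchar(PRIMER_341F) - 1] <- Inf
    rs <- which.min(dr)
    expect_equal(r$start, fs - 1L)
    expect_equal(r$length, rs + 17 - fs)
  }
})

test_that("rarefaction clips low counts and is exact at full depth", {
  tab <- matrix(c(1000, 21, 20), ncol = 1,
                dimnames = list(c("a", "b", "c"), "s1"))
  reps <- rarefy_with_clipping(tab, depth = 1041, clip = 20, replicates = 2,
                               seed = 1)
  for (r in reps) expect_equal(unname(r[, 1]), c(1000, 21, 0))

  # clip = 0 removes nothing but zeros
  r0 <- rarefy_with_clipping(tab, depth = 1041, clip = 0, replicates = 1,
                             seed = 1)[[1]]
  expect_equal(unname(r0[, 1]), c(1000, 21, 20))

  # largest-remainder rounding preserves totals of fractional tables
  ftab <- matrix(c(10.4, 10.3, 10.3), ncol = 1,
                 dimnames = list(c("a", "b", "c"), "s1"))
  r1 <- rarefy_with_clipping(ftab, depth = 31, clip = 0, replicates = 1,
                             seed = 1)[[1]]
  expect_equal(sum(r1), 31)

  expect_error(rarefy_with_clipping(tab, depth = 2000, seed = 1), "s1")
  # determinism and clipping monotonicity on a random table
  set.seed(63)
  big <- matrix(rpois(40, 40), 20, 2,
                dimnames = list(sprintf("o%d", 1:20), c("x", "y")))
  a <- rarefy_with_clipping(big, 500, clip = 5, replicates = 3, seed = 9)
  b <- rarefy_with_clipping(big, 500, clip = 5, replicates = 3, seed = 9)
  expect_identical(a, b)
  hi <- rarefy_with_clipping(big, 500, clip = 10, replicates = 3, seed = 9)
  for (k in 1:3) expect_true(all(hi[[k]] <= a[[k]]))
})

test_that("clipped observed-OTU counts match an independent Monte-Carlo oracle", {
  # known 100-OTU geometric community
  set.seed(64)
  counts <- round(1e5 * 0.93^(0:99) * (1 - 0.93) / (1 - 0.93^100))
  tab <- matrix(counts, ncol = 1, dimnames = list(sprintf("o%d", 1:100), "s"))
  depth <- 1e4
  reps <- rarefy_with_clipping(tab, depth, clip = 20, replicates = 200, seed = 65)
  got <- mean(vapply(reps, function(r) sum(r > 0), numeric(1)))

  # independent oracle: multivariate-hypergeometric draw via randomized
  # assignment of depth slots among the pooled reads
  N <- sum(tab)
  cum <- cumsum(counts)
  oracle <- mean(replicate(200, {
    picks <- sample.int(N, depth)
    cnt <- tabulate(findInterval(picks - 1, cum) + 1L, nbins = 100)
    sum(cnt > 20)
  }))
  expect_lt(abs(got - oracle) / oracle, 0.02)
})

test_that("end-bias histogram is degenerate when all fragments start at 0", {
  hits <- data.frame(candidate_id = "c", start_fwd = 0L, start_rc = 182L,
                     rc_mate = 2L, insert = 275L)[rep(1, 50), ]
  prof <- end_bias_profile(hits, c(c = strrep("A", 1464)))
  expect_equal(prof$histogram$fraction[1], 1.0)
})
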