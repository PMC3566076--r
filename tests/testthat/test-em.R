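# EM core: E-step posteriors, abundance and consensus M-steps, merging,
# and the full reconstruction loop

test_that("E-step applies Bayes rule over priors and likelihoods", {
  # single candidate: posterior 1
  h1 <- data.frame(pair_id = c("a", "b"), candidate_id = "c1",
                   loglik = c(-5, -7))
  p1 <- e_step(h1, c(c1 = 1))
  expect_equal(p1$post, c(1, 1))

  # equal likelihoods: posterior equals the prior
  h2 <- data.frame(pair_id = "a", candidate_id = c("c1", "c2"),
                   loglik = c(-3, -3))
  expect_equal(e_step(h2, c(c1 = 0.8, c2 = 0.2))$post, c(0.8, 0.2))

  # 9:1 likelihood ratio with flat priors
  h3 <- data.frame(pair_id = "a", candidate_id = c("c1", "c2"),
                   loglik = c(log(9) - 10, log(1) - 10))
  expect_equal(e_step(h3, c(c1 = 0.5, c2 = 0.5))$post, c(0.9, 0.1))
})

test_that("abundance M-step averages posteriors over mapped pairs", {
  post <- data.frame(pair_id = sprintf("p%d", 1:100),
                     candidate_id = rep(c("A", "B"), c(70, 30)),
                     post = 1)
  expect_equal(m_step_abundance(post), c(A = 0.7, B = 0.3))
  # degenerate: everything on one candidate
  post$candidate_id <- "A"
  expect_equal(m_step_abundance(post), c(A = 1))
  # symmetric fractional posteriors
  post2 <- data.frame(pair_id = rep(sprintf("p%d", 1:10), each = 2),
                      candidate_id = rep(c("A", "B"), 10), post = 0.5)
  expect_equal(m_step_abundance(post2), c(A = 0.5, B = 0.5))
  expect_equal(sum(m_step_abundance(post2)), 1)
  expect_error(m_step_abundance(post[0, ], 0), "no mapped")
})

test_that("consensus M-step accumulates weighted evidence and flips variants", {
  set.seed(40)
  cons <- random_seq(120)
  # ten error-free 40-base pairs all covering positions 10..59 (0-based)
  reads <- data.frame(id = sprintf("p%d", 1:10),
                      seq1 = substr(cons, 11, 50), qual1 = strrep("5", 40),
                      seq2 = revcomp(substr(cons, 21, 60)), qual2 = strrep("5", 40))
  hits <- fake_hits(1:10, "c1", start_fwd = 10L, start_rc = 20L,
                    rc_mate = 2L, post = 1)
  cand <- list(id = "c1", consensus = cons, prior_abundance = 1)
  up <- m_step_consensus(hits, reads, cand)
  expect_identical(up$consensus, cons)  # unanimity keeps every base
  # weight at a doubly-covered position: 20 reads' worth of (1 - 0.01)
  b <- match(substr(cons, 31, 31), c("A", "C", "G", "T"))
  expect_equal(unname(up$base_weights[b, 31]), 20 * 0.99, tolerance = 1e-9)
  # uncovered positions keep the prior base with zero weight
  expect_equal(sum(up$base_weights[, 100]), 0)
  expect_identical(substr(up$consensus, 100, 100), substr(cons, 100, 100))

  # planted variant: model says A, reads say G -> consensus flips
  pos <- 25L  # 0-based; covered by read 1 window
  cons_var <- cons
  substr(cons_var, pos + 1, pos + 1) <- if (substr(cons, pos + 1, pos + 1) == "A") "G" else "A"
  cand2 <- list(id = "c1", consensus = cons_var, prior_abundance = 1)
  up2 <- m_step_consensus(hits, reads, cand2)
  expect_identical(up2$consensus, cons)
})

test_that("merging respects the identity threshold transitively", {
  set.seed(41)
  a <- random_seq(500)
  mk <- function(id, seq, ab) list(id = id, consensus = seq,
                                   prior_abundance = ab, base_weights = NULL)
  # byte-identical pair collapses, abundances sum
  m <- merge_candidates(list(mk("x", a, 0.3), mk("y", a, 0.2)))
  expect_length(m, 1)
  expect_equal(m[[1]]$id, "x")
  expect_equal(m[[1]]$prior_abundance, 0.5)

  # 96% identity: both retained at join threshold 0.97
  b96 <- perturb_seq(a, n_subs = 20)
  m2 <- merge_candidates(list(mk("x", a, 0.5), mk("y", b96, 0.5)), 0.97)
  expect_length(m2, 2)

  # chain A~B 98%, B~C 98%, A~C 96%: one survivor via transitive closure
  b <- perturb_seq(a, n_subs = 10)
  cc <- perturb_seq(b, n_subs = 10)
  expect_lt(pairwise_identity(a, cc), 0.97)
  m3 <- merge_candidates(list(mk("A", a, 0.5), mk("B", b, 0.3), mk("C", cc, 0.2)))
  expect_length(m3, 1)
  expect_equal(m3[[1]]$prior_abundance, 1.0)

  # idempotence
  m4 <- merge_candidates(m2, 0.97)
  expect_equal(vapply(m4, `[[`, "", "id"), vapply(m2, `[[`, "", "id"))
})

test_that("abundance filtering is inclusive and never renormalizes", {
  res <- data.frame(id = c("a", "b", "c"),
                    abundance = c(0.5, 0.4999, 0.0001))
  expect_equal(nrow(filter_by_abundance(res)), 3)
  res2 <- data.frame(id = c("a", "b"), abundance = c(0.99995, 0.00005))
  kept <- filter_by_abundance(res2)
  expect_equal(kept$id, "a")
  expect_equal(kept$abundance, 0.99995)  # unchanged share of the full library
  expect_equal(nrow(filter_by_abundance(res2[0, ])), 0)
})

test_that("single-species error-free library is recovered exactly", {
  refs <- make_synthetic_references(1, seed = 50)
  cfg <- sim_config(setNames(1, refs$id), n_pairs = 500, error_rate = 0, seed = 51)
  lib <- simulate_library(cfg, refs)
  res <- run_emirge(lib$reads, refs, n_iterations = 5,
                    insert_mean = 275, insert_sd = 15)
  expect_equal(nrow(res$results), 1)
  expect_equal(res$results$abundance, 1.0)
  expect_identical(res$results$sequence, lib$amplicons[[1]])
  expect_gte(res$mapped_fraction, 0.999)
})

test_that("two-species abundances are recovered within sampling error", {
  refs <- make_synthetic_references(2, seed = 52)
  comm <- setNames(c(0.7, 0.3), refs$id)
  cfg <- sim_config(comm, n_pairs = 2e4, error_rate = 0.01, seed = 53)
  lib <- simulate_library(cfg, refs)
  res <- run_emirge(lib$reads, refs, n_iterations = 8,
                    insert_mean = 275, insert_sd = 15)
  est <- setNames(res$results$abundance, res$results$id)[names(comm)]
  expect_true(all(abs(est - comm) < 0.02))
  expect_identical(res$results$sequence[res$results$id == refs$id[1]],
                   lib$amplicons[[1]])
  # abundance normalization held on every iteration
  expect_true(all(abs(res$log$abundance_sum - 1) < 1e-9))
})

test_that("a divergent seed converges onto the true sequence", {
  # database seed differing from the truth at 2% of positions; deep
  # error-free coverage corrects every position within a few iterations
  refs <- make_synthetic_references(1, seed = 54)
  seed_db <- data.frame(id = "seed1",
                        seq = mutate_sequence(refs$seq, rate = 0.02, seed = 55))
  cfg <- sim_config(setNames(1, refs$id), n_pairs = 400, error_rate = 0, seed = 56)
  lib <- simulate_library(cfg, refs)
  res <- run_emirge(lib$reads, seed_db, n_iterations = 3,
                    insert_mean = 275, insert_sd = 15)
  expect_identical(res$results$sequence, lib$amplicons[[1]])
})
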