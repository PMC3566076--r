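# emrec

Reconstruction of near-full-length 16S rRNA gene sequences and their
relative abundances from **sheared-amplicon paired-end short-read
libraries**, by iterative expectation-maximization.

## The problem

Full-length 16S amplicons (~1.5 kb, 27F–1492R) resolve taxonomy far
better than single hypervariable regions, but short-read sequencers
cannot read them directly. Shearing the amplicon pool into ~300-bp
fragments makes it sequenceable — and anonymizes every read. `emrec`
reassembles the community from that soup: starting from a database of
candidate 16S genes, each EM iteration aligns read pairs to the current
candidates, attributes each pair probabilistically among them,

$$q_{ij} = \frac{\pi_j\,P(r_i \mid s_j)}{\sum_k \pi_k\,P(r_i \mid s_k)},
\qquad
P(r_i \mid s_j) = \prod_b (1-\varepsilon_b)^{[\mathrm{match}]}
  \left(\tfrac{\varepsilon_b}{3}\right)^{[\mathrm{mismatch}]},$$

then updates abundances ($\pi_j' = \sum_i q_{ij}/n$) and per-position
consensus bases from the posterior-weighted evidence, merging candidates
that converge to ≥ 97% identity. It is aimed at microbial ecologists who
want to profile communities — including members at 0.01% relative
abundance — with full-length marker resolution from ordinary Illumina
paired-end data.

The package also provides the surrounding workflow: reference database
preparation (length filter 1200–1900 bp, IUPAC resolution, greedy 97%
clustering), quality trimming, a quality-aware ungapped paired mapper, a
synthetic sheared-library simulator with the characteristic ~100-fold
fragment-start enrichment at amplicon ends, a closed-form
expected-coverage model, and community post-processing
(abundance-ordered OTU picking, adjusted expected-count tables, in
silico V3 excision, rarefaction with count clipping, replicate
screens, end-bias diagnostics).

## Worked example

Simulate a 3-species community at 60/30/10% and reconstruct it from
20,000 read pairs at 1% per-base error, seeding the EM with the true
references:

```r
library(emrec)
refs      <- make_synthetic_references(3, seed = 7)
community <- setNames(c(0.6, 0.3, 0.1), refs$id)
cfg <- sim_config(community, n_pairs = 20000, error_rate = 0.01, seed = 11)
lib <- simulate_library(cfg, refs)
res <- run_emirge(lib$reads, refs, n_iterations = 20,
                  insert_mean = 275, insert_sd = 15)
print(res)
#> emrec reconstruction: 3 sequence(s) reported (3 before the abundance filter)
#> mapped pairs: 19853 / 20000 (99.3%)
#>        id                    sequence abundance expected_reads
#> 1 ref_001 AGAGTTTGATCCTGGCTCAGCGGT... 0.5962827          11838
#> 2 ref_002 AGAGTTTGATCCTGGCTCAGCAAA... 0.3026747           6009
#> 3 ref_003 AGAGTTTGATCCTGGCTCAGCCAA... 0.1010427           2006
```

99.3% of pairs map to a retained sequence; the estimated abundances
(59.6/30.3/10.1%) recover the simulated mixture to within sampling
error, and each reconstructed consensus is identical to its true
amplicon (`pairwise_identity(res$results$sequence[1], lib$amplicons[1])`
returns 1). The closed-form coverage model explains why members down to
0.01% are recoverable from a million-pair library:

```r
ec <- expected_coverage(1e6, 93, 1e-4, amplicon_len = 1464,
                        insert_len = 275, end_bias_weight = 100,
                        depth_threshold = 5)
#> interior depth 10.87X; 98.4% of bases >= 5X
```

See `vignettes/emrec-methods.Rmd` for the model, its assumptions, and
every numerical choice.

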