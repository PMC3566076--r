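---
title: "Methods: EM reconstruction of 16S genes from sheared amplicon libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EM reconstruction of 16S genes from sheared amplicon libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Near-full-length 16S rRNA gene amplicons (~1.5 kb, bounded by the 27F and
1492R primers) carry far more taxonomic information than any single short
hypervariable region, but short-read sequencers cannot read them directly.
One workable design shears the pooled amplicons into ~300-bp fragments and
sequences those as paired-end reads. The cost is that each read no longer
identifies its template; recovering the community requires reassembling
full-length gene sequences *and* their relative abundances from a soup of
anonymous fragments.

`emrec` implements a template-guided expectation-maximization (EM)
reconstruction for this design, together with the pieces needed to study
it end to end: candidate-database preparation, quality trimming, a
quality-aware ungapped paired-end mapper, a synthetic library simulator
whose defaults mirror the sheared-amplicon library structure, a
closed-form expected-coverage model, and the downstream community-table
procedures (OTU picking, adjusted expected-count tables, V3 excision,
rarefaction with clipping, replicate-specificity screens, and end-bias
diagnostics).

## The mixture model and the EM

Let $s_j$ be candidate sequences with mixture weights (relative
abundances) $\pi_j$, and $r_i$ the read pairs. A placement of pair $i$ on
candidate $j$ is gapless for both mates; its likelihood is the standard
Phred–Bernoulli substitution model

$$P(r_i \mid s_j) \;=\; \prod_b
\begin{cases} 1-\varepsilon_b & \text{base matches}\\
\varepsilon_b/3 & \text{base mismatches,}\end{cases}$$

with $\varepsilon_b$ the Phred-implied error probability of the read base,
capped at 0.25 so that no base can count as worse than uninformative.
Each iteration alternates:

* **E-step** — posterior attribution
  $q_{ij} = \pi_j P(r_i\mid s_j) / \sum_k \pi_k P(r_i\mid s_k)$,
  computed in log space.
* **M-step (abundance)** — $\pi_j' = \sum_i q_{ij} / n_{\text{mapped}}$,
  so abundances are shares of mapped pairs.
* **M-step (consensus)** — per position, each covering read base
  contributes weight $q_{ij}(1-\varepsilon_b)$; the consensus base is the
  arg-max (ties prefer the current base, then alphabetical order), and
  uncovered positions keep the current base.
* **Merge** — candidates whose consensuses reach the join threshold
  (default 0.97 identity) are merged transitively; the survivor is the
  more abundant member, inheriting summed abundance and pooled base
  weights after an ungapped offset alignment.
* **Prune** — candidates expected to attract fewer than 0.05 reads are
  dropped. The pruning rule is this package's own addition: without it a
  large candidate database never shrinks and the E-step stays quadratic
  in decoys. The threshold is configurable and logged.

Reads are conceptually re-mapped against every consensus each iteration;
because the mapper is deterministic, the implementation re-maps only
candidates whose consensus actually changed, which is exact and makes
late iterations cheap. After the final iteration, sequences at or above
the reporting floor (default 0.01%) are returned without renormalizing,
so reported abundances remain shares of the full mapped library. On
iterations where no consensus change, merge or prune occurred, the total
data log-likelihood is non-decreasing (the classic EM guarantee); the
test suite asserts this on the iteration log. Candidate splitting for
co-occurring strain variants and indel handling are deliberately out of
scope.

## Mapping

The mapper is seed-and-extend: 15-base exact seeds at three offsets per
mate locate candidate positions, which are verified end-to-end without
gaps; both mate orientations are tried, per-mate mismatches are capped at
6% of the mate length, and the implied insert must fall within the
accepted window (mean ± 3 sd, estimated by an initial mapping when not
supplied). Within one candidate only the best-likelihood placement is
kept (one fragment has one origin); ties break leftmost, so runs are
reproducible. With three overlapping seed windows, a placement can only
be missed when every window contains an error — rare at the error rates
this design produces, and self-correcting across iterations because a
corrected consensus is re-mapped. An exhaustive all-positions,
both-orientations scan serves as the test oracle.

## Sequence identity

Clustering, merging and OTU picking all rest on one identity definition:
a banded global alignment with match +1, mismatch −1, internal gap −2
per base, and terminal gap −1 per base; identity is matched columns over
aligned columns, with terminal-gap columns excluded from the count.
Penalizing terminal gaps lightly (half an internal gap) keeps the
conventional behaviour that a substitution is not "escaped" by sliding
the alignment — two equal-length sequences differing at one position are
90%…99.9% identical by their mismatch count, not 100% via a spurious
offset — while still letting genuinely different lengths align freely.
The band half-width is 5% of the shorter length plus the length
difference, ample for the near-identical rRNA comparisons the threshold
tests (97%) care about; strongly shifted optima outside the band are not
sought. An unbanded dynamic program with identical scoring is the test
oracle.

## The simulator

`sim_config()` defaults encode the library structure the package
targets: amplicons excised at the best-matching 27F/1492R sites (any
number of primer mismatches allowed), inserts normal with mean 275 bp and
sd 15 bp truncated to `[read length, amplicon length]`, 93-bp mates read
inward from the fragment ends, a uniform 1% per-base substitution rate
with matching constant Phred qualities, and fragment starts drawn with
weight 100 at the two terminal placements versus 1 elsewhere — the
~100-fold end enrichment characteristic of sheared, end-ligated amplicon
libraries. The truth table (source reference, fragment start, insert
length, error count per pair) supports parameter-recovery tests.

What the simulator does *not* emulate — and what passing tests therefore
do not demonstrate about real libraries: PCR chimeras and polymerase
bias, indel errors, position-dependent quality decay (the optional ramp
was left out in favour of the uniform model), copy-number variation, and
real rRNA phylogenetic structure. Synthetic references are random cores
between primer sites, so distinct species are ~25% identical; real
communities contain continua of 94–99% relatives that make merging and
OTU picking genuinely harder. The synthetic spike-in and recovery tests
show the estimator is correct under its own model, not that the model is
complete.

## The coverage model

For a member at relative abundance $a$ in a library of $N$ read pairs of
length $L_r$, naive depth is $2 N a L_r / L_a$ on an amplicon of length
$L_a$. End bias concentrates a fraction of fragment starts at the two
terminal placements; the interior share of start mass is
$(n_{pos}-2)/(2w + n_{pos}-2)$ with $n_{pos} = L_a - L_i + 1$ placements
for insert $L_i$ and terminal weight $w$. Interior per-base depth is the
product of the two, and the fraction of bases reaching a threshold is a
Poisson tail at that mean. At the defaults ($N = 10^6$, $L_r = 93$,
$a = 10^{-4}$, $L_a = 1464$, $L_i = 275$, $w = 100$) this gives an
interior mean depth of 10.87X (~11X) and 98.4% of bases at ≥ 5X. The
"library of one million reads" is interpreted as one million *pairs*
(200 reads of 93 bp for the 0.01% member): the pair reading reproduces
~11X, whereas 100 single reads would give 6.4X. At $w = 1$ the interior
depth equals naive depth up to the two terminal placements' own share of
start mass (a factor $(n_{pos}-2)/n_{pos}$, about 0.2% here).

## Quality trimming

The trim rule uses a *centred* 10-base window: a mate is cut just before
the first position whose window (positions $i-4..i+5$, truncated at the
read ends) has mean quality below the threshold (default Q20). The
centred window cuts a clean Q40→Q2 boundary exactly at the boundary,
which neither a leading- nor a trailing-anchored window does. Pairs with
either mate under 60 bases after trimming are rejected and counted.

## Community procedures

* **OTU picking** processes sequences pooled across samples in
  decreasing-abundance order (ties by id) and clusters greedily at 97%
  against representatives.
* The **adjusted table** converts per-sample abundances to expected read
  counts, `mapped_total(s) × Σ abundance`, so column sums conserve each
  sample's reported abundance mass exactly.
* **V3 excision** plants the 341F/518R sites by minimal Hamming distance
  with unlimited mismatches (every sequence yields a candidate region);
  the reverse site is searched strictly downstream of the forward site,
  and regions outside 100–225 bp are rejected as likely errors.
* **Rarefaction** rounds expected counts to integers by largest-remainder
  rounding (preserving column totals), draws without replacement
  (multivariate hypergeometric — a full-depth draw returns the sample
  unchanged), and zeroes all counts at or below the clip (default 20).
  Without-replacement sampling is the standard rarefaction draw and the
  only one under which full-depth rarefaction is the identity.
* The **end-bias profile** records each fragment's distance to the
  nearest amplicon end; the enrichment factor is the per-position rate at
  distance 0 over the mean interior per-position rate, which recovers the
  generative weight (interior distances are two-fold degenerate and are
  counted as such).

## Numerical choices and determinism

All coordinates are 0-based half-open; all ties break deterministically
(current base, then alphabetical; leftmost placements; lexicographic
ids). Every stochastic function takes an explicit seed and restores the
caller's RNG state; the pipeline derives per-stage seeds from one master
seed so stages can be re-run independently. Identical configuration and
seed reproduce byte-identical FASTA/TSV outputs. The per-base error
probability is capped at 0.25; posteriors are computed by
log-sum-exp; abundance normalization is asserted each iteration at 1e-9.

## Problem sizes used by the test suite

The suite exercises the estimator at sizes chosen to give tight sampling
bounds while keeping a default run comfortably interactive: the
20-species log-spaced recovery test uses $10^5$ pairs at 1% error for 120
iterations; the spike-in analogue (0.5% spike, database seed 3%
divergent) uses $5\times10^4$ pairs for 40 iterations; end-bias recovery
uses $10^5$ pairs; oracle comparisons use hundreds of bases and tens of
replicates. These are the package's own scale choices; the model itself
has no scale-dependent switches.

## Known limitations

Gapless mapping and indel-free consensus mean a true template with an
insertion relative to its best seed reconstructs with a substitution
scar, exactly as an indel-blind estimator should be expected to behave.
Abundance estimates are shares of mapped pairs, so systematic
mappability differences between templates bias shares accordingly. The
greedy clusterers are order-dependent by design (input order for the
database, abundance order for OTUs) and are documented as such. The
banded identity is a declared substitute for whatever identity a
particular external clustering tool implements; thresholds quoted against
such tools are comparable only approximately.
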