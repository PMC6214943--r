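---
title: "Reconstructing multigene-family transcripts from CCS reads"
author: "isoresolve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing multigene-family transcripts from CCS reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoresolve)
```

## The problem

Ampliconic gene families - for example the nine multicopy gene families of
the human Y chromosome - consist of several near-identical gene copies (up
to 99.99% identity), each of which can express several alternatively spliced
isoforms. Targeted Iso-Seq sequencing yields full-length circular consensus
(CCS) reads that span each transcript end to end, but at per-base error
rates of roughly 0.5% for ~1 kb transcripts up to ~6% for ~6 kb transcripts
(longer templates get fewer polymerase passes). The analysis problem is to
recover the *exact* transcript sequences present in the sample - separating
true inter-copy and inter-isoform variants, which may be a single
nucleotide, from sequencing errors - without using a reference genome.

`isoresolve()` solves this in two stages.

## Stage 1: iterative clustering and partial error correction

Reads are vertices of a *nearest-neighbor graph*: a directed edge runs from
read $x$ to read $y$ whenever $y$ minimizes the edit distance to $x$ among
all other reads (identical duplicate reads are distinct vertices at
distance 0). The graph is partitioned by repeatedly taking the vertex that
the most vertices can reach, cutting out everything that reaches it (the
cluster, with that vertex as *center*), and recursing on the rest. Each
string is guaranteed to share a cluster with one of its closest neighbors.

Within a cluster, all members are globally aligned to the center (affine
scoring: match +2, mismatch −2, gap open −3, gap extend −1; ties in the
traceback are resolved deterministically) and stacked into a
multi-alignment matrix whose columns are the center's positions plus shared,
left-aligned insertion columns. Each cell is classified against the
column consensus as match, substitution, insertion, or deletion, and its
*support* is $n_j^t / n^t$ - the count of its state $t$ in its column $j$
relative to all occurrences of $t$ in the matrix. Making support
state-specific means that indels, the dominant CCS error type, need more
column support than substitutions before they are left uncorrected.

Each read is then *partially* corrected: of its $k$ variant cells, only the
$\lceil k/2 \rceil$ with the lowest support are set to the column majority,
and never at columns where the majority is not unique. Partitioning and
correction alternate until every cluster is internally identical. Three
safeguards bound the loop: a correction is undone if it increased the
read's distance to its center relative to the previous round; a return to a
previously seen global state stops the loop (cycle); and a round that
changes nothing stops it (stall - every remaining difference sits at a tied
column, so iterating further is a no-op). The ceiling in
$\lceil k/2 \rceil$ is a deliberate choice: it makes single-error reads
correctable. A hard cap of 20 rounds exists as a safety valve; if it is
ever reached the driver warns and returns the current centers rather than
aborting, since a partial candidate set is still useful to the filtering
stage.

The distinct converged centers are the *candidate transcripts*. This stage
is tuned for sensitivity - a rare transcript only needs its handful of
reads to form their own cluster - and therefore over-produces candidates;
precision is the next stage's job.

## Stage 2: quality-weighted statistical filtering

The original, uncorrected reads are greedily assigned to their closest
candidates (the candidate covering the most unassigned reads is picked
first). Each candidate $c$ is then tested against each of its
closest-neighbor candidates $d$ under the null hypothesis that all reads
assigned to the pair originated from $d$ and that the variant positions
$V$ (columns where $c$ and $d$ disagree) are sequencing errors.

For read $i$, the support indicator $s_i$ is 1 iff the read shows $c$'s
characters at every column of $V$, and $p_i = \prod_{j \in V} p_{ij}$ is
the probability of that happening by error, with $p_{ij}$ derived from the
read's Phred score at the position: substitution variants use
$10^{-q/10}/3$ (the error must produce the specific base $c$ carries),
indel variants use $10^{-q/10}$, a read-gap position uses the minimum
flanking base quality, and all values are clamped to $[10^{-7}, 0.5]$. The
test statistic is the weighted support

$$T = \prod_{i:\, s_i = 1} \frac{1}{p_i},$$

so high-quality reads, and candidates with many linked variants, need fewer
supporting reads. After the normalization
$T' = \log T / \max_k(-\log p_k)$, $T'$ is a weighted sum of independent
Bernoulli variables with coefficients in $(0,1]$, and a Chernoff-type bound
gives the closed-form significance value

$$P(T \ge t) < \left(\frac{e^\delta}{(1+\delta)^{1+\delta}}\right)^\mu,
\qquad \mu = E(T'),\; \delta = t'/\mu .$$

If $t' \le \mu$ the observed support is below its null expectation and the
value 0.5 is reported. Candidate pairs with more than `max_variants`
(default 10) variant positions are not evaluated - their p-value would be
essentially zero - and are treated as significant.

Each candidate keeps its *least* significant pairwise value; candidates
above `alpha` (default 0.01) are removed, at most `tau` (default 10) per
round, worst first, and the assign-test-remove loop repeats until every
survivor is significant. P-values are recomputed from scratch each round;
only the (deterministic) read-to-candidate alignments are cached.

### A note on the $\delta$ convention

With $\delta = t'/\mu$ the bound is formally evaluated at
$(1+\delta)\mu = t' + \mu$, slightly above the observed $t'$. As a bound on
$P(T \ge t)$ it can therefore be anti-conservative, but only in the
near-null regime $t' \gtrsim \mu$ where its value is large (empirically
always $> 0.1$, far above any working `alpha`); wherever the returned value
is small enough to drive a removal decision it is a valid bound, and the
test suite verifies both facts against a Monte-Carlo oracle. Setting
`test_params(delta_convention = "shifted")` uses $\delta = t'/\mu - 1$,
which evaluates the bound exactly at $t'$ and is valid everywhere. The
default follows the printed form.

### Assumptions

The test assumes the reference candidate $d$ is error-free, that errors at
different positions and in different reads are independent, and that where
$c$ and $d$ agree they are not both wrong. These are assumptions of
validity, documented here; nothing asserts them at runtime. Real CCS
quality strings only approximate per-base error probabilities (quality
co-varies with pass count, homopolymer length, and the base identity), so
the significance values are approximations on real data.

## Grouping transcripts into gene copies

Isoforms of one gene copy differ from each other only by exon
presence/absence: aligned pairwise, they show large indels but no
substitutions. `minimum_group_cover()` builds this compatibility graph
(`indel_only_compatible()`: a substitution-free alignment, every gap run at
least `min_indel_length` = 20 nt, and at least that much genuinely shared
aligned sequence), takes its maximal cliques as groups, and finds the
minimum number of maximal cliques covering all transcripts by exhaustive
search (guarded at 64 transcripts). A transcript may fall into several
groups - that happens when the exon carrying the copy-distinguishing
variant is skipped - so the group count is a conservative estimate of the
copy number, and group sizes are upper bounds on per-copy isoform counts.
The 20 nt default is a policy choice: real exons are far longer, while
sequencing-error indel runs in corrected transcripts are far shorter.

## The simulator

`simulate_family()` emulates the targeted-sequencing study design:

* **Root genes** of three built-in profiles spanning the realistic range:
  914 nt / 6 exons at 0.5% CCS error, 2668 nt / 6 exons at 2.6%, and
  5904 nt / 28 exons at 6.1% (error increasing with length because long
  templates get fewer passes).
* **Gene copies**: copy 1 is the root; each later copy mutates a uniformly
  chosen earlier copy with independent per-base substitutions at
  `mutation_rate` (default 0.01, i.e. roughly nine substitutions on a 1 kb
  gene - "highly similar" copies). Only substitutions are modeled; gene
  conversion is not.
* **Isoforms** by exon skipping (default patterns: full inclusion plus each
  single internal-exon skip; 6 copies × 5 patterns = 30 isoforms), with
  absolute abundances drawn from $\{2^i, i = 1..8\}$, which yields relative
  abundances from about 0.1% to about 15%.
* **Reads**: origins drawn by relative abundance; each read's error rate is
  the profile rate times a lognormal factor (sdlog 0.5, meanlog
  $-\sigma^2/2$ so the mean is unbiased) standing in for pass-count
  variability; errors are substitution : insertion : deletion = 1 : 1 : 1;
  every base is emitted with the Phred score matching the per-base error
  probability actually used (capped at Phred 60).

What the generator does *not* emulate: position- and base-dependent quality
(real CCS qualities dip in homopolymers and at C/G), RT-PCR artifacts,
chimeras, and within-read quality variation. Passing tests on simulated
data therefore demonstrate the algorithmic properties - exact
reconstruction, rare-variant sensitivity, error-rate robustness - not
performance on any particular instrument run.

Evaluation is by exact sequence match: recall is the fraction of true
transcripts matched exactly by a prediction, precision the fraction of
predictions matching a true transcript.

## Problem sizes used in the checks

The test suite re-runs the headline simulation behaviours at sizes chosen
for a per-commit run: the recall-vs-depth sweep on the short-family profile
uses 8 equally abundant gene copies at depths 4-16× with 2 replicate seeds
(the acceptance script `scripts/acceptance.R` runs the full sweep, depths
2-24×, 5 seeds); the precision check runs the 30-isoform design at 500
total reads; and the high-error check runs the 6.1% error profile at 410×
per-transcript depth on a scaled-down family (600 nt over 6 exons, 3
copies) rather than the full 5.9 kb / 28 exon configuration, whose
all-against-all distance computations are a nightly-scale job. The
tail-bound validity check uses 200 random support profiles against
$10^6$-draw Monte-Carlo estimates.

## Numerical and design choices

* Unit-cost Levenshtein distances are computed with a bit-parallel
  (64 positions per machine word) algorithm in C++; alignments use a Gotoh
  affine-gap aligner with full traceback. Both are cross-checked in the
  tests against independent implementations (quadratic DP, and
  `Biostrings::pairwiseAlignment`-free oracles built in the test helpers).
* All probability arithmetic is in log space; the pipeline handles
  $p_i$ down to $10^{-300}$ and thousands of reads without underflow
  ($T$ itself may overflow to `Inf`; `log T` never does).
* Tie-breaks everywhere are deterministic (lexicographic or by abundance),
  so the whole pipeline is a pure function of the input read order - no
  seeds, no randomness.
* Reads containing ambiguity codes are dropped with a warning by default
  (`read_ccs_fastq(..., ambiguous = "mask")` instead replaces each with an
  uninformative base at error probability ~0.75). The behaviour is a policy
  choice; the upstream CCS pipeline rarely emits such reads.
* `tau` (candidates removed per filtering round) defaults to 10; the removal
  cap mainly smooths the re-assignment dynamics when many weak candidates
  coexist.

## Known limitations

* At the highest error rates the partition fragments: small groups of reads
  that are mutually closest converge to near-duplicate candidates
  (1-2 nt from a real transcript), and once a group is internally identical
  it can never rejoin another cluster (its members' nearest neighbors are
  each other, at distance 0). Recall is unaffected but precision at 6%
  error depends on the statistical stage, which removes most - not
  always all - of these near-duplicates, since a candidate is only tested
  against its closest neighbors.
* The group count is exact for the compatibility graph it is given, but
  transcript-to-transcript alignment in repeat-rich families can itself be
  ambiguous, and RNA editing or identical-exon copies bias the estimate in
  opposite directions.
* Exact-match evaluation gives no credit for almost-correct
  reconstructions; that is intentional (the package's purpose is
  nucleotide-exact transcripts) but worth remembering when comparing
  against tools scored with tolerant matching.
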