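---
title: "Genome-free miRNA discovery: models, parameters and design choices"
author: "mirfree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-free miRNA discovery: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirfree)
```

## The problem

Deep-sequenced small-RNA libraries from organisms without a reference genome
cannot be annotated by mapping. `mirfree` implements a discovery pipeline
that works from the reads themselves: unique sequences are collapsed,
filtered and clustered into end-variant families; known miRNAs are called by
per-family sequence profiles; miRNA\* (star) sequences by alignment against
mature-masked hairpin references; structural RNA, piRNA-like and
endosymbiont fragments are removed by exact matching against contaminant
sets; the remaining abundant sequences form a similarity network whose
communities define non-redundant novel candidates; candidates are validated
on assembled contigs by hairpin folding and miRNA:miRNA\* duplex calling;
and the accompanying statistics (Shannon library diversity, read-count vs
qPCR correlation, an efficiency-corrected knockdown randomization test)
quantify what the sequencing data can and cannot support. The motivating
system is a pair of insect libraries — one whole-body, one ovary — from a
hemimetabolan species with no sequenced genome.

## Pre-processing

Reads are stored internally in the DNA alphabet (`U` normalized to `T`) and
collapsed to unique sequences with per-library counts. Filtering applies,
in order:

* a **length floor** of 19 nt (`min_length`),
* an **ambiguity limit** of zero `N` residues (`max_ambiguous`),
* a **read-count floor** of 6 (`min_count`): the "more than 5 reads" rule
  read strictly. Both the strict and the inclusive convention are one
  parameter away.

The count floor applies to the library being filtered; libraries are
filtered independently and merged afterwards. A 36-nt artefact class with a
U-rich 3'-terminal decanucleotide is flagged by an inclusive threshold
(`u_fraction >= 0.5` of `T` in the last 10 nt), inclusive because observed
artefact tails sit barely above one half uracil.

## Sequence similarity and clustering

All pairwise comparisons use one fixed local-alignment scoring scheme:
match +1, mismatch −1, gap −2 (linear). Two derived quantities drive every
decision:

* **identity** — matches over aligned columns, gap columns included;
* **coverage** — the fraction of the *shorter* sequence covered by the
  aligned span. The shorter-sequence convention is a deliberate choice: the
  objects being clustered are 5'/3' length variants of one miRNA, and a
  trimmed variant fully contained in a longer one should count as covered.
  At equal lengths the larger of the two spans is used, keeping the measure
  symmetric.

Variant clustering is single linkage over all pairs at ≥ 90% identity and
≥ 80% coverage; the representative of a cluster is its most abundant member
(ties: lexicographically smallest sequence). Single linkage mirrors the
transitive behavior of the classical clustering tools for this task, and
makes the partition independent of input order. Where the original
protocol used an e-value cutoff (a database-size-dependent quantity that is
not reproducible outside the original search engine), edges additionally
require an aligned span of ≥ 16 columns — a deterministic equivalent at
miRNA lengths.

An 8-mer sharing pre-filter restricts which pairs are aligned. At
identity ≥ 0.9 over ≥ 16 columns a shared exact 8-mer is guaranteed
(pigeonhole on at most one edit per 16 columns), so the pre-filter cannot
change the result; the brute-force all-pairs oracle in the test suite
verifies this.

## Known-miRNA annotation

Each known family is summarized by a position-specific scoring matrix
built from its aligned members: per column,
`score(b) = log2(((n_b + 0.25) / (N + 1)) / 0.25)` — observed frequency
with a pseudocount of 0.25 per base, against a uniform background. The
construction details are a package choice (the protocol being reproduced
states only that profiles were built), so the standard log-odds form is
used. Reads slide ungapped along the profile consensus over offsets
−3..+3 nt; identity is computed over the *compared* (overlapping)
positions, so an untemplated 3' addition hanging off the consensus end is
not penalized. A read is labeled at ≥ 90% identity; identity ties between
families go to the higher summed PSSM score. The offset range absorbs the
documented 5'/3' end heterogeneity of miRNA processing.

Star detection aligns the full read (global on the read, local on the
reference) against hairpin references whose mature interval has been
replaced by `N`. `N` matches nothing — not even another `N` — so a read
lying inside or straddling the mask fails the 90% identity requirement
simply by arithmetic.

Contaminant labeling is exact: ≥ 95% of the read must occur verbatim
(either strand) in the contaminant set. Multi-set hits resolve by the fixed
precedence rRNA > tRNA > snRNA > piRNA/transposon > endosymbiont,
reflecting that structural RNAs are removed before miRNA calling. The same
matcher, against other-species small-RNA sets, separates **conserved** from
**specific** candidates (100% identity, 95% coverage).

## The candidate network

Unassigned sequences with ≥ 100 total reads (inclusive) are the candidate
set. The network is built on these *sequences* — not on the cluster
representatives — because the redundancy structure the community analysis
is meant to resolve (hundreds of end variants of a single dominant
candidate, connected through intermediate variants) only exists at the
sequence level; each sequence inherits its cluster representative's
annotation for the exclusion of known/contaminant material. Edges require
90% identity and 95% coverage (span ≥ 16), unweighted: the protocol defines
links by threshold, not by weight.

Modularity follows `Q = sum_i (e_ii − a_i^2)` with `e_ii` the fraction of
edges inside community `i` and `a_i` its fraction of edge endpoints.
Community detection is the agglomerative fast-greedy scheme: start from
singletons, repeatedly merge the connected pair with the largest `dQ`
(`dQ = e_ij/m − 2 a_i a_j`; ties broken by the smallest community-id pair,
community ids being the smallest member node index), and return the
partition of maximal Q along the merge path. Merging runs per connected
component; Q is reported over the whole graph. Within-development
cross-checks against an independent library implementation and against
exhaustive partition search on bridged two-clique graphs (≤ 10 nodes) pin
both the Q bookkeeping and the tie-break behavior.

The largest component is always partitioned by the greedy algorithm; each
smaller component is kept as one cluster unless its own partition reaches
`Q > 0.3` (`q_threshold`), generalizing the original analysis, which
applied modularity only to the major component and treated the remaining
"obvious clusters" as units. One representative per community (most
abundant member, lexicographic ties) yields the non-redundant candidate
table, with community counts summed.

## Precursor discovery on contigs

Candidates map to assembled contigs by exact substring search on both
strands (default); an identity ≥ 0.95 local-alignment mode exists for noisy
contigs. A contig qualifies for folding only if it carries two *distinct*
candidates at strictly non-overlapping positions — "different regions" is
not quantified in the source protocol, and strict non-overlap is the
documented choice.

Folding is base-pair maximization (Nussinov-style dynamic programming) with
A-T, G-C and G-T wobble pairs and a minimum loop of 3 nt, with a
deterministic traceback (position *i* pairs with its smallest admissible
partner). This replaces a thermodynamic folder on purpose: it is
dependency-free, exactly reproducible, and preserves the decision structure
the pipeline needs — paired arms, a loop, and pairedness thresholds — at
the cost of not modeling stacking energies. An externally computed
dot-bracket string can be supplied instead (`structure =`), restoring a
thermodynamic model where one is available.

The **arms** of a fold are defined through its longest stem chain: the
longest run of nested pairs in which each pair has exactly one child pair
(bulges allowed; branching ends a chain). The chain's outer pair bounds the
arms, its inner pair closes the loop. This definition was chosen over
"stem around the largest hairpin loop" because maximal pairing of a real
contig routinely folds small spurious hairpins inside the true loop and
multiloops inside the stem, which break loop-based definitions.

A duplex verdict requires one hit ≥ 80% inside the 5' arm, another ≥ 80%
inside the 3' arm (distinct candidates, non-overlapping), and ≥ 60% of each
hit's positions paired to positions of the other hit. The 0.8 and 0.6
thresholds are documented knobs (`min_arm_frac`, `min_pairing`); the source
protocol gives none.

## Statistics

* **Shannon diversity**: `H' = −sum p_i ln p_i` over per-sequence read
  proportions, natural log (the classical convention; the base is a
  parameter).
* **Reads vs qPCR**: Pearson correlation on miRNAs with *more than* 100
  reads (strict, `min_reads = 101`; the candidate-definition filter "at
  least 100" is inclusive — both phrasings are taken literally and both are
  parameters), with two-sided significance from
  `t = R sqrt((n−2)/(1−R^2))` on `n−2` degrees of freedom.
* **Knockdown validation**: the efficiency-corrected expression ratio
  `E_t^(dCt_t) / E_r^(dCt_r)` (`dCt` = mean control − mean treated), with a
  pair-wise fixed-reallocation randomization test: target and reference Ct
  values stay paired within a sample while group labels are permuted;
  the two-sided p-value is the fraction of reallocations with `|log ratio|`
  at least the observed. Reallocations are exhaustive up to
  `n_randomizations` (default 10,000), sampled beyond. The reallocation
  unit is the sample, not the individual Ct replicate — the source protocol
  does not specify, and permuting samples preserves the pairing that the
  ratio depends on. Amplification efficiencies default to 2.0 (perfect
  doubling) and are configurable per gene.

With three replicates per group the exhaustive test has 20 reallocations
and, because complementary label swaps give the same `|log ratio|`, its
smallest attainable p-value is 0.1; small studies cannot reach p < 0.05 by
this test regardless of effect size. The simulated knockdown experiment
therefore uses six replicates per group (924 reallocations).

## The synthetic-data generator

The generator plants ground truth with the statistical structure the
analysis assumes:

* **Hairpins**: 60–120 nt precursors containing a perfect inverted repeat
  (mature arm 21–23 nt, star arm its reverse complement, loop 8–15 nt,
  flanks 3–8 nt), each verified to fold with arm pairedness ≥ 0.8 under the
  package's own folder. Three family tags: `known` (12 loci, each with a
  miRBase-style family alignment and a hairpin reference with mature
  coordinates), `novel_conserved` (8; the mature also appears in
  other-species sets) and `novel_specific` (16). The scaled-down locus
  counts keep the full suite fast while preserving the known : conserved :
  specific proportions of the motivating study.
* **Abundances**: per-locus power law, exponent 1.5, truncated to
  [150, 5×10^4] reads, times per-library multipliers. The floor of 150
  makes planted loci discoverable by the ≥ 100-read candidate rule — the
  planted novel hairpins model the *discoverable* loci of a real library,
  not its unbounded low-count tail — while the heavy tail still lets single
  loci dominate a library, as in the real data. Artefact and contaminant
  counts keep a floor of 1.
* **End heterogeneity**: 5' shifts in −2..+2 (mode 0.70 at 0), 3' shifts
  from the same distribution re-centered so emitted reads mode at 22 nt
  whatever the planted arm length (3' processing trims/extends toward the
  canonical length; this matches the observation that ~70% of abundant
  candidate sequences are 22 nt and calibrates the 21–23-nt read fraction
  of the whole-body preset to ~73%, inside the 72 ± 5 band, essentially
  independent of the seed), and one untemplated 3' addition with
  probability 0.2, base weights U 0.6 / A 0.3 / C 0.05 / G 0.05.
* **Artefacts and contaminants**: 36-nt reads with a U-rich 3'
  decanucleotide at 13% (whole-body preset) or 22% (ovary preset) of
  reads, nearly all singletons (unique artefact sequences are capped at
  5,000 to bound memory; the excess piles onto a few sequences);
  contaminant fragments (21–29 nt substrings of fabricated rRNA / tRNA /
  snRNA / piRNA-transposon / endosymbiont references) at sub-percent
  fractions.
* **Libraries**: the `whole_body` preset multiplies known loci ×20; the
  `ovary` preset multiplies conserved ×10 and specific ×20 — reproducing
  the known-enriched vs candidate-enriched contrast between the two
  motivating libraries.
* **Contigs**: each novel precursor embedded verbatim in a flanked contig
  (≤ 200 nt); decoys are dinucleotide-preserving shuffles of planted
  precursors, re-shuffled until no planted mature or star survives as a
  substring.
* **qPCR**: `Ct = baseline − log_E(abundance) + N(0, sd)` with a fixed-
  abundance U6-like normalizer; treated groups apply per-gene effect
  multipliers (a dicer-1-like knockdown halves every mature miRNA). At
  zero noise the model inverts exactly, making `R = 1` a closed-form check.

What the simulator does **not** model: per-base sequencing error,
assembly artifacts in contigs (planted precursors are exact substrings),
cross-mapping between paralogous families, adaptor remnants, and any
genome-scale background of unrelated transcripts. Passing the end-to-end
recovery tests therefore shows the pipeline's logic is correct under its
own assumptions — not that a real library of ~10^7 reads would yield the
same counts. The headline counts of the motivating study (tens of known
miRNAs, hundreds of candidates) depend on the full-depth libraries and a
contemporaneous miRNA reference release and are out of reach at this
problem size by design.

## Numerical and degenerate-input choices

* All interval arithmetic is 0-based half-open internally; reports are
  1-based inclusive where human-read.
* Threshold comparisons on identity, coverage, counts and the U-fraction
  are inclusive (`>=`), except the two "more than" rules read strictly from
  their phrasing (read-count > 5; qPCR filter > 100 reads).
* Ties are always resolved deterministically: representatives by count then
  lexicographic sequence; `dQ` by smallest community-id pair; traceback by
  smallest pairing partner.
* Degenerate inputs fail loudly (empty read sets, edgeless graphs for
  modularity, all-zero counts, out-of-range folding lengths) or degrade
  with a warning where the result is still well-defined (edgeless
  components, contigs shorter than 40 nt, reads shorter than the artefact
  window).
* Every source of randomness flows from one integer seed through fixed
  derivations; all generator outputs are byte-identical across runs.

## Problem sizes

The default test and acceptance conditions use 36 planted hairpins across
two simulated libraries of roughly 0.5–1.5 million reads (collapsing to
~10,000 unique sequences each), 34 planted or decoy contigs, 2,000 null
randomization-test simulations and 200 folding-oracle trials — sizes chosen
so the entire suite and the acceptance script each run in minutes on one
CPU while every stage still sees the statistical structure it was built
for.

## Known limitations

* Base-pair maximization over-pairs relative to thermodynamic folding;
  arm pairedness values are optimistic, and the 0.6 inter-arm pairing
  threshold compensates only partially. Supplying external dot-bracket
  structures is the recommended route when a thermodynamic folder is
  available.
* Exact-substring contaminant matching cannot see diverged contaminants;
  it reproduces the original 100%-identity protocol rather than a
  sensitive homology search.
* The PSSM scan slides ungapped; an indel inside a read (rare in
  miRNA-length sequences) shifts identity down rather than being absorbed.
* Star detection requires hairpin references with mature coordinates;
  novel stars are discovered only through the candidate network and duplex
  calling, not by the masked-hairpin scan.
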