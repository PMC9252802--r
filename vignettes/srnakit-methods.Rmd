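---
title: "srnakit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{srnakit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnakit)
```

srnakit is a desk-scale toolkit for small RNA sequencing (miRNA-seq) data.
This vignette explains the statistical and algorithmic choices behind each
stage: what is computed, which constants matter, what the synthetic-data
generator does and does not emulate, and where the design was genuinely
open.

## Read model and collapsing

A small RNA read is a short insert (typically a 20–24 nt mature miRNA or a
fragment of another small non-coding RNA) followed by a ligated 3' adapter
that the sequencer reads through. Some library preparation kits additionally
place randomized nucleotides (commonly 4 on each side, "4N" protocols) between
insert and adapter to reduce ligation bias. Because small RNA libraries are
highly redundant, all computation after loading happens on *collapsed reads*:
unique sequences with a multiplicity count, ranked by abundance
(ties broken lexicographically so every ordering is reproducible). Quality
values are not used beyond an optional mean-quality cutoff, off by default;
the downstream statistics operate on counts, not qualities.

## Automated protocol detection

Detection proceeds in five steps and reports one of four statuses
(`already_trimmed`, `detected`, `guessed`, `failed`):

1. **Trimmed-input check.** Raw runs have an (almost) constant machine read
   length, while trimmed input shows the insert-length distribution. The
   input is called trimmed when the modal length holds less than 90% of the
   reads, or when the modal length is below 30 nt (raw small RNA runs are
   sequenced at 36 nt or more). The two constants are deliberately
   conservative: a raw run with up to 10% length-trimmed stragglers is still
   treated as raw.
2. **Catalogue probing.** For every adapter in an editable catalogue
   (`inst/extdata/adapters.tsv`: kit name, 3' adapter, declared randomized-end
   lengths) the first 12 nt of the adapter are searched exactly in each read,
   requiring at least 15 nt of insert before the hit. An adapter is accepted
   when it occurs in **more than 50%** of the reads
   (multiplicity-weighted) *and* the adapter-trimmed inserts contain at
   least **20% of the miRNA complement** — the fraction of *distinct* mature
   sequences of the species found as exact substrings, not the fraction of
   reads, so a library dominated by two miRNAs cannot fake coverage. The
   12 nt exact probe tolerates no mismatches; sequencing-error tolerance is
   delegated to the 50% read-fraction criterion instead of fuzzy matching.
   Coverage is computed on the un-stripped trimmed insert: stripping declared
   randomized ends before a substring search could cut into the mature when
   the declared lengths do not match the actual protocol, and the actual
   lengths are inferred in steps 4–5 anyway.
3. **Guess-adapter fallback.** If no catalogue entry passes, the adapter is
   guessed by a k-mer vote: among the 1000 most abundant reads (after
   removing low-complexity reads, which carry no adapter signal and would
   otherwise flood the vote with mononucleotide k-mers), all 12-mers starting
   at offsets 18–26 — the plausible 3' ends of a mature insert with up to a
   4 nt random prefix — are counted once per read. The winner is accepted if
   it occurs in at least 20% of the considered reads. Because a slightly
   3'-shifted adapter k-mer receives (nearly) the same votes as the true
   adapter start, the winner is then anchored by leftward extension: while
   the base immediately preceding the k-mer is near-unanimous (two-thirds
   weighted majority) across reads, it is prepended. Inside the adapter the
   preceding base is fixed; at the insert boundary it varies, so the walk
   stops at the true adapter start. The default offset window assumes at
   most 4 random 5' nucleotides; 4N-on-both-sides protocols with long
   inserts can place the adapter outside the window, which is why catalogue
   probing (step 2) — not the guess — is the intended path for such kits.
   Guessed calls are flagged as such.
4. **Mature anchoring.** Canonical mature sequences are located as exact
   substrings of the adapter-trimmed reads and the 5'/3' flank lengths are
   recorded, multiplicity-weighted.
5. **Randomized-length inference.** The modes of the two flank-length
   distributions are the randomized-end lengths. Modes are robust: an
   error inside the mature removes the read from the anchored set rather
   than shifting a flank, and an error inside a random flank leaves its
   length unchanged. Ties break toward the smaller length (conservative
   trimming), and fewer than 100 anchored reads yields (0, 0) with a
   low-support flag rather than a noisy estimate.

Trimming then cuts at the first probe occurrence with at least 15 nt of
insert, strips the inferred randomized ends, rejects reads without adapter
or shorter than 15 nt after trimming (tallied by reason), and re-collapses.
Counts are conserved exactly: kept plus rejected equals the input.

**Low-complexity filter.** The complexity ratio of a read is the fraction
of its most frequent nucleotide; reads with ratio **at or above 0.80** are
removed (the boundary is inclusive: a 10 nt read with 8 A's is removed).
Such reads map to very many loci and are almost always ligation or
synthesis artefacts.

## Full-length k-mismatch alignment

All mapping in the toolkit uses one contract: ungapped, full-length
alignment with at most *m* ∈ {0, 1, 2} substitutions, on both strands,
reporting *all* positions — the semantics of bowtie's `-v` mode, which the
conservation analysis is calibrated against. `N` never matches anything,
including another `N`; an undetermined base cannot be evidence of identity.

The implementation is seed-and-verify with a pigeonhole guarantee: a query
is partitioned into *m*+1 disjoint seeds of length
⌊min-query-length / (*m*+1)⌋, so every window within the mismatch budget
contains at least one exact seed. Exact seed lookups against a positional
k-mer table of the concatenated reference (records separated by a
non-nucleotide sentinel, so no hit can span records) produce candidate
offsets, which are verified by a vectorised Hamming count. The test suite
holds the implementation to a position-wise sliding-window oracle on every
instance, so any method passing the suite could be substituted. Multi-hit
reporting is exhaustive because the profiler's multiple-assignment policy
and the conservation matrix both need presence at *every* locus.

## Hierarchical profiling

Annotation libraries are scanned in a fixed, user-overridable order
(default: mature miRNA, hairpin, tRNA, further ncRNA classes, cDNA — the
hairpin directly after the mature so that precursor-only reads are labeled
`hairpin` rather than leaking into later classes). A read is assigned to
the first library it maps to and never reconsidered; classes are therefore
mutually exclusive, and permuting the tail of the order can never change
the counts of the classes before the permuted region. Orientation is
resolved per read: sense if any sense hit exists, antisense otherwise
(sense takes precedence because sense tables are the primary report).

There is no single accepted convention for multi-mapping reads within a
library, so both views are reported: the read's count is added to
*every* record it hits (multiple assignment) and, when it hits exactly one
record, also to that record's unique-mapper column. Downstream users choose
which column to trust. Per-class read-length distributions and the
count/RPM matrices (RPM = count × 10⁶ / total assigned reads of the
sample) are derived from the same result object, so totals always agree.

Microbial attribution (`microbes_profile()`) maps a read set — typically
the unassigned remainder of a profiling run — against each grouped
collection (one multi-FASTA per bacterial phylum or virus host group)
*independently*: a read may count toward several phyla, and the report
header states this. Percentages use the input to the attribution step as
denominator, and the residual is the percentage of reads hitting no
collection at all.

## BLAST species disambiguation

Short queries match many database entries with equal quality. From a
12-column tabular BLAST result the toolkit keeps, per read, only hits above
the 90% identity threshold that share the read's maximal bitscore
("highest score" is read as bitscore, the BLAST ranking convention, not
percent identity). Species are then ranked by the number of reads whose
kept set contains them (a species counts once per read), and each read is
assigned to its highest-ranked kept species, presenting that species' best
hit (bitscore, then identity, then first occurrence — fully deterministic
and invariant under permutation of the input lines). The threshold
comparison is strict (`>`) by default; the inclusive reading (`>=`) is a
flag, because the boundary sits exactly at a round number users may
reasonably interpret either way. The ranking is computed once, not
re-estimated iteratively after assignment: the procedure is two sequential
passes, not an EM loop.

One subtlety uncovered by testing: per-species assigned counts are *not*
monotone in the identity threshold, because raising it can remove a read's
top-bitscore hit and promote a hit of a different species. Monotonicity
holds at the identity-filter stage (survivor sets only shrink) and for the
total number of reads retaining a presented hit; the test suite asserts
exactly those two properties.

## Positional target consensus

The position-free consensus of several target-prediction methods is the
intersection of their (miRNA, transcript) pair sets. The positional
consensus additionally demands spatial agreement. "All methods predict an
overlapping interaction in the same region" is formalized as: a consensus
site is a **maximal run of transcript positions covered by at least one
predicted site of every selected method**. This is equivalent to the union
of the common intersections over all one-site-per-method tuples (which the
test oracle enumerates exhaustively), it is canonical, and it is invariant
under permutation of methods and of sites — properties a greedy
left-to-right chaining of raw sites does not have when same-method sites
nest. It is computed by interval algebra: per-method union of sites, then
intersection across methods. A relaxed `pairwise` mode (merged runs of the
pooled sites that contain at least one site of every method, i.e. chained
overlap) is available behind a flag.

Each consensus row reports the consensus interval plus one member site per
method (the first, by start, overlapping the interval) with its
method-specific score; scores are deliberately *not* combined, since the
methods' scales are incommensurable. Coordinates in all input and output
tables are 1-based inclusive; converters to and from 0-based half-open
coordinates are provided and tested. The three output files are
`positionalConsensus.tsv`, `multipleTargets.tsv` (pairs with two or more
consensus sites) and `perTranscript.tsv` (all consensus sites per
transcript, sorted by position).

## Conservation depth

To estimate how widely a small RNA sequence is conserved, the non-redundant
query set (identical sequences collapsed, one id chosen as representative
by a seeded random draw — seeded so pipelines are reproducible, with the
seed recorded in the redundancy report) is mapped full-length against every
genome of a collection at 0, 1 and 2 mismatches, both strands. A single
scan at the largest level yields the minimal mismatch count per
(sequence, genome); presence at smaller levels follows by monotonicity
without re-scanning. Two reports are derived: conservation depth per
sequence (percentage of genomes containing it) and coverage per genome
(percentage of query sequences present). Percentages are written with one
decimal place; internal values keep full precision.

Very short queries are expected to produce chance hits; each genome's
coverage row therefore carries an informational expected random-hit
probability, `1 − (1 − 0.25^L)^(2G)` for mean query length `L` and genome
length `G` — the probability that an unrelated random sequence of that
length appears somewhere on either strand of a random genome of that size.
It is a calibration aid, not a correction. Seed-region-aware miRNA homology
is out of scope.

## Synthetic data: what it emulates, and what it does not

The generator produces, deterministically per seed: a uniform-random toy
genome; a planted miRNA complement (non-overlapping 20–24 nt matures inside
longer hairpin windows, coordinates recorded 0-based half-open); and reads
assembled as `rand5 + insert + rand3 + adapter`, padded with random bases
to the machine read length (51 nt by default), or the bare insert for
pre-trimmed protocols. Expression across matures is log-normal
(meanlog 2, sdlog 1) — a generic heavy-tailed model chosen because real
miRNA expression spans orders of magnitude; no specific distribution is
prescribed by the problem. Errors are i.i.d. per-base substitutions (1% by
default); there are no indels, matching the ungapped alignment contract.
Junk reads are mononucleotide runs with at most 10% foreign bases, so they
always sit at or above the 0.8 complexity boundary. Contaminant reads are
windows of a second genome on either strand. Default study conditions used
across the test suite: 20,000 reads (50,000 for profiling mixtures), 30
matures on a 50 kb genome, 20% junk, 1% error.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: position- and motif-dependent error profiles,
ligation bias, isomiR end-heterogeneity, quality-score structure, adapter
dimers, repeat-rich or GC-skewed genomes (real junk and multimapping are
harder), and cross-hybridizing paralogue families beyond what random
sequence produces. The tests demonstrate correctness of the algorithms
under their stated model, not field performance on any particular
instrument or organism.

## Problem sizes and numerical choices

The suite runs the protocol grid (four randomized-end configurations × two
adapters × three seeds at 20,000 reads each), a 500-query oracle comparison
against a 50 kb genome at all three mismatch levels, and 50,000-read
profiling mixtures; these sizes give binomial sampling errors well inside
the asserted tolerances (for a 10% class at n = 30,000, the standard error
is 0.17 percentage points) while keeping a full run in the order of a
minute. All randomness is routed through explicit seeds; ties anywhere
(collapsing order, mode inference, k-mer votes, species ranking, member
selection) are broken by fixed deterministic rules, so every pipeline stage
is bit-identical across runs with the same inputs — itself an asserted
property of the suite. Degenerate inputs (empty read sets, empty libraries,
empty consensus) either return well-defined empty results or raise errors
where a statistic would be undefined (e.g. complement coverage without a
miRNA complement, genome distribution of zero reads).

## Known limitations

* The aligner targets desk-scale references (collections of libraries and
  toy genomes up to a few megabases); it is exact but not tuned for
  mammalian-genome indexes.
* Protocol detection assumes 3'-adapter protocols; 5'-adapter ligation and
  UMI-based deduplication are out of scope (randomized nucleotides are
  trimmed, not used for deduplication).
* The guess-adapter window assumes inserts of roughly mature length; long
  inserts with double-sided randomized ends need catalogue probing.
* Differential expression is deliberately not included; count and RPM
  matrices are exported for established downstream tools.
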