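---
title: "Methods: patching draft assemblies with corrected long reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: patching draft assemblies with corrected long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
# Alignment-backed examples need NCBI BLAST+ on the PATH; the vignette is
# shipped as source and its chunks are display-only.
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the data model

A draft microbial assembly built from short reads is typically correct
at the base level but structurally deficient in three ways: it is
fragmented wherever a repeat exceeds the read length, it may contain
N-gaps (runs of unknown bases inside scaffolded contigs), and it may
contain chimeric contigs (two loci wrongly concatenated) and redundant
contigs (sequences almost entirely contained in others). Corrected
PacBio long reads (CPBLRs) — kb-scale reads whose residual error rate is
on the order of 0.01% after short-read correction — are long enough to
span kb-scale repeats and accurate enough that exact substring matching
and near-exact alignment are meaningful operations on them.

`asmpatch` represents all sequences uniformly as a `seq_set`: a data
frame of `id`, `seq`, `origin` (`"contig"` or `"cpblr"`) and `length`.
All interval coordinates in the package are 0-based, half-open.
Pairwise alignment is delegated to NCBI `blastn` (megablast task,
dust/soft-masking off, single thread); hits are parsed into a normalized
table with strand-aware coordinates, the trivial full-length self-hit
removed and non-trivial self-hits (internal or inverted duplications)
retained.

## Stage 1 — assembly modification

**Gap filling.** Each maximal N-run in a contig defines a gap with two
100-bp flanks (`flank_len`). A long read *spans* the gap when both
flanks occur in it (either orientation) exactly once, right flank
downstream of the left; flank search is exact-match first, with an
alignment fallback at `flank_identity` (0.9) guarded by an exact-anchor
pre-check for speed. The substrings between the flanks are grouped by
exact equality, and the gap is replaced by the most frequent substring
only when its count is at least `min_votes` (3, i.e. "more than two")
and strictly exceeds the runner-up; ties and thin evidence leave the gap
untouched. Gaps are processed right-to-left so coordinates stay valid,
and a winning empty substring closes the gap to a direct junction.

**Zero-coverage splitting.** When raw short reads are supplied, each
read is placed at every position of every contig where it matches
exactly (either strand); chimeric junction sequence exists in no real
read, so it acquires zero depth. Contigs are split at interior
zero-depth runs, with two exemptions: runs inside the terminal
`end_fraction` (1%) windows are ignored (coverage legitimately tapers at
contig ends), and split pieces shorter than `min_segment` (50 bp) are
discarded. Gap filling runs before coverage so reads are placed against
real sequence rather than N-runs.

## Stage 2 — representative selection

When an expected genome size is known, the read pool is first reduced to
the longest reads whose cumulative length reaches `depth_factor` (15)
times the genome size. Contigs and reads are then passed through a
greedy longest-first selection: the longest remaining sequence becomes a
representative, and every remaining sequence whose containment in it —
alignment rate (interval-union of its aligned bases divided by its
length) and length-weighted identity — are both strictly above 0.95 is
removed and recorded as *delineated* by that representative. Removal is
a partition: every input is either a representative or delineated by
exactly one representative, which stage 3 exploits for rescue.

*Design note:* the all-vs-all alignment is computed once up front and
the greedy loop reuses it, instead of re-aligning after each selection.
With alignments restricted to `min_aln_len` ≥ 100 at ≥ 0.9 identity the
hit table is stable under removal, so the result is identical and the
cost drops from O(k) aligner invocations to one.

## Stage 3 — iterative connection

The connection stage maintains a *pool*: the current sequences, a
per-sequence layout tracing every base to an input, and a table mapping
each sequence end to the container and container-end where it now sits.
Joins orient the two containers head-to-tail, splice in the bridging
read's inter-alignment substring (or trim the mutual overlap from the
shorter container when the two target alignments overlap on the bridge),
consume the two joined ends, and retire the bridge from the pool.

- **Strict bridging.** A pool sequence is a strict bridge when each of
  its ends has a unique best end-to-end overlap — best at least
  `uniq_ratio` (1.25) times the second best — and the two targets are
  distinct, at least one being a contig. Applied longest-bridge-first,
  recomputing the overlap graph after every round, to a fixpoint.
- **Repeat-size estimation.** The pool is self-aligned and the longest
  alignment that is neither a proper dovetail nor part of a containment
  pair (nor the trivial self-hit) is taken as `max_repeat` — the longest
  stretch that could mislead an end-to-end join.
- **Easy bridging and rescue.** Reads longer than `max_repeat` whose
  ends each overlap exactly one contig (distinct contigs, no second
  partner tolerated) are applied as easy bridges. Unused representative
  reads then get a second chance through the reads they delineated in
  stage 2, which re-enter as easy-bridge candidates under the same
  gates.
- **Merging.** Contigs sharing a reciprocal-best dovetail longer than
  `max_repeat` are joined directly, the overlap trimmed from the
  shorter sequence.
- The estimation/easy/rescue cycle repeats (up to `max_iter`) while it
  keeps reducing the number of free ends — each applied join strictly
  decreases them, which is the termination witness. Reads never used as
  bridges are dropped from the assembly and logged.

Dovetail classification itself is geometric: an alignment is an
end-to-end overlap when it reaches within `max_overhang` (50 bp) of
exactly one end of each sequence, with compatible ends for its strand,
and is at least `min_overlap` (200 bp) long. These two constants, the
per-stage identity floors (0.95 contig-vs-contig, 0.90 when a read is
involved) and `min_aln_len` (100 bp) are this implementation's own
defaults; all other constants above belong to the reference procedure
the package implements. Everything
is collected in `patch_config()` and overridable.

## Synthetic scenarios and validation

The generator is a first-class module. `sim_scenario()` fixes a seed
and the scenario shape; `simulate_genome()` plants repeat families
(copies mutated down to a target identity, placed ≥2 kb apart);
`fragment_assembly()` cuts the genome at repeat loci (withholding repeat
interiors, as a short-read assembler would), plants mid-contig N-gaps
and concatenates chimera pairs with a 30-bp random spacer — clean
concatenation would leave no zero-coverage witness under exact read
matching, so the spacer is what makes the chimera detectable, and it is
checked to occur nowhere in the genome. `simulate_cpblrs()` draws
uniform starts with truncated-normal lengths and plants substitutions
and single-base indels at the residual error rate (default 1e-4);
`simulate_short_reads()` draws error-free fixed-length reads. Each
component uses a sub-seed derived from the scenario seed, so adding
reads does not perturb the genome. All truth (repeat loci, contig
placements, gap sequences) is returned alongside.

Validation is oracle-based: the blast-backed aligner is checked against
a Smith–Waterman oracle on planted-block instances; dovetail
classification against an exhaustive geometric oracle on random hits;
representative selection against an independent brute-force greedy
re-implementation; assemblies against the truth genome via
`check_misjoins()`, which chains colinear alignments (consistent strand,
monotone coordinates, bounded diagonal shift) and requires one chain to
cover ≥98% of each output sequence. Conservation is asserted
throughout: layout tiles rebuild every output byte-exactly, the N count
never increases, and free ends strictly decrease per join.

Problem sizes in the tests (a 200-kb reference scenario with three 4-kb
repeat families, and 40–60-kb scenarios elsewhere) are chosen so the
full suite runs in minutes on one CPU while still exercising repeats
longer than typical reads, gap filling, chimera splitting and every
bridging mode; they are this package's own choice, not a claim about
real genomes.

## A complete run

```{r example}
library(asmpatch)
sc <- sim_scenario(seed = 1, genome_len = 200000,
                   repeat_specs = data.frame(length = rep(4000, 3),
                                             copies = rep(2, 3),
                                             identity = rep(0.98, 3)),
                   n_gap_specs = data.frame(contig = 2, length = 300),
                   chimera_specs = list(c(4, 6)))
g   <- simulate_genome(sc)
fr  <- fragment_assembly(g$genome, g$truth, sc)
lr  <- simulate_cpblrs(g$genome, sc)
sr  <- simulate_short_reads(g$genome, sc)
res <- patch_assembly(fr$contigs, lr$reads, reads = sr,
                      genome_size = sc$genome_len)
res$stats                                  # 6 contigs -> 1 sequence
check_misjoins(res$records, g$genome)      # chain_cover 1, clean TRUE
```
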