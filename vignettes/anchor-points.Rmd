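---
title: "Detecting consistent anchor points for multiple sequence alignment"
author: "ms4anchors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting consistent anchor points for multiple sequence alignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ms4anchors)
```

## The problem

Global multiple-alignment programs can be steered with *anchor points*:
positions the aligner is told to place in the same column.  Good anchors
— genuine multiple local similarities — improve accuracy, especially on
sequences of unequal lengths; bad anchors, in particular anchors that
contradict the left-to-right order of the sequences, can wreck an
alignment.  This package detects candidate anchors from unaligned
sequences, certifies (or restores) their mutual order-consistency, and
writes them in the formats consumed by anchor-aware aligners (ClustalW
via BALLAST-style files, DIALIGN's anchor option, T-Coffee library
files).

## Sites, columns, consistency

The *site space* of `n` sequences is the set of positions `(i, p)`
(0-based internally; every exported format is 1-based).  A set of sites
is *ambiguous* if it contains two positions of the same sequence — an
internal repeat, which can never appear as one alignment column.  A
non-ambiguous site set is a *partial alignment column*.  A collection of
partial columns is *consistent* when the joint order generated by column
co-membership and the per-sequence successor order still restricts to
the plain left-to-right order on every sequence; only consistent
collections can be embedded in a multiple alignment.

## N-local decoding and the MS4 selection rule

Candidate columns come from *N-local decoding* (NLD): fix a word length
`N`; whenever the identical length-`N` word occurs at several places in
the sequence set, the corresponding positions at equal offsets inside
the word are directly related, and the partition `nldPartition()`
returns is the transitive closure of that relation.  Chaining through
overlapping occurrences lets a class tolerate an unspecified number of
mismatches without any score matrix or fixed window.  The implementation
hashes all words of length `N` and merges offset positions with a
union-find structure; a linear-time algorithm exists but is unnecessary
at the scale this package targets, and the output is verified in the
test suite against an explicit build-the-relation-then-close oracle.

Decodings for successive `N` are nested: sharing a word of length `N+1`
implies sharing its length-`N` prefix at a consistent offset, so each
class of level `N+1` sits inside one class of level `N`.
`buildPartitionTree()` stacks the levels into a tree whose root is the
whole site space.  `nldAll()` stops at the first level where every class
is a singleton (deeper levels cannot merge anything), at the longest
sequence length, or at an explicit cap.

The *MS4 rule* (`selectColumns()`) picks the topmost non-ambiguous
frontier of that tree: nodes that are non-ambiguous while their direct
ancestor is ambiguous.  Descendants of a selected node are never
selected, so the output columns are pairwise disjoint.  Two filters
apply:

* `sMin` (default **6**): a column must span at least `sMin` distinct
  sequences.  Benchmarks across alignment families show raw MS4 columns
  hurt below about 5 spanning sequences and help above; 6 is a good
  overall setting, and the threshold is fully user-controllable.
* singleton frontier classes are discarded even when `sMin` would allow
  them — a one-site column constrains nothing.  (Whether such
  singletons should count is genuinely open; discarding them is this
  package's choice.)

## Restoring consistency

MS4 columns exclude internal repeats by construction, but *global*
order-contradictions remain possible (two sequences can carry two
columns in opposite orders).  `buildSuccessionGraph()` encodes the
evidence: an edge `C -> C'` weighted by the number of sequences in which
`C` lies left of `C'`, plus marker vertices `v_start`/`v_end` wired to
the columns that are leftmost/rightmost somewhere.  A column set is
consistent iff this graph is acyclic (`isConsistent()`).

`dagify()` breaks cycles with a weight-threshold heuristic for the
(NP-hard) minimum weighted feedback arc set: find the smallest `k*` such
that keeping only inter-column edges of weight `> k*` is acyclic —
majority evidence survives, minority evidence goes.  Numerical choices:

* **`k* = 0` is admitted.**  An already-acyclic graph is returned
  untouched.  Filtering weight-1 edges out of a consistent graph would
  only weaken the induced order and cause needless site loss, so the
  threshold search starts at 0, and the consistent-input path is the
  identity.
* Edges incident to the markers are never removed, and after filtering
  the graph is reconnected (`v_start -> u` for predecessor-less columns,
  `u -> v_end` for successor-less ones) so every column stays on a
  start-to-end route.

Deleting an edge does not by itself say which *sites* to delete.
`resolveColumns()` takes the transitive closure of the dagified graph
and, for each sequence independently, keeps the longest chain of its
columns that the closure order accepts in the sequence's own
left-to-right order; every column off the chain loses its site in that
sequence.  Because each sequence reads only the closure and its own
site order, the processing order of sequences is immaterial (the
`sequenceOrder` argument exists purely to demonstrate this).  Columns
reduced below 2 sites are dropped; the spanning threshold is *not*
re-applied after trimming, since a trimmed column that still pairs two
sequences remains an informative anchor.  The succession graph of the
output is acyclic by construction — every surviving transition embeds in
the closure of a DAG — and the package asserts this after every run.

Tie-breaking among equal-length chains (on which the method is
otherwise silent) is deterministic: prefer the chain whose columns carry
the most sites in the input set (minimising expected loss and favouring
widely-shared columns), then the lexicographically smallest column-id
sequence.  Other implementations may legitimately differ on exactly
tied instances.

## Anchor files

Aligners consume pairs of matching segments, so `extractSegments()`
unrolls the columns: for each sequence pair, every maximal diagonal run
of positions that are column-co-members (consecutive pairs may come from
*different* columns) becomes one segment.  `weightSegments()` implements
the two published schemes: `length10` (weight `10 * length`, for
ClustalW/DIALIGN anchors) and `tcoffee_uniform` (a uniform `100 * M`
with `M` the number of sequences, for T-Coffee libraries).  Three
writers emit DIALIGN anchor lines, a BALLAST-style list, and a
`TC_LIB_FORMAT_01` library; all are deterministic and golden-file
tested.  The BALLAST grammar is not publicly standardised, so that
writer freezes a documented dialect (header `QUERY <id>`, then
`idA idB startA startB length weight` records) and is isolated in one
function should a dialect fix ever be needed.

## Scoring alignments

`spScore()`/`tcScore()` compare a test alignment with a reference over a
core-column mask: SP is the fraction of reference core residue pairs
reproduced, TC the fraction of core columns reproduced entirely (one
misplaced residue zeroes a column).  `alignmentSpecificity()` swaps the
roles of test and reference — the proportion of *correct* pairs/columns
among those the test aligns — transporting the mask onto the test as the
set of test columns containing at least one core residue.  Masked
reference columns count in the TC denominator regardless of gap content
(with `core = "all"`, columns with fewer than two residues carry no
constraint and are skipped); how reference core columns containing gaps
should be treated is not standardised, and this rule is this package's
documented choice.

## The synthetic generator

`generatePlanted()` builds seeded fixtures: i.i.d. background residues
(20-letter protein or 4-letter DNA alphabet) with exact motif copies
planted non-overlapping in their carrier sequences, and optional *swap
directives* that transpose two motifs in chosen sequences, creating
exactly the minority-order conflicts the consistency engine removes.  A
rejection-sampling screen (capped at 50 retries) re-draws a sequence
when any motif occurs away from its planted offsets, and the ground
truth is computed from the final sequences, so tests never chase phantom
columns.  What the generator does *not* emulate: substitutions and
indels inside motif copies, compositional bias, and homology detectable
only through mismatches — passing the recovery battery therefore shows
the machinery is correct on exact repeats, not that MS4 finds every
biologically meaningful similarity in real protein families.

## Problem sizes and verification

The test suite validates each stage against an independent oracle at
sizes chosen to keep full enumeration honest: the NLD partition against
an explicit relation-closure oracle on 200 random sets (up to 8
sequences of up to 40 residues over alphabets of 2, 4 and 20 letters, at
every feasible `N`); consistency against a Warshall-closure oracle on
exhaustive two- and three-sequence instances plus 500 random sets;
resolution for acyclicity, idempotence and order-independence on 500
random (frequently cyclic) sets; the scorers against brute-force pair
enumeration on 100 random alignment pairs; and a 20-seed planted-motif
battery (4 sequences of 80-120 residues, two 8-mers) for end-to-end
recovery.  `scripts/acceptance.R` re-runs the pipeline quantities from
scratch under a caller-supplied seed.

## Known limitations

* The feedback-arc heuristic is deliberately simple; a lighter edge set
  (and fewer lost sites) could sometimes be found by exact or more
  refined methods.  Contradicting columns are trimmed, never split into
  separately consistent sub-columns.
* MS4 matches words exactly; ambiguity codes (`X`, `N`) are ordinary
  symbols.  Divergent homologies without exact shared words are
  invisible to the detector (the consistency engine, however, accepts
  partial columns from any external detector via the column text
  format or the `consistify` subcommand).
* Single-sequence input parses fine but yields no multi-sequence
  columns.
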