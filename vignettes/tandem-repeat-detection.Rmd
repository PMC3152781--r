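---
title: "Detecting and summarizing tandem repeats with trscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and summarizing tandem repeats with trscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trscan)
```

## The problem

Tandem repeats (TRs) — two or more adjacent, approximately identical
copies of a nucleotide unit — cover a substantial fraction of most
eukaryotic genomes, from mononucleotide microsatellites to minisatellites
with units of hundreds of base pairs.  Comparing repeat landscapes across
genomes, or between genomic regions (coding sequence, introns, UTRs,
intergenic DNA), needs a detector whose inclusion rule is explicit and
identical everywhere: which imperfect arrays count as repeats, how
imperfection is penalized, and how competing interpretations of the same
locus are ranked.  `trscan` implements such a detector together with the
canonicalization, density statistics, annotation stratification and
synthetic-data machinery needed to run and validate a complete survey.

## The scoring model

A candidate repeat is evaluated by aligning its region against a perfect
tiling of its unit.  Columns score: match `+1`, mismatch `-5`, gap `-5`,
N `0` (all configurable via `scoring_scheme()`).  The first repeat unit
of every TR is not scored, so a perfect array of unit size $p$ and total
length $L$ scores $L - p$.  A repeat qualifies when its score reaches 12
for unit sizes up to 12 bp, or the unit size itself for larger units.
Two consequences are useful sanity checks because they are forced by the
arithmetic alone: the smallest qualifying perfect mono-, di- and
trinucleotide repeats are exactly 13, 14 and 15 bp, and for unit sizes
above 12 bp a perfect repeat must be at least two units long.

```{r thresholds}
find_repeats(strrep("A", 13))[, c("start", "end", "unit", "score")]
nrow(find_repeats(strrep("A", 12)))
```

Imperfections are explored with two bounds taken from the standard
configuration of this kind of search: a *recursion depth* of five — at
most five consecutive edit columns (mismatch, insertion or deletion)
before a match or N column must resume — and a *maximum score reduction*,
an X-drop rule that abandons an extension direction once the running
score falls a fixed amount below the best score seen on that side.  The
short-range preset (units 1–50 bp) leaves the reduction unlimited; the
long-range preset (units 1–4000 bp) caps it at 30, trading a small amount
of sensitivity for tractable genome-scale scans.  At most four successive
unknown bases (Ns) are allowed inside a repeat; N columns score 0.

### Model details the scoring rules do not fix

The inclusion rule above leaves several alignment-level details open; the
package pins them down as follows, and both search routes (the production
detector and the exhaustive test oracle) implement exactly these rules:

* **Anchoring.**  A hit starts with a perfect, fully matching first unit
  (the unscored one); its unit string is the sequence's own first $p$
  bases at the start position.  The first scored column and the last
  column of a hit are matches — trailing or leading edits can never raise
  the score, and N columns raise it by nothing.
* **N runs.**  The four-successive-N cap applies to consumed sequence Ns:
  a run of five Ns can never be crossed, not even by paying deletion
  columns to break up the N columns (a loophole the column-level reading
  would allow).
* **Ties.**  Among equal-score interpretations, the smaller unit size
  wins, then the leftmost start; for a fixed anchor, the shortest
  extension is reported.  An equal-score *leading* extension is therefore
  kept (leftmost rule), while an equal-score trailing one is not.  Among
  equal-score alignments of the same interval, the one with fewer
  columns, then fewer gap columns, is preferred, which makes the reported
  column counts deterministic.
* **Primitive units.**  Anchor units that are themselves periodic (like
  `ACAC`) are never used: the same hit anchored at the primitive period
  scores strictly higher, so every reported unit is primitive and no
  repeat is classified under several unit sizes.
* **Consensus.**  The reported unit of an imperfect hit is the
  per-position majority vote over its aligned copies, ties towards the
  alphabetically first base, in phase with the hit's start.

### Overlap resolution and alternative readings

All qualifying candidates are generated first; overlapping candidates are
then resolved by score (ties: smaller unit, leftmost).  Interpretations
that lose over the *identical* interval are kept in the winner's
`alternatives` column, together with the in-phase rescoring of the hit at
each proper divisor of its unit size whose identity stays above 50% — the
classic example being a perfect hexanucleotide that can also be read as
an imperfect dinucleotide:

```{r acacat}
find_repeats(strrep("ACACAT", 4))[, c("unit", "score", "alternatives")]
```

Densities are computed on the resolved (non-overlapping) hit set by
default so coverage can never exceed 100%; `find_repeats(resolve =
FALSE)` exposes the raw candidate set for sensitivity analyses.

## Search strategy and the independent oracle

The production detector seeds on maximal perfect tandem stretches of
length at least $p + \min(p, 4)$ and extends each seed in both directions
with a frontier dynamic program over (tiling phase, edit run, N run)
states, pruned by the X-drop rule when the maximum score reduction is
finite.  Any qualifying hit must contain a long perfect stretch — each
imperfection costs 5 while a match gains 1 — so seeding loses essentially
nothing; configurations that defeat it (a qualifying hit whose longest
perfect stretch is below the seed length, possible in principle for unit
sizes ≥ 4) require so many precisely placed edits that they do not arise
in random or planted data.  This is the one place the detector is not
provably exhaustive; it is why the package ships a second, independent
search route.

`naive_repeat_oracle()` enumerates *every* anchor position and unit size
and computes the optimal gapped alignment by the same dynamic program run
to completion, with no seeding and no X-drop.  It refuses sequences over
500 bp and unit sizes over 12 — it exists purely as a reference.  The
test suite holds the two routes to byte-identical output over a thousand
seeded random instances, half of them salted with near-threshold,
partially corrupted arrays so the agreement is tested where it is hardest.

## Repeat types, motifs and classes

Units are canonicalized at three levels: the *repeat class* is the unit
size; the *repeat motif* is the alphabetically first rotation of the unit
(strand-aware); the *repeat type* additionally folds in the reverse
complement, so `AAG`, `AGA`, `GAA`, `TTC`, `TCT` and `CTT` are all the
type `AAG`, but the motifs `AAG` and `CTT` stay distinct.  Motif-level
tables on sense-strand region fragments are what reveal strandedness —
systematic density differences between a motif and its reverse
complement in transcribed regions.  `cyclic_rc_mismatches()` measures how
close a unit is to being its own reverse complement (0 for `AT`); it is
the statistic behind the observation that the dominant 17 bp units differ
from their reverse complements in only 5 positions.

Lexicographic order is plain C-locale ordering (`A < C < G < N < T`).
Units containing N have no defined canonical form and are excluded from
type/motif tables.

## Densities and summary tables

Density is the fraction of base pairs covered by repeats, reported in
bp/Mbp of *effective* — non-N — sequence; every denominator in the
package is N-corrected, so appending N runs to a sequence changes no
statistic.  `summarize_repeats()` produces per-group records (count,
density, relative density, mean/SD/max length, mean perfection);
`unit_range_partition()` folds class densities into unit-size ranges; and
`strandedness_table()` pairs each motif with its reverse complement per
region, labelling pairs `-` (palindromic), `A/B` (both present), `a` or
`b` (one-sided).  Two conventions are not dictated by the definitions and
are therefore explicit arguments or documented defaults: length SDs are
population SDs (divide by $n$; `sd_type = "sample"` switches), and mean
perfection is unweighted by length.

## Region stratification

`read_gff()` accepts GFF3 attributes, GTF-style quoted attributes and
bare GFF2 group tokens, because real annotation releases mix all three.
Gene models are deduplicated with the rule used for multiply annotated
loci: when two same-strand models overlap, the *longer* span is removed
(iterated until stable, processing by ascending start; equal spans drop
the rightmost) — keeping the shorter model avoids over-representing a
locus, and nested antisense genes survive because the rule conditions on
the reading direction.  The same longer-loses rule applies to overlapping
exons or CDS features within one model.  Span length means genomic span,
not summed exon length.  Introns are inter-exon gaps; UTRs are inferred
from start/stop codon annotations where available (models whose codons
fall outside their exons are flagged and get no UTRs); intergenic DNA is
the complement of deduplicated gene spans.  Stranded fragments carry the
sense strand — minus-strand fragments are reverse-complemented — and
region-level scans run *inside* the fragments, so repeats truncate at
region boundaries exactly as they would in a region-split genome scan.
Exon fragments are produced but excluded from default reports since they
merely recombine CDS and UTR content.

One asymmetry is worth knowing: because hits are anchored on a perfect
first unit, a repeat whose terminal copy is imperfect can score one or
two points differently on the two strands.  Perfect repeats and plants
with edits away from both terminal units mirror exactly, and the strand
symmetry tests use such cases.

## The synthetic fixture generator

`make_fixture_genome()` emulates what the statistics need from real data:
multi-scaffold backgrounds at a chosen GC content, gene models on both
strands with codon-annotated CDS (emitted as GFF3), and a panel of
planted repeats of known truth — unit sizes from 1 bp to tens of bp,
controlled substitutions/indels/N runs placed outside the terminal units,
and strand-biased motif placements to exercise strandedness.  Expected
scores are exact by construction: a substitution costs 6, an indel 5–6,
an N run its length in lost matches.  Backgrounds are rejection-filtered
with the detector until repeat-free, and each plant's flanks are
resampled until local detection recovers exactly the intended interval —
otherwise background bases that happen to continue the repeat pattern
would legitimately extend a hit and make the truth table wrong, not the
detector.  Plants keep at least 60 bp of separation, which under the
fixture scheme's score reduction of 30 makes merging impossible.

The default fixture is two scaffolds of 30 and 20 kbp scanned with units
1–50 bp and a maximum score reduction of 30; the property suites use
2.5 kbp backgrounds with three plants each, 100 fixtures per run, and the
oracle comparisons use sequences up to 500 bp.  These sizes keep every
validation exact while a full run of the suite stays in the minutes
range.  What the fixtures deliberately do not emulate: the mutational
life cycle of repeats (plants are arrays plus independent edits, not
slippage histories), long-range compositional structure, heterochromatin,
and assembly artifacts such as scaffolds that begin or end inside an
array.  Passing the recovery suite therefore certifies the detector and
bookkeeping, not the biology of any particular genome.

## Limitations

* Seeding assumes qualifying hits contain a perfect stretch of length
  $p + \min(p, 4)$; pathological counterexamples exist for $p \ge 4$.
* The long-range preset's X-drop (30) can truncate repeats whose score
  dips more than 30 below a running maximum — deeply imperfect arrays.
* Strand symmetry of scores is exact only when terminal copies are
  perfect (see above).
* Units containing N are detected but carry no type/motif classification.
* `naive_repeat_oracle()` is deliberately size-limited; it is not a
  production scanner.
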