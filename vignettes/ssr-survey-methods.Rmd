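---
title: "Methods: EST-SSR mining, survey statistics and in-silico transferability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EST-SSR mining, survey statistics and in-silico transferability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrmine)
```

## Scope

`ssrmine` surveys simple sequence repeats (SSRs, microsatellites) in
EST/cDNA databases and assesses marker transferability in silico. The
input is assumed to be pre-clustered, non-redundant ESTs ("virtual
transcripts"); redundancy reduction (e.g. CAP3 contig assembly), quality
trimming and vector screening are upstream of this package, and functional
annotation (Gene Ontology, BLAST) and selection statistics (dN/dS) are out
of scope.

## The detection model

A locus is a **maximal perfect tandem repeat**: a primitive motif of 1-10
bases repeated at least twice with no mismatches or indels, not extendable
by one full motif copy on either side. Only whole copies count: trailing
partial copies are excluded from the tract, so a tract length is always
`motif_length * repeat_count`. Primitivity means the motif is not itself a
repetition of a shorter unit (`AT`, never `ATAT`); a non-primitive period
would double-report the same run. IUPAC ambiguity characters cannot match
any base, so an `N` terminates a tract and runs are split around it.

Detection compares the sequence with itself at lag `p` for each period
`p = 1..10`; maximal runs of agreement of length `>= p` correspond
one-to-one to maximal repeat regions, from which whole-copy tracts are cut,
anchored at the leftmost position of the run. The test suite checks this
against an independent quadratic brute-force scan over all (start, period)
candidates on random 2 kb sequences.

**Class I filter.** Marker-grade loci are those with tract length
`>= min_tract_bp` (default 20 bases). With whole-copy counting this
implies minimum repeat counts of 20 (mono), 10 (di), 7 (tri), 5 (tetra), 4
(penta, hexa), 3 (7-9-mers) and 2 (10-mers). Whether partial copies should
count towards the threshold is a genuinely open convention among SSR search
tools; this package counts whole copies only, which makes the threshold,
the tract arithmetic and the truth tables of the synthetic generator
mutually consistent.

**Overlap elimination.** Adjacent repeats of different periods can
overlap (the tail of an `AAG` tract is also the head of an `AG` tract).
Published survey tools state that such overlaps are eliminated without
specifying how, so the rule here is an explicit, deterministic greedy:
longest tract first, ties by leftmost start, then smaller motif length; a
candidate overlapping a selected locus is truncated to its largest free
sub-interval cut to whole (phase-rotated) copies and survives only if it
still meets the class I threshold. The greedy is verified against an eager
mask-based oracle in the tests.

**Single vs compound.** Non-overlapping class I loci on one sequence are
merged transitively into a compound SSR when consecutive gaps are at most
`compound_max_interruption` (default 100 bases, the convention of the MISA
comparator family; the parameter is exposed because published surveys do
not state their value). Everything else is a single. Singles plus compound
members always conserve the input loci.

**Canonical pairs.** Motifs are reported strand-independently by pairing
each motif with its reverse complement, printing the alphabetically smaller
member first: `AG` and `CT` are one class `AG/CT`. Cyclic rotations are
*not* merged — `GA/TC` is a different class — matching how plant EST-SSR
surveys count motifs. Self-reverse-complementary motifs are labelled
`X/X` (e.g. `GC/GC`).

**Homopolymers.** Mononucleotide tracts are detected but flagged
(`homopolymer`), since EST poly-A tails make them suspect as markers;
primer design skips them by default.

## Survey statistics and rounding conventions

Per database the survey reports locus counts, SSR/EST incidence, the mean
tract length of single loci (compound members excluded, following the
published table convention), sequences with >= 1 and >= 2 loci, and
canonical motif frequency tables per motif length.

Two reporting conventions deserve an explicit note:

* `ssr_per_est_pct` is **truncated** to two decimals rather than rounded.
  Published per-species SSR/EST percentages are reproducible from their
  printed locus and EST counts only under truncation (e.g. 980 loci on
  40,525 ESTs prints as 2.41, not 2.42); all other percentages in those
  tables behave as ordinarily rounded, and this package mirrors both
  conventions so its worked examples match the printed values digit for
  digit.
* All other rounding is *half away from zero* (commercial rounding), not
  banker's rounding, again to reproduce printed table values such as
  integer average bp per EST.
* The column "sequences containing more than one SSR (%)" has no
  documented denominator in published tables and cannot be back-calculated
  consistently; `ssrmine` reports the count plus a percentage of the
  sequences that contain at least one SSR, as its own documented
  convention.

GC content is pooled over residues, with `N`/IUPAC codes excluded from
numerator and denominator so the statistic stays defined on masked ESTs.
Cross-database aggregates are unweighted means, since the databases differ
in size by orders of magnitude and the comparative question is about
species, not sequences.

## Amino-acid and codon-bias profiles

Trimer, hexamer and nonamer motifs are translated as repeat units under the
standard genetic code; other lengths are counted untranslatable. Because
the reading frame of an EST-SSR is unknown without ORF annotation, the
default is frame 0 of the motif as observed, with frames 1-2 available as a
rotation of the unit (`translate_motif(motif, frame)`); motifs are
translated on the observed strand only, one residue string per motif class.
Stop codons are retained as `*` rather than dropped. Codon-usage tables
(Kazusa-style text, RNA or DNA alphabet, with or without occurrence counts)
are normalized to per-codon fractions; `GCk` is the total usage of codons
with G/C at position `k`, and motif-codon concordance ranks each frequent
trimer among its synonymous codons (rank 1 with non-zero usage =
concordant).

## In-silico PCR

Primer picking is a deterministic window rule, not thermodynamic design:
one fixed-length window (default 20 bases) per flank, at least 3 bases from
the tract, scanning outward and rejecting windows with ambiguity characters
or mononucleotide runs longer than 5. The contribution being assessed is
flank conservation across species, so a minimal reproducible picker is
preferable to an optimizer.

Scanning reports *every* (forward site, reverse site) combination on a
target where each primer matches with at most `max_mismatches_per_primer`
(default 1) mismatches outside an exactly matching 3' anchor (default 5
bases), sites do not overlap, and the product — primer sites included, as a
gel would show it — is at most `max_product_bp` (default 5000). These
defaults are this package's own, exposed on the API and CLI, since the
electronic-PCR literature the workflow descends from names tools but not
settings. The amplicon set is monotone non-decreasing in the mismatch
allowance and the product cap, and scanning with zero mismatches reduces to
exact substring search; both properties are tested.

An amplicon is **on-target** when its span contains a class I locus of the
same canonical pair as the source locus; the transfer rate from source to
target is the percentage of primer pairs with at least one amplicon there.
The denominators are all supplied pairs (published transfer studies leave
their "tested primer" denominators unstated). `virtual_gel()` groups
product sizes into lanes keyed by (pair, target) and `render_gel()` draws
them against a log-spaced ladder, collapsing co-migrating duplicates into
one band annotated `xN`.

## The synthetic data generator

`generate_database()` emulates what matters for validating this toolkit:
sequence lengths in a configurable range (default 300-1000 bases, typical
of clustered ESTs), an i.i.d. background with tunable GC, planted perfect
tracts at known coordinates with margins (default 120 bases, chosen to
exceed the default compound interruption so planted loci mine as singles),
and optional 3' poly-A tails (default length 15, deliberately below the
class I threshold). Each sequence is verified by mining it and comparing
against the plan; backgrounds that accidentally create, extend or distort a
class I locus are redrawn, so the truth table is exactly the mineable locus
set and recall/precision against it are meaningful at 100%. A single
integer seed drives sequence lengths, tail assignment, gap placement and
background draws in that fixed order, making runs byte-identical across
platforms.

`derive_ortholog_database()` applies point substitutions at a chosen rate
outside the planted tracts (optionally also freezing the primer windows
within 30 bases of each tract), emulating cross-species divergence with
conserved repeat regions. It does not model indels, chimeric ESTs,
sequencing-quality decay or expression-level redundancy — so passing tests
demonstrate the correctness of the machinery on clean, clustered input, not
robustness to raw-read artifacts.

## Problem sizes and numerical notes

The shipped test suite exercises oracle equivalence on 200 random 2 kb
sequences, planted-locus recovery on ten databases of 1,000 sequences each,
and self-amplification on a 120-sequence database; the acceptance script
uses 50 oracle sequences of 1 kb, three 300-sequence recovery databases and
one 60-sequence self-transfer database, sizes at which every property is
already stable across seeds. Degenerate inputs are defined rather than
accidental: empty databases error in `database_stats()`/`summarize`,
repeat-free input yields empty loci tables, empty motif classes yield empty
frequency tables, an all-ambiguous database has undefined GC (error), and
infeasible planting specifications fail before any sequence is emitted.

## Known limitations

* Perfect repeats only; imperfect/approximate repeats (common in pines, for
  example) are out of scope by design.
* Motif units above 10 bases (minisatellites) are not searched.
* The e-PCR model has no melting-temperature or primer-dimer
  thermodynamics, and amplicon homology is judged only by contained SSR
  class, not by alignment.
* Mining is implemented for EST-scale records; chromosome-scale scanning
  would want a compiled inner loop.
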