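---
title: "Methods: SSR mining, primer design, electronic PCR and cross-genus conservation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SSR mining, primer design, electronic PCR and cross-genus conservation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palmsat)
```

palmsat implements the marker-discovery strategy used for large plant
genome surveys: mine every perfect microsatellite from an assembly, design
locus-specific flanking primers, screen the primers electronically against
the source genome (copy number) and against a second genome (cross-genus
conservation), and relate SSR density to genes and transposable elements.
This vignette records the model choices, the defaults and why they were
chosen, what the synthetic fixtures do and do not emulate, and the known
limitations.

## Repeat model

A microsatellite here is a *maximal perfect tandem repeat* of a *primitive*
unit of 1–6 bp. Primitive means the unit is not itself a repetition of a
shorter unit, so a run of `ATATATAT` is reported once, as (at)~4~, never as
(atat)~2~ — without this rule every dinucleotide locus would be double- or
triple-counted and tier totals would not add up. Maximal means the run
cannot be extended by one unit on either side; at a contig end maximality
holds vacuously. `N` terminates a run: a repeat spanning an assembly gap is
not a perfect repeat. Scanning is case-insensitive.

The minimum repeat counts are 12 for mononucleotides and 4 for di- through
hexanucleotides (`default_thresholds()`), the thresholds conventionally
used for genome-wide surveys of this kind; the mononucleotide threshold is
counted in repeat units, i.e. 12 bases.

Two conventions deserve a note because the field's tools differ:

* **Phase.** A maximal periodic run is labelled by the unit rotation at its
  leftmost base, and only that one locus is reported. In the degenerate
  string `TATATATAT` both a (ta)~4~ at offset 0 and an (at)~4~ at offset 1
  are "maximal"; the scanner reports the leftmost. Rotational phases are
  *not* merged into one class: `ca/tg` and `gt/ac` are distinct motif
  classes, as survey tables conventionally list them.
* **Strand.** A unit is paired with its reverse complement into a motif
  class label (`tc` → `tc/ga`), because the same locus read from the other
  strand produces the complementary unit. Self-reverse-complementary units
  (`at`, `cg`) keep a single-part label.

The scanner works per period *k*: it computes the boolean vector
`s[i] == s[i+k]`, takes maximal runs of matches, and keeps runs whose unit
is primitive and whose full-unit count meets the threshold. The test suite
validates it against an independently written brute-force oracle
(a unit-table dynamic program with explicit left-maximality and
phase-deduplication) on hundreds of seeded random sequences.

## Primer design

Constraints follow the usual microsatellite-marker recipe: Tm 58–62 °C,
length 18–24 bp, GC 45–55 %, product 100–250 bp, primers strictly flanking
the repeat (`default_primer_constraints()`). The search enumerates every
(window, length) candidate on each side of the locus within the product
budget, rejects windows containing `N`, filters on GC then Tm, crosses the
surviving sides under the product-size constraint, and returns the
best-scoring pair. The score is the sum of distances of both primers' Tm
and GC, and of the product size, from their range midpoints, each distance
normalized by its half-range so that degrees, percentage points and bases
are commensurate. Ties break deterministically: smaller product, then
leftmost forward start, then shortest primers. Determinism matters more
here than the precise weighting — no downstream result depends on *which*
valid pair is chosen, only on constraint satisfaction, and identical inputs
always give identical pairs.

Undesignable loci keep a failure record naming the dominant blocking
constraint. Loci too close to a contig end (either flank shorter than the
minimum primer length) are reported as `insufficient_flank`, the dominant
failure mode for real assemblies; otherwise the constraint that eliminated
the most candidate windows is reported (`gc_out_of_range`,
`tm_out_of_range`, `ambiguous_bases`, `product_size`).

Melting temperature uses nearest-neighbor thermodynamics with the unified
duplex parameter set at 50 mM monovalent salt and 50 nM total oligo, with
the entropic salt correction and a total-strand-concentration/4 term; no
self-complementarity correction is applied, since primers are assumed in
excess over template. The Wallace rule 2(A+T)+4(G+C) is available as an
alternative. Under this model the 58–62 °C window is attainable
essentially only by the longer (≈24 bp) candidates at 45–55 % GC, which is
why designed primers cluster at the maximum length; tools that default to
older nearest-neighbor tables report 5–8 °C higher for the same oligo, so
absolute Tm values are model-specific even though constraint *satisfaction*
is well-defined. The unit tests pin the implementation to three frozen
reference values from an independent implementation of the same unified
table, within 0.1 °C.

## Electronic PCR

Stringent screening allows at most 1 mismatch per primer, no gaps, and
keeps products whose size deviates from the expected size by strictly less
than 100 bp — deliberately tighter than the permissive 2-mismatch/1-gap
convention, trading false negatives for reliability. Binding sites are
located on both strands by Hamming distance (`N` never matches);
orientation-consistent convergent site pairs within the size window become
amplicons, in either arrangement of the two primers; sites may not overlap
each other, so the minimum product is the sum of the primer lengths. All
qualifying pairings count toward copy number, within and across sequences.
Copy-number classes are 1, 2, 3 and >3; a pair with no product falls
outside the classes.

Mismatch placement is unrestricted by default (`three_prime_protect = 0`)
because only a mismatch *count* is specified for the screen; 3'-anchoring
is exposed as a parameter since polymerase extension is most sensitive
there. The permissive gapped mode uses a small banded dynamic program that
counts substitutions and indels separately, with greedy selection among
overlapping alternative alignments; it exists for completeness and
parameter exploration, and nothing downstream depends on it.

The same size window is applied to the self-genome screen and the
cross-genome screen, the simplest defensible choice given that the screen
is defined by its cross-genome criteria.

## Conservation pipeline

Stage order is fixed: mine genome A → design primers → self-ePCR on A
(keep pairs with ≥1 product) → ePCR on B → conserved = pairs with ≥1
qualifying product in both genomes. Conservation does not filter on B copy
number — multi-copy markers in B are conserved, merely annotated with
their class. Two conservation rates are reported, against the designed
count and against the self-amplifying count; published surveys are
ambiguous about which denominator the headline number uses, and emitting
both costs nothing. Survivor counts are asserted monotone non-increasing
along the funnel on every run.

Wet-lab validation is represented only by `transferability_rate()`, which
scores a user-supplied marker × species 0/1 amplification matrix; the
package never simulates gels.

## Genomic context

Window densities use 1 Mb non-overlapping windows (matching per-Mb density
reporting), assigning each feature to the window containing its start
coordinate; the final partial window keeps its true span so window spans
sum exactly to the sequence length. Start-coordinate assignment (rather
than overlap-weighting) is the simplest convention consistent with per-Mb
units, and for features that are short relative to the window the
difference is negligible. Correlations between SSR, gene and TE window
counts are computed per chromosome with the ordinary product-moment
coefficient; a constant vector leaves the coefficient undefined and it is
reported as absent.

Genic context is classified by locus start position with precedence
CDS > UTR > intron across all overlapping isoforms, because a single call
per locus is wanted even where isoforms disagree; 5' and 3' UTRs are
collapsed. When an annotation carries no explicit UTR features, UTR is
derived as exon minus CDS per sequence. Inside a gene span but outside any
exon is intron; everything else is intergenic.

## Synthetic data

`generate_genome()` draws i.i.d. background bases at a requested GC
fraction and plants (a) perfect SSRs whose flanking bases are deterministically
chosen to break the periodicity, so each planted locus is recovered with
exactly its planted coordinates, and (b) primer target blocks (forward
site + spacer + reverse-complemented reverse site) of a given product
size and copy count. Chance SSRs in the background are left in place — the
truth for whole-genome comparisons is defined by the brute-force oracle,
not by the plant list. `diverge_genome()` applies per-base independent
substitutions and geometric-length indels, recording every event with
original and derived coordinates.

The generator emulates what the engines need to be tested: motif spectra,
designable flanks, orthologous sites at controlled divergence. It does
*not* emulate higher-order base composition, repeat clustering,
centromere/telomere structure, segmental duplication, or realistic indel
spectra — so green tests demonstrate algorithmic correctness and the
direction of divergence effects, not that any particular real-genome count
will be reproduced.

Study sizes used by the test suite and the acceptance script — 8–20 kb
sequences, ~6 planted loci, a 0–10 % substitution grid with 5 seeds per
level — were chosen as the smallest sizes at which every stage of the
funnel is exercised with non-trivial survivor counts at each level.

## Numerical and degenerate-input choices

* Internal coordinates are 0-based half-open everywhere; 1-based inclusive
  conversion happens exactly once, at the GFF3 boundary (BED passes
  through). Round-trip tests pin this.
* The size window and the mismatch budget are compared with strict `<` and
  non-strict `≤` respectively: a deviation of exactly 100 bp is rejected,
  a single mismatch is accepted.
* Zero loci give a zero-density summary; zero spacing is reported absent
  rather than infinite. Zero denominators in rate computations are input
  errors.
* All randomness flows through explicit integer seeds; the caller's RNG
  state is never touched.

## Limitations

Imperfect, interrupted and compound repeats, units longer than 6 bp, and
minisatellites are out of scope. Primer design performs no
dimer/hairpin/self-complementarity screening and no multiplexing
compatibility checks. e-PCR is purely combinatorial — no thermodynamic
binding model, no degenerate bases. TE discovery is consumed as an
annotation file, never computed. Conservation between more than two
genomes, polymorphism prediction and map construction are not attempted.

## A worked micro-example

```{r example, eval = FALSE}
syn <- generate_genome(
  n_sequences = 1, length = 15000, gc = 0.5,
  planted_ssrs = tibble::tibble(unit = rep(c("at", "ag", "aac"), 2),
                                repeat_count = rep(c(7, 9, 5), 2)),
  seed = 1)
div <- diverge_genome(syn$genome, substitution_rate = 0.02, seed = 2)
pip <- run_pipeline(syn$genome, div$genome)
print(pip)
generics::glance(pip)
autoplot(pip)
```
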