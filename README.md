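# palmsat

Genome-wide microsatellite (SSR) marker discovery and cross-genus
transferability screening, for plant genomicists who need large panels of
locus-specific, transferable markers from genome assemblies — the setting
in which only one or two species of a family have been sequenced and
markers must carry over to their unsequenced relatives.

## What it computes

**Mining.** Every maximal perfect tandem repeat of a primitive 1–6 bp unit
meeting the minimum repeat counts (12, 4, 4, 4, 4, 4 for mono- through
hexanucleotides). Loci are labelled by the unit phase at their leftmost
base and grouped with the reverse complement into motif classes
(`tc/ga`; rotations such as `ca/tg` vs `gt/ac` stay distinct). Summary
tables report per-tier/per-class counts, percentages, repeat ranges and
total lengths, plus overall density: for *n* loci in *L* bases,

&nbsp;&nbsp;&nbsp;&nbsp;density = *n* / (*L*/10⁶) loci per Mb,&nbsp;&nbsp;
spacing = (*L*/10³) / *n* kb per locus.

**Primer design.** One deterministic best-scoring pair per locus under
Tm 58–62 °C (unified nearest-neighbor thermodynamics, 50 mM Na⁺, 50 nM
oligo), length 18–24 bp, GC 45–55 %, product 100–250 bp, primers strictly
flanking the repeat; undesignable loci keep a reason
(`insufficient_flank`, …).

**Electronic PCR.** Mismatch-tolerant binding-site location on both
strands (stringent mode: ≤1 mismatch, 0 gaps), enumeration of convergent
site pairs whose product size deviates from the expected size by strictly
less than 100 bp, and copy-number classification (1 / 2 / 3 / >3).

**Conservation.** Mine genome A → design → self-ePCR on A → ePCR on
genome B; a marker is conserved when it has at least one qualifying
product in both genomes. Rates are reported against both the designed and
the self-amplifying pair count. `transferability_rate()` scores wet-lab
marker × species 0/1 matrices.

**Genomic context.** 1 Mb window counts of SSRs/genes/TEs, per-chromosome
Pearson correlations between them, and genic-context classification
(CDS > UTR > intron > intergenic) from GFF3 annotation.

A seed-controlled synthetic genome generator with planted SSRs, planted
primer target sites and a divergence operator (substitutions + indels,
fully ledgered) makes every stage testable without downloading assemblies.

## Worked example

```r
library(palmsat)

syn <- generate_genome(
  n_sequences = 1, length = 15000, gc = 0.5,
  planted_ssrs = tibble::tibble(unit = rep(c("at", "ag", "aac"), 2),
                                repeat_count = rep(c(7, 9, 5), 2)),
  seed = 1)
loci <- find_ssrs(syn$genome)
loci
#> # A tibble: 8 × 8
#>   seq_id start   end unit  unit_length repeat_count motif_class length
#>   <chr>  <int> <int> <chr>       <int>        <int> <chr>        <int>
#> 1 synth1   271   279 cg              2            4 cg               8
#> 2 synth1  4710  4724 at              2            7 at              14
#> 3 synth1  4995  5003 gc              2            4 gc               8
#> 4 synth1  6187  6205 ag              2            9 ag/ct           18
#> 5 synth1  7980  7995 aac             3            5 aac/gtt         15
#> 6 synth1  9110  9125 aac             3            5 aac/gtt         15
#> 7 synth1  9944  9962 ag              2            9 ag/ct           18
#> 8 synth1 14405 14419 at              2            7 at              14
```

The six planted loci come back at exactly their planted coordinates; rows
1 and 3 are chance background repeats, which are kept — background truth
is defined by a brute-force oracle, not the plant list. Now diverge a copy
of the genome by 2 % substitutions and run the full funnel:

```r
div <- diverge_genome(syn$genome, substitution_rate = 0.02, seed = 2)
pip <- run_pipeline(syn$genome, div$genome)
pip
#> palmsat conserved-marker pipeline
#>   loci mined:            8
#>   primer pairs designed: 8
#>   self-amplifying in A:  8
#>   conserved in B:        6
#>   conservation rate:     75.00% of designed (75.00% of self-amplifying)
```

All eight mined loci were designable and self-amplify; after divergence,
two markers lost a primer site (≥2 mismatches) or drifted outside the
size window, leaving six conserved markers. `tidy(pip)` gives the
per-marker table (primers, Tm/GC, product counts and copy-number class in
each genome), `glance(pip)` the one-row funnel summary, `autoplot(pip)`
the funnel figure.

A thin command-line front end over the same functions lives at
`inst/cli/palmsat` (`mine`, `design`, `epcr`, `run`, `context`,
`simulate`).

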