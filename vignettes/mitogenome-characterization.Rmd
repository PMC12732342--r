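---
title: "Methods: characterizing a small circular mitogenome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterizing a small circular mitogenome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitochar)
```

mitochar implements the descriptive analyses that a mitogenome
announcement paper runs on a newly assembled insect mitochondrial genome:
gene organization and adjacency, nucleotide composition and strand
asymmetry, codon-usage-bias diagnostics, pairwise divergence across a gene
panel, and repeat/control-region structure. This vignette records the
models behind each stage, the parameter choices, and the places where the
design was genuinely open.

## The genome model

A `genome_record` is a circular (or linear) DNA string plus an ordered
feature table. Coordinates are 1-based and inclusive throughout — the
convention of GenBank flat files and of published mitogenome annotation
tables — and are only ever converted at module boundaries, never exposed
converted. Features carry one of five categories (`PCG`, `tRNA`, `rRNA`,
`control_region`, `repeat_region`) and a strand label `J`/`N` (majority /
minority coding strand, the standard insect-mitogenome nomenclature).
Non-coding regions are first-class features: they participate in
adjacency, which is what makes a published intergenic column reproducible
from coordinates alone.

Ambiguity handling is conservative by design: IUPAC codes are retained in
the sequence, but every composition and codon statistic excludes non-ACGT
positions from its counts. A finished mitogenome is normally unambiguous,
so this choice only defines behaviour on imperfect input rather than
shaping results.

For consecutive features in genome order, the intergenic distance is
`start(next) − end(prev) − 1`; negative values are overlaps, zero is
contiguity, and on a circular record the last feature wraps to the first.
Summed around the circle, `intergenic + size` telescopes to the genome
length — a property test in the suite.

## Coding sequences and the genetic code

Protein-coding genes are extracted on their own coding strand (reverse
complement for `N`-strand genes) under NCBI translation table 5 (the
invertebrate mitochondrial code: `TGA` = Trp, `ATA` = Met, `AGA`/`AGG` =
Ser; 62 sense codons, stops `TAA`/`TAG`). Table 2 (vertebrate
mitochondrial) is also supported; codes come from
`Biostrings::getGeneticCode()`.

Animal mitochondrial CDSs often end in a truncated stop completed by
polyadenylation of the transcript. The trim rule is strict: length mod 3
of 1 with a final `T` is classed `incomplete_T`; mod 3 of 2 ending `TA`
is `incomplete_TA`; a complete frame must end in a genuine stop codon.
Anything else — including an internal stop — is a loud validation error
naming the gene and codon index, because a silent frame slip would
corrupt every downstream codon statistic. Sense codons exclude the
terminal stop in every count.

## Composition and skew

AT/GC content is reported as a fraction of counted bases; skews are
`(A − T)/(A + T)` and `(G − C)/(G + C)`, with an `NA` sentinel when a
base pair is absent. The per-codon-position rows of the composition table
concatenate one position across all sense codons of a gene set, so their
"size" column is a codon count, not a base-pair count — matching how
published composition tables report per-position rows. Strand-class rows
(`J`-strand PCGs, `N`-strand PCGs) are computed on each gene's own coding
strand; computed on the genome strand they would mix complementary
alphabets and mean nothing. Report formatting is fixed once (contents to
1 decimal as percentages, skews to 3), so reruns are byte-identical;
internal values keep full precision.

## Codon-usage-bias indices

**RSCU.** For codon *c* in a synonymous family of size *k* with family
total *n*: RSCU = *k·count(c)/n*. Families are the full synonymous sets
of the code — Leu is 6-fold and Ser 8-fold under table 5. The familiar
Leu1/Leu2 (CUN/UUR) and Ser1/Ser2 (AGN/UCN) labels are reporting labels
only; treating them as separate families would cap RSCU at the subfamily
size and make the high UUR values seen in AT-rich mitogenomes
unattainable. A `family_mode = "split"` flag exists as a sensitivity
check for comparison with tools that split by decoding tRNA.

**ENc.** Wright's effective number of codons, generalized to the
family-size classes of the active code. Per family with total `n ≥ 2`,
the homozygosity estimate is `F = (n·Σp² − 1)/(n − 1)`; per class the
mean `F̄` over estimable families; `ENc = Σ_s N_s / F̄_s`, clamped above
at the code's sense-codon count (62 under table 5). Under table 5 there
are no singleton families, so the floor is the family count, 20 —
asserted analytically in the tests. When a class has no estimable family
(short genes such as *atp8* trigger this for the 6- and 8-fold classes),
its `F̄` is imputed as `1/k` plus the mean deviation of the estimable
classes from their own `1/k`, clamped to (0, 1]; the imputation is
reported via `message()` and an attribute rather than silently. Under
the standard code this reduces to the usual "average the neighbouring
classes" recommendation.

**ENc plot, PR2, neutrality.** The expected-ENc reference curve is
`2 + GC3s + 29/(GC3s² + (1 − GC3s)²)`, maximal (60.5) at GC3s = 0.5.
PR2 coordinates are `G3/(G3 + C3)` against `A3/(A3 + T3)` over
third positions of sense codons, with (0.5, 0.5) the parity expectation.
The neutrality fit is unweighted ordinary least squares of GC12 on GC3,
both on the percent scale — the scale on which such regressions are
conventionally printed, and the one that makes intercepts comparable to
published values. GC3s differs from GC3 only through families of size
< 2; under table 5 every family is degenerate and the two coincide,
but the exclusion rule is applied generically so table 2 behaves
correctly.

## Divergence

**Nucleotide diversity.** π is the mean pairwise proportion of differing
sites. Within each sliding window (defaults 200 bp / 20 bp step, the
conventional DnaSP-style setting), any column containing a gap or
ambiguity in any row is excluded from numerator and denominator alike
(complete deletion per window); the whole-gene mean applies the same
rule. A window wider than the alignment collapses to a single
whole-length window; all-gap windows are omitted.

**Ka/Ks.** Nei–Gojobori (1986) counting with equal-weight pathway
averaging and Jukes–Cantor correction `d = −(3/4)·ln(1 − 4p/3)` — the
classic approximate method that the standard desktop tools default to.
Per codon, each position contributes the fraction of its three possible
changes that are synonymous; mutations creating stop codons count as
nonsynonymous, which keeps synonymous + nonsynonymous sites equal to
exactly 3 per codon (a property test enumerates all 62 sense codons
against a brute-force neighbour oracle). Multi-hit codon pairs average
over all minimal mutational pathways, skipping pathways through stops; a
codon pair whose every pathway is blocked is excluded and counted in a
diagnostics field. Gaps and ambiguities are handled by pairwise deletion
at codon granularity. Saturation (`p ≥ 3/4`) yields an `NA` distance
rather than a number. `Ka/Ks` is undefined when `Ks = 0` — including for
identical sequences — and reported as `NA`, never coerced to 0 or
infinity.

## Repeats and region structure

The repeat finder reports *maximal exact* pairs in the four REPuter
orientations (forward, reverse, complement, palindromic) at a default
minimum of 30 bp, the conventional reporting cutoff for mitogenome
repeat scans. Matching walks diagonals (forward/complement) and
anti-diagonals (reverse/palindromic) of the implicit match matrix with
vectorized run-length encoding: O(n²) worst case, entirely adequate at
mitogenome scale, and the API does not preclude swapping in an indexed
matcher. Approximate (edit-distance) repeats are out of scope.

Tandem arrays are found per candidate unit length by seeding on exact
period-*u* runs and chaining whole units while adjacent units differ by
at most 10% Hamming distance, then validating against the array
consensus with the same per-unit budget (near-identical units are the
biological expectation; the budget makes the rule explicit). Fractional
final copies count. Homopolymers are excluded — they are periodic at
every unit length and are not tandem arrays in any useful sense. Arrays
whose unit is an exact multiple of another reported unit over the same
span are collapsed; genuinely ambiguous alternative unit lengths (a
long-unit reading vs a short-unit-plus-spacer reading of the same locus)
are deliberately both reported rather than adjudicated.

The stem-loop detector is structural, not thermodynamic: the longest
exact inverted repeat whose arms flank a loop within a configurable
range (default 3–50 bp), ties broken by smaller loop then leftmost
position. Minimum-free-energy folding is a non-goal; outputs are only
qualitatively comparable to folding-tool figures.

Control-region decomposition claims segments in priority order — tandem
arrays, longest poly-T run (≥ 8 bp), best stem-loop, then the longest
window with AT ≥ 0.95 and ≥ 100 bp — each detected only outside
already-claimed segments. The priority order exists because the classes
overlap logically (a poly-T run is AT-rich; a tandem unit may contain
T-runs): structure-specific detectors claim first, the generic AT-rich
window last. The uncovered prefix is labelled `lead`, remaining gaps
`spacer`.

## The synthetic generator

`generate_genome()` emulates an aphid-like mitogenome so every stage is
testable offline: the standard 37-gene layout (13 PCGs, 22 tRNAs,
2 rRNAs, repeat and control regions) at its published sizes, placed
contiguously; genome AT content targeted at 0.84; codon usage drawn from
per-base product weights (A = T = 0.42, G = C = 0.08), which makes `TTA`
dominate the Leu family as it does in real AT-rich mitogenomes — a
fixture calibration, not a claim about any real genome. PCG sizes whose
remainder mod 3 is 1 or 2 receive planted incomplete `T`/`TA` stops, so
the stop-trim rule is exercised by construction. The control region
plants a 65 bp lead, three identical 109 bp tandem copies, an AT-rich
tract, a 13 bp poly-T run and a 137 bp stem-loop (45 bp arms, 47 bp
loop; the arm length was chosen so the loop sits inside the detector's
default range). The AT-rich tract is generated pure-A/T with its T-runs
broken below the planted poly-T length and A-anchored ends, so the
planted poly-T remains the unique longest T-homopolymer — the generator
guarantees identifiability of its own ground truth.

What the generator does *not* emulate: realistic mutation spectra,
indels, tRNA/rRNA secondary structure, gene overlaps (features are
contiguous, so synthetic adjacency is all-zero by design), and
base-composition heterogeneity along the genome. Tests passing on
synthetic data therefore validate the *statistics and detectors*, not
any biological claim about real genomes.

`evolve_panel()` grows a star-tree alignment from a root CDS: proposals
are single-base codon changes at a per-site rate; synonymous proposals
are always accepted, nonsynonymous ones with probability ω, stops always
rejected. A star tree keeps the true accepted synonymous/nonsynonymous
counts exact per branch, which is all that pairwise NG86 and π need;
a bifurcating topology would add realism the estimators under test do
not use. With ω = 0 the NG86 Ka is exactly 0 — a forced fixed point the
suite asserts — and across ω ∈ {0.05, 0.2, 0.8} the estimated mean
Ka/Ks rises monotonically (averaged over 10 seeds).

All randomness in a generator run flows from the single spec seed
through R's global generator in documented order, so fixtures are
byte-stable.

## Numerical and scale choices

Problem sizes in the test-suite simulations are deliberately modest —
genes of 100–300 codons, panels of 2–6 taxa, 10-seed averages,
500 bp sequences for exhaustive repeat cross-checks — sizes at which
brute-force oracles (O(n²·L) pairwise counts, full neighbour
enumeration, closed-form OLS) are exact and fast, so every non-trivial
statistic is checked against an independent computation rather than a
frozen constant. Oracle comparisons use 1e−9 tolerances for closed
forms and exact equality for counts.

Known limitations: no maximum-likelihood dN/dS (no codon models), no
alignment computation (alignments are inputs), no tree building, no
figure rendering (plot-data tables only), single-record GenBank only,
and no handling of joined/intron locations, which do not occur in animal
mitogenomes.
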