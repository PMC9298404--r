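---
title: "Full-gene ABO allele analysis: models, parameters and design choices"
author: "aboseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Full-gene ABO allele analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aboseq)
```

# The problem

Routine ABO genotyping sequences exons 6 and 7, occasionally exons 1–7.
That leaves two blind spots. First, subtype phenotypes (A3, Bw, Ael, ...)
sometimes show no coding or splice-site variant at all: the causal change
sits in the erythroid cell-specific regulatory element in intron 1 (the
+5.8 kb enhancer with GATA and RUNX1 motifs). Second, without intronic
sequence there is no way to notice that a haplotype is a patchwork of two
allele lineages — an intragenic recombinant — because the common alleles
differ over most of their length only at intronic positions.

`aboseq` implements the downstream analysis for full-gene (start codon to
stop codon) ABO data at the variant-call level: the coordinate arithmetic,
the diploid allele caller, the derivation of allele-specific intronic
marker SNVs from homozygote panels, regulatory-element annotation, and
recombination breakpoint inference, together with a synthetic cohort
generator that makes the whole pipeline testable without any sequencing
data.

# Coordinate model

A `GeneModel` holds contiguous cDNA exon spans, per-intron lengths, a
contig name and the genomic coordinate of c.1. HGVS c. positions are pairs
(anchor, offset): offset 0 is exonic; `+k` counts into the intron from the
last base of an exon, `-j` counts back from the first base of the next
exon. The package defines a total order — exonic anchors ascend; within an
intron all `+` positions precede all `-` positions, `+` ascending and `-`
descending — which agrees with genomic order whenever each intron is longer
than the largest `+` and `-` offsets used in it combined. `GeneModel`
validity enforces exactly that, and `validateModelForVariants()` re-checks
it for any variant set.

The bundled model has exon spans 1–28, 29–98, 99–155, 156–203, 204–239,
240–374 and 375–1065. The coding region is 1062 bp; the model's cDNA axis
runs three bases further so the stop codon is addressable, which is
immaterial in practice because every variant the package bundles lies at or
before c.964. Two rows of the published intronic catalog are labeled
"intron 1" but anchor on c.98/c.99, the boundary of exon 2; under the model
they classify as intron 2, and the package follows the model (the
discrepancy is surfaced in the catalog tests rather than patched over).

Fixture intron lengths are 13000, 760, 1200, 1480, 600 and 1000 bp. Intron
1 dominates the real ~20 kb locus at over 13 kb, which the fixture
reproduces; the others are synthetic. Each length is chosen so that every
bundled variant is strictly nearer its own anchor exon than the opposite
one. That makes `genomicToC()` — which uses the standard nearest-exon HGVS
convention with ties going to the `+` side — a bijection over all bundled
positions, so VCF round-trips are exact. (A 1400 bp intron 4, for example,
would break this: c.203+738 would read back as c.204-662.)

# Zygosity profiles

A `SampleProfile` is an ordered set of calls (hom_ref / het / hom_alt,
depth, alt-read fraction) keyed by canonical HGVS label. Input formats are
a TSV dialect (`hgvs_c, zygosity, depth, alt_fraction`) and single-sample
VCF 4.2. VCF writing left-anchors indels with a padding base; every record
carries `INFO/HGVSC` so that notations genomic coordinates cannot express
uniquely (the bracketed repeat insertion `c.239+103_239+105insC[3]`)
round-trip verbatim. Reading trusts `HGVSC` when present and reconstructs
labels from REF/ALT otherwise; multiallelic records and foreign contigs are
rejected rather than normalised.

Two parameters matter and are exposed everywhere: the minimum depth for a
full-confidence call (default 50 reads — calls below it are kept but
flagged `low_coverage`), and the alt-fraction thresholds for deriving
zygosity from fractions (hom_ref < 0.15, het in [0.30, 0.70], hom_alt >
0.85, gaps flagged `ambiguous`). The depth floor mirrors the review
practice for amplicon NGS; the fraction bands are ordinary diploid-calling
practice since the source protocol publishes no numbers beyond the
coverage floor.

# Allele assignment

The allele table (YAML, replaceable by the full ISBT catalog) defines each
allele as coding variants relative to the ABO*A1.01 reference, optionally
as a delta on a parent (ABO*B3.10 = ABO*B.01 + c.28G>A). The caller
enumerates all unordered pairs, predicts hom_alt/het per variant, and keeps
pairs that reproduce the observed coding pattern exactly; observed variants
carried by neither allele become novel variants on the pair's background.
Ranking is by total unexplained observations (zygosity contradictions plus
novel variants), then by contradictions, then name — so explanations
through named alleles are preferred, and with `tolerant = TRUE` the caller
degrades gracefully on noisy input instead of failing. All consistent
pairs are returned in `alternatives`: unphased calls genuinely cannot
separate some pairs, and that ambiguity should be visible, not resolved by
an undisclosed prior.

Mechanism classification for subtype specimens is deliberately coarse:
`coding_variant` if the pair contains a subtype-defining allele or novel
coding/splice-site (offset magnitude ≤ 2) variants are present;
`regulatory_variant` if the coding region is clean but a variant falls in
the element window [c.28+5856, c.28+5958]; `unexplained` otherwise. The
bundled association table maps c.28+5872C>T to B3/AB3, c.28+5882C>T to
Bweak/ABweak and c.28+5956T>A to A3; in-window variants without an entry
are reported as "element, unknown effect" rather than dropped.

# Marker derivation

Given homozygous samples with assigned lineages, variant *v* is a marker
for lineage X iff *v* is hom_alt in **every** X/X sample and absent
(hom_ref or uncalled) in **every** other sample. Strict unanimity is the
default because the published catalogs arise from a small panel (47
usable homozygotes) where unanimity is both achievable and the strongest
statement; with per-call error the rule is brittle, so a tolerance `delta`
is available (presence in ≥ 1−delta of X samples, ≤ delta of each other
lineage) and is property-tested at a 2% flip rate with delta = 0.1 on
30-per-lineage panels. Indels and delins count as markers on equal footing
with substitutions — the published catalog itself contains a delins, a dup
and a repeat insertion.

A heterozygous call inside a supposed homozygote disqualifies the variant
and raises a sample-quality warning. This is not just hygiene: it is the
mechanism by which a recombinant hiding in the panel announces itself
(het at one lineage's markers over part of the gene). `deriveMarkerCatalog()`
therefore runs two passes — derive, exclude warned samples, re-derive —
mirroring the workflow in which one B/B specimen was excluded from the
panel after its recombination was noticed.

# Recombination inference

For a genotyped sample, every intronic position known to the allele table
or catalog has an expected zygosity under the called pair. Positions where
either the expectation or the observation is non-reference form the walk;
call-level data carries no signal at doubly-reference positions, so they
are excluded — this matters, because it is exactly why the published
intron-1 interval is bounded by the deletion at c.29-1053 and not by the
three O.01.01 markers between it and c.29-86 that the recombinant simply
lacks.

Detection fits a single-crossover hypothesis: donor allele D substituted
onto one haplotype over a 5' or 3' segment. A hypothesis is feasible when
every position on the donor side matches the substituted pair's expectation
— including predicted-but-absent variants, which is the refuting evidence
that separates an O.01.01 donor from an O.01.02 donor — and every position
on the other side matches the called pair. The breakpoint interval runs
from the last discordant position to the first *observed* position that
discriminates the called pair from the donor hypothesis; background
variants shared by both lineages are silent and cannot bound the crossover.
When several donors remain feasible the interval is the union of their
feasible ranges and all donors are reported. Discordance that no single
crossover explains — two internal boundaries, multiple runs, no consistent
donor — is reported as an `untypical` pattern with the offending positions,
and no interval is asserted; three of the six recombinant specimens in the
bundled presets exercise exactly this path.

Segments supported by fewer than `min_run = 2` discordant positions are
reported `low_confidence`: a lone discordant marker is indistinguishable
from a genotyping error. Intervals are always printed (5' flank, 3' flank)
in gene-axis order.

Read-backed phasing (`phaseByReads`) assigns a novel variant to a
haplotype by co-occurrence: fragments jointly covering the target and an
anchor and carrying at least one alternate allele are informative; ≥ 90%
co-occurrence is cis, ≤ 10% trans, anything else (or fewer than 3
informative fragments) unknown. A variant trans to every marker of one
haplotype's lineage belongs to the other haplotype — the argument used to
place the novel element variant on the A allele.

# The synthetic cohort generator

`makeCohort()` encodes the study conditions as presets:

* `table2` — 88 donors: 12 A1.02/A1.02, 14 B.01/B.01, one B/B carrying the
  intron-1 recombinant haplotype, 13 O.01.01/O.01.01, 8 O.01.02/O.01.02,
  one O.01.01 homozygote with the novel c.964G>A, and 38 further
  heterozygotes in the published proportions (the B/B row is modeled as
  14 + 1 recombinant so both published readings total 88).
* `subtypes` — 22 specimens: 17 with coding-variant mechanisms (named
  subtype alleles or novel coding variants on common backgrounds; five of
  these carry recombinant haplotypes) and 5 with only regulatory-element
  variants.
* `full` — both, 110 samples.

Haplotypes are built from the allele table plus the bundled marker catalog.
The intron-1 deletion c.29-1053_29-1037del is carried as a *shared*
O-lineage variant (on both O backgrounds): it is not in the published
specific-marker catalog, yet it bounds the intron-1 crossover, and making
it O.01.01-exclusive would wrongly inflate the derived O.01.01 marker count
to 11. Donor identification still resolves to O.01.01 through the absence
of O.01.02-specific intron-1 markers in the donor segment.

Twenty seeded shared-lineage background variants (4 shared A1.02+B, 8
O-lineage, 4 B+O.01.01+O.01.02, 4 B+O.01.02) are added to the table per
cohort: they are the true negatives marker derivation must reject, they
give A1.02 its intronic background, and they populate the walk with
positions that are silent for donor inference. Their positions are drawn
deterministically from the seed, avoiding bundled variant spans, the
regulatory window and the two modeled crossover windows (a background
variant inside a crossover window would change the breakpoint interval the
preset is designed to reproduce).

The intron-1 recombinant's crossover is placed at c.29-1000 — between the
deletion and c.29-780delinsGG — so the recombinant lacks the three
O.01.01-specific markers downstream, as the published zygosity pattern
requires. The intron-5 recombinant crosses at c.240-100 and additionally
retains c.28G>A. The three "untypical" specimens carry a two-crossover
haplotype (a subtype-B backbone with O.01.01-derived introns 3–5), which
the single-crossover model correctly refuses to bound.

Noise is a per-call zygosity flip with probability ε (default 0); depths
are negative-binomial (mean 500, size 10, so the default depth floor of 50
is rarely triggered); alt fractions are drawn consistently with the
(possibly flipped) zygosity. Everything derives from one seed, and
identical seeds give byte-identical cohorts.

What the generator does **not** emulate: read-level error models, amplicon
dropout, allele-frequency structure, alignment artifacts near the indels,
and the full per-sample intronic variant inventories (only the
allele-specific subset plus synthetic background is modeled — sample-level
intronic totals against the reference are therefore smaller than in real
data). Passing tests demonstrate the algorithms' correctness under the
modeled conditions, not robustness to raw-data pathology upstream of
variant calling.

# The synthetic reference and in-silico PCR

`syntheticReference()` builds a deterministic stand-in for the genomic
reference: random sequence over 500 bp flanks plus the modeled gene, with
the reference bases of every bundled variant patched in (so HGVS ref
alleles agree with the sequence) and the two long-range primer pairs
embedded such that the amplicons measure 12.8 kb and 8.7 kb, overlapping in
intron 1 — the published tiling design. It is labeled synthetic throughout;
`insilicoPcr()` itself is exact-match primer search on any supplied FASTA
and applies unchanged to the real RefSeqGene record, which the offline test
environment does not download.

# Problem sizes and numerical choices

The test suite and acceptance script run the 88-, 22- and 110-sample
presets, a 120-sample noise panel, and 200 randomized single-crossover
trials; the full suite completes in well under a minute on one CPU. Gene-
axis keys are exact doubles (largest composite ≈ 1e10, far inside the 2^53
integer range). Ties in genomic-to-c conversion go to the `+` side; ties
between equally ranked genotype pairs are broken case-insensitively by
allele name so results are locale-independent and deterministic.

# Known limitations

* Single-gene, plus-strand scope; no multi-transcript HGVS, no 5'/3'-UTR
  (`c.-n` / `c.*n`) arithmetic.
* One recombinant haplotype per sample, single crossover; double
  recombinants are detected but not bounded.
* The bundled allele table is a fixture following ISBT convention for the
  handful of alleles the presets need; production use should load the full
  ISBT catalog.
* Genotype calling uses coding variants only; two alleles identical in
  coding sequence but differing intronic content are separated only
  downstream, by the marker walk.
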