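---
title: "Localised heterogeneity in phage populations: models and methods"
author: "quasipop maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localised heterogeneity in phage populations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quasipop)
```

## The problem

Deep sequencing of a nominally clonal phage stock does not return one genome.
Lytic dsDNA phages — conspicuously the phiKMV-like viruses of *Pseudomonas* —
maintain clouds of single-nucleotide variants segregating at population
frequencies from below 1% to well above 40%, concentrated in the structural
module of the genome and especially in the tail fibre, the main host-range
determinant. Detecting this localised heterogeneity from Illumina data is a
low-frequency variant-calling problem with three characteristic difficulties:

1. sequencing error (≈0.1–1% per base) lives on the same frequency scale as
   the variants of interest;
2. the *sample consensus* may differ from the database reference, so variants
   must be defined against the sequenced population's own majority sequence,
   or majority changes masquerade as low-frequency sites;
3. frequency alone says nothing about linkage — whether two variants ride the
   same genomes — which requires counting individual sequenced fragments that
   span both sites.

quasipop implements the full analysis as a tested pipeline, together with a
population/read simulator that makes every stage verifiable against
machine-readable truth.

## The population model

A *haplotype population* is a weighted set of genome haplotypes over one
reference: haplotype $k$ carries a subset $S_k$ of planted single-nucleotide
variants and weight $w_k$, $\sum_k w_k = 1$. Truth quantities follow in
closed form:

* marginal frequency of variant $v$: $f_v = \sum_{k : v \in S_k} w_k$;
* pairwise co-occurrence of $(i, j)$:
  $C_{ij} = 100 \cdot \frac{P_{ij}}{f_i + f_j - P_{ij}}$, where
  $P_{ij} = \sum_{k : i,j \in S_k} w_k$ — the percentage of variant-bearing
  genomes carrying both.

`build_population()` takes explicit haplotypes. Realising an arbitrary target
co-occurrence matrix is under-determined, so co-occurrence is always
*derived* from the haplotype structure, never prescribed.
`build_population_independent()` realises arbitrary marginals on a pool of
$K$ equally weighted genomes (default $K = 10^4$, i.e. 0.01% resolution) by
assigning each variant to $\mathrm{round}(f K)$ genomes at random; pairs are
then approximately independent and the realised co-occurrence is recorded as
truth.

## Read simulation

`simulate_reads()` emulates the targeted sequencing design: 2×300 bp pairs,
Normal insert sizes (default 600 ± 60 bp, so mates abut or overlap slightly),
uniform fragment starts on a *linear* genome, haplotypes drawn proportional
to weight, i.i.d. substitution errors (default 0.2% per base) and constant
base quality Q35 emitted independently of the error process. Design choices
worth stating:

* **Linear genome.** Fragments never wrap the origin; phage termini handling
  is deliberately not modelled. Consequence: coverage ramps from ~0 to full
  over roughly one insert length at each end, exactly as in real libraries
  of linear DNA.
* **Substitution-only errors, no indels.** The analysis surface is
  single-nucleotide variation; indel-bearing real data enters through
  `read_sam()` from an external mapper.
* **Quality decoupled from error.** Real MiSeq errors correlate with low
  quality; modelling that would let quality filters "cheat". Constant Q keeps
  the truth tractable and makes the caller face every injected error.
* **Determinism.** With `seed` set, output is byte-identical across runs;
  the RNG state drives genome, variants, fragments and errors.
* A mutation-spectrum option biases planted variants toward AT→GC
  transitions (A→G, T→C), mirroring the spectrum generated by error-prone
  phage DNA polymerases; it is off by default.

`simulate_coinfection_pool()` mixes fragments from two populations — the
sequencing analogue of co-infecting one host with two phages. `mix_fraction`
is the per-fragment probability of the first genome. Note that equal
*genome-copy* mixtures of unequal genomes contribute fragments proportional
to length; `mix_fraction_equal_copies()` returns the fraction giving both
genomes equal coverage.

## Read quality control

Two regimes, applied pair-wise (a pair is dropped when either mate fails):

* `sliding_window_trim()` — 5-base windows advancing one base; at the first
  window whose mean Phred quality drops below 20 the read is cut just before
  the first below-threshold base in that window (the Trimmomatic
  convention). Trimming iterates to a fixed point so it is idempotent.
* `variant_read_filter()` — remove reads with mean quality < 30 **or**
  length < 50. The disjunctive reading is deliberate: a conjunctive filter
  would retain a full-length Q5 read, defeating the stated purpose of
  minimising false positives. A `rule = "and"` switch preserves the literal
  alternative.

## Alignment

`map_reads()` is a seed-and-extend, *ungapped* mapper: exact 21-mers sampled
every 10 bases along the read (plus the terminal k-mer), looked up on both
orientations, every candidate placement scored by full mismatch count, best
placement accepted when mismatches ≤ 10% of read length. Ties break
deterministically (fewest mismatches, then smallest start, then + strand);
a score tie between distinct placements yields mapping confidence 0.
Ungapped alignment suffices because the call surface is substitution-only;
external gapped mappers are supported through the text `read_sam()` reader,
which skips records with CIGAR operations beyond M/=/X and terminal soft
clips, counting them in a warning.

One honest limitation of seeding: a read in which *every* sampled seed
carries an error goes unmapped although an exhaustive scan would place it.
At the default 0.2% error rate this is vanishingly rare; at 1% error it
affects ≈0.5% of 100 bp reads. The test suite asserts exact agreement with
an exhaustive-placement oracle for every read the mapper does place.

## Pileup, consensus and calling

`build_pileup()` tallies reference-oriented bases per position, split by
strand, excluding bases below Q20 by default. Overlapping mates contribute
**once** per fragment: the higher-quality mate's base wins (ties to mate 1),
so 2×300 bp libraries with ~600 bp inserts are not double-counted in the
overlap.

`call_consensus()` takes the modal allele per position (ties and zero-depth
positions fall back to the reference). All variants are then reported
against this sample consensus — the in-pipeline equivalent of assembling
each genome before calling, which prevents majority changes of the sequenced
population from being miscalled as low-frequency variants. A site where the
alternative allele exceeds 50% flips the consensus and the *former
reference* becomes the reported variant.

`call_variants()` applies three rules at each position: qualifying depth
≥ 100×; alternative-allele frequency strictly > 1%; and supporting reads
≥ `min_alt_count` (default 2, suppressing singleton errors — not a
published threshold, but any strict >1% rule at ≥100× already implies ≥2
reads). Multi-allelic positions emit one call per alternative allele, so a
codon carrying two segregating substitutions yields two records.

`run_multi_config()` emulates a multi-tool consensus (three mappers × two
callers in the original design) with six internal parameterizations:
`min_base_q` ∈ {15, 20, 25} × `min_alt_count` ∈ {2, 4}. A site's six
frequency estimates (0 where a configuration did not detect it) must all lie
within two *sample* standard deviations (n−1 denominator) of their mean —
`consensus_filter()`, with the all-equal (SD = 0) case passing. A site seen
by only one configuration of six always fails this band; a site seen by
three of six passes the band but usually fails the mean-frequency threshold
(`low_freq`). The reported frequency is the mean of the six estimates. A
list of six externally mapped SAM files can replace the internal grid to
reproduce the original multi-mapper design faithfully.

## Read-backed co-occurrence

For two called sites, `cooccurrence()` classifies every fragment covering
*both* positions as carrying both alternative alleles, exactly one, or
neither; fragments showing a third allele at either site are excluded and
tallied separately. The headline statistic is

$$\mathrm{pct} = 100 \cdot \frac{n_\mathrm{both}}{n_\mathrm{both} + n_{\mathrm{only},i} + n_{\mathrm{only},j}}$$

— the percentage of variant-bearing fragments carrying both variants, the
read-level analogue of the genome-level $C_{ij}$ above, to which it
converges as coverage grows. "Fragment" means a mate pair merged (maximising
span for overlapping libraries); a per-read mode exists for comparison. Raw
counts are always emitted so any alternative ratio can be recomputed.
`cooccurrence_matrix()` evaluates all call pairs, reporting NA percentages
for pairs beyond the fragment span (default 900 bp) or with fewer than 20
informative fragments, while keeping their counts.

## Gene-module localisation

`assign_category()` is a 1-based interval lookup against a non-overlapping
gene annotation with four categories — non-structural, structural,
adsorption-associated (tail-fibre complex; a subset of the structural
module), other/unknown — and implicit non-coding for intergenic positions.
`summarise_categories()` tallies SNPs and distinct genes-with-SNP per
category, optionally rolling structural + adsorption into a
`structural_module` row. `codon_consequence()` translates reference and
mutated codons under the standard genetic code (codon $N$ spans coding bases
$3N{-}2..3N$; minus-strand genes are read reverse-complemented), labelling
changes as `E123K`-style strings or `synonymous`; `multi_snp_codons()`
surfaces codons carrying two or more segregating variants. Overlapping genes
are rejected at load time rather than resolved by precedence; real phage
annotations with minor overlaps must be pre-trimmed.

## What the simulator establishes — and what it does not

A green suite establishes that the thresholds, the consensus rule, the 2-SD
filter, the co-occurrence counting and the annotation arithmetic do exactly
what they claim on data whose truth is known, at realistic depths and error
rates. The generator does **not** model PCR or GC bias, indels, real MiSeq
error profiles (quality-correlated, position-dependent), duplicate
fragments, or library chemistry; a green run is therefore evidence about the
*method*, not a validation against real instrument artefacts.

Two boundary phenomena are worth knowing when interpreting counts near the
thresholds, both visible in the acceptance scenarios:

* at ~500× depth, an alternative-allele count of exactly 5 clears the strict
  1% threshold, so i.i.d. errors at 0.2% produce a few genome-wide false
  positives on large genomes (expected ≈4 on 86 kb) — at the >6000× depths
  of real deep-sequencing runs this effect vanishes;
* sites planted just below threshold (0.5%) occasionally sample above it,
  and the linear-genome coverage ramp near the termini lowers the local
  error-count bar.

## Numerical choices

* Coordinates are 1-based fully-closed everywhere (SAM/GFF/VCF convention).
* Frequency thresholds are strict (`>`), depth thresholds inclusive (`≥`).
* The consensus is derived from the Q20 pileup of the first configuration.
* The agreement filter uses the sample SD (n−1); SD = 0 includes.
* Consensus ties retain the reference base; mapper ties prefer the smaller
  start, then the + strand; mate-overlap quality ties prefer mate 1.
* The binomial checks in the tests use 3 standard deviations/errors at the
  simulated depth; fixed seeds make every suite run deterministic.

## Worked example

```{r example, eval = FALSE}
library(quasipop)
set.seed(1)
ref <- random_genome(43000, id = "phage_sim")
v <- make_planted_variants(ref, c(0.0144, 0.0831, 0.40))
pop <- build_population_independent(ref, v)
reads <- simulate_reads(pop, sim_config(seed = 1))
res <- run_pipeline(pipeline_config(reference = ref, reads = reads,
                                    outdir = "run1", seed = 1))
res$pass
compare_to_truth(res$pass, pop$truth$frequencies)
```

## Known limitations

* Ungapped internal alignment: indel-bearing data must be mapped externally
  and ingested as SAM.
* No haplotype reconstruction beyond pairwise fragment counting; LD
  statistics (D′, r²) are left to downstream computation from the emitted
  counts.
* BAM is out of scope (text SAM only); convert externally.
* The six-configuration grid shares one pileup engine, so with constant
  simulated qualities the three base-quality tiers coincide; the grid
  becomes fully informative with real (variable-quality) data or six
  external SAM inputs.
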