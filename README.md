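# quasipop

Low-frequency variant calling and read-backed SNP co-occurrence for deep-sequenced
bacteriophage populations.

## What this is for

Deep sequencing of a "clonal" lytic phage stock reveals a cloud of
single-nucleotide variants segregating at population frequencies from ~1% to
above 40%, typically concentrated in the structural module of the genome
(tail fibre and neighbouring adsorption genes) — a quasispecies-like,
localised heterogeneity with direct consequences for host-range evolution.
quasipop is an R toolkit for detecting and characterising that heterogeneity,
aimed at phage and viral population genomics:

* **simulate** phage populations with planted variants on weighted haplotypes
  and paired-end reads with machine-readable truth (frequencies *and*
  pairwise co-occurrence are known in closed form), including two-phage
  co-infection pools;
* **filter** reads with the standard regimes (5-base sliding-window Q20 trim;
  mean-Q30 / length-50 removal);
* **map** reads with a deterministic seed-and-extend ungapped aligner, or
  ingest text SAM from external mappers;
* **call** variants against the *sample consensus* under the field's
  thresholds — coverage ≥ 100×, frequency > 1% — with a six-configuration
  consensus in which all frequency estimates must lie within two standard
  deviations of their mean;
* **link** variants by counting sequenced fragments that span two sites:
  `pct = 100 · n_both / (n_both + n_only_i + n_only_j)`;
* **localise** variants on annotated gene modules (non-structural /
  structural / adsorption / other / non-coding), with codon-level
  consequences (`E123K`, `synonymous`, multi-SNP codons).

The methods vignette (`vignettes/quasipop-methods.Rmd`) documents the models,
defaults and numerical choices in detail.

## Worked example

```r
library(quasipop)
set.seed(1)
ref   <- random_genome(43000, id = "phage_sim")
v     <- make_planted_variants(ref, c(0.0144, 0.0831, 0.40))
pop   <- build_population_independent(ref, v)
reads <- simulate_reads(pop, sim_config(seed = 1))   # 2x300 bp, 1000x, 0.2% error
res   <- run_pipeline(pipeline_config(reference = ref, reads = reads,
                                      outdir = tempfile(), seed = 1))
res$pass[, c("pos", "ref", "alt", "freq", "depth", "filter")]
```

```
    pos ref alt       freq depth filter
2  9676   C   A 0.01337449   972   PASS
3 18042   T   G 0.39225422  1007   PASS
4 20033   G   A 0.08424182  1009   PASS
```

Three planted sites in, three PASS calls out, with frequency estimates within
binomial error of the planted 1.44%, 40% and 8.31%:

```r
cmp <- compare_to_truth(res$pass, pop$truth$frequencies)
unlist(cmp[c("precision", "recall", "mean_abs_freq_error")])
#>           precision              recall mean_abs_freq_error
#>         1.000000000         1.000000000         0.003304373
```

The run directory contains `calls.vcf` (VCF 4.2, INFO fields AF/DP/AC/NCONF,
FILTER `PASS`/`sd2_fail`/`low_freq`/`low_cov`), TSV mirrors of the calls and
pairwise co-occurrence, a category summary when an annotation is supplied,
and a log naming the configuration hash and seed.

## Command line

A thin CLI wraps the same functions:

```sh
Rscript -e 'quasipop::quasipop_cli()' simulate --config sim.json --outdir sim --seed 1
Rscript -e 'quasipop::quasipop_cli()' run --ref sim/reference.fasta \
    --r1 sim/sim_R1.fastq --r2 sim/sim_R2.fastq --outdir run1 --seed 1
Rscript -e 'quasipop::quasipop_cli()' compare --vcf run1/calls.vcf --truth sim/truth_variants.tsv
```

Subcommands: `simulate`, `qc`, `align`, `call`, `linkage`, `annotate`, `run`,
`compare` (see `?quasipop_cli`).

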