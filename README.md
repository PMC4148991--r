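# agios

Gene-based average genomic identity for bacterial species delineation.

## The problem

Modern descriptions of new bacterial species combine phenotype with
genome-derived relatedness measures ("taxono-genomics"). Two such measures
recur throughout the literature:

* **16S rRNA identity** against the closest named relative, compared with
  the conventional **98.7%** threshold: an isolate below it is a candidate
  new species without DNA–DNA hybridization.
* **AGIOS** (Average Genomic Identity Of gene Sequences), an ANI-like
  statistic restricted to genic regions. For two genomes *A* and *B* with
  orthologous gene pairs `(a_i, b_i), i = 1..n` detected as reciprocal best
  hits (RBH) on the protein sequences,

  ```
  AGIOS(A, B) = (1/n) * sum_i  100 * matches(a_i, b_i) / columns(a_i, b_i)
  ```

  where `matches` and `columns` come from a Needleman–Wunsch **global**
  alignment of the nucleotide CDS pair with affine gap costs, and gap
  columns count in the denominator.

This package implements that pipeline end to end, self-contained and
oracle-tested: FASTA and 12-column ("outfmt 6") hit-table I/O, an
affine-gap global aligner, RBH orthology with a shared-k-mer prefilter,
AGIOS and the multi-genome comparison matrix, the dual-threshold ORFan
rule, genome composition / COG category summaries, the delineation check,
and a divergence simulator that produces gene-set pairs with a
machine-readable truth table so every stage can be validated without any
downloads.

Who it is for: microbial taxonomists writing species descriptions, and
anyone who needs a transparent, dependency-light reference implementation
of gene-based identity statistics.

## Worked example

Simulate a pair of gene sets at 5% per-site divergence and recover it:

```r
library(agios)

sim <- simulate_pair(simulation_config(n_genes = 50, divergence_d = 0.05,
                                       seed = 42))
res <- compute_agios(sim$set_a, sim$set_b)
res
#> <agios_result> A vs B
#>   orthologs: 50 | AGIOS: 95.02%
round(sim$truth$mean_realized_identity, 2)
#> [1] 95.01
```

All 50 simulated orthologs are recovered and AGIOS reproduces the
simulator's realized identity (the fraction of sites actually unchanged)
to two decimals — at 5% nominal divergence roughly 95% identity remains.

A three-genome star phylogeny, rendered in the layout used by species
descriptions (diagonal: gene counts; upper triangle: ortholog counts;
lower triangle: AGIOS %):

```r
star <- simulate_star(simulation_config(n_genes = 30,
                                        gene_length_range = c(60, 120),
                                        seed = 7),
                      divergences = c(0.02, 0.05, 0.10))
agios_matrix(star$sets)
#> <agios_matrix> 3 genomes (diagonal: genes; upper: orthologs; lower: AGIOS %)
#>   A     B     C
#> A 30    30    30
#> B 93.56 30    30
#> C 88.24 85.78 30
```

The closest pair (A,B — total branch divergence 0.07) scores highest,
the farthest (B,C — 0.15) lowest, as it must.

The delineation check:

```r
delineation_check(96.7)
#> 16S identity 96.70% vs 98.70% threshold: candidate new species
```

A command-line wrapper with `align`, `agios`, `orfans`, `stats`,
`delineate` and `simulate` subcommands ships in
`inst/scripts/agios-cli.R`.

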