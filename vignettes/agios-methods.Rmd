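---
title: "Gene-based average genomic identity: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-based average genomic identity: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agios)
```

## The statistic and its assumptions

AGIOS (Average Genomic Identity Of gene Sequences) summarises the
relatedness of two bacterial genomes as the mean nucleotide identity over
their orthologous genes. It differs from whole-genome ANI methods in that
it is strictly genic: orthologs are detected on the protein sequences,
then the corresponding nucleotide CDS are aligned. The chain is

1. translate each CDS (bacterial code, table 11);
2. detect orthologs as reciprocal best hits (RBH) between the two
   proteomes under global alignment score;
3. globally align each orthologous CDS pair at the nucleotide level;
4. average the per-pair percent identities, unweighted.

The statistic therefore assumes that the input gene sets are trustworthy
(gene calling is upstream of this package), that orthology is 1:1 (RBH is
a matching; paralog families contribute at most one pair), and that a
global — not local — alignment is meaningful, i.e. the paired sequences
are homologous over their full length.

## Alignment model

`global_align()` is a three-state (match / gap-in-A / gap-in-B) affine-gap
Needleman–Wunsch dynamic program with end gaps penalized like any other
gap. A gap of length $L$ costs $g_o + L \cdot g_e$. Defaults, all
overridable through `scoring_scheme()`:

| mode | substitution | $g_o$ | $g_e$ |
|---|---|---|---|
| nucleotide | match $+5$, mismatch $-4$ | 10 | 0.5 |
| protein | BLOSUM62 | 11 | 1 |

These are the familiar megablast/blastp-like parameter sets, chosen
because the method descriptions this pipeline follows name the algorithm
but not its parameters; fixing documented defaults keeps runs
reproducible. The dynamic program is verified in the test suite two ways:
against exhaustive enumeration of *all* global alignments for short
sequences, and against an independent affine-gap aligner (Biostrings) on
longer random pairs.

Numerical and tie-break choices:

* **Identity denominator.** Percent identity is
  $100 \cdot \text{matches} / \text{columns}$ over *all* alignment
  columns, including internal and terminal gaps — the most conservative
  convention. Because published identity values are sensitive to this
  choice and the original tools rarely state it,
  `percent_identity(aln, "exclude_terminal_gaps")` reports the other
  convention side by side.
* **Ambiguity codes** (IUPAC nucleotides, `X`/`*` in proteins) are
  accepted on input but never count as identity matches and score as
  mismatches: conservative and deterministic.
* **Traceback ties** prefer a residue/residue column over a gap in the
  second sequence over a gap in the first, at every cell and at the final
  state, so output is identical across platforms. When several distinct
  alignments are co-optimal, aligning $(b,a)$ instead of $(a,b)$ may
  legitimately return a different one with the same score; score is
  symmetric, the reported column statistics need not be.

## Orthology parameters

`rbh_params()` controls ortholog detection:

* `min_pct_identity = 30` (%): below ~30% protein identity homology
  inference from pairwise alignment alone is unreliable ("twilight
  zone"), so candidate pairs under it are discarded.
* `min_coverage = 0.5`: residue/residue columns must cover at least half
  of the shorter protein, excluding fragment-on-domain matches.
* `prefilter_kmer = 5`: protein pairs sharing no exact 5-mer are skipped
  before any alignment. This is a heuristic: sharing zero 5-mers does not
  *prove* a pair could not pass the thresholds, but at the identity
  levels the thresholds demand, conserved 5-mers are abundant. The test
  suite re-runs fixtures with the prefilter disabled (`NA`) and asserts
  identical output.

Best hits are ranked by the affine-gap global alignment score itself
rather than a local-alignment bit score — a deliberate deviation from
BLAST-based RBH that keeps the whole pipeline on one oracle-verified
engine; ties break towards the lexicographically smaller partner id.
Internally the all-vs-all scan computes scores only; full alignments are
computed lazily, walking each query's candidates in score order until one
passes the identity/coverage filter, which yields exactly the matching of
filter-everything-then-take-best because the filter does not alter
scores.

Genes whose CDS does not translate (internal stop, length not a multiple
of three) are excluded from RBH but still counted in the per-genome gene
totals shown on the comparison-matrix diagonal. When no orthologs pass,
AGIOS is reported as missing (`NA`), never 0. A length-weighted mean is
available (`weighted = TRUE`) next to the default unweighted mean, which
follows the statistic's definition as a mean over ortholog pairs.

## The ORFan rule

A gene is an ORFan when no database hit qualifies as homology evidence.
A hit qualifies when E-value ≤ `1e-3` for alignments longer than 80
amino-acid columns, or E-value ≤ `1e-5` for alignments of 80 or fewer
(short alignments reach small E-values more easily by chance, so they get
the stricter cut). Three boundary decisions, all exposed in
`orfan_policy()`:

* exactly 80 columns routes to the *stricter* branch ("longer than 80"
  read verbatim);
* E-value comparison is inclusive (≤);
* self-hits (query id = subject id) are ignored.

Some published wordings of this rule state it inverted (a gene "is an
ORFan if" its hit's E-value is *below* the threshold). Taken literally
that would flag well-conserved genes, contradicting ORFans being a small
minority of any genome; the conventional reading is the default and
`literal_rule = TRUE` exists for exact-wording replication.

## Composition summaries and delineation

`gc_content()` counts G, C and the ambiguity code S (G-or-C) towards G+C;
every other code, including N, counts only in the denominator.
`coding_fraction()` merges overlapping gene intervals (IRanges) before
counting covered bases, so a base under two genes is counted once; the
unmerged sum is available with `merge_overlaps = FALSE`. Published
genome-description tables occasionally print a coding percentage that
disagrees with its own printed base count; this package always computes
the quotient and never reprints an inconsistent pair.

`cog_distribution()` increments every category of a multi-category gene,
so category counts may sum to more than the number of assigned genes;
percentages use the protein-coding gene total as denominator (the
convention of published tables, verified arithmetically against them) and
the distinct-gene count is carried in an attribute so both denominators
are explicit. `build_cog_assignments()` reconstructs a concrete
assignment list from published per-category counts for exactly this kind
of arithmetic replication.

`delineation_check()` applies the 98.7% 16S threshold strictly: identity
*below* the threshold flags a candidate new species; identity exactly at
it does not.

## What the simulator emulates — and what it does not

`simulate_pair()` draws ancestral genes codon-wise (stop codons redrawn)
with base probabilities $P(G) = P(C) = \text{gc}/2$, then derives
descendant B by mutating every site independently with probability $d$ to
a uniformly chosen different base, redrawing mutations that would create
an internal stop. Descendant A is the ancestor itself, so the pair's
divergence is exactly one branch of length $d$. This is a Jukes–Cantor-
like uniform substitution model, chosen deliberately: AGIOS is an
identity statistic, not a rate or dN/dS statistic, so exact bookkeeping
of *realized* identity (the fraction of sites actually unchanged, written
to the truth table) matters more than codon-model realism. Defaults — 200
genes of 100–500 codons, G+C 0.62, $d = 0.05$ — put simulated pairs in
the identity regime where gene-based statistics separate closely related
species from distinct ones.

Features of real data the simulator does not emulate: paralogous gene
families, rearrangement and horizontal transfer, intergenic sequence,
length variation beyond single codon indels, compositional heterogeneity
along the genome, and sequencing/assembly error. Passing the recovery
tests therefore demonstrates that the pipeline's machinery is correct
(orthology recovery is exact, AGIOS tracks realized identity to within
0.5 points across $d \in [0.01, 0.2]$), not that RBH resolves paralogs
or that AGIOS is robust to assembly artefacts.

Stop-codon avoidance biases realized G+C slightly relative to the raw
base probabilities (the excluded codons are A/T-rich, so the bias is
upward of target at low G+C and negligible at 0.62); the generator
promises ±2 points on average and the tests check that.

Gene loss is i.i.d. per gene per descendant, so the shared-gene count is
Binomial$(n, (1-p)^2)$; recovery tests compare detected ortholog counts
against that expectation within three binomial standard errors.

## Problem sizes and reproducibility

The validation suite uses 200-gene simulations for parameter-recovery
checks (four divergence levels, three seeds each, plus a 10% gene-loss
condition) and 10–50-gene simulations elsewhere; the exhaustive alignment
oracle sweeps 500 random nucleotide pairs of length ≤ 8, the scale at
which full enumeration is tractable. These sizes give the recovery
statistics comfortable margins (a 200-gene pair carries ~180,000 coding
sites, putting the binomial standard error of mean identity near 0.05
points) while keeping a full validation run in minutes on one core.

Every stochastic component is driven by an explicit integer seed
(`simulation_config(seed = )`, `--seed` in the command-line wrapper and
acceptance script), and the pipeline writes byte-identical reports for
identical (inputs, config, seed) — asserted in the test suite.

## Known limitations

* RBH under global-alignment score is not identical to Proteinortho-style
  RBH on local-alignment bit scores; on gene sets with large length
  variation between true orthologs, global end-gap penalties can demote a
  true pair below a spurious same-length partner. The coverage filter
  mitigates but does not eliminate this.
* The k-mer prefilter's soundness is empirical, not proven; it is
  validated on the test fixtures and can be disabled.
* AGIOS is reported for whatever orthologs pass the filters; with very
  few orthologs the mean is noisy, and callers should inspect
  `n_orthologs` (the comparison matrix prints it alongside).
* 16S identity feeding `delineation_check()` should be computed on
  near-full-length sequences; the check itself is a threshold comparison
  and does not guard against partial-sequence inflation.
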