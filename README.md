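# biofilters

Pipe-composable command-line filters — `bioseq`, `bioaln`, `biopop`,
`biotree` — for molecular sequences, multiple alignments, allelic
population samples, and phylogenetic trees, written as an R package.

## Who this is for

Comparative genomics and molecular-evolution work is full of small,
serially dependent text transformations: translate a set of CDS,
align the proteins, back-translate to a codon alignment, infer a tree,
root it, prune it, and compute polymorphism statistics along the way.
`biofilters` packages those steps as UNIX-style utilities that read
standard input when no file is given and write nothing but payload to
standard output, so whole workflows run as shell pipelines with no
temporary files — and every operation is equally available as a plain R
function for interactive use.

Each command owns one object type and one default serialization:

| command   | object              | default format |
|-----------|---------------------|----------------|
| `bioseq`  | sequences           | FASTA (GenBank via `-i genbank`) |
| `bioaln`  | alignments          | CLUSTAL (FASTA/PHYLIP via `-i`/`-o`) |
| `biopop`  | allelic samples     | FASTA |
| `biotree` | phylogenetic trees  | Newick |

## The statistics at the core

For an aligned sample of *n* allelic sequences, restricted to the
columns where every allele carries an unambiguous A/C/G/T:

- **Segregating sites** *S*: columns with ≥ 2 distinct nucleotides.
- **Nucleotide diversity** π: the mean number of differing sites over
  all *n(n−1)/2* unordered pairs (raw differences; `--per-site`
  normalizes by usable sites).
- **Watterson's estimator** θ_W = *S* / *a*, with
  *a* = Σ_{i=1}^{n−1} 1/i.
- **Mismatch distribution**: the histogram of pairwise difference
  counts (its mean is π by construction).
- **Coding SNPs**: variable codons classified as synonymous,
  nonsynonymous, or multi-hit under the standard genetic code.

Tree surgery (midpoint and outgroup rerooting, OTU deletion, subtree
extraction, support-threshold collapsing) preserves the patristic
distance matrix among surviving leaves exactly; collapsing an edge adds
its length to each promoted child so root-to-tip depths survive too.

## Worked example

Shipped toy inputs (regenerable with the package's own seeded
generators) live in `inst/extdata/`.  In R:

```r
library(biofilters)
fa  <- system.file("extdata", "example_cds.fasta", package = "biofilters")
pop <- system.file("extdata", "example_pop.fasta", package = "biofilters")
nwk <- system.file("extdata", "example_tree.nwk",  package = "biofilters")

bioseq(c("-t1", fa))          # translate three CDS
#> >gene1
#> MSPDATLSET
#> >gene2
#> MECREERANY
#> >gene3
#> MCRLFGGIWT

biopop(c("-s", pop))          # segregating sites in a 5-allele sample
#> 4
biopop(c("-t", "pi,theta", pop))
#> pi      2.2
#> theta   1.92
```

Here `pi = 2.2` means an average pair of alleles differs at 2.2 of the
60 sites, and `theta = 1.92` is S = 4 divided by the harmonic number
a₄ = 1 + 1/2 + 1/3 + 1/4 ≈ 2.083 — the two classic estimators of the
population mutation rate for this sample.

The same commands compose on the shell (the launchers are installed
under `inst/bin/`; invoke them via `Rscript` or add them to `PATH`):

```sh
bioaln -o fasta aln.aln | bioseq -p 're:B31' | bioseq -g | bioseq -t1
biotree -m tree.dnd | biotree -D 75 | biotree -d 'L1,L2'
bioseq -t1 cds.fas | mafft --clustalout /dev/stdin \
  | bioaln --pep2dna cds.fas -o fasta
```

The second pipeline midpoint-roots a tree, collapses every branch with
bootstrap support below 75, and discards two OTUs; on the shipped
example tree it prints:

```
(L1:0.0483461,L2:4.868854447,(L4:0.3599869222,L6:0.7480269018)92:2.760166385,L5:2.601035391,L3:2.167631513);
```

— the nodes supported at 59, 59 and 69 have become polytomies, the node
at 92 survives, and every root-to-tip depth is unchanged.

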