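---
title: "biofilters: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{biofilters: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biofilters)
```

`biofilters` implements four pipe-composable utilities — `bioseq`,
`bioaln`, `biopop`, `biotree` — for sequences, alignments, allelic
samples and trees.  This vignette records the models behind the
statistics, the conventions behind the formats, and the choices made
where the design was genuinely open.  Every empirical claim here is
recomputed by the test suite; nothing below is asserted from memory.

## The pipes-and-filters contract

Each invocation performs at most one operation: zero operation flags
means identity pass-through (useful for format conversion, e.g.
`bioaln -o fasta`), more than one is an error.  Payload goes to
standard output only; warnings, errors and the seed notice for
stochastic operations go to the diagnostic stream, so `a | b` chains
never feed log text into a parser.  Every documented error path exits
nonzero.  Absent file arguments (or `-`) mean standard input, and
reading from a path or from the same bytes on standard input yields
identical objects.

## Formats

* **FASTA** — headers split at the first whitespace into id and
  description; output wraps residues at 60 columns (a conventional
  width; the choice only affects bytes, not objects, and round trips
  byte-identically).
* **CLUSTAL** — interleaved blocks merged per id; conservation lines
  (leading whitespace) ignored.
* **PHYLIP** — relaxed interleaved dialect with an `ntax nchar` header.
  Names are *not* truncated to 10 characters: truncation would make
  id-addressed operations (pick, delete, back-translation) lossy, and
  every downstream tool we care about accepts relaxed names.
* **GenBank** — only LOCUS (id), DEFINITION (description) and ORIGIN
  (residues) are interpreted; feature tables are out of scope.
* **Newick** — parsing is delegated to `ape` after a structural
  pre-check that reports character offsets for unbalanced parentheses
  and non-numeric branch lengths.  A bare internal label that parses as
  a number is a support value; otherwise it is a node name (so clades
  can be addressed by name).  Missing branch lengths read as 0 with a
  warning; trifurcating roots are accepted.

Residues are normalized to upper case on input; ids are kept verbatim.

## Sequence operations

Translation uses the standard genetic code only; the original option
surface documents no code table switch, and adding one silently would
invite wrong-code mistakes on organellar data.  Trailing partial codons
are dropped, stops render as `*`, and a codon containing IUPAC
ambiguity translates to the unique amino acid all its resolutions share
or `X` otherwise.  Frames `3`/`6` tag output ids with `_f+1` … `_f-3`.
Reverse-complement uses the full IUPAC complement map and keeps gaps in
place, which makes `degap` and `revcom` commute.

The restriction table is a small curated set (EcoRI, BamHI, HindIII,
NotI, TaqI) with recognition site and cut offset; sites are located on
the forward strand and fragments always concatenate back to the input.
Selectors (`id:`, `order:`, `re:`) address records by identifier,
1-based inclusive order ranges, or a regular expression searched within
the id only — descriptions are free text and matching into them makes
selections irreproducible across annotation edits.

## Alignment operations

Average percent identity uses pairwise deletion: for each member pair,
columns gapped in either member leave both numerator and denominator.
No formula was prescribed, so the choice is documented and checked
against an all-pairs brute-force oracle.  Pairs with no comparable
columns are excluded from the mean.

`concat` requires identical id sets rather than padding missing rows
with gaps: silent gap-filling fabricates data, and in the
thousands-of-loci use case an id mismatch almost always means an
upstream bug worth surfacing.

`pep2dna` (codon-aware back-translation) requires that each CDS's
frame-1 translation equal its degapped aligned protein, tolerating one
terminal stop codon; each residue expands to its source codon, each gap
to `---`, so output length is exactly 3× the protein alignment and
translating the degapped output reproduces the degapped input.

Stochastic operations (`bootstrap`, `shuffle-sites`, `mutate-sites`)
take an explicit `--seed`; the default (42) is printed to the
diagnostic stream so published pipelines stay reproducible.
`mutate-sites` mutates *residues*, not columns: each non-gap character
is independently replaced with probability `rate` by a different
uniformly chosen nucleotide.  The column interpretation was the open
alternative; per-residue semantics compose more naturally with the
bootstrap (which resamples columns) and is what "mutation rate" means
in simulation practice.

## Population statistics

All `biopop` statistics share a single site mask: a column is usable
only when every allele carries an unambiguous A/C/G/T.  One shared rule
keeps numerators and denominators consistent — S, π and the mismatch
histogram are all counted over the same columns, so the identity
"histogram mean = π" holds exactly, and S ≤ usable sites by
construction.  π is reported as raw average pairwise differences
(matching the "average nucleotide differences" reading of the option),
with `--per-site` for the normalized variant.  θ_W = S/a with
a = Σ 1/i, i < n.  Multi-allelic sites count once toward S.  Coding-SNP
classification fixes the reading frame at column 1, skips codons
overlapping masked columns, and calls a variable codon synonymous when
all observed codons translate identically, nonsynonymous when exactly
one position segregates and the amino acids differ, multi-hit when more
than one position segregates (no parsimony pathway reconstruction is
attempted for multi-hit codons).

## Tree operations

Tree containers are `ape::phylo` objects; rerooting, pruning and
distance code builds on `ape` and `phangorn` rather than reimplementing
them ("wrap, don't write"), with contracts enforced and tested at this
package's surface.  Invariants the suite checks at 1e-9: midpoint and
outgroup rerooting preserve the full patristic matrix and total length;
deletion and subsetting preserve distances among survivors; after
midpoint rooting the two deepest root-to-tip depths (one per root
child) are equal.

Outgroup rerooting inserts the root at the midpoint of the outgroup's
pendant edge.  Implementation note: after `ape::root()` the two root
edges form a single edge of the unrooted tree, so redistributing their
total length evenly is distance-neutral — that is how the midpoint
placement is realized.

Support-threshold collapsing (`-D`) contracts internal edges whose
child support is *strictly below* the threshold ("less than" semantics,
matching the `-D 1.0` = remove-below-100% usage).  The contracted
edge's length is added to each promoted child's edge, preserving
root-to-leaf depths and therefore OTU depths and distances — the
alternative (discarding the length) would shrink the tree by an amount
that depends on topology, which makes downstream rate estimates
uninterpretable.  Support labels are compared numerically with no
rescaling, so percentage (75) and fractional (0.9) scales both work
against a matching threshold; unlabeled internal nodes are never
collapsed and trigger a warning.  Surviving support labels are
retained.  When a `--subset` target names both a leaf and an internal
node, the leaf wins with a warning.

## Synthetic data: what the generators emulate

The fixture generators make every test self-contained:

* `make_cds_set` — in-frame CDS starting with ATG and free of internal
  stops, with translations recorded for oracle use.
* `make_allele_sample` — a deliberately simple neutral-sample model,
  not a full coalescent: the mutation count is Poisson with mean
  θ·a_n, and each mutation's derived-allele count *i* is drawn from the
  neutral site-frequency spectrum P(i) ∝ 1/i before being placed at a
  distinct site (infinite-sites style).  Under this model E[π] =
  E[θ_W] = θ *exactly*, which is what makes the parameter-recovery
  criterion a property of the stated world rather than a tuned number.
  What it does not emulate: genealogical correlation between sites
  (variances are smaller than coalescent variances), recombination,
  indels, rate heterogeneity.  A green recovery test therefore
  establishes estimator correctness, not robustness to real data.
* `make_tree` — Yule (pure-birth) topology by uniform leaf splitting,
  exponential branch lengths, uniform integer support labels in a
  configurable range.

All generators are pure functions of their arguments; the same seed
reproduces byte-identical output.  Default scales in the tests (e.g.
locus length 500 for θ = 5, n = 20; 30-leaf trees for the metamorphic
suite) were chosen once as realistic desk-scale values and keep the
whole suite under a minute.

## Numerical and degenerate-input choices

* Tolerances: metamorphic tree identities at 1e-9 (pure additions of
  doubles); Newick round trips at 1e-8 (decimal serialization at 10
  significant digits).
* Midpoint falling on an existing vertex introduces no zero-length
  edge; ties for the diameter pair are broken deterministically.
* Empty sequence input is an empty set (so `bioseq -n` reports 0), but
  an empty alignment file is a format error.
* `degap` may produce empty records; they are kept, with length 0.
* `avg_pid` on fewer than 2 members, pairwise statistics on n < 2, and
  subtree extraction leaving < 2 leaves are errors, not NA.

## Known limitations

GenBank parsing is intentionally minimal; NEXUS, FASTQ and VCF are out
of scope, as are alignment inference (use MUSCLE/MAFFT), tree inference
(FastTree), neutrality tests beyond π/θ_W, and graphical output.  The
ASCII preview is a topology sketch (unit edge lengths), not a
branch-length plot.
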