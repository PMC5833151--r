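## biopop statistics over aligned allelic nucleotide sequences.
##
## All statistics share one site mask: a column is "usable" only when
## every allele carries an unambiguous A/C/G/T there (complete deletion
## of gapped/ambiguous columns), so numerators and denominators are
## consistent across S, pi, the mismatch distribution and theta.

#' Construct an allele sample from an alignment
#'
#' @param aln A nucleotide `bio_aln` alignment (or `bio_seqs` of equal
#'   lengths) of same-locus allelic sequences.
#' @return An object of class `allele_sample` with fields `aln`, `n`,
#'   `matrix` and `usable_sites` (indices of fully resolved columns).
#' @export
allele_sample <- function(aln) {
  if (!inherits(aln, "bio_aln")) aln <- as_alignment(aln)
  if (!is_nucleotide_set(aln)) {
    bf_stop("allele samples must be nucleotide sequences")
  }
  m <- aln_matrix(aln)
  usable <- which(apply(m, 2L, function(col) all(col %in% c("A", "C", "G", "T"))))
  structure(list(aln = aln, n = length(aln), matrix = m,
                 usable_sites = usable),
            class = "allele_sample")
}

as_allele_sample <- function(x) {
  if (inherits(x, "allele_sample")) x else allele_sample(x)
}

require_pairs <- function(sample) {
  if (sample$n < 2L) {
    bf_stop("need at least 2 sequences for pairwise statistics")
  }
}

#' Number of segregating sites
#'
#' Counts usable columns where at least two distinct nucleotides occur
#' (multi-allelic sites count once).
#'
#' @param sample An `allele_sample` (or alignment, coerced).
#' @return Integer S.
#' @export
segregating_sites <- function(sample) {
  sample <- as_allele_sample(sample)
  require_pairs(sample)
  if (length(sample$usable_sites) == 0L) return(0L)
  m <- sample$matrix[, sample$usable_sites, drop = FALSE]
  sum(apply(m, 2L, function(col) length(unique(col)) > 1L))
}

pair_diff_counts <- function(sample) {
  m <- sample$matrix[, sample$usable_sites, drop = FALSE]
  n <- sample$n
  diffs <- integer(0L)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      diffs <- c(diffs, sum(m[i, ] != m[j, ]))
    }
  }
  diffs
}

#' Nucleotide diversity (average pairwise differences)
#'
#' Mean over all `n(n-1)/2` unordered pairs of the number of usable
#' sites at which the pair differs.  Raw differences by default; set
#' `per_site = TRUE` to divide by the number of usable sites.
#'
#' @param sample An `allele_sample` (or alignment).
#' @param per_site Normalize by usable site count.
#' @return Numeric pi.
#' @export
nucleotide_diversity <- function(sample, per_site = FALSE) {
  sample <- as_allele_sample(sample)
  require_pairs(sample)
  val <- mean(pair_diff_counts(sample))
  if (per_site) {
    if (length(sample$usable_sites) == 0L) return(0)
    val <- val / length(sample$usable_sites)
  }
  val
}

#' Watterson's theta
#'
#' `theta_W = S / a` with `a = sum_{i=1}^{n-1} 1/i` and S the number of
#' segregating sites.
#'
#' @param sample An `allele_sample` (or alignment).
#' @return Numeric theta estimate (raw, same scale as S).
#' @export
watterson_theta <- function(sample) {
  sample <- as_allele_sample(sample)
  require_pairs(sample)
  s <- segregating_sites(sample)
  a <- sum(1 / seq_len(sample$n - 1L))
  s / a
}

#' Pairwise mismatch distribution
#'
#' @param sample An `allele_sample` (or alignment).
#' @return Named integer vector: for k = 0..max observed, the number of
#'   unordered pairs differing at exactly k usable sites.  Counts sum
#'   to `n(n-1)/2`; the histogram mean equals [nucleotide_diversity()].
#' @export
mismatch_distribution <- function(sample) {
  sample <- as_allele_sample(sample)
  require_pairs(sample)
  diffs <- pair_diff_counts(sample)
  ks <- 0:max(diffs)
  stats::setNames(vapply(ks, function(k) sum(diffs == k), integer(1L)),
                  as.character(ks))
}

#' Classify coding SNPs by codon
#'
#' The alignment is read as in-frame CDS alleles (length divisible
#' by 3; codon phase fixed at column 1).  Codons containing any
#' non-ACGT character in any allele are skipped, consistent with the
#' shared usable-site mask.  A variable codon is `synonymous` when all
#' observed codons translate identically, `nonsynonymous` when a single
#' position segregates and amino acids differ, and `multi-hit` when
#' more than one position in the codon segregates.
#'
#' @param sample An `allele_sample` (or alignment).
#' @return A list with `table` (data frame: `codon`, `alleles`,
#'   `effect`) and `counts` (named totals per class).
#' @export
snp_coding <- function(sample) {
  sample <- as_allele_sample(sample)
  require_pairs(sample)
  len <- aln_width(sample$aln)
  if (len %% 3L != 0L) {
    bf_stop("alignment length ", len, " is not divisible by 3")
  }
  m <- sample$matrix
  rows <- list()
  for (cd in seq_len(len %/% 3L)) {
    cols <- (3L * cd - 2L):(3L * cd)
    block <- m[, cols, drop = FALSE]
    if (!all(block %in% c("A", "C", "G", "T"))) next
    codons <- apply(block, 1L, paste, collapse = "")
    uniq <- unique(codons)
    if (length(uniq) < 2L) next
    nseg <- sum(apply(block, 2L, function(col) length(unique(col)) > 1L))
    effect <- if (nseg > 1L) {
      "multi-hit"
    } else {
      aas <- unique(vapply(uniq, translate_codon, character(1L)))
      if (length(aas) == 1L) "synonymous" else "nonsynonymous"
    }
    rows[[length(rows) + 1L]] <-
      data.frame(codon = cd, alleles = paste(sort(uniq), collapse = "/"),
                 effect = effect, stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(codon = integer(0L), alleles = character(0L),
               effect = character(0L), stringsAsFactors = FALSE)
  counts <- c(synonymous = sum(tab$effect == "synonymous"),
              nonsynonymous = sum(tab$effect == "nonsynonymous"),
              `multi-hit` = sum(tab$effect == "multi-hit"))
  list(table = tab, counts = counts)
}

#' Bundle of named population statistics
#'
#' @param sample An `allele_sample` (or alignment).
#' @param names Character vector drawn from `"pi"` and `"theta"`.
#' @return Named numeric vector, one element per requested statistic.
#' @export
stats_bundle <- function(sample, names) {
  if (length(names) == 0L) bf_stop("no statistics requested")
  supported <- c("pi", "theta")
  bad <- setdiff(names, supported)
  if (length(bad) > 0L) {
    bf_stop("unknown statistic(s): ", paste(bad, collapse = ", "),
            "; supported: ", paste(supported, collapse = ", "))
  }
  sample <- as_allele_sample(sample)
  vapply(names, function(nm) {
    switch(nm,
           pi = nucleotide_diversity(sample),
           theta = watterson_theta(sample))
  }, numeric(1L))
}
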