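# Independent brute-force oracles used across the suite.  Deliberately
# naive (explicit double loops, no shared code with the package
# internals beyond the public matrix accessor).

aln_char_matrix <- function(aln) {
  ids <- vapply(aln, function(r) r$id, character(1L))
  m <- do.call(rbind, strsplit(vapply(aln, function(r) r$seq, character(1L)),
                               "", fixed = TRUE))
  rownames(m) <- ids
  m
}

usable_columns <- function(m) {
  ok <- logical(ncol(m))
  for (j in seq_len(ncol(m))) {
    ok[j] <- all(m[, j] %in% c("A", "C", "G", "T"))
  }
  which(ok)
}

oracle_seg_sites <- function(aln) {
  m <- aln_char_matrix(aln)
  s <- 0L
  for (j in usable_columns(m)) {
    if (length(unique(m[, j])) > 1L) s <- s + 1L
  }
  s
}

oracle_pair_diffs <- function(aln) {
  m <- aln_char_matrix(aln)
  use <- usable_columns(m)
  n <- nrow(m)
  out <- integer(0L)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      d <- 0L
      for (k in use) if (m[i, k] != m[j, k]) d <- d + 1L
      out <- c(out, d)
    }
  }
  out
}

oracle_pi <- function(aln) mean(oracle_pair_diffs(aln))

oracle_mismatch <- function(aln) {
  d <- oracle_pair_diffs(aln)
  counts <- integer(max(d) + 1L)
  for (x in d) counts[x + 1L] <- counts[x + 1L] + 1L
  stats::setNames(counts, as.character(0:max(d)))
}

oracle_avg_pid <- function(aln) {
  m <- aln_char_matrix(aln)
  n <- nrow(m)
  vals <- c()
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      same <- 0L; comp <- 0L
      for (k in seq_len(ncol(m))) {
        if (m[i, k] != "-" && m[j, k] != "-") {
          comp <- comp + 1L
          if (m[i, k] == m[j, k]) same <- same + 1L
        }
      }
      vals <- c(vals, if (comp > 0L) 100 * same / comp else NA_real_)
    }
  }
  mean(vals, na.rm = TRUE)
}

# harmonic number via digamma: sum_{i=1}^{k} 1/i = digamma(k+1) - digamma(1)
oracle_harmonic <- function(k) digamma(k + 1) - digamma(1)

# patristic distance via root depths and the LCA, independently of
# cophenetic(): d(x, y) = depth(x) + depth(y) - 2 * depth(lca)
oracle_patristic <- function(tree) {
  dep <- ape::node.depth.edgelength(tree)
  nt <- ape::Ntip(tree)
  m <- matrix(0, nt, nt, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(nt - 1L)) {
    for (j in seq.int(i + 1L, nt)) {
      lca <- ape::getMRCA(tree, c(i, j))
      m[i, j] <- m[j, i] <- dep[i] + dep[j] - 2 * dep[lca]
    }
  }
  m
}

# allele sample of n haplotypes with exactly s segregating sites:
# haplotype 2 differs from the rest at the first s columns
synthetic_s_sample <- function(n, s) {
  len <- max(s, 1L)
  recs <- lapply(seq_len(n), function(i) {
    base <- rep("A", len)
    if (s > 0L && i == 2L) base[seq_len(s)] <- "C"
    seq_record(paste0("h", i), paste(base, collapse = ""))
  })
  allele_sample(as_alignment(seq_set(recs)))
}

rand_gapped_aln <- function(n = 5L, len = 40L, seed = 1L) {
  as_alignment(make_seq_set(n_seqs = n, seq_length = len, gap_prob = 0.1,
                            seed = seed))
}
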