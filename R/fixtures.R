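## Seeded generators for synthetic test inputs: random sequence sets,
## in-frame CDS sets, allelic samples with known theta, and random
## trees with support labels.  All generators are pure functions of
## their arguments (identical seed => byte-identical output).

#' Generate a random sequence set
#'
#' @param n_seqs Number of records.
#' @param seq_length Residues per record.
#' @param alphabet `"dna"` or `"protein"`.
#' @param gap_prob Per-position probability of a gap character.
#' @param gc_content GC proportion for DNA (ignored for protein).
#' @param seed Integer seed.
#' @param prefix Id prefix (ids are `<prefix>1..n`).
#' @return A `bio_seqs` record set.
#' @export
make_seq_set <- function(n_seqs = 5L, seq_length = 100L, alphabet = "dna",
                         gap_prob = 0, gc_content = 0.5, seed = 1L,
                         prefix = "seq") {
  letters_pool <- if (alphabet == "dna") c("A", "C", "G", "T") else
    chars("ACDEFGHIKLMNPQRSTVWY")
  probs <- if (alphabet == "dna") {
    c((1 - gc_content) / 2, gc_content / 2, gc_content / 2,
      (1 - gc_content) / 2)
  } else rep(1 / 20, 20L)
  with_seed(seed, {
    recs <- lapply(seq_len(n_seqs), function(i) {
      s <- sample(letters_pool, seq_length, replace = TRUE, prob = probs)
      if (gap_prob > 0) {
        s[stats::runif(seq_length) < gap_prob] <- "-"
      }
      seq_record(paste0(prefix, i), paste(s, collapse = ""))
    })
    seq_set(recs)
  })
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Generate an in-frame CDS set
#'
#' Records start with ATG, contain no internal stop codons, and carry
#' their known translations as an attribute.
#'
#' @param n_seqs Number of CDS records.
#' @param seq_length Nucleotides per record (multiple of 3).
#' @param gc_content GC proportion.
#' @param seed Integer seed.
#' @param prefix Id prefix.
#' @return A `bio_seqs` set with attribute `translations` (named
#'   character vector of frame-1 translations).
#' @export
make_cds_set <- function(n_seqs = 5L, seq_length = 30L, gc_content = 0.5,
                         seed = 1L, prefix = "cds") {
  if (seq_length %% 3L != 0L || seq_length < 3L) {
    bf_stop("CDS length must be a positive multiple of 3")
  }
  probs <- c((1 - gc_content) / 2, gc_content / 2, gc_content / 2,
             (1 - gc_content) / 2)
  with_seed(seed, {
    recs <- lapply(seq_len(n_seqs), function(i) {
      codons <- c("ATG", vapply(seq_len(seq_length %/% 3L - 1L),
                                function(k) {
        repeat {
          cd <- paste(sample(c("A", "C", "G", "T"), 3L, replace = TRUE,
                             prob = probs), collapse = "")
          if (!cd %in% STOP_CODONS) return(cd)
        }
      }, character(1L)))
      seq_record(paste0(prefix, i), paste(codons, collapse = ""))
    })
    out <- seq_set(recs)
    attr(out, "translations") <-
      vapply(stats::setNames(out, seq_ids(out)),
             function(r) translate_string(r$seq), character(1L))
    out
  })
}

#' Simulate an allelic sample with known theta
#'
#' A coalescent-free stand-in for a neutral sample: the number of
#' segregating mutations is Poisson with mean `theta * a_n`
#' (`a_n = sum 1/i`), and each mutation's derived-allele count i is
#' drawn from the neutral site-frequency spectrum (P(i) proportional
#' to 1/i), placed at a distinct site of a random ancestral sequence
#' (infinite-sites style).  Under this model both pi and Watterson's
#' theta have expectation `theta` exactly.
#'
#' @param n_seqs Sample size (>= 2).
#' @param seq_length Locus length in bp (must comfortably exceed the
#'   expected mutation count).
#' @param theta Population mutation parameter (> 0) on the raw
#'   (per-locus) scale.
#' @param seed Integer seed.
#' @param prefix Id prefix (ids `<prefix>1..n`).
#' @return A `bio_aln` nucleotide alignment with attributes `true_S`
#'   (number of mutations placed) and `theta` (the simulated value).
#' @export
make_allele_sample <- function(n_seqs = 20L, seq_length = 1000L, theta = 5,
                               seed = 1L, prefix = "allele") {
  if (n_seqs < 2L) bf_stop("need n_seqs >= 2")
  if (theta <= 0) bf_stop("theta must be > 0")
  a_n <- sum(1 / seq_len(n_seqs - 1L))
  with_seed(seed, {
    anc <- sample(c("A", "C", "G", "T"), seq_length, replace = TRUE)
    s <- stats::rpois(1L, theta * a_n)
    s <- min(s, seq_length)          # infinite-sites needs distinct sites
    sites <- sample.int(seq_length, s)
    m <- matrix(rep(anc, each = n_seqs), nrow = n_seqs)
    freq_probs <- (1 / seq_len(n_seqs - 1L)) / a_n
    for (k in seq_len(s)) {
      i <- sample.int(n_seqs - 1L, 1L, prob = freq_probs)
      carriers <- sample.int(n_seqs, i)
      derived <- sample(setdiff(c("A", "C", "G", "T"),
                                anc[[sites[[k]]]]), 1L)
      m[carriers, sites[[k]]] <- derived
    }
    rownames(m) <- paste0(prefix, seq_len(n_seqs))
    out <- aln_from_matrix(m)
    attr(out, "true_S") <- s
    attr(out, "theta") <- theta
    out
  })
}

#' Generate a random tree with support labels
#'
#' Pure-birth (Yule) topology: starting from two leaves, a uniformly
#' chosen leaf is split until `n_leaves` is reached.  Branch lengths
#' are exponential with rate `birth_rate`; internal nodes get uniform
#' support labels in `support_range` (rounded to integers).
#'
#' @param n_leaves Number of leaves (>= 2).
#' @param birth_rate Rate of the exponential branch-length law.
#' @param support_range Two-element numeric range for support labels.
#' @param seed Integer seed.
#' @param prefix Leaf-name prefix (leaves `<prefix>1..n`).
#' @return A `phylo` tree with attribute `gen_total_length` (sum of the
#'   generated branch lengths).
#' @export
make_tree <- function(n_leaves = 10L, birth_rate = 1, support_range = c(50, 100),
                      seed = 1L, prefix = "L") {
  if (n_leaves < 2L) bf_stop("need n_leaves >= 2")
  with_seed(seed, {
    new_leaf <- function(id) {
      list(label = paste0(prefix, id), len = stats::rexp(1L, birth_rate),
           children = NULL)
    }
    root <- list(label = "", len = NA_real_,
                 children = list(new_leaf(1L), new_leaf(2L)))
    next_id <- 3L
    ## split the `target`-th leaf (left-to-right order) into a cherry
    split_random_leaf <- function(nd, target) {
      ## returns list(node, done)
      if (is.null(nd$children)) {
        if (target == 1L) {
          nd <- list(label = "", len = nd$len,
                     children = list(
                       list(label = nd$label,
                            len = stats::rexp(1L, birth_rate),
                            children = NULL),
                       new_leaf(next_id)))
          next_id <<- next_id + 1L
          return(list(node = nd, used = 1L, done = TRUE))
        }
        return(list(node = nd, used = 1L, done = FALSE))
      }
      used <- 0L
      for (i in seq_along(nd$children)) {
        res <- split_random_leaf(nd$children[[i]], target - used)
        nd$children[[i]] <- res$node
        used <- used + res$used
        if (res$done) return(list(node = nd, used = used, done = TRUE))
      }
      list(node = nd, used = used, done = FALSE)
    }
    n_now <- 2L
    while (n_now < n_leaves) {
      target <- sample.int(n_now, 1L)
      root <- split_random_leaf(root, target)$node
      n_now <- n_now + 1L
    }
    ## support labels on internal non-root nodes
    label_internals <- function(nd, is_root = FALSE) {
      if (is.null(nd$children)) return(nd)
      if (!is_root) {
        nd$label <- as.character(round(stats::runif(1L, support_range[[1L]],
                                                    support_range[[2L]])))
      }
      nd$children <- lapply(nd$children, label_internals)
      nd
    }
    root <- label_internals(root, is_root = TRUE)
    phy <- ape::read.tree(text = list_to_newick(root))
    attr(phy, "gen_total_length") <- sum(phy$edge.length)
    phy
  })
}
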