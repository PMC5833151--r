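## bioaln operations: summaries, slicing, member pick/delete,
## concatenation, codon-aware back-translation, bootstrap and site
## permutations.

#' Alignment summary statistics
#'
#' `avg_pid` is the mean over all unordered member pairs of
#' `identical columns / compared columns * 100`, where columns with a
#' gap in either member are excluded from both numerator and
#' denominator (pairwise deletion).
#'
#' @param aln A `bio_aln` alignment.
#' @param metric `"length"`, `"nseq"` or `"avg_pid"`.
#' @return A single number.
#' @export
aln_summary <- function(aln, metric = c("length", "nseq", "avg_pid")) {
  metric <- match.arg(metric)
  stopifnot(inherits(aln, "bio_aln"))
  if (metric == "length") return(aln_width(aln))
  if (metric == "nseq") return(length(aln))
  if (length(aln) < 2L) {
    bf_stop("avg_pid needs at least 2 members")
  }
  m <- aln_matrix(aln)
  n <- nrow(m)
  pids <- c()
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      pids <- c(pids, if (any(ok)) {
        100 * sum(m[i, ok] == m[j, ok]) / sum(ok)
      } else NA_real_)
    }
  }
  mean(pids, na.rm = TRUE)
}

#' Parse a slice range
#'
#' `"10,20"` selects columns 10..20 inclusive; an open marker `-` means
#' column 1 (`"-,20"`) or the last column (`"20,-"`).
#'
#' @param spec Range string.
#' @param len Alignment length used to resolve open markers.
#' @return Integer vector `c(start, end)`.
#' @export
parse_slice <- function(spec, len) {
  parts <- trimws(strsplit(spec, ",", fixed = TRUE)[[1L]])
  if (length(parts) != 2L) bf_stop("bad slice range '", spec, "'")
  resolve <- function(p, open) {
    if (p == "-") return(open)
    if (!grepl("^[0-9]+$", p)) bf_stop("bad slice bound '", p, "'")
    as.integer(p)
  }
  c(resolve(parts[[1L]], 1L), resolve(parts[[2L]], len))
}

#' Slice an alignment by columns
#'
#' @param aln A `bio_aln` alignment.
#' @param start,end 1-based inclusive column bounds.
#' @return Alignment of columns `start..end`, member order preserved.
#' @export
slice_alignment <- function(aln, start, end) {
  len <- aln_width(aln)
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end < start || end > len) {
    bf_stop("slice out of range for alignment of length ", len)
  }
  as_alignment(seq_set(lapply(aln, function(r) {
    seq_record(r$id, substr(r$seq, start, end), r$desc)
  })))
}

#' Pick or delete alignment members by id
#'
#' Alignment length is unchanged (no automatic gap-column removal).
#'
#' @param aln A `bio_aln` alignment.
#' @param ids Character vector of member ids (all must exist).
#' @param mode `"pick"` or `"delete"`.
#' @return Filtered alignment.
#' @export
filter_members <- function(aln, ids, mode = c("pick", "delete")) {
  mode <- match.arg(mode)
  missing <- setdiff(ids, seq_ids(aln))
  if (length(missing) > 0L) {
    bf_stop("id(s) not found in alignment: ", paste(missing, collapse = ", "))
  }
  keep <- if (mode == "pick") seq_ids(aln) %in% ids else !(seq_ids(aln) %in% ids)
  as_alignment(seq_set(unclass(aln)[keep]))
}

#' Concatenate alignments sharing an id set
#'
#' Residues are concatenated per id, in input order; member order
#' follows the first alignment.
#'
#' @param alignments List of `bio_aln` alignments over identical id sets.
#' @return Alignment of length equal to the sum of input lengths.
#' @export
concat_alignments <- function(alignments) {
  stopifnot(length(alignments) >= 1L)
  ref_ids <- seq_ids(alignments[[1L]])
  for (a in alignments[-1L]) {
    diff <- c(setdiff(ref_ids, seq_ids(a)), setdiff(seq_ids(a), ref_ids))
    if (length(diff) > 0L) {
      bf_stop("alignments have different id sets; differing ids: ",
              paste(unique(diff), collapse = ", "))
    }
  }
  recs <- lapply(ref_ids, function(id) {
    pieces <- vapply(alignments,
                     function(a) seq_strings(a)[[id]], character(1L))
    seq_record(id, paste(pieces, collapse = ""))
  })
  as_alignment(seq_set(recs))
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Each amino-acid column expands to its source codon and each gap to
#' `---`, so the output has 3x the protein alignment length and its
#' frame-1 translation (after degapping) reproduces the degapped
#' protein rows.  For every aligned protein a same-id CDS must exist
#' whose frame-1 translation (ignoring a terminal stop) equals the
#' degapped protein.
#'
#' @param protein_aln A `bio_aln` protein alignment.
#' @param cds_records A `bio_seqs` set of in-frame CDS nucleotide
#'   sequences with matching ids.
#' @return Nucleotide codon alignment.
#' @export
pep2dna <- function(protein_aln, cds_records) {
  stopifnot(inherits(protein_aln, "bio_aln"))
  cds_map <- seq_strings(cds_records)
  recs <- lapply(protein_aln, function(r) {
    if (!r$id %in% names(cds_map)) {
      bf_stop("no CDS found for aligned protein '", r$id, "'")
    }
    cds <- gsub("-", "", cds_map[[r$id]], fixed = TRUE)
    pep <- gsub("-", "", r$seq, fixed = TRUE)
    tr <- translate_string(cds)
    if (nchar(tr) == nchar(pep) + 1L && endsWith(tr, "*")) {
      tr <- substr(tr, 1L, nchar(tr) - 1L)   # tolerate terminal stop
      cds <- substr(cds, 1L, 3L * nchar(tr))
    }
    if (tr != pep) {
      mism <- which(chars(tr)[seq_len(min(nchar(tr), nchar(pep)))] !=
                    chars(pep)[seq_len(min(nchar(tr), nchar(pep)))])
      pos <- if (length(mism)) mism[[1L]] else min(nchar(tr), nchar(pep)) + 1L
      bf_stop("CDS of '", r$id, "' does not translate to the aligned ",
              "protein (first mismatch at residue ", pos, ")")
    }
    out <- character(nchar(r$seq))
    k <- 0L
    for (i in seq_len(nchar(r$seq))) {
      aa <- substr(r$seq, i, i)
      if (aa == "-") {
        out[[i]] <- "---"
      } else {
        out[[i]] <- substr(cds, 3L * k + 1L, 3L * k + 3L)
        k <- k + 1L
      }
    }
    seq_record(r$id, paste(out, collapse = ""), r$desc)
  })
  as_alignment(seq_set(recs))
}

#' Bootstrap alignment columns
#'
#' Samples `length` columns uniformly with replacement; member ids and
#' count are unchanged.  Deterministic for a fixed seed.
#'
#' @param aln A `bio_aln` alignment with at least 1 column.
#' @param seed Integer seed (NULL leaves the global RNG in charge).
#' @return Resampled alignment of identical dimensions.
#' @export
aln_bootstrap <- function(aln, seed = NULL) {
  len <- aln_width(aln)
  if (len < 1L) bf_stop("cannot bootstrap an empty alignment")
  idx <- with_seed(seed, sample.int(len, len, replace = TRUE))
  m <- aln_matrix(aln)[, idx, drop = FALSE]
  aln_from_matrix(m, vapply(aln, `[[`, character(1L), "desc"))
}

#' Permute alignment columns
#'
#' Columns are kept intact and reordered uniformly at random, so
#' per-site patterns are preserved.
#'
#' @inheritParams aln_bootstrap
#' @return Column-permuted alignment.
#' @export
shuffle_sites <- function(aln, seed = NULL) {
  len <- aln_width(aln)
  idx <- with_seed(seed, sample.int(len, len, replace = FALSE))
  m <- aln_matrix(aln)[, idx, drop = FALSE]
  aln_from_matrix(m, vapply(aln, `[[`, character(1L), "desc"))
}

#' Randomly mutate alignment residues
#'
#' Each non-gap residue is independently replaced, with probability
#' `rate`, by a uniformly chosen different nucleotide.
#'
#' @param aln A nucleotide `bio_aln` alignment.
#' @param rate Per-residue mutation probability in [0, 1].
#' @param seed Integer seed.
#' @return Mutated alignment.
#' @export
mutate_sites <- function(aln, rate, seed = NULL) {
  rate <- as.numeric(rate)
  if (is.na(rate) || rate < 0 || rate > 1) {
    bf_stop("mutation rate must be in [0, 1]")
  }
  if (!is_nucleotide_set(aln)) {
    bf_stop("mutate_sites requires a nucleotide alignment")
  }
  m <- aln_matrix(aln)
  with_seed(seed, {
    targets <- which(m != "-" & matrix(stats::runif(length(m)) < rate,
                                       nrow = nrow(m)))
    for (t in targets) {
      pool <- setdiff(c("A", "C", "G", "T"), m[[t]])
      m[[t]] <- pool[[sample.int(length(pool), 1L)]]
    }
  })
  aln_from_matrix(m, vapply(aln, `[[`, character(1L), "desc"))
}
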