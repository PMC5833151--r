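## Containers: sequence records, record sets, alignments.
##
## A record set (`bio_seqs`) is an ordered list of records; an alignment
## (`bio_aln`) is a record set whose members all have the same gapped
## length.  `bio_aln` inherits from `bio_seqs`, mirroring the
## alignment-is-a-set-of-sequences inheritance the command suite relies
## on (sequence operations remain applicable to alignments).

VALID_RESIDUE_RE <- "^[A-Za-z*.-]*$"

#' Create a single sequence record
#'
#' @param id Record identifier; non-empty, no whitespace.
#' @param seq Residues (nucleotide or protein, IUPAC codes, `-` gaps).
#'   Normalized to upper case.
#' @param desc Free-text description (may be empty).
#' @return An object of class `seq_record` with fields `id`, `desc`, `seq`.
#' @export
seq_record <- function(id, seq, desc = "") {
  if (!is.character(id) || length(id) != 1L || !nzchar(id) ||
      grepl("[[:space:]]", id)) {
    bf_stop("record id must be a non-empty token without whitespace")
  }
  if (!grepl(VALID_RESIDUE_RE, seq)) {
    bad <- regmatches(seq, regexpr("[^A-Za-z*.-]", seq))
    bf_stop("record '", id, "' contains invalid residue character '", bad, "'")
  }
  structure(list(id = id, desc = as.character(desc), seq = toupper(seq)),
            class = "seq_record")
}

#' Build a set of sequence records
#'
#' @param records List of `seq_record` objects (or a single record).
#' @return An ordered record set of class `bio_seqs`.
#' @export
seq_set <- function(records = list()) {
  if (inherits(records, "seq_record")) records <- list(records)
  stopifnot(all(vapply(records, inherits, logical(1L), "seq_record")))
  structure(records, class = "bio_seqs")
}

#' @export
print.bio_seqs <- function(x, ...) {
  cat(sprintf("<%s> %d record(s)\n",
              if (inherits(x, "bio_aln")) "alignment" else "sequence set",
              length(x)))
  for (r in utils::head(x, 6L)) {
    cat(sprintf("  %s [%d] %s\n", r$id, nchar(r$seq),
                substr(r$seq, 1L, 40L)))
  }
  if (length(x) > 6L) cat("  ...\n")
  invisible(x)
}

seq_ids <- function(x) vapply(x, `[[`, character(1L), "id")
seq_strings <- function(x) {
  stats::setNames(vapply(x, `[[`, character(1L), "seq"), seq_ids(x))
}

#' Interpret a record set as an alignment
#'
#' All members must share the same (gapped) length and carry unique ids.
#'
#' @param x A `bio_seqs` record set or list of `seq_record`s.
#' @return An object of class `bio_aln` (which also inherits `bio_seqs`).
#' @export
as_alignment <- function(x) {
  if (!inherits(x, "bio_seqs")) x <- seq_set(x)
  ids <- seq_ids(x)
  if (anyDuplicated(ids)) {
    bf_stop("duplicate ids in alignment: ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  lens <- vapply(x, function(r) nchar(r$seq), integer(1L))
  if (length(lens) > 0L && length(unique(lens)) != 1L) {
    off <- ids[lens != lens[[1L]]][[1L]]
    bf_stop("ragged alignment: record '", off, "' has length ",
            lens[ids == off][[1L]], ", expected ", lens[[1L]])
  }
  structure(unclass(x), class = c("bio_aln", "bio_seqs"),
            width = if (length(lens)) lens[[1L]] else 0L)
}

#' Number of columns of an alignment
#' @param aln A `bio_aln` alignment.
#' @return Integer column count.
#' @export
aln_width <- function(aln) {
  stopifnot(inherits(aln, "bio_aln"))
  attr(aln, "width")
}

## character matrix view (rows = members, columns = sites)
aln_matrix <- function(aln) {
  stopifnot(inherits(aln, "bio_aln"))
  if (length(aln) == 0L) {
    return(matrix(character(0L), nrow = 0L, ncol = 0L))
  }
  m <- do.call(rbind, strsplit(seq_strings(aln), "", fixed = TRUE))
  rownames(m) <- seq_ids(aln)
  m
}

aln_from_matrix <- function(m, descs = NULL) {
  recs <- lapply(seq_len(nrow(m)), function(i) {
    seq_record(rownames(m)[i], paste(m[i, ], collapse = ""),
               desc = if (is.null(descs)) "" else descs[[i]])
  })
  as_alignment(seq_set(recs))
}

## heuristic alphabet guess; protein-only letters force "protein"
guess_alphabet <- function(seq) {
  s <- gsub("[-.*]", "", toupper(seq))
  if (!nzchar(s)) return("auto")
  if (grepl("[EFILPQJZXO]", s)) return("protein")
  if (grepl("^[ACGTUNRYSWKMBDHV]*$", s)) {
    return(if (grepl("U", s)) "rna" else "dna")
  }
  "protein"
}

is_nucleotide_set <- function(records) {
  all(vapply(records, function(r) guess_alphabet(r$seq) %in%
               c("dna", "rna", "auto"), logical(1L)))
}
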