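## Alignment I/O: CLUSTAL (default), gapped FASTA, relaxed interleaved
## PHYLIP.  The PHYLIP dialect keeps full-length names (no 10-character
## truncation) so ids survive a round trip.

#' Read a multiple alignment
#'
#' @param source File path or `"-"` for standard input.
#' @param format `"clustalw"` (default), `"fasta"` or `"phylip"`.
#' @param text Optional character vector of raw lines.
#' @return A `bio_aln` alignment, members in file order.
#' @export
read_alignment <- function(source = "-",
                           format = c("clustalw", "fasta", "phylip"),
                           text = NULL) {
  format <- match_format(format, c("clustalw", "fasta", "phylip"))
  lines <- stream_lines(source, text)
  switch(format,
         clustalw = parse_clustal(lines),
         fasta = as_alignment(parse_fasta(lines)),
         phylip = parse_phylip(lines))
}

parse_clustal <- function(lines) {
  if (length(lines) == 0L || all(!nzchar(trimws(lines)))) {
    bf_stop("malformed CLUSTAL: empty input")
  }
  if (!grepl("^CLUSTAL", lines[[1L]])) {
    bf_stop("malformed CLUSTAL: missing CLUSTAL header at line 1")
  }
  pieces <- list()
  order <- character(0L)
  for (i in seq_along(lines)[-1L]) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln))) next
    if (grepl("^[[:space:]]", ln)) next   # conservation line
    m <- regmatches(ln, regexec("^(\\S+)\\s+([A-Za-z*.-]+)\\s*[0-9]*\\s*$", ln))[[1L]]
    if (length(m) == 0L) {
      bf_stop("malformed CLUSTAL: unparseable line ", i)
    }
    id <- m[[2L]]; chunk <- m[[3L]]
    if (!id %in% order) order <- c(order, id)
    pieces[[id]] <- c(pieces[[id]], chunk)
  }
  recs <- lapply(order, function(id) {
    seq_record(id, paste(pieces[[id]], collapse = ""))
  })
  as_alignment(seq_set(recs))
}

parse_phylip <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) bf_stop("malformed PHYLIP: empty input")
  hdr <- regmatches(lines[[1L]],
                    regexec("^\\s*([0-9]+)\\s+([0-9]+)\\s*$", lines[[1L]]))[[1L]]
  if (length(hdr) == 0L) {
    bf_stop("malformed PHYLIP: bad 'ntax nchar' header at line 1")
  }
  ntax <- as.integer(hdr[[2L]]); nchar_exp <- as.integer(hdr[[3L]])
  body <- lines[-1L]
  if (length(body) %% ntax != 0L) {
    bf_stop("malformed PHYLIP: expected blocks of ", ntax, " lines")
  }
  nblock <- length(body) %/% ntax
  ids <- character(ntax)
  seqs <- rep("", ntax)
  for (b in seq_len(nblock)) {
    for (t in seq_len(ntax)) {
      ln <- body[[(b - 1L) * ntax + t]]
      if (b == 1L) {
        m <- regmatches(ln, regexec("^(\\S+)\\s+(.*)$", ln))[[1L]]
        if (length(m) == 0L) {
          bf_stop("malformed PHYLIP: unparseable name line for taxon ", t)
        }
        ids[[t]] <- m[[2L]]
        seqs[[t]] <- paste0(seqs[[t]], gsub("[[:space:]]", "", m[[3L]]))
      } else {
        seqs[[t]] <- paste0(seqs[[t]], gsub("[[:space:]]", "", ln))
      }
    }
  }
  lens <- nchar(seqs)
  if (any(lens != nchar_exp)) {
    off <- which(lens != nchar_exp)[[1L]]
    bf_stop("malformed PHYLIP: record '", ids[[off]], "' has length ",
            lens[[off]], ", header says ", nchar_exp)
  }
  as_alignment(seq_set(mapply(seq_record, ids, seqs, SIMPLIFY = FALSE)))
}

#' Serialize an alignment
#'
#' @param aln A `bio_aln` alignment.
#' @param format `"clustalw"`, `"fasta"` or `"phylip"`.
#' @param width Residues per block line (default 60).
#' @return Character vector of output lines.
#' @export
write_alignment <- function(aln, format = c("clustalw", "fasta", "phylip"),
                            width = 60L) {
  format <- match_format(format, c("clustalw", "fasta", "phylip"))
  stopifnot(inherits(aln, "bio_aln"))
  switch(format,
         fasta = write_seqs(aln, width = width),
         clustalw = write_clustal(aln, width),
         phylip = write_phylip(aln, width))
}

aln_blocks <- function(aln, width) {
  len <- aln_width(aln)
  starts <- if (len > 0L) seq.int(1L, len, by = width) else integer(0L)
  list(starts = starts, ends = pmin(starts + width - 1L, len))
}

write_clustal <- function(aln, width) {
  out <- c("CLUSTAL W multiple sequence alignment", "")
  ids <- seq_ids(aln)
  pad <- if (length(ids)) max(nchar(ids)) + 4L else 0L
  b <- aln_blocks(aln, width)
  for (k in seq_along(b$starts)) {
    for (r in aln) {
      out <- c(out, sprintf("%-*s%s", pad, r$id,
                            substr(r$seq, b$starts[[k]], b$ends[[k]])))
    }
    out <- c(out, "")
  }
  out
}

write_phylip <- function(aln, width) {
  ids <- seq_ids(aln)
  out <- sprintf("%d %d", length(aln), aln_width(aln))
  pad <- if (length(ids)) max(nchar(ids)) + 2L else 0L
  b <- aln_blocks(aln, width)
  for (k in seq_along(b$starts)) {
    for (r in aln) {
      chunk <- substr(r$seq, b$starts[[k]], b$ends[[k]])
      out <- c(out, if (k == 1L) sprintf("%-*s%s", pad, r$id, chunk)
                    else sprintf("%-*s%s", pad, "", chunk))
    }
    if (k < length(b$starts)) out <- c(out, "")
  }
  out
}
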