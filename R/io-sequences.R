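## Sequence I/O: FASTA and GenBank readers, FASTA writer.
##
## Readers accept a file path, "-" (standard input) or a `text`
## argument; records come back in input order, FASTA headers split at
## the first whitespace into id/description, GenBank LOCUS names become
## ids.  Empty input is an empty set, not an error, so downstream
## counts report 0.

#' Read sequences from FASTA or GenBank
#'
#' @param source File path or `"-"` for standard input.
#' @param format `"fasta"` (default) or `"genbank"`.
#' @param text Optional character vector of raw lines (overrides `source`).
#' @return A `bio_seqs` record set in input order.
#' @export
read_seqs <- function(source = "-", format = c("fasta", "genbank"),
                      text = NULL) {
  format <- match_format(format, c("fasta", "genbank"))
  lines <- stream_lines(source, text)
  switch(format,
         fasta = parse_fasta(lines),
         genbank = parse_genbank(lines))
}

parse_fasta <- function(lines) {
  keep <- nzchar(trimws(lines))
  if (!any(keep)) return(seq_set())
  recs <- list()
  cur_id <- NULL; cur_desc <- ""; cur_seq <- character(0L)
  flush <- function() {
    if (!is.null(cur_id)) {
      recs[[length(recs) + 1L]] <<-
        seq_record(cur_id, paste(cur_seq, collapse = ""), cur_desc)
    }
  }
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln))) next
    if (startsWith(ln, ">")) {
      flush()
      header <- trimws(substring(ln, 2L))
      if (!nzchar(header)) {
        bf_stop("malformed FASTA: empty header at line ", i)
      }
      cur_id <- sub("\\s.*$", "", header)
      cur_desc <- if (grepl("\\s", header)) {
        trimws(sub("^\\S+\\s+", "", header))
      } else ""
      cur_seq <- character(0L)
    } else {
      if (is.null(cur_id)) {
        bf_stop("malformed FASTA: sequence data before any header at line ", i)
      }
      piece <- gsub("[[:space:]]", "", ln)
      if (!grepl(VALID_RESIDUE_RE, piece)) {
        bf_stop("malformed FASTA: invalid residue characters at line ", i)
      }
      cur_seq <- c(cur_seq, piece)
    }
  }
  flush()
  seq_set(recs)
}

parse_genbank <- function(lines) {
  keep <- nzchar(trimws(lines))
  if (!any(keep)) return(seq_set())
  recs <- list()
  i <- 1L; n <- length(lines)
  while (i <= n) {
    while (i <= n && !grepl("^LOCUS", lines[[i]])) {
      if (nzchar(trimws(lines[[i]]))) {
        bf_stop("malformed GenBank: expected LOCUS at line ", i)
      }
      i <- i + 1L
    }
    if (i > n) break
    toks <- strsplit(trimws(lines[[i]]), "[[:space:]]+")[[1L]]
    if (length(toks) < 2L) {
      bf_stop("malformed GenBank: LOCUS without a name at line ", i)
    }
    id <- toks[[2L]]
    desc <- ""
    seq_parts <- character(0L)
    in_origin <- FALSE
    i <- i + 1L
    while (i <= n && !grepl("^//", lines[[i]])) {
      ln <- lines[[i]]
      if (grepl("^DEFINITION", ln)) {
        desc <- trimws(sub("^DEFINITION\\s*", "", ln))
        desc <- sub("\\.$", "", desc)
      } else if (grepl("^ORIGIN", ln)) {
        in_origin <- TRUE
      } else if (in_origin) {
        seq_parts <- c(seq_parts, gsub("[^A-Za-z]", "", ln))
      }
      i <- i + 1L
    }
    if (i > n) bf_stop("malformed GenBank: record '", id,
                       "' not terminated by //")
    if (!in_origin) bf_stop("malformed GenBank: record '", id,
                            "' has no ORIGIN section")
    recs[[length(recs) + 1L]] <-
      seq_record(id, paste(seq_parts, collapse = ""), desc)
    i <- i + 1L
  }
  seq_set(recs)
}

#' Serialize records as FASTA
#'
#' Headers are `>id description` (description omitted when empty);
#' residues are wrapped at `width` columns.  Output is deterministic.
#'
#' @param records A `bio_seqs` record set.
#' @param width Wrap width in columns (default 60).
#' @return Character vector of output lines.
#' @export
write_seqs <- function(records, width = 60L) {
  out <- character(0L)
  for (r in records) {
    header <- if (nzchar(r$desc)) paste0(">", r$id, " ", r$desc)
              else paste0(">", r$id)
    out <- c(out, header, wrap_seq(r$seq, width))
  }
  out
}

wrap_seq <- function(s, width) {
  n <- nchar(s)
  if (n == 0L) return("")
  starts <- seq.int(1L, n, by = width)
  substring(s, starts, pmin(starts + width - 1L, n))
}

match_format <- function(format, supported) {
  format <- format[[1L]]
  if (!format %in% supported) {
    bf_stop("unknown format '", format, "'; supported: ",
            paste(supported, collapse = ", "))
  }
  format
}
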