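## bioseq operations: summaries, reverse-complement, pick/delete,
## sub-sequence, translation, degapping, restriction digestion.

## IUPAC nucleotide ambiguity sets
IUPAC_NUC <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"))

## complement map over the full IUPAC alphabet (U -> A); gaps unchanged
COMPLEMENT_FROM <- "ACGTURYSWKMBDHVN"
COMPLEMENT_TO   <- "TGCAAYRSWMKVHDBN"

## standard genetic code (translation table 1)
GENETIC_CODE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

## built-in restriction enzymes: recognition site + cut offset
## (cut falls after `offset` bases of the site, e.g. EcoRI G^AATTC)
RESTRICTION_ENZYMES <- list(
  EcoRI   = list(site = "GAATTC",   offset = 1L),
  BamHI   = list(site = "GGATCC",   offset = 1L),
  HindIII = list(site = "AAGCTT",   offset = 1L),
  NotI    = list(site = "GCGGCCGC", offset = 2L),
  TaqI    = list(site = "TCGA",     offset = 1L))

#' Summarize a record set
#'
#' @param records A `bio_seqs` record set.
#' @param metric `"length"` (per-record lengths), `"count"` (number of
#'   records) or `"composition"` (per-record and pooled residue
#'   percentages over non-gap characters).
#' @return Named integer vector, integer, or a data frame with columns
#'   `id`, `residue`, `percent` (pooled rows have id `"all"`).
#' @export
summarize_seqs <- function(records, metric = c("length", "count",
                                               "composition")) {
  metric <- match.arg(metric)
  if (metric == "count") return(length(records))
  if (metric == "length") {
    return(stats::setNames(vapply(records, function(r) nchar(r$seq),
                                  integer(1L)), seq_ids(records)))
  }
  comp_one <- function(id, seq) {
    res <- chars(seq)
    res <- res[res != "-"]
    if (length(res) == 0L) return(NULL)
    tab <- table(res)
    data.frame(id = id, residue = names(tab),
               percent = 100 * as.numeric(tab) / length(res),
               stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, lapply(records, function(r) comp_one(r$id, r$seq)))
  pooled <- comp_one("all", paste(vapply(records, `[[`, character(1L), "seq"),
                                  collapse = ""))
  out <- rbind(per, pooled)
  if (is.null(out)) {
    out <- data.frame(id = character(0L), residue = character(0L),
                      percent = numeric(0L), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Reverse-complement nucleotide records
#'
#' Uses the full IUPAC complement map (R<->Y, S<->S, W<->W, K<->M,
#' B<->V, D<->H, N<->N); gaps stay in place after reversal.
#'
#' @param records A `bio_seqs` record set (nucleotide).
#' @return Record set of the same length.
#' @export
revcom <- function(records) {
  if (!is_nucleotide_set(records)) {
    bf_stop("reverse-complement undefined for protein")
  }
  out <- lapply(records, function(r) {
    comp <- chartr(COMPLEMENT_FROM, COMPLEMENT_TO, r$seq)
    rev_seq <- paste(rev(chars(comp)), collapse = "")
    seq_record(r$id, rev_seq, r$desc)
  })
  seq_set(out)
}

#' Parse a pick/delete selector
#'
#' Syntax: `"id:B31,N40"`, `"order:1-3,5"` (1-based inclusive ranges) or
#' `"re:B31"` (regular expression, searched within the id).  A bare
#' comma-separated list without a prefix is treated as an id list.
#'
#' @param spec Selector string.
#' @return A list with fields `mode` and `payload`.
#' @export
parse_selector <- function(spec) {
  if (grepl("^(id|order|re):", spec)) {
    mode <- sub(":.*$", "", spec)
    payload <- sub("^[a-z]+:", "", spec)
  } else {
    mode <- "id"
    payload <- spec
  }
  if (mode == "id") {
    ids <- trimws(strsplit(payload, ",", fixed = TRUE)[[1L]])
    ids <- ids[nzchar(ids)]
    if (length(ids) == 0L) bf_stop("empty id selector")
    list(mode = "id", payload = ids)
  } else if (mode == "order") {
    parts <- trimws(strsplit(payload, ",", fixed = TRUE)[[1L]])
    idx <- integer(0L)
    for (p in parts) {
      if (grepl("^[0-9]+$", p)) {
        idx <- c(idx, as.integer(p))
      } else if (grepl("^[0-9]+-[0-9]+$", p)) {
        ab <- as.integer(strsplit(p, "-", fixed = TRUE)[[1L]])
        if (ab[[1L]] > ab[[2L]]) bf_stop("descending order range '", p, "'")
        idx <- c(idx, seq.int(ab[[1L]], ab[[2L]]))
      } else {
        bf_stop("bad order selector element '", p, "'")
      }
    }
    list(mode = "order", payload = idx)
  } else {
    ok <- tryCatch({grepl(payload, "x"); TRUE},
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) bf_stop("invalid regular expression '", payload, "'")
    list(mode = "re", payload = payload)
  }
}

selector_matches <- function(records, selector) {
  ids <- seq_ids(records)
  if (selector$mode == "id") {
    missing <- setdiff(selector$payload, ids)
    if (length(missing) > 0L) {
      bf_stop("id(s) not found: ", paste(missing, collapse = ", "))
    }
    ids %in% selector$payload
  } else if (selector$mode == "order") {
    if (length(selector$payload) && max(selector$payload) > length(records)) {
      bf_stop("order selector exceeds record count (", length(records), ")")
    }
    seq_along(records) %in% selector$payload
  } else {
    grepl(selector$payload, ids)
  }
}

#' Pick or delete records by selector
#'
#' @param records A `bio_seqs` record set.
#' @param selector A selector string or the result of [parse_selector()].
#' @param mode `"pick"` keeps matches, `"delete"` removes them.
#' @return Filtered record set, original order preserved.
#' @export
filter_records <- function(records, selector, mode = c("pick", "delete")) {
  mode <- match.arg(mode)
  if (is.character(selector)) selector <- parse_selector(selector)
  hit <- selector_matches(records, selector)
  keep <- if (mode == "pick") hit else !hit
  if (mode == "pick" && !any(hit)) {
    warning("pick selector matched no records", call. = FALSE)
  }
  seq_set(unclass(records)[keep])
}

#' Extract a sub-sequence from every record
#'
#' Coordinates are 1-based and inclusive; descriptions are annotated
#' with the extracted range.
#'
#' @param records A `bio_seqs` record set.
#' @param start,end 1-based inclusive positions, `start <= end`.
#' @return Record set of sub-sequences of length `end - start + 1`.
#' @export
subseq <- function(records, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end < start) {
    bf_stop("bad sub-sequence range: need 1 <= start <= end")
  }
  out <- lapply(records, function(r) {
    if (end > nchar(r$seq)) {
      bf_stop("range end ", end, " beyond length ", nchar(r$seq),
              " of record '", r$id, "'")
    }
    note <- sprintf("subseq(%d,%d)", start, end)
    seq_record(r$id, substr(r$seq, start, end),
               if (nzchar(r$desc)) paste(r$desc, note) else note)
  })
  seq_set(out)
}

## one codon -> one amino acid; ambiguity codes resolve to a single
## residue only when every resolution agrees, otherwise 'X'
translate_codon <- function(codon) {
  aa <- unname(GENETIC_CODE[codon])
  if (!is.na(aa)) return(aa)
  sets <- IUPAC_NUC[chars(codon)]
  if (any(vapply(sets, is.null, logical(1L)))) {
    bf_stop("cannot translate codon '", codon, "'")
  }
  combos <- expand.grid(sets, stringsAsFactors = FALSE)
  aas <- unique(unname(GENETIC_CODE[apply(combos, 1L,
                                          paste, collapse = "")]))
  if (length(aas) == 1L) aas else "X"
}

translate_string <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return("")
  codons <- substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- unname(GENETIC_CODE[codons])
  amb <- which(is.na(aa))
  for (i in amb) aa[[i]] <- translate_codon(codons[[i]])
  paste(aa, collapse = "")
}

#' Translate nucleotide records
#'
#' Frame 1 keeps the input id; frames 3 and 6 emit one record per frame
#' with ids suffixed `_f+1` ... `_f-3` (negative frames translate the
#' reverse complement).  The standard genetic code is used, trailing
#' partial codons are dropped, stops are `*`, and ambiguous codons give
#' `X` unless every resolution agrees.  Input must be gap-free
#' (degap first).
#'
#' @param records A `bio_seqs` record set (nucleotide, ungapped).
#' @param frames 1, 3 or 6.
#' @return Protein record set (1, 3 or 6 records per input record).
#' @export
translate <- function(records, frames = 1L) {
  frames <- as.integer(frames)
  if (!frames %in% c(1L, 3L, 6L)) {
    bf_stop("frames must be 1, 3 or 6")
  }
  if (!is_nucleotide_set(records)) {
    bf_stop("translation undefined for protein input")
  }
  if (any(grepl("-", seq_strings(records), fixed = TRUE))) {
    bf_stop("translation requires gap-free input; degap first")
  }
  out <- list()
  for (r in records) {
    fwd <- r$seq
    if (frames == 1L) {
      out[[length(out) + 1L]] <-
        seq_record(r$id, translate_string(fwd), r$desc)
      next
    }
    revc <- revcom(seq_set(seq_record(r$id, fwd)))[[1L]]$seq
    frame_set <- if (frames == 3L) 1:3 else c(1:3, -(1:3))
    for (f in frame_set) {
      s <- if (f > 0L) substring(fwd, f) else substring(revc, -f)
      tag <- sprintf("_f%+d", f)
      out[[length(out) + 1L]] <-
        seq_record(paste0(r$id, tag), translate_string(s), r$desc)
    }
  }
  seq_set(out)
}

#' Remove gap characters
#'
#' @param records A `bio_seqs` record set.
#' @return Record set with all `-` removed; empty sequences are kept.
#' @export
degap <- function(records) {
  seq_set(lapply(records, function(r) {
    seq_record(r$id, gsub("-", "", r$seq, fixed = TRUE), r$desc)
  }))
}

#' Digest records with a restriction enzyme
#'
#' The sequence is cut at every occurrence of the recognition site at
#' the enzyme's cut offset (EcoRI: `G^AATTC`).  Fragments are emitted
#' 5'->3' with ids suffixed `_frag<i>`; a site-free sequence yields one
#' fragment equal to the input.
#'
#' @param records A `bio_seqs` record set (nucleotide).
#' @param enzyme Enzyme name from the built-in table (EcoRI, BamHI,
#'   HindIII, NotI, TaqI).
#' @return A list with one element per record: `list(id, enzyme, site,
#'   offset, fragments)` where `fragments` is a `bio_seqs` set.
#' @export
restrict_digest <- function(records, enzyme) {
  if (!enzyme %in% names(RESTRICTION_ENZYMES)) {
    bf_stop("unknown enzyme '", enzyme, "'; available: ",
            paste(names(RESTRICTION_ENZYMES), collapse = ", "))
  }
  if (!is_nucleotide_set(records)) {
    bf_stop("restriction digestion requires nucleotide input")
  }
  enz <- RESTRICTION_ENZYMES[[enzyme]]
  lapply(records, function(r) {
    hits <- gregexpr(enz$site, r$seq, fixed = TRUE)[[1L]]
    cuts <- if (hits[[1L]] < 0L) integer(0L) else hits + enz$offset - 1L
    bounds <- c(0L, cuts, nchar(r$seq))
    frags <- lapply(seq_len(length(bounds) - 1L), function(i) {
      seq_record(sprintf("%s_frag%d", r$id, i),
                 substr(r$seq, bounds[[i]] + 1L, bounds[[i + 1L]]),
                 r$desc)
    })
    list(id = r$id, enzyme = enzyme, site = enz$site,
         offset = enz$offset, fragments = seq_set(frags))
  })
}
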