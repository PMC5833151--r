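## Newick tree I/O, backed by ape's parser after a structural
## pre-validation pass that reports character offsets.  Internal-node
## labels that parse as numbers are support values; other labels are
## node names.  Unrooted (trifurcating-root) trees are accepted.

#' Read a Newick tree
#'
#' @param source File path or `"-"` for standard input.
#' @param text Optional Newick string or lines.
#' @return An [ape::read.tree()] `phylo` object; missing branch lengths
#'   are set to 0 with a warning.
#' @export
read_tree <- function(source = "-", text = NULL) {
  s <- paste(trimws(stream_lines(source, text)), collapse = "")
  if (!nzchar(s)) bf_stop("empty Newick input")
  validate_newick(s)
  phy <- ape::read.tree(text = s)
  if (is.null(phy)) bf_stop("could not parse Newick input")
  if (is.null(phy$edge.length)) {
    warning("tree has no branch lengths; treating all as 0", call. = FALSE)
    phy$edge.length <- rep(0, nrow(phy$edge))
  } else if (anyNA(phy$edge.length)) {
    warning("missing branch lengths read as 0", call. = FALSE)
    phy$edge.length[is.na(phy$edge.length)] <- 0
  }
  phy
}

validate_newick <- function(s) {
  cs <- chars(s)
  depth <- 0L
  for (i in seq_along(cs)) {
    if (cs[[i]] == "(") depth <- depth + 1L
    if (cs[[i]] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        bf_stop("unbalanced parentheses at character ", i)
      }
    }
  }
  if (depth != 0L) {
    bf_stop("unbalanced parentheses: ", depth,
            " unclosed '(' at character ", nchar(s))
  }
  if (!grepl(";", s, fixed = TRUE)) {
    bf_stop("Newick string lacks terminating ';' at character ", nchar(s))
  }
  ## every ':' must introduce a numeric branch length
  ms <- gregexpr(":[^,():;]*", s)[[1L]]
  if (ms[[1L]] > 0L) {
    lens <- attr(ms, "match.length")
    for (j in seq_along(ms)) {
      tok <- substring(s, ms[[j]] + 1L, ms[[j]] + lens[[j]] - 1L)
      if (!is_number_token(tok)) {
        bf_stop("non-numeric branch length at character ", ms[[j]])
      }
    }
  }
  invisible(TRUE)
}

#' Serialize a tree as Newick
#'
#' @param tree A `phylo` object.
#' @return A single Newick string (with trailing newline semantics left
#'   to the caller).
#' @export
write_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, digits = 10)
}
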