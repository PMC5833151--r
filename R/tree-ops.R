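## biotree operations over ape "phylo" trees: length, rerooting,
## OTU deletion, subtree extraction, support-threshold collapsing,
## patristic distances, OTU depths, ASCII preview.

tree_root_node <- function(phy) ape::Ntip(phy) + 1L

node_label <- function(phy, node) {
  ntip <- ape::Ntip(phy)
  if (node <= ntip) return(phy$tip.label[[node]])
  if (is.null(phy$node.label)) return("")
  lab <- phy$node.label[[node - ntip]]
  if (is.na(lab)) "" else lab
}

node_children <- function(phy, node) {
  phy$edge[phy$edge[, 1L] == node, 2L]
}

#' Total tree length
#'
#' @param tree A `phylo` tree.
#' @return Sum of all branch lengths (including any root edge).
#' @export
total_length <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  sum(tree$edge.length) + (tree$root.edge %||% 0)
}

#' Midpoint rooting
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path, so
#' the two deepest root-to-tip depths are equal.  Total length and all
#' pairwise leaf distances are preserved.  Internal-node labels are
#' treated as support values and stay attached to the correct edges.
#'
#' @param tree A `phylo` tree with >= 2 leaves.
#' @return Midpoint-rooted `phylo` tree.
#' @export
midpoint_root <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (ape::Ntip(tree) < 2L) bf_stop("midpoint rooting needs >= 2 leaves")
  if (total_length(tree) <= 0) {
    bf_stop("midpoint rooting undefined for a zero-length tree")
  }
  out <- if (is.null(tree$node.label)) {
    phangorn::midpoint(tree)
  } else {
    phangorn::midpoint(tree, node.labels = "support")
  }
  if (!is.null(out$node.label)) {
    out$node.label[is.na(out$node.label) | out$node.label == "NA"] <- ""
  }
  out$root.edge <- NULL
  out
}

#' Reroot at an outgroup
#'
#' Inserts the new root on the outgroup's pendant edge, split at its
#' midpoint; all pairwise leaf distances are preserved.
#'
#' @param tree A `phylo` tree.
#' @param otu Leaf name to use as outgroup.
#' @return Rerooted `phylo` tree.
#' @export
reroot_outgroup <- function(tree, otu) {
  stopifnot(inherits(tree, "phylo"))
  if (!otu %in% tree$tip.label) bf_stop("unknown OTU '", otu, "'")
  tip <- which(tree$tip.label == otu)
  root <- tree_root_node(tree)
  already <- tip %in% node_children(tree, root) &&
    length(node_children(tree, root)) == 2L
  out <- if (already) tree else {
    ape::root(tree, outgroup = otu, resolve.root = TRUE, edgelabel = TRUE)
  }
  ## the two root edges form one unrooted edge; splitting its total
  ## length evenly places the root at the pendant-edge midpoint without
  ## touching any leaf-to-leaf distance
  root <- tree_root_node(out)
  ch <- which(out$edge[, 1L] == root)
  if (length(ch) == 2L) {
    tot <- sum(out$edge.length[ch])
    out$edge.length[ch] <- tot / 2
  }
  if (!is.null(out$node.label) &&
      out$node.label[[1L]] %in% c("Root")) {
    out$node.label[[1L]] <- ""
  }
  out$root.edge <- NULL
  out
}

#' Delete OTUs from a tree
#'
#' Unifurcations left by the removal are spliced out with their edge
#' lengths summed, so distances among surviving leaves are unchanged.
#'
#' @param tree A `phylo` tree.
#' @param otus Character vector of leaf names to drop.
#' @return Pruned `phylo` tree (>= 2 leaves must survive).
#' @export
delete_otus <- function(tree, otus) {
  stopifnot(inherits(tree, "phylo"))
  missing <- setdiff(otus, tree$tip.label)
  if (length(missing) > 0L) {
    bf_stop("unknown OTU(s): ", paste(missing, collapse = ", "))
  }
  if (length(setdiff(tree$tip.label, otus)) < 2L) {
    bf_stop("deletion would leave fewer than 2 leaves")
  }
  ape::drop.tip(tree, otus)
}

#' Extract a subtree
#'
#' With a vector of leaf names, returns the minimal subtree spanning
#' them, rooted at their last common ancestor with chain nodes spliced.
#' With a single name matching an internal-node label, returns that
#' clade intact.  When a name matches both a leaf and an internal node,
#' the leaf interpretation wins (with a warning).
#'
#' @param tree A `phylo` tree.
#' @param targets Character vector of leaf names, or one internal-node
#'   name.
#' @return Subtree as a `phylo` object.
#' @export
subset_tree <- function(tree, targets) {
  stopifnot(inherits(tree, "phylo"))
  labels <- tree$node.label %||% character(0L)
  if (length(targets) == 1L && targets %in% labels) {
    if (targets %in% tree$tip.label) {
      warning("'", targets, "' names both a leaf and an internal node; ",
              "using the leaf interpretation", call. = FALSE)
    } else {
      node <- ape::Ntip(tree) + which(labels == targets)[[1L]]
      return(ape::extract.clade(tree, node))
    }
  }
  missing <- setdiff(targets, tree$tip.label)
  if (length(missing) > 0L) {
    bf_stop("unknown OTU(s): ", paste(missing, collapse = ", "))
  }
  if (length(unique(targets)) < 2L) {
    bf_stop("subtree extraction needs >= 2 OTUs or an internal node name")
  }
  ape::keep.tip(tree, unique(targets))
}

## --- nested-list tree view used by the support collapser -------------

phylo_to_list <- function(phy) {
  build <- function(node, len) {
    kids <- node_children(phy, node)
    list(label = node_label(phy, node), len = len,
         children = if (length(kids) == 0L) NULL else
           lapply(kids, function(k) {
             e <- which(phy$edge[, 1L] == node & phy$edge[, 2L] == k)
             build(k, phy$edge.length[[e]])
           }))
  }
  build(tree_root_node(phy), NA_real_)
}

list_to_newick <- function(nd) {
  render <- function(n) {
    lab <- n$label %||% ""
    body <- if (is.null(n$children)) lab else {
      paste0("(", paste(vapply(n$children, render, character(1L)),
                        collapse = ","), ")", lab)
    }
    if (is.na(n$len)) body else paste0(body, ":", sprintf("%.10g", n$len))
  }
  paste0(render(nd), ";")
}

#' Collapse low-support branches
#'
#' Every internal (non-root) edge whose child node carries a numeric
#' support label strictly less than `threshold` is contracted: the
#' child's children attach to its parent and the contracted edge's
#' length is added to each promoted child's edge, preserving
#' root-to-leaf depths.  Supports are compared numerically with no
#' rescaling, so bootstrap percentages (`75`) and fractional supports
#' (`0.9`) both work against a matching threshold.  Unlabeled internal
#' nodes are never collapsed (a warning is emitted when present).
#'
#' @param tree A `phylo` tree with support labels on internal nodes.
#' @param threshold Numeric support threshold.
#' @return `phylo` tree, possibly with polytomies; leaf set unchanged.
#' @export
collapse_low_support <- function(tree, threshold) {
  stopifnot(inherits(tree, "phylo"))
  threshold <- suppressWarnings(as.numeric(threshold))
  if (is.na(threshold)) bf_stop("support threshold must be numeric")
  tl <- phylo_to_list(tree)
  saw_unlabeled <- FALSE
  simplify <- function(nd, is_root = FALSE) {
    if (is.null(nd$children)) return(nd)
    new_children <- list()
    for (ch in nd$children) {
      ch <- simplify(ch)
      if (!is.null(ch$children)) {
        sup <- suppressWarnings(as.numeric(ch$label))
        if (is.na(sup)) {
          if (!nzchar(ch$label %||% "")) saw_unlabeled <<- TRUE
          new_children <- c(new_children, list(ch))
        } else if (sup < threshold) {
          promoted <- lapply(ch$children, function(g) {
            g$len <- g$len + ch$len
            g
          })
          new_children <- c(new_children, promoted)
        } else {
          new_children <- c(new_children, list(ch))
        }
      } else {
        new_children <- c(new_children, list(ch))
      }
    }
    nd$children <- new_children
    nd
  }
  out <- simplify(tl, is_root = TRUE)
  if (saw_unlabeled) {
    warning("unlabeled internal nodes present; they are never collapsed",
            call. = FALSE)
  }
  ape::read.tree(text = list_to_newick(out))
}

#' Patristic distance matrix
#'
#' @param tree A `phylo` tree with >= 2 leaves.
#' @return Symmetric numeric matrix of path-length distances between
#'   all leaf pairs (zero diagonal), rows/columns in tip order.
#' @export
patristic_distances <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (ape::Ntip(tree) < 2L) bf_stop("need >= 2 leaves for distances")
  m <- stats::cophenetic(tree)
  m[tree$tip.label, tree$tip.label]
}

#' Root-to-leaf depths
#'
#' @param tree A rooted `phylo` tree.
#' @return Named numeric vector of root-to-leaf path lengths per OTU.
#' @export
otu_depths <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  d <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  stats::setNames(d, tree$tip.label)
}

#' ASCII cladogram preview
#'
#' Deterministic monospace rendering: one line per node, every leaf
#' label appearing exactly once.
#'
#' @param tree A `phylo` tree.
#' @return Character vector of lines.
#' @export
ascii_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  lines <- character(0L)
  walk <- function(node, prefix, connector, child_prefix) {
    lab <- node_label(tree, node)
    lines[[length(lines) + 1L]] <<- paste0(prefix, connector, lab)
    kids <- node_children(tree, node)
    for (i in seq_along(kids)) {
      last <- i == length(kids)
      walk(kids[[i]],
           paste0(prefix, child_prefix),
           if (last) "\\-- " else "+-- ",
           if (last) "    " else "|   ")
    }
  }
  walk(tree_root_node(tree), "", "", "")
  lines
}
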