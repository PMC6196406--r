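# Newick export with FigTree-compatible bracket comments.
#
# ape writes plain Newick only; branch annotations of the form
# [&subs="..."] (as understood by FigTree) are attached here by a small
# recursive writer. Parsing strips the comments back out and hands the bare
# topology to ape::read.tree, so topology handling stays with ape.

#' Write a tree as Newick with per-branch bracket annotations
#'
#' Each annotated branch is identified by its child node number; the
#' annotation is attached to that node as a `[&<attr>="..."]` comment,
#' which FigTree displays as a branch attribute.
#'
#' @param tree An [ape::phylo] tree (node numbers: tips `1..n`, ancestors
#'   `n+1..`).
#' @param labels Named character vector; names are child node numbers of
#'   the branches to annotate.
#' @param attr_name Attribute key used inside the bracket comment.
#' @return A single Newick string (terminated by `;`).
#' @export
write_annotated_newick <- function(tree, labels = character(), attr_name = "subs") {
  stopifnot(inherits(tree, "phylo"))
  n_tip <- length(tree$tip.label)
  if (length(labels)) {
    if (is.null(names(labels)) || any(!nzchar(names(labels)))) {
      pml_stop("pamlsubs_unknown_branch", "labels must be named by child node number")
    }
    known <- as.character(tree$edge[, 2])
    missing <- setdiff(names(labels), known)
    if (length(missing)) {
      pml_stop("pamlsubs_unknown_branch",
               "no branch with child node %s in tree", missing[1L])
    }
  }
  kids <- split(tree$edge[, 2], factor(tree$edge[, 1]))
  decorate <- function(node) {
    base <- if (node <= n_tip) tree$tip.label[node] else ""
    ann <- labels[as.character(node)]
    if (length(ann) == 1L && !is.na(ann)) {
      paste0(base, "[&", attr_name, "=\"", ann, "\"]")
    } else {
      base
    }
  }
  rec <- function(node) {
    ch <- kids[[as.character(node)]]
    if (is.null(ch)) return(decorate(node))
    paste0("(", paste(vapply(ch, rec, character(1)), collapse = ","), ")",
           decorate(node))
  }
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1L]
  paste0(rec(root), ";")
}

#' Parse annotated Newick written by [write_annotated_newick()]
#'
#' @param text A Newick string, possibly containing `[&key="value"]`
#'   comments.
#' @param attr_name Attribute key to extract.
#' @return A list with `tree` (an [ape::phylo]) and `labels`, a named
#'   character vector keyed by child node number in the RETURNED tree's
#'   numbering (ape renumbers nodes on read; tip annotations can be matched
#'   by tip label, internal ones by topology).
#' @export
parse_annotated_newick <- function(text, attr_name = "subs") {
  rx <- paste0("\\[&", attr_name, "=\"([^\"]*)\"\\]")
  m <- gregexpr(rx, text)
  hits <- regmatches(text, m)[[1]]
  values <- sub(rx, "\\1", hits)
  # replace each comment with a placeholder label token ape can carry
  tokens <- sprintf("__ann%d__", seq_along(hits))
  stripped <- text
  for (i in seq_along(hits)) {
    stripped <- sub(rx, tokens[i], stripped)
  }
  tr <- ape::read.tree(text = stripped)
  if (is.null(tr)) {
    pml_stop("pamlsubs_unrecognized_format", "not a parseable Newick string")
  }
  labels <- character()
  tok_rx <- "__ann(\\d+)__$"
  hit_tip <- grepl(tok_rx, tr$tip.label)
  for (i in which(hit_tip)) {
    k <- as.integer(sub(paste0(".*", tok_rx), "\\1", tr$tip.label[i]))
    labels[as.character(i)] <- values[k]
    tr$tip.label[i] <- sub(tok_rx, "", tr$tip.label[i])
  }
  if (!is.null(tr$node.label)) {
    hit_node <- grepl(tok_rx, tr$node.label)
    n_tip <- length(tr$tip.label)
    for (i in which(hit_node)) {
      k <- as.integer(sub(paste0(".*", tok_rx), "\\1", tr$node.label[i]))
      labels[as.character(n_tip + i)] <- values[k]
      tr$node.label[i] <- sub(tok_rx, "", tr$node.label[i])
    }
    if (all(!nzchar(tr$node.label))) tr$node.label <- NULL
  }
  list(tree = tr, labels = labels)
}
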