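# Per-branch annotation of classified substitutions, the compact
# "<seq>_<count>@<Class><position>" annotation grammar, highlighting
# queries, and export of the two annotated Newick trees (amino-acid
# changes and the nonsynonymous nucleotide changes behind them).
#
# Conventions (the annotation grammar itself is fixed; the change-string
# formats are this package's): amino-acid changes are written
# "<fromAA><codon index><toAA>" (e.g. L45P, 1-based codon index);
# nucleotide changes "<from base><site><to base>" in lower case (e.g.
# a263t, 1-based nucleotide site). Segment order in annotation strings is
# Ts before Tv, codon positions ascending, zero-count cells omitted.

#' Summarize classified events per tree branch
#'
#' @param events A `substitution_events` data frame.
#' @param tree An [ape::phylo] in rst numbering; defaults to the tree
#'   recorded on `events`.
#' @return A list of class `branch_annotations`; one element per branch
#'   bearing at least one event, each a `branch_annotation` list with
#'   `parent`, `child`, `seq_index` (the child node number: the tip index
#'   for external branches), `counts` (2x3 matrix, rows Ts/Tv, columns
#'   codon positions), `aa_changes` and `nt_changes` (nonsynonymous events
#'   only).
#' @export
annotate_branches <- function(events, tree = attr(events, "tree")) {
  if (is.null(tree)) {
    pml_stop("pamlsubs_unknown_branch", "a tree is required")
  }
  if (nrow(events) > 0L) {
    edge_key <- paste(tree$edge[, 1], tree$edge[, 2])
    ev_key <- paste(events$parent, events$child)
    if (any(!(ev_key %in% edge_key))) {
      bad <- which(!(ev_key %in% edge_key))[1L]
      pml_stop("pamlsubs_unknown_branch", "branch %d..%d not in tree",
               events$parent[bad], events$child[bad])
    }
  }
  out <- list()
  for (grp in split(seq_len(nrow(events)),
                    paste(events$parent, events$child))[unique(paste(events$parent, events$child))]) {
    ev <- events[grp, , drop = FALSE]
    counts <- matrix(0L, 2L, 3L,
                     dimnames = list(c("Ts", "Tv"), paste0("pos", 1:3)))
    tab <- table(factor(ev$class, levels = c("Ts", "Tv")),
                 factor(ev$codon_position, levels = 1:3))
    counts[] <- as.integer(tab)
    ns <- ev[ev$effect == "nonsynonymous", , drop = FALSE]
    ann <- list(
      parent = ev$parent[1L], child = ev$child[1L],
      seq_index = ev$child[1L],
      counts = counts,
      aa_changes = paste0(ns$from_aa, ns$codon_index, ns$to_aa),
      nt_changes = paste0(tolower(ns$from_base), ns$site, tolower(ns$to_base))
    )
    class(ann) <- "branch_annotation"
    out[[length(out) + 1L]] <- ann
  }
  structure(out, class = "branch_annotations", tree = tree)
}

#' Format a branch annotation string
#'
#' Produces the compact per-branch summary used on annotated trees, e.g.
#' `"18_1@Ts1_3@Ts2_2@Tv1"`: sequence (child node) number 18 carries one
#' transition at codon position 1, three transitions at position 2 and two
#' transversions at position 1. Classes are ordered Ts then Tv, positions
#' ascending; zero-count cells are omitted.
#'
#' @param a A `branch_annotation`, or a bare 2x3 count matrix together
#'   with `seq_index`.
#' @param seq_index Overrides the annotation's sequence index.
#' @return A single annotation string.
#' @export
format_annotation <- function(a, seq_index = NULL) {
  if (inherits(a, "branch_annotation")) {
    counts <- a$counts
    if (is.null(seq_index)) seq_index <- a$seq_index
  } else {
    counts <- a
  }
  stopifnot(is.matrix(counts), identical(dim(counts), c(2L, 3L)),
            !is.null(seq_index))
  if (sum(counts) < 1L) {
    pml_stop("pamlsubs_empty_annotation",
             "annotation requires at least one substitution")
  }
  segs <- character()
  for (cl in c("Ts", "Tv")) {
    for (p in 1:3) {
      k <- counts[cl, p]
      if (k > 0L) segs <- c(segs, sprintf("%d@%s%d", k, cl, p))
    }
  }
  paste(c(seq_index, segs), collapse = "_")
}

#' Parse a branch annotation string
#'
#' Exact inverse of [format_annotation()].
#'
#' @param text Annotation string, e.g. `"18_1@Ts1_3@Ts2_2@Tv1"`.
#' @return A list with `seq_index` and `counts` (2x3 matrix, rows Ts/Tv,
#'   columns codon positions 1-3).
#' @export
parse_annotation <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  parts <- strsplit(text, "_", fixed = TRUE)[[1]]
  if (length(parts) < 2L || !grepl("^\\d+$", parts[1L])) {
    pml_stop("pamlsubs_annotation_syntax", "bad annotation string: %s", text)
  }
  counts <- matrix(0L, 2L, 3L,
                   dimnames = list(c("Ts", "Tv"), paste0("pos", 1:3)))
  for (seg in parts[-1L]) {
    m <- regexec("^(\\d+)@(Ts|Tv)([123])$", seg)
    if (m[[1]][1] == -1L) {
      pml_stop("pamlsubs_annotation_syntax",
               "bad annotation segment '%s' in %s", seg, text)
    }
    g <- regmatches(seg, m)[[1]]
    counts[g[3], as.integer(g[4])] <-
      counts[g[3], as.integer(g[4])] + as.integer(g[2])
  }
  list(seq_index = as.integer(parts[1L]), counts = counts)
}

#' Select branches whose substitution counts meet a criterion
#'
#' Supports queries such as "all sequences with transitions at the second
#' codon position", used to highlight tips or branches in tree displays.
#'
#' @param annotations A `branch_annotations` list.
#' @param class `"Ts"`, `"Tv"`, or both.
#' @param position Codon positions to consider (subset of 1:3).
#' @param min_count Minimum summed count over the selected cells.
#' @return Integer vector of child node numbers of the matching branches.
#' @export
highlight_branches <- function(annotations, class = c("Ts", "Tv"),
                               position = 1:3, min_count = 1L) {
  class <- match.arg(class, several.ok = TRUE)
  stopifnot(all(position %in% 1:3))
  hits <- vapply(annotations, function(a) {
    sum(a$counts[class, position, drop = FALSE]) >= min_count
  }, logical(1))
  vapply(annotations[hits], `[[`, integer(1), "child")
}

#' Export the two annotated Newick trees
#'
#' Writes one tree whose branches carry the inferred amino-acid changes
#' and a second carrying the corresponding nonsynonymous nucleotide
#' changes; branches without nonsynonymous events are unlabeled.
#'
#' @param annotations A `branch_annotations` list.
#' @param tree An [ape::phylo]; defaults to the tree recorded on
#'   `annotations`.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of the two file paths
#'   (`tree_aa_changes.nwk`, `tree_nt_changes.nwk`), invisibly; the Newick
#'   strings are attached as the `"newick"` attribute.
#' @export
export_trees <- function(annotations, tree = attr(annotations, "tree"), out_dir) {
  if (is.null(tree)) pml_stop("pamlsubs_unknown_branch", "a tree is required")
  pick <- function(field) {
    vals <- lapply(annotations, `[[`, field)
    keep <- vapply(vals, length, integer(1)) > 0L
    stats::setNames(vapply(vals[keep], paste, character(1), collapse = ","),
                    vapply(annotations[keep], `[[`, integer(1), "child"))
  }
  aa_nwk <- write_annotated_newick(tree, pick("aa_changes"), attr_name = "aa")
  nt_nwk <- write_annotated_newick(tree, pick("nt_changes"), attr_name = "nt")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(out_dir, c("tree_aa_changes.nwk", "tree_nt_changes.nwk"))
  writeLines(aa_nwk, paths[1L])
  writeLines(nt_nwk, paths[2L])
  invisible(structure(paths, newick = c(aa_nwk, nt_nwk)))
}

#' @export
print.branch_annotations <- function(x, ...) {
  cat(sprintf("branch_annotations: %d annotated branches, %d substitutions\n",
              length(x), sum(vapply(x, function(a) sum(a$counts), integer(1)))))
  for (a in x) {
    cat(sprintf("  %d..%d  %s\n", a$parent, a$child, format_annotation(a)))
  }
  invisible(x)
}
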