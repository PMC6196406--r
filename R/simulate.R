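# Seeded codon-sequence evolution along a tree with an exact event log.
#
# The simulator's purpose is format and count fidelity, not biological
# realism: it produces ground-truth substitution histories in exactly the
# rst dialect the parser consumes, so that every downstream stage (parsing,
# classification, profiles, matrices, annotations) can be checked against a
# known answer. Substitution placement follows a Kimura-style scheme: per
# branch a Poisson number of events at distinct sites, with the target base
# drawn with transition:transversion odds kappa : 1 (each of the two
# transversion alternatives carrying half the transversion weight).
# Proposals that would create a stop codon -- either in the parent-frame
# codon carrying just that change or in the accumulating child sequence --
# are rejected and redrawn.

#' Simulate a substitution history along a tree
#'
#' @param tree An [ape::phylo] with numbered nodes (tips `1..n`); by
#'   default a random rooted binary tree with `tips` tips and labels
#'   `t1..tn` is drawn.
#' @param tips Number of tips for the default random tree.
#' @param length_codons Alignment length in codons; the root sequence is
#'   drawn uniformly over the 61 sense codons.
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param events_per_branch Expected (Poisson) number of substitutions per
#'   branch.
#' @param seed Integer seed; the whole history is reproducible from it.
#' @return A list of class `ground_truth` with `tree`, `taxa`,
#'   `alignment_length` (nt), `node_sequences` (named by node number),
#'   `events` (a classified event data frame with the same columns as
#'   [classify_substitutions()] output) and `params`.
#' @export
simulate_substitutions <- function(tree = NULL, tips = 10L, length_codons = 300L,
                                   kappa = 4, events_per_branch = 20,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length_codons < 1L || kappa <= 0 || events_per_branch < 0) {
    pml_stop("pamlsubs_parameter_error",
             "need length_codons >= 1, kappa > 0, events_per_branch >= 0")
  }
  if (is.null(tree)) {
    if (tips < 3L) {
      pml_stop("pamlsubs_parameter_error", "need >= 3 tips")
    }
    tree <- ape::rtree(tips, tip.label = paste0("t", seq_len(tips)))
    tree$edge.length <- NULL
  }
  stopifnot(inherits(tree, "phylo"))
  tree <- ape::reorder.phylo(tree, "cladewise")  # parents precede children
  n_tip <- length(tree$tip.label)
  n_sites <- 3L * as.integer(length_codons)
  code <- genetic_code()
  sense <- names(code)[code != "*"]

  root <- n_tip + 1L
  root_seq <- paste(sample(sense, length_codons, replace = TRUE), collapse = "")
  seqs <- list()
  seqs[[as.character(root)]] <- root_seq

  ev_list <- list()
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1L]
    child <- tree$edge[e, 2L]
    parent_seq <- seqs[[as.character(parent)]]
    child_seq <- parent_seq
    n_ev <- min(stats::rpois(1L, events_per_branch), n_sites)
    open_sites <- seq_len(n_sites)
    placed <- 0L
    while (placed < n_ev && length(open_sites) > 0L) {
      site <- if (length(open_sites) == 1L) open_sites else sample(open_sites, 1L)
      open_sites <- setdiff(open_sites, site)
      pos <- ((site - 1L) %% 3L) + 1L
      cstart <- site - pos + 1L
      from_base <- substr(parent_seq, site, site)
      from_codon <- substr(parent_seq, cstart, cstart + 2L)
      child_codon <- substr(child_seq, cstart, cstart + 2L)
      alts <- setdiff(.dna_bases, from_base)
      w <- ifelse(substitution_class(from_base, alts) == "Ts", kappa, 0.5)
      # reject targets creating a stop in either codon frame
      ok <- vapply(alts, function(b) {
        fc <- from_codon; substr(fc, pos, pos) <- b
        cc <- child_codon; substr(cc, pos, pos) <- b
        code[[fc]] != "*" && code[[cc]] != "*"
      }, logical(1))
      if (!any(ok)) next
      to_base <- sample(alts[ok], 1L, prob = w[ok])
      to_codon <- from_codon
      substr(to_codon, pos, pos) <- to_base
      substr(child_seq, site, site) <- to_base
      from_aa <- code[[from_codon]]
      to_aa <- code[[to_codon]]
      cls <- substitution_class(from_base, to_base)
      effect <- if (from_aa == to_aa) "synonymous" else "nonsynonymous"
      ev_list[[length(ev_list) + 1L]] <- data.frame(
        parent = parent, child = child, site = site,
        codon_index = (site - 1L) %/% 3L + 1L, codon_position = pos,
        from_base = from_base, to_base = to_base,
        from_codon = from_codon, to_codon = to_codon,
        from_aa = from_aa, to_aa = to_aa,
        class = cls, effect = effect,
        category = if (cls == "Ts") {
          if (effect == "synonymous") "As" else "Aa"
        } else {
          if (effect == "synonymous") "Bs" else "Ba"
        },
        posterior = round(stats::runif(1L, 0.90, 1.00), 4L),
        stringsAsFactors = FALSE
      )
      placed <- placed + 1L
    }
    seqs[[as.character(child)]] <- child_seq
  }
  events <- if (length(ev_list)) {
    do.call(rbind, ev_list)
  } else {
    data.frame(parent = integer(), child = integer(), site = integer(),
               codon_index = integer(), codon_position = integer(),
               from_base = character(), to_base = character(),
               from_codon = character(), to_codon = character(),
               from_aa = character(), to_aa = character(),
               class = character(), effect = character(),
               category = character(), posterior = double(),
               stringsAsFactors = FALSE)
  }
  rownames(events) <- NULL
  structure(list(
    tree = tree,
    taxa = data.frame(index = seq_len(n_tip), name = tree$tip.label,
                      stringsAsFactors = FALSE),
    alignment_length = n_sites,
    node_sequences = seqs,
    events = events,
    params = list(kappa = kappa, events_per_branch = events_per_branch,
                  length_codons = as.integer(length_codons), seed = seed)
  ), class = "ground_truth")
}

#' Serialize a simulated history as a PAML-style rst file
#'
#' Emits the rst dialect consumed by [parse_rst()], in either the baseml
#' flavor (single-base change lines) or the codeml flavor (codon plus
#' amino-acid change lines). Coordinates are 1-based nucleotide sites.
#'
#' @param log A `ground_truth` from [simulate_substitutions()].
#' @param dialect `"codeml"` or `"baseml"`.
#' @param file Optional path; when given the text is also written there.
#' @return The rst text as a character vector of lines (invisibly when
#'   `file` is given).
#' @export
write_rst <- function(log, dialect = c("codeml", "baseml"), file = NULL) {
  stopifnot(inherits(log, "ground_truth"))
  dialect <- match.arg(dialect)
  tree <- log$tree
  n_tip <- length(tree$tip.label)

  header <- sprintf(
    "Supplemental results for %s (seqf: alignment.phy  treef: tree.nwk)",
    if (dialect == "codeml") "CODEML" else "BASEML")

  numbered <- tree
  numbered$tip.label <- paste0(seq_len(n_tip), "_", tree$tip.label)
  tree_line <- ape::write.tree(numbered)

  name_w <- max(nchar(c(tree$tip.label, "node #999"))) + 4L
  seq_lines <- character()
  for (i in seq_len(n_tip)) {
    seq_lines <- c(seq_lines, sprintf("%-*s%s", name_w, tree$tip.label[i],
                                      log$node_sequences[[as.character(i)]]))
  }
  for (node in sort(as.integer(names(log$node_sequences)))) {
    if (node <= n_tip) next
    seq_lines <- c(seq_lines, sprintf("%-*s%s", name_w,
                                      sprintf("node #%d", node),
                                      log$node_sequences[[as.character(node)]]))
  }

  blocks <- character()
  ev <- log$events
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1L]
    child <- tree$edge[e, 2L]
    label <- if (child <= n_tip) sprintf("  (%s)", tree$tip.label[child]) else ""
    blocks <- c(blocks, "",
                sprintf("Branch %d:  %2d..%-2d%s", e, parent, child, label), "")
    rows <- which(ev$parent == parent & ev$child == child)
    rows <- rows[order(ev$site[rows])]
    for (i in rows) {
      blocks <- c(blocks, if (dialect == "codeml") {
        sprintf("%8d %s (%s) %.4f -> %s (%s)", ev$site[i],
                ev$from_codon[i], ev$from_aa[i], ev$posterior[i],
                ev$to_codon[i], ev$to_aa[i])
      } else {
        sprintf("%8d %s %.4f -> %s", ev$site[i],
                ev$from_base[i], ev$posterior[i], ev$to_base[i])
      })
    }
  }

  out <- c(header, "",
           "Ancestral reconstruction on the numbered tree below.", "",
           tree_line, "",
           "List of extant and reconstructed sequences", "",
           seq_lines, "",
           "Summary of changes along branches.",
           blocks, "")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d tips, %d nt, %d events (kappa = %g)\n",
              length(x$tree$tip.label), x$alignment_length, nrow(x$events),
              x$params$kappa))
  invisible(x)
}
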