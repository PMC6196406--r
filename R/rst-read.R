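# Reading PAML rst files (the auxiliary output written by baseml/codeml when
# ancestral reconstruction is requested).
#
# Supported dialect, fixed by the fixture generator in simulate.R:
#   * a header line naming the program ("Supplemental results for BASEML"
#     or "... CODEML");
#   * a parenthesized Newick tree whose tips are numbered "k_name";
#   * a "List of extant and reconstructed sequences" section with one line
#     per node ("name  SEQ" for tips, "node #k  SEQ" for ancestors);
#   * a "Summary of changes along branches" section with blocks headed
#     "Branch N: a..b (label)" and change lines
#       "site base prob -> base"               (baseml)
#       "site codon (aa) prob -> codon (aa)"   (codeml)
#     with 1-based nucleotide-site coordinates throughout.
# Lines outside this grammar are skipped with a logged warning so that
# harmless PAML version drift does not abort a run.

.rx_branch <- "^Branch\\s+(\\d+):\\s*(\\d+)\\.\\.(\\d+)\\s*(?:\\((\\S+)\\))?\\s*$"
.rx_codeml <- "^\\s*(\\d+)\\s+([A-Za-z-]{3})\\s+\\(([A-Za-z*-])\\)\\s+([0-9.]+)\\s+->\\s+([A-Za-z-]{3})\\s+\\(([A-Za-z*-])\\)\\s*$"
.rx_baseml <- "^\\s*(\\d+)\\s+([A-Za-z-])\\s+([0-9.]+)\\s+->\\s+([A-Za-z-])\\s*$"

.as_lines <- function(text) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(text)
  }
}

#' Identify which PAML program wrote an rst file
#'
#' @param text rst file contents: a single string or a character vector of
#'   lines.
#' @return `"baseml"` or `"codeml"`.
#' @export
detect_program <- function(text) {
  lines <- .as_lines(text)
  if (length(lines) == 0L || all(!nzchar(trimws(lines)))) {
    pml_stop("pamlsubs_unrecognized_format", "empty input: not an rst file")
  }
  head_lines <- lines[seq_len(min(5L, length(lines)))]
  if (any(grepl("CODEML|CODONML", head_lines))) return("codeml")
  if (any(grepl("BASEML", head_lines))) return("baseml")
  # fall back on the shape of the change lines
  if (any(grepl(.rx_codeml, lines))) return("codeml")
  if (any(grepl(.rx_baseml, lines)) &&
      any(grepl("Summary of changes", lines))) return("baseml")
  pml_stop("pamlsubs_unrecognized_format",
           "input does not look like a baseml or codeml rst file")
}

#' Read a PAML rst file
#'
#' @param file Path to an rst file.
#' @param ... Passed on to [parse_rst()].
#' @return An `rst_document`; see [parse_rst()].
#' @export
read_rst <- function(file, ...) {
  parse_rst(readLines(file, warn = FALSE), ...)
}

#' Parse PAML rst text into a structured document
#'
#' @param text rst contents: a single string or a character vector of lines.
#' @return A list of class `rst_document` with elements
#'   \describe{
#'     \item{program}{`"baseml"` or `"codeml"`.}
#'     \item{alignment_length}{Nucleotide alignment length.}
#'     \item{taxa}{Data frame of tip `index` and `name` (rst numbering,
#'       tips `1..n`).}
#'     \item{tree}{An [ape::phylo] tree whose node numbers are the rst node
#'       numbers (tips `1..n`, ancestors `n+1..2n-1`).}
#'     \item{branches}{Data frame of `branch` (block number), `parent`,
#'       `child`, `child_label`, `n_changes`.}
#'     \item{changes}{Data frame of raw change records: `parent`, `child`,
#'       `site`, `from_state`, `to_state`, `from_aa`, `to_aa`, `from_base`,
#'       `to_base`, `posterior`.}
#'     \item{node_sequences}{Named list, node number -> sequence string
#'       (extant tips and reconstructed ancestors).}
#'   }
#'
#' Sequences containing gaps or ambiguity codes abort with a structured
#' error: the upstream alignment must be gap-free protein-coding sequence.
#' A codeml document whose alignment length is not a multiple of 3 raises a
#' frame error.
#' @export
parse_rst <- function(text) {
  lines <- .as_lines(text)
  program <- detect_program(lines)

  # --- numbered tree -------------------------------------------------------
  tree_i <- grep("^\\s*\\(.*;\\s*$", lines)
  if (length(tree_i) == 0L) {
    pml_stop("pamlsubs_unrecognized_format", "no numbered Newick tree found")
  }
  tree_str <- trimws(lines[tree_i[1L]])
  tips <- regmatches(tree_str, gregexpr("(\\d+)_([A-Za-z0-9._|-]+)", tree_str))[[1]]
  if (length(tips) == 0L) {
    pml_stop("pamlsubs_unrecognized_format", "tree has no numbered tips (k_name)")
  }
  taxa <- data.frame(
    index = as.integer(sub("_.*$", "", tips)),
    name = sub("^\\d+_", "", tips),
    stringsAsFactors = FALSE
  )
  taxa <- taxa[order(taxa$index), , drop = FALSE]
  rownames(taxa) <- NULL
  n_tip <- nrow(taxa)
  if (!identical(taxa$index, seq_len(n_tip))) {
    pml_stop("pamlsubs_unrecognized_format",
             "tip numbering is not 1..%d", n_tip)
  }

  # --- node sequences ------------------------------------------------------
  seq_head <- grep("List of extant and reconstructed sequences", lines)
  sum_head <- grep("Summary of changes along branches", lines)
  if (length(seq_head) == 0L || length(sum_head) == 0L) {
    pml_stop("pamlsubs_unrecognized_format",
             "missing sequence list or branch-change summary section")
  }
  seq_lines <- lines[(seq_head[1L] + 1L):(sum_head[1L] - 1L)]
  node_sequences <- list()
  name_to_index <- stats::setNames(taxa$index, taxa$name)
  for (k in seq_along(seq_lines)) {
    ln <- seq_lines[k]
    if (!nzchar(trimws(ln))) next
    m <- regexec("^\\s*node\\s*#(\\d+)\\s+(.*)$", ln)
    if (m[[1]][1] != -1L) {
      g <- regmatches(ln, m)[[1]]
      node <- as.integer(g[2])
      seqchr <- gsub("\\s", "", g[3])
    } else {
      m2 <- regexec("^\\s*(\\S+)\\s+(.*)$", ln)
      if (m2[[1]][1] == -1L) next
      g <- regmatches(ln, m2)[[1]]
      if (!(g[2] %in% names(name_to_index))) {
        pml_warn("pamlsubs_skipped_line",
                 "skipping unrecognized sequence line %d: %s",
                 seq_head[1L] + k, substr(trimws(ln), 1, 40))
        next
      }
      node <- name_to_index[[g[2]]]
      seqchr <- gsub("\\s", "", g[3])
    }
    bad <- gsub("[ACGT]", "", seqchr)
    if (nzchar(bad)) {
      pml_stop("pamlsubs_gap_error",
               "sequence for node %d contains gap/ambiguity character '%s'; rst files must come from gap-free, unambiguous coding alignments",
               node, substr(bad, 1, 1))
    }
    node_sequences[[as.character(node)]] <- seqchr
  }
  if (length(node_sequences) == 0L) {
    pml_stop("pamlsubs_unrecognized_format", "no node sequences found")
  }
  lens <- unique(nchar(unlist(node_sequences)))
  if (length(lens) != 1L) {
    pml_stop("pamlsubs_unrecognized_format",
             "node sequences differ in length (%s)",
             paste(lens, collapse = ", "))
  }
  alignment_length <- lens
  if (program == "codeml" && alignment_length %% 3L != 0L) {
    pml_stop("pamlsubs_frame_error",
             "codeml alignment length %d is not a multiple of 3", alignment_length)
  }

  # --- per-branch change blocks -------------------------------------------
  branches <- list()
  changes <- list()
  cur <- NULL
  for (k in seq(from = sum_head[1L] + 1L, length.out = length(lines) - sum_head[1L])) {
    ln <- lines[k]
    if (!nzchar(trimws(ln))) next
    bm <- regexec(.rx_branch, trimws(ln))
    if (bm[[1]][1] != -1L) {
      g <- regmatches(trimws(ln), bm)[[1]]
      cur <- list(branch = as.integer(g[2]), parent = as.integer(g[3]),
                  child = as.integer(g[4]),
                  child_label = if (is.na(g[5]) || !nzchar(g[5])) "" else g[5])
      branches[[length(branches) + 1L]] <- cur
      next
    }
    cm <- regexec(.rx_codeml, ln)
    if (cm[[1]][1] != -1L) {
      if (is.null(cur)) {
        pml_stop("pamlsubs_malformed_block",
                 "change line outside any branch block at line %d", k)
      }
      g <- regmatches(ln, cm)[[1]]
      states <- toupper(c(g[3], g[6]))
      if (grepl("[^ACGT]", paste0(states, collapse = ""))) {
        pml_stop("pamlsubs_gap_error",
                 "non-DNA state in change line %d", k)
      }
      changes[[length(changes) + 1L]] <- data.frame(
        parent = cur$parent, child = cur$child, site = as.integer(g[2]),
        from_state = states[1], to_state = states[2],
        from_aa = toupper(g[4]), to_aa = toupper(g[7]),
        from_base = NA_character_, to_base = NA_character_,
        posterior = as.numeric(g[5]), stringsAsFactors = FALSE
      )
      next
    }
    bl <- regexec(.rx_baseml, ln)
    if (bl[[1]][1] != -1L) {
      if (is.null(cur)) {
        pml_stop("pamlsubs_malformed_block",
                 "change line outside any branch block at line %d", k)
      }
      g <- regmatches(ln, bl)[[1]]
      states <- toupper(c(g[3], g[5]))
      if (grepl("[^ACGT]", paste0(states, collapse = ""))) {
        pml_stop("pamlsubs_gap_error", "non-DNA state in change line %d", k)
      }
      changes[[length(changes) + 1L]] <- data.frame(
        parent = cur$parent, child = cur$child, site = as.integer(g[2]),
        from_state = states[1], to_state = states[2],
        from_aa = NA_character_, to_aa = NA_character_,
        from_base = states[1], to_base = states[2],
        posterior = as.numeric(g[4]), stringsAsFactors = FALSE
      )
      next
    }
    if (grepl("->", ln, fixed = TRUE)) {
      pml_stop("pamlsubs_malformed_block",
               "unparseable change line %d: %s", k, substr(trimws(ln), 1, 60))
    }
    pml_warn("pamlsubs_skipped_line", "skipping unrecognized line %d: %s",
             k, substr(trimws(ln), 1, 40))
  }
  if (length(branches) == 0L) {
    pml_stop("pamlsubs_malformed_block", "no branch blocks found")
  }
  branch_df <- do.call(rbind, lapply(branches, function(b) {
    data.frame(branch = b$branch, parent = b$parent, child = b$child,
               child_label = b$child_label, stringsAsFactors = FALSE)
  }))
  change_df <- if (length(changes)) {
    do.call(rbind, changes)
  } else {
    data.frame(parent = integer(), child = integer(), site = integer(),
               from_state = character(), to_state = character(),
               from_aa = character(), to_aa = character(),
               from_base = character(), to_base = character(),
               posterior = double(), stringsAsFactors = FALSE)
  }
  if (program == "codeml" && nrow(change_df) > 0L) {
    # derive the altered base from the codon pair
    pos <- codon_position(change_df$site)
    change_df$from_base <- substr(change_df$from_state, pos, pos)
    change_df$to_base <- substr(change_df$to_state, pos, pos)
  }
  if (nrow(change_df) > 0L) {
    if (any(change_df$site < 1L | change_df$site > alignment_length)) {
      pml_stop("pamlsubs_malformed_block",
               "change site outside alignment of length %d", alignment_length)
    }
    if (any(change_df$from_state == change_df$to_state)) {
      pml_stop("pamlsubs_malformed_block",
               "change line with identical from/to state")
    }
    key <- paste(change_df$parent, change_df$child, change_df$site)
    if (anyDuplicated(key)) {
      pml_stop("pamlsubs_malformed_block",
               "more than one change at one site on one branch")
    }
  }

  tree <- .tree_from_edges(branch_df$parent, branch_df$child, taxa$name)
  branch_df$n_changes <- vapply(seq_len(nrow(branch_df)), function(i) {
    sum(change_df$parent == branch_df$parent[i] &
          change_df$child == branch_df$child[i])
  }, integer(1))

  structure(list(
    program = program,
    alignment_length = alignment_length,
    taxa = taxa,
    tree = tree,
    branches = branch_df,
    changes = change_df,
    node_sequences = node_sequences
  ), class = "rst_document")
}

# Rebuild the phylo topology from the branch records; rst numbering (tips
# 1..n, ancestors n+1..2n-1, root n+1) coincides with ape's convention.
.tree_from_edges <- function(parent, child, tip_labels) {
  n_tip <- length(tip_labels)
  if (any(parent <= n_tip)) {
    pml_stop("pamlsubs_malformed_block",
             "branch record with a tip (%d) as parent", parent[parent <= n_tip][1L])
  }
  edge <- cbind(as.integer(parent), as.integer(child))
  nodes <- sort(unique(c(parent, child)))
  tr <- structure(list(
    edge = edge,
    tip.label = tip_labels,
    Nnode = length(nodes) - n_tip
  ), class = "phylo", order = "cladewise")
  tr
}

#' @export
print.rst_document <- function(x, ...) {
  cat(sprintf("PAML rst document (%s)\n", x$program))
  cat(sprintf("  %d taxa, alignment length %d nt\n",
              nrow(x$taxa), x$alignment_length))
  cat(sprintf("  %d branches, %d inferred substitutions\n",
              nrow(x$branches), nrow(x$changes)))
  invisible(x)
}
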