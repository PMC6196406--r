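# Classification of inferred substitutions: transition vs transversion,
# codon position, and phenotypic effect (synonymous vs nonsynonymous).
#
# The four-way category labels follow the standard molecular-evolution
# shorthand: As = synonymous transitions, Bs = synonymous transversions,
# Aa = nonsynonymous transitions, Ba = nonsynonymous transversions.

.dna_bases <- c("A", "C", "G", "T")

#' Classify a base change as transition or transversion
#'
#' Transitions are the purine/purine and pyrimidine/pyrimidine exchanges
#' (A<->G, C<->T); the four remaining unordered pairs are transversions.
#'
#' @param from,to Character vectors of single DNA bases (recycled).
#' @return Character vector of `"Ts"` / `"Tv"`.
#' @examples
#' substitution_class("A", "G")  # "Ts"
#' substitution_class("G", "C")  # "Tv"
#' @export
substitution_class <- function(from, to) {
  n <- max(length(from), length(to))
  from <- rep_len(from, n)
  to <- rep_len(to, n)
  bad <- !(from %in% .dna_bases) | !(to %in% .dna_bases) | from == to
  if (any(bad)) {
    pml_stop("pamlsubs_invalid_base",
             "need two distinct DNA bases, got (%s, %s)",
             from[which(bad)[1L]], to[which(bad)[1L]])
  }
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  unname(ifelse(purine[from] == purine[to], "Ts", "Tv"))
}

#' Codon position of a nucleotide site
#'
#' @param site Integer vector of 1-based nucleotide positions.
#' @return Integer vector in `1:3`.
#' @export
codon_position <- function(site) {
  site <- as.integer(site)
  if (any(is.na(site) | site < 1L)) {
    pml_stop("pamlsubs_domain_error", "site must be a positive integer")
  }
  ((site - 1L) %% 3L) + 1L
}

#' Codon index of a nucleotide site
#'
#' @param site Integer vector of 1-based nucleotide positions.
#' @return Integer vector of 1-based codon indices.
#' @export
codon_index <- function(site) {
  site <- as.integer(site)
  if (any(is.na(site) | site < 1L)) {
    pml_stop("pamlsubs_domain_error", "site must be a positive integer")
  }
  ((site - 1L) %/% 3L) + 1L
}

#' Classify every inferred substitution in an rst document
#'
#' Turns the raw per-branch change records of a parsed rst document into a
#' fully classified event table. The codon context of each change is taken
#' from the PARENT node's reconstructed sequence with only the changed base
#' substituted: PAML reports changes parent -> child, so the
#' pre-substitution reading frame is the parent's. When several sites of
#' one codon change on the same branch, each event is therefore evaluated
#' against the parent codon independently (a documented simplification).
#'
#' For codeml documents the codons and amino acids printed in the rst file
#' are cross-checked against this derivation; a mismatch raises a warning,
#' not an error.
#'
#' @param doc An `rst_document` from [read_rst()] / [parse_rst()].
#' @param posterior_threshold Drop events whose reconstruction posterior is
#'   below this value (default 0: keep every inferred change, matching the
#'   way the counts are defined).
#' @return A data frame of class `substitution_events`, sorted by branch and
#'   site, with columns `parent`, `child`, `site`, `codon_index`,
#'   `codon_position`, `from_base`, `to_base`, `from_codon`, `to_codon`,
#'   `from_aa`, `to_aa`, `class` (Ts/Tv), `effect`
#'   (synonymous/nonsynonymous), `category` (As/Bs/Aa/Ba) and `posterior`.
#'   The alignment length and tree are carried as attributes.
#' @export
classify_substitutions <- function(doc, posterior_threshold = 0) {
  stopifnot(inherits(doc, "rst_document"))
  if (!is.numeric(posterior_threshold) || posterior_threshold < 0 ||
      posterior_threshold > 1) {
    pml_stop("pamlsubs_config_error", "posterior_threshold must be in [0, 1]")
  }
  ch <- doc$changes
  empty <- data.frame(
    parent = integer(), child = integer(), site = integer(),
    codon_index = integer(), codon_position = integer(),
    from_base = character(), to_base = character(),
    from_codon = character(), to_codon = character(),
    from_aa = character(), to_aa = character(),
    class = character(), effect = character(), category = character(),
    posterior = double(), stringsAsFactors = FALSE
  )
  if (nrow(ch) == 0L) {
    return(.as_events(empty, doc))
  }
  keep <- is.na(ch$posterior) | ch$posterior >= posterior_threshold
  ch <- ch[keep, , drop = FALSE]
  if (nrow(ch) == 0L) return(.as_events(empty, doc))

  pos <- codon_position(ch$site)
  cidx <- codon_index(ch$site)
  parent_key <- as.character(ch$parent)
  missing_parent <- !(parent_key %in% names(doc$node_sequences))
  if (any(missing_parent)) {
    pml_stop("pamlsubs_missing_ancestor",
             "no reconstructed sequence for ancestral node %s",
             parent_key[which(missing_parent)[1L]])
  }
  codon_start <- (cidx - 1L) * 3L + 1L
  from_codon <- vapply(seq_len(nrow(ch)), function(i) {
    substr(doc$node_sequences[[parent_key[i]]], codon_start[i],
           codon_start[i] + 2L)
  }, character(1))
  from_base <- substr(from_codon, pos, pos)
  to_base <- if ("to_base" %in% names(ch) && !all(is.na(ch$to_base))) {
    ch$to_base
  } else {
    # codeml records carry codons; extract the altered base
    substr(ch$to_state, pos, pos)
  }
  to_codon <- from_codon
  substr(to_codon, pos, pos) <- to_base

  # cross-check against what codeml printed, where available
  if (doc$program == "codeml" && all(nchar(ch$from_state) == 3L)) {
    mism <- ch$from_state != from_codon |
      (!is.na(ch$from_aa) & ch$from_aa != translate_codon(from_codon))
    if (any(mism)) {
      pml_warn("pamlsubs_reconstruction_mismatch",
               "%d change line(s) disagree with the parent-sequence codon context (first at site %d)",
               sum(mism), ch$site[which(mism)[1L]])
    }
  }

  from_aa <- translate_codon(from_codon)
  to_aa <- translate_codon(to_codon)
  if (any(from_aa == "*" | to_aa == "*")) {
    i <- which(from_aa == "*" | to_aa == "*")[1L]
    pml_stop("pamlsubs_stop_codon",
             "implied stop codon at site %d (%s -> %s): corrupt reconstruction",
             ch$site[i], from_codon[i], to_codon[i])
  }
  cls <- substitution_class(from_base, to_base)
  effect <- ifelse(from_aa == to_aa, "synonymous", "nonsynonymous")
  category <- ifelse(cls == "Ts",
                     ifelse(effect == "synonymous", "As", "Aa"),
                     ifelse(effect == "synonymous", "Bs", "Ba"))
  ev <- data.frame(
    parent = ch$parent, child = ch$child, site = ch$site,
    codon_index = cidx, codon_position = pos,
    from_base = from_base, to_base = to_base,
    from_codon = from_codon, to_codon = to_codon,
    from_aa = from_aa, to_aa = to_aa,
    class = cls, effect = effect, category = category,
    posterior = ch$posterior, stringsAsFactors = FALSE
  )
  ev <- ev[order(ev$parent, ev$child, ev$site), , drop = FALSE]
  rownames(ev) <- NULL
  .as_events(ev, doc)
}

.as_events <- function(ev, doc) {
  attr(ev, "alignment_length") <- doc$alignment_length
  attr(ev, "tree") <- doc$tree
  class(ev) <- c("substitution_events", "data.frame")
  ev
}
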