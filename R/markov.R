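# 4x4 substitution count matrix and its Markov (conditional-probability)
# normalization.

#' Count matrix of nucleotide substitutions
#'
#' @param events A `substitution_events` data frame.
#' @return A list of class `substitution_matrix` with `counts`, a 4x4
#'   integer matrix indexed (from base, to base) over A, C, G, T with a
#'   zero diagonal, and `n_events`.
#' @export
count_matrix <- function(events) {
  counts <- table(factor(events$from_base, levels = .dna_bases),
                  factor(events$to_base, levels = .dna_bases))
  counts <- matrix(as.integer(counts), 4L, 4L,
                   dimnames = list(from = .dna_bases, to = .dna_bases))
  structure(list(counts = counts, n_events = sum(counts)),
            class = "substitution_matrix")
}

#' Probability normalization of a substitution count matrix
#'
#' The default, `"conditional"`, divides each row by its total: cell (i, j)
#' is then the probability that a substitution away from ancestral base i
#' goes to base j -- a Markov matrix of conditional substitution
#' probabilities. The alternative, `"joint"`, divides every cell by the
#' total event count, giving the relative frequency of each of the twelve
#' base changes. Rows of the conditional matrix with no observed
#' substitutions are left all-zero and flagged in the `"empty_rows"`
#' attribute rather than filled with NaN.
#'
#' @param m A `substitution_matrix` from [count_matrix()].
#' @param normalization `"conditional"` (row-stochastic) or `"joint"`.
#' @return The matrix `m` with a `probabilities` element added (and
#'   `normalization` / `"empty_rows"` metadata).
#' @export
conditional_probabilities <- function(m, normalization = c("conditional", "joint")) {
  stopifnot(inherits(m, "substitution_matrix"))
  normalization <- match.arg(normalization)
  counts <- m$counts
  if (normalization == "conditional") {
    rs <- rowSums(counts)
    probs <- counts / ifelse(rs > 0, rs, 1)
    empty <- rs == 0
  } else {
    tot <- sum(counts)
    probs <- if (tot > 0) counts / tot else counts * 0
    empty <- rep(sum(counts) == 0, 4L)
    names(empty) <- rownames(counts)
  }
  m$probabilities <- probs
  m$normalization <- normalization
  attr(m$probabilities, "empty_rows") <- empty
  m
}

#' @export
print.substitution_matrix <- function(x, ...) {
  cat(sprintf("substitution_matrix: %d events\n", x$n_events))
  print(x$counts)
  if (!is.null(x$probabilities)) {
    cat(sprintf("%s probabilities:\n", x$normalization))
    print(round(x$probabilities, 4))
  }
  invisible(x)
}
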