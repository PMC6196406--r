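# Standard genetic code (NCBI translation table 1) as a single named
# character vector, the swappable data structure behind all synonymy tests.
# Codons are enumerated with the first base cycling slowest in the
# conventional T, C, A, G order.
.genetic_code <- local({
  b <- c("T", "C", "A", "G")
  codons <- paste0(rep(b, each = 16L), rep(rep(b, each = 4L), 4L), rep(b, 16L))
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"
  ), "")[[1]]
  stats::setNames(aa, codons)
})

#' The standard genetic code
#'
#' @return Named character vector of length 64 mapping codons (uppercase DNA)
#'   to one-letter amino-acid codes, with `"*"` for the three stop codons.
#' @export
genetic_code <- function() .genetic_code

#' Translate codons under the standard genetic code
#'
#' @param codon Character vector of codons, each exactly three uppercase DNA
#'   bases (`A`, `C`, `G`, `T`).
#' @return Character vector of one-letter amino acids; stop codons translate
#'   to `"*"`.
#' @examples
#' translate_codon("ATG")
#' translate_codon(c("CTT", "TAA"))
#' @export
translate_codon <- function(codon) {
  if (length(codon) == 0L) return(character())
  bad <- is.na(codon) | nchar(codon) != 3L | grepl("[^ACGT]", codon)
  if (any(bad)) {
    pml_stop("pamlsubs_invalid_codon",
             "invalid codon(s): %s (need three characters from A,C,G,T)",
             paste(unique(codon[bad]), collapse = ", "))
  }
  unname(.genetic_code[codon])
}

#' Test whether a codon change is synonymous
#'
#' Two codons are synonymous when they translate to the same amino acid.
#' Stop codons cannot occur inside a valid protein-coding alignment, so a
#' stop on either side signals corrupt input and raises an error rather
#' than returning a value.
#'
#' @param from,to Character vectors of codons (recycled to common length);
#'   each pair must differ at one or more positions.
#' @return Logical vector.
#' @export
is_synonymous <- function(from, to) {
  n <- max(length(from), length(to))
  from <- rep_len(from, n)
  to <- rep_len(to, n)
  aa_from <- translate_codon(from)
  aa_to <- translate_codon(to)
  if (any(from == to)) {
    pml_stop("pamlsubs_invalid_codon", "codons must differ at >= 1 position")
  }
  stop_hit <- aa_from == "*" | aa_to == "*"
  if (any(stop_hit)) {
    pml_stop("pamlsubs_stop_codon",
             "stop codon in substitution (%s -> %s): corrupt coding alignment",
             from[which(stop_hit)[1L]], to[which(stop_hit)[1L]])
  }
  aa_from == aa_to
}
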