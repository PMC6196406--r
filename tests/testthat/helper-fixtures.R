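# Shared fixture builders: everything is generated in code at test time.

# small simulated history + rst text in one go
sim_fixture <- function(tips = 6, length_codons = 50, kappa = 4,
                        events_per_branch = 5, seed = 1, dialect = "codeml") {
  log <- simulate_substitutions(tips = tips, length_codons = length_codons,
                                kappa = kappa,
                                events_per_branch = events_per_branch,
                                seed = seed)
  list(log = log, rst = write_rst(log, dialect))
}

# events sorted the way classify_substitutions() sorts, for exact comparison
sort_events <- function(ev) {
  ev <- ev[order(ev$parent, ev$child, ev$site), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

# a hand-built classified event table (bypassing parsing) for unit tests
manual_events <- function(site, category, length = 30L,
                          parent = 11L, child = 1L) {
  class <- ifelse(category %in% c("As", "Aa"), "Ts", "Tv")
  effect <- ifelse(category %in% c("As", "Bs"), "synonymous", "nonsynonymous")
  from_base <- ifelse(class == "Ts", "A", "A")
  to_base <- ifelse(class == "Ts", "G", "C")
  n <- length(site)
  ev <- data.frame(
    parent = rep(parent, n), child = rep(child, n), site = as.integer(site),
    codon_index = codon_index(site), codon_position = codon_position(site),
    from_base = from_base, to_base = to_base,
    from_codon = rep("AAA", n), to_codon = rep("AAA", n),
    from_aa = rep("K", n), to_aa = rep("K", n),
    class = class, effect = effect, category = category,
    posterior = rep(0.99, n), stringsAsFactors = FALSE
  )
  attr(ev, "alignment_length") <- as.integer(length)
  class(ev) <- c("substitution_events", "data.frame")
  ev
}
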