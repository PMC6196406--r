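# Structured error conditions. Every user-facing failure mode carries a
# dedicated condition class so callers (and the command-line wrapper) can
# map errors to distinct diagnostics without string matching.

pml_stop <- function(class, msg, ..., call = sys.call(-1)) {
  stop(structure(
    class = c(class, "pamlsubs_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = call)
  ))
}

pml_warn <- function(class, msg, ...) {
  warning(structure(
    class = c(class, "pamlsubs_warning", "warning", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}
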