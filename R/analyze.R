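# End-to-end pipeline: rst in, plots + tables + annotated trees out.

#' Run the full substitution-pattern analysis on an rst file
#'
#' Parses the rst file, classifies every inferred substitution, computes
#' the per-site profile, sliding-window and cumulative series and the
#' substitution matrix, annotates the tree, and writes eleven PDF plots,
#' two CSV reports, two annotated Newick trees and a machine-readable JSON
#' run manifest into `out_dir`.
#'
#' @param input Path to a PAML rst file (baseml or codeml flavor), or its
#'   text contents.
#' @param out_dir Output directory, created if needed.
#' @param window Sliding-window width in nucleotides (>= 3).
#' @param step Window shift and cumulative-curve step in nucleotides (>= 1).
#' @param posterior_threshold Drop inferred changes below this posterior
#'   (default 0: keep all).
#' @param format Table format (only `"csv"`).
#' @return A list (invisibly) with the parsed document, events, profile,
#'   window and cumulative series, matrix, annotations and the file
#'   manifest.
#' @export
analyze_rst <- function(input, out_dir, window = 90L, step = 9L,
                        posterior_threshold = 0, format = "csv") {
  window <- suppressWarnings(as.integer(window))
  step <- suppressWarnings(as.integer(step))
  if (is.na(window) || window < 3L) {
    pml_stop("pamlsubs_config_error", "window must be an integer >= 3")
  }
  if (is.na(step) || step < 1L) {
    pml_stop("pamlsubs_config_error", "step must be an integer >= 1")
  }
  doc <- if (length(input) == 1L && file.exists(input)) {
    read_rst(input)
  } else {
    parse_rst(input)
  }
  events <- classify_substitutions(doc, posterior_threshold = posterior_threshold)
  profile <- site_counts(events, doc$alignment_length)
  windows <- sliding_windows(profile, window = min(window, doc$alignment_length),
                             step = step)
  cumulative <- cumulative_series(profile, step = step)
  mat <- count_matrix(events)
  annotations <- annotate_branches(events, doc$tree)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  plot_manifest <- render_plots(profile, windows, cumulative, mat,
                                annotations, out_dir)
  table_paths <- export_tables(profile, windows, cumulative, mat,
                               annotations, events, out_dir, format = format)
  tree_paths <- export_trees(annotations, doc$tree, out_dir)

  manifest <- list(
    program = doc$program,
    alignment_length = doc$alignment_length,
    n_taxa = nrow(doc$taxa),
    n_branches = nrow(doc$branches),
    n_events = nrow(events),
    category_totals = as.list(colSums(site_counts(events, doc$alignment_length)$counts)),
    window = window, step = step,
    posterior_threshold = posterior_threshold,
    plots = stats::setNames(as.list(basename(plot_manifest$file)),
                            plot_manifest$plot_id),
    tables = basename(table_paths),
    trees = basename(as.character(tree_paths))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(
    document = doc, events = events, profile = profile, windows = windows,
    cumulative = cumulative, matrix = mat, annotations = annotations,
    plot_manifest = plot_manifest, table_paths = table_paths,
    tree_paths = as.character(tree_paths),
    manifest_path = file.path(out_dir, "run_manifest.json")
  ))
}
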