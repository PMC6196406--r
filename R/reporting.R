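# Rendering of the eleven summary plots and export of the two tabular
# reports. Every number in the tables is a view over the classified event
# list: re-exporting from the events alone reproduces the reports
# bit-identically.

.plot_manifest <- data.frame(
  plot_id = sprintf("%02d", 1:11),
  file = c("01_ts_per_site_by_position.pdf",
           "02_tv_per_site_by_position.pdf",
           "03_change_types_by_position.pdf",
           "04_synonymous_per_site.pdf",
           "05_nonsynonymous_per_site.pdf",
           "06_window_category_means.pdf",
           "07_window_dn_ds.pdf",
           "08_window_dnds_ratio.pdf",
           "09_cumulative_synonymous.pdf",
           "10_cumulative_nonsynonymous.pdf",
           "11_cumulative_total.pdf"),
  description = c(
    "Transitions per site, one panel per codon position",
    "Transversions per site, one panel per codon position",
    "Counts of the twelve base-change types at each codon position",
    "Synonymous transitions (As) and transversions (Bs) per site",
    "Nonsynonymous transitions (Aa) and transversions (Ba) per site",
    "Sliding-window means of As, Bs, Aa, Ba",
    "Sliding-window dS (As+Bs) and dN (Aa+Ba)",
    "Sliding-window dN/dS ratio (gaps where dS = 0)",
    "Cumulative As and Bs along the sequence",
    "Cumulative Aa and Ba along the sequence",
    "Cumulative total substitutions Kt along the sequence"),
  stringsAsFactors = FALSE
)

.per_site_panels <- function(values, positions, main, col) {
  graphics::par(mfrow = c(3, 1), mar = c(4, 4, 2, 1))
  for (p in 1:3) {
    v <- values
    v[positions != p] <- 0
    graphics::plot(seq_along(v), v, type = "h", col = col,
                   xlab = "nucleotide position", ylab = "substitutions",
                   main = sprintf("%s, codon position %d", main, p))
  }
}

#' Render the eleven summary plots
#'
#' @param profile A `site_profile`.
#' @param windows A `window_series`.
#' @param cumulative A `cumulative_series`.
#' @param matrix A `substitution_matrix` (counts; used for the manifest
#'   only, the matrix itself is tabular).
#' @param annotations A `branch_annotations` list (unused by the current
#'   plot set but part of the report bundle signature).
#' @param out_dir Output directory, created if needed.
#' @return Data frame manifest (`plot_id`, `file`, `description`) with
#'   absolute paths, invisibly.
#' @export
render_plots <- function(profile, windows, cumulative, matrix = NULL,
                         annotations = NULL, out_dir) {
  if (!inherits(profile, "site_profile")) {
    pml_stop("pamlsubs_config_error", "a site_profile is required")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  man <- .plot_manifest
  man$file <- file.path(out_dir, man$file)
  pos <- codon_position(seq_len(profile$length))
  x <- seq_len(profile$length)

  pdf_plot <- function(path, fun) {
    grDevices::pdf(path, width = 8, height = 6)
    on.exit(grDevices::dev.off(), add = TRUE)
    fun()
  }

  pdf_plot(man$file[1], function() {
    .per_site_panels(profile$ts, pos, "Transitions (Ts)", "steelblue")
  })
  pdf_plot(man$file[2], function() {
    .per_site_panels(profile$tv, pos, "Transversions (Tv)", "firebrick")
  })
  pdf_plot(man$file[3], function() {
    graphics::par(mar = c(6, 4, 2, 1))
    graphics::barplot(t(profile$type_position), beside = TRUE,
                      legend.text = colnames(profile$type_position),
                      las = 2, col = c("grey30", "grey60", "grey85"),
                      main = "Substitution types by codon position",
                      ylab = "count")
  })
  pdf_plot(man$file[4], function() {
    graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
    graphics::plot(x, profile$counts[, "As"], type = "h", col = "steelblue",
                   xlab = "nucleotide position", ylab = "count",
                   main = "Synonymous transitions (As)")
    graphics::plot(x, profile$counts[, "Bs"], type = "h", col = "firebrick",
                   xlab = "nucleotide position", ylab = "count",
                   main = "Synonymous transversions (Bs)")
  })
  pdf_plot(man$file[5], function() {
    graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
    graphics::plot(x, profile$counts[, "Aa"], type = "h", col = "steelblue",
                   xlab = "nucleotide position", ylab = "count",
                   main = "Nonsynonymous transitions (Aa)")
    graphics::plot(x, profile$counts[, "Ba"], type = "h", col = "firebrick",
                   xlab = "nucleotide position", ylab = "count",
                   main = "Nonsynonymous transversions (Ba)")
  })
  pdf_plot(man$file[6], function() {
    cols <- c(As = "steelblue", Bs = "skyblue", Aa = "firebrick", Ba = "salmon")
    graphics::matplot(windows$start, as.matrix(windows[, c("As", "Bs", "Aa", "Ba")]),
                      type = "l", lty = 1, col = cols,
                      xlab = "window start (nt)", ylab = "mean count / site",
                      main = "Windowed substitution categories")
    graphics::legend("topright", legend = names(cols), col = cols, lty = 1)
  })
  pdf_plot(man$file[7], function() {
    graphics::matplot(windows$start, as.matrix(windows[, c("dS", "dN")]),
                      type = "l", lty = 1, col = c("steelblue", "firebrick"),
                      xlab = "window start (nt)", ylab = "mean count / site",
                      main = "Windowed dS (As+Bs) and dN (Aa+Ba)")
    graphics::legend("topright", legend = c("dS", "dN"),
                     col = c("steelblue", "firebrick"), lty = 1)
  })
  pdf_plot(man$file[8], function() {
    y <- windows$dNdS
    ylim <- if (all(is.na(y))) c(0, 1) else range(y, na.rm = TRUE)
    graphics::plot(windows$start, y, type = "l", col = "darkgreen",
                   ylim = ylim, xlab = "window start (nt)", ylab = "dN/dS",
                   main = "Windowed dN/dS (gaps where dS = 0)")
    graphics::abline(h = 1, lty = 2, col = "grey50")
  })
  pdf_plot(man$file[9], function() {
    graphics::matplot(cumulative$position,
                      as.matrix(cumulative[, c("As", "Bs")]),
                      type = "s", lty = 1, col = c("steelblue", "skyblue"),
                      xlab = "nucleotide position", ylab = "cumulative count",
                      main = "Cumulative synonymous substitutions")
    graphics::legend("topleft", legend = c("As", "Bs"),
                     col = c("steelblue", "skyblue"), lty = 1)
  })
  pdf_plot(man$file[10], function() {
    graphics::matplot(cumulative$position,
                      as.matrix(cumulative[, c("Aa", "Ba")]),
                      type = "s", lty = 1, col = c("firebrick", "salmon"),
                      xlab = "nucleotide position", ylab = "cumulative count",
                      main = "Cumulative nonsynonymous substitutions")
    graphics::legend("topleft", legend = c("Aa", "Ba"),
                     col = c("firebrick", "salmon"), lty = 1)
  })
  pdf_plot(man$file[11], function() {
    graphics::plot(cumulative$position, cumulative$Kt, type = "s",
                   col = "black", xlab = "nucleotide position",
                   ylab = "cumulative count",
                   main = "Cumulative total substitutions (Kt)")
  })
  invisible(man)
}

.long_block <- function(sheet, position, series, value) {
  if (length(value) == 0L) {
    return(data.frame(sheet = character(), position = integer(),
                      series = character(), value = double(),
                      stringsAsFactors = FALSE))
  }
  data.frame(sheet = sheet, position = position, series = series,
             value = as.numeric(value), stringsAsFactors = FALSE)
}

#' Export the two tabular reports
#'
#' Report 1 (`report_plot_data.csv`) stacks, in long format
#' (`sheet`, `position`, `series`, `value`), every series shown in the
#' plots: per-site category and Ts/Tv counts, the change-type-by-position
#' table, windowed means (including dS, dN, dN/dS), cumulative series, and
#' the substitution matrix under both its count and probability
#' normalizations (conditional row-stochastic and joint relative
#' frequency). Report 2 (`report_tree_data.csv`) holds the per-branch
#' annotation summary and the full classified event list, distinguished by
#' a `sheet` column. Undefined dN/dS windows are exported as empty cells,
#' never as infinities.
#'
#' @param profile A `site_profile`.
#' @param windows A `window_series`.
#' @param cumulative A `cumulative_series`.
#' @param matrix A `substitution_matrix` (counts filled).
#' @param annotations A `branch_annotations` list.
#' @param events The classified `substitution_events` data frame.
#' @param out_dir Output directory.
#' @param format Only `"csv"` is supported.
#' @return Character vector of the two file paths, invisibly.
#' @export
export_tables <- function(profile, windows, cumulative, matrix, annotations,
                          events, out_dir, format = "csv") {
  if (!identical(format, "csv")) {
    pml_stop("pamlsubs_config_error",
             "unsupported table format '%s' (only \"csv\" is available)", format)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  x <- seq_len(profile$length)
  blocks <- list()
  for (cat in c(.categories)) {
    blocks[[length(blocks) + 1L]] <-
      .long_block("per_site", x, cat, profile$counts[, cat])
  }
  blocks[[length(blocks) + 1L]] <- .long_block("per_site", x, "Ts", profile$ts)
  blocks[[length(blocks) + 1L]] <- .long_block("per_site", x, "Tv", profile$tv)
  tp <- profile$type_position
  blocks[[length(blocks) + 1L]] <- .long_block(
    "type_by_position",
    rep(1:3, each = nrow(tp)),
    rep(rownames(tp), times = 3L),
    as.vector(tp))
  for (col in c("As", "Bs", "Aa", "Ba", "dS", "dN", "dNdS")) {
    blocks[[length(blocks) + 1L]] <-
      .long_block("windowed", windows$start, col, windows[[col]])
  }
  for (col in c("As", "Bs", "Aa", "Ba", "Kt")) {
    blocks[[length(blocks) + 1L]] <-
      .long_block("cumulative", cumulative$position, col, cumulative[[col]])
  }
  cond <- conditional_probabilities(matrix, "conditional")$probabilities
  joint <- conditional_probabilities(matrix, "joint")$probabilities
  cells <- as.vector(t(outer(.dna_bases, .dna_bases,
                             function(f, t) paste0(f, "->", t))))
  mat_long <- function(sheet, m) {
    .long_block(sheet, rep(NA_integer_, 16L), cells, as.vector(t(m)))
  }
  blocks[[length(blocks) + 1L]] <- mat_long("matrix_counts", matrix$counts)
  blocks[[length(blocks) + 1L]] <- mat_long("matrix_conditional", cond)
  blocks[[length(blocks) + 1L]] <- mat_long("matrix_joint", joint)
  report1 <- do.call(rbind, blocks)

  branch_rows <- if (length(annotations)) {
    do.call(rbind, lapply(annotations, function(a) {
      data.frame(
        sheet = "branches", parent = a$parent, child = a$child,
        seq_index = a$seq_index, annotation = format_annotation(a),
        n_events = sum(a$counts),
        aa_changes = paste(a$aa_changes, collapse = ","),
        nt_changes = paste(a$nt_changes, collapse = ","),
        stringsAsFactors = FALSE)
    }))
  } else {
    NULL
  }
  event_rows <- if (nrow(events)) {
    cbind(data.frame(sheet = "events", stringsAsFactors = FALSE),
          as.data.frame(events))
  } else {
    NULL
  }
  report2 <- .rbind_fill(branch_rows, event_rows)

  paths <- file.path(out_dir, c("report_plot_data.csv", "report_tree_data.csv"))
  utils::write.csv(report1, paths[1L], row.names = FALSE, na = "")
  utils::write.csv(report2, paths[2L], row.names = FALSE, na = "")
  invisible(paths)
}

# rbind two data frames over the union of their columns
.rbind_fill <- function(a, b) {
  if (is.null(a) && is.null(b)) {
    return(data.frame(sheet = character(), stringsAsFactors = FALSE))
  }
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  cols <- union(names(a), names(b))
  for (cl in setdiff(cols, names(a))) a[[cl]] <- NA
  for (cl in setdiff(cols, names(b))) b[[cl]] <- NA
  rbind(a[cols], b[cols])
}
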