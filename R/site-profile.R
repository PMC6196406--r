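# Per-site substitution profiles, sliding-window series and cumulative
# curves.
#
# Note on dN/dS as computed here: dS and dN are RAW substitution counts
# (dS = As + Bs, dN = Aa + Ba), averaged over windows. They are NOT
# per-site-normalized rates in the NG86/GY94 sense -- no correction for the
# number of synonymous vs nonsynonymous sites is applied. The ratio is a
# descriptive scan statistic for spotting regions of elevated amino-acid
# change, not a formal selection estimator.

.categories <- c("As", "Bs", "Aa", "Ba")

#' Per-site substitution counts
#'
#' Tallies classified substitution events at every alignment site, split by
#' the four-way category (As/Bs/Aa/Ba) and, derived from those, by
#' transition/transversion at each codon position.
#'
#' @param events A `substitution_events` data frame
#'   (see [classify_substitutions()]).
#' @param length Alignment length in nucleotides; defaults to the length
#'   recorded on `events`.
#' @return A list of class `site_profile`: `length`; `counts`, a
#'   `length x 4` integer matrix with columns As, Bs, Aa, Ba; `ts`/`tv`
#'   per-site totals; and `type_position`, a 12 x 3 matrix of counts of
#'   each ordered base change at each codon position.
#' @export
site_counts <- function(events, length = attr(events, "alignment_length")) {
  if (is.null(length)) {
    pml_stop("pamlsubs_config_error", "alignment length is required")
  }
  length <- as.integer(length)
  if (nrow(events) > 0L && any(events$site < 1L | events$site > length)) {
    pml_stop("pamlsubs_site_range",
             "event site outside alignment of length %d", length)
  }
  counts <- matrix(0L, nrow = length, ncol = 4L,
                   dimnames = list(NULL, .categories))
  types <- as.vector(t(outer(.dna_bases, .dna_bases,
                             function(f, t) paste0(f, "->", t))))
  types <- types[substr(types, 1, 1) != substr(types, 4, 4)]
  type_position <- matrix(0L, nrow = 12L, ncol = 3L,
                          dimnames = list(types, paste0("pos", 1:3)))
  if (nrow(events) > 0L) {
    for (cat in .categories) {
      s <- events$site[events$category == cat]
      if (length(s)) counts[, cat] <- tabulate(s, nbins = length)
    }
    tp <- table(factor(paste0(events$from_base, "->", events$to_base),
                       levels = types),
                factor(events$codon_position, levels = 1:3))
    type_position[] <- as.integer(tp)
  }
  structure(list(
    length = length,
    counts = counts,
    ts = counts[, "As"] + counts[, "Aa"],
    tv = counts[, "Bs"] + counts[, "Ba"],
    type_position = type_position
  ), class = "site_profile")
}

#' @export
print.site_profile <- function(x, ...) {
  cat(sprintf("site_profile: %d nt, %d substitutions (As %d, Bs %d, Aa %d, Ba %d)\n",
              x$length, sum(x$counts),
              sum(x$counts[, "As"]), sum(x$counts[, "Bs"]),
              sum(x$counts[, "Aa"]), sum(x$counts[, "Ba"])))
  invisible(x)
}

#' Sliding-window averages of substitution counts
#'
#' Windows start at 1, 1+step, ... for as long as a full window fits;
#' trailing partial windows are dropped so that per-window means stay
#' comparable. Each value is the arithmetic mean over the window of the
#' per-site counts; `dS = As + Bs` and `dN = Aa + Ba` window means are
#' summed from the category means, and `dNdS` is their ratio, `NA` wherever
#' `dS` is zero.
#'
#' @param profile A `site_profile`.
#' @param window Window width in nucleotides (default 90 nt = 30 codons).
#' @param step Shift between consecutive window starts (default 9 nt).
#' @return A data frame of class `window_series` with columns `start`,
#'   `end`, `As`, `Bs`, `Aa`, `Ba`, `dS`, `dN`, `dNdS`.
#' @export
sliding_windows <- function(profile, window = 90L, step = 9L) {
  stopifnot(inherits(profile, "site_profile"))
  window <- as.integer(window)
  step <- as.integer(step)
  if (is.na(window) || window < 3L || window > profile$length) {
    pml_stop("pamlsubs_window_error",
             "window must satisfy 3 <= window <= alignment length (%d)",
             profile$length)
  }
  if (is.na(step) || step < 1L) {
    pml_stop("pamlsubs_window_error", "step must be >= 1")
  }
  starts <- seq.int(1L, profile$length - window + 1L, by = step)
  cs <- rbind(0, apply(profile$counts, 2L, cumsum))
  means <- (cs[starts + window, , drop = FALSE] - cs[starts, , drop = FALSE]) / window
  out <- data.frame(start = starts, end = starts + window - 1L)
  out <- cbind(out, as.data.frame(means))
  out$dS <- out$As + out$Bs
  out$dN <- out$Aa + out$Ba
  out$dNdS <- ifelse(out$dS > 0, out$dN / out$dS, NA_real_)
  attr(out, "window") <- window
  attr(out, "step") <- step
  class(out) <- c("window_series", "data.frame")
  out
}

#' Per-window dN/dS ratio
#'
#' The ratio of window-mean nonsynonymous to synonymous substitution
#' counts; undefined (`NA`) wherever the window holds no synonymous
#' substitutions -- rendered as a gap in plots and left empty in tables,
#' never coerced to infinity.
#'
#' @param series A `window_series` from [sliding_windows()].
#' @return Numeric vector, one ratio (or `NA`) per window.
#' @export
dn_ds <- function(series) {
  stopifnot(inherits(series, "window_series"))
  ifelse(series$dS > 0, series$dN / series$dS, NA_real_)
}

#' Cumulative substitution counts along the sequence
#'
#' Running totals of As, Bs, Aa, Ba and the grand total Kt, evaluated at
#' positions `step, 2*step, ...`; the final alignment position is always
#' included so the last Kt equals the total event count.
#'
#' @param profile A `site_profile`.
#' @param step Evaluation step in nucleotides.
#' @return A data frame of class `cumulative_series` with columns
#'   `position`, `As`, `Bs`, `Aa`, `Ba`, `Kt`.
#' @export
cumulative_series <- function(profile, step = 9L) {
  stopifnot(inherits(profile, "site_profile"))
  step <- as.integer(step)
  if (is.na(step) || step < 1L) {
    pml_stop("pamlsubs_window_error", "step must be >= 1")
  }
  at <- seq.int(step, profile$length, by = step)
  if (length(at) == 0L || at[length(at)] != profile$length) {
    at <- c(at, profile$length)
  }
  cs <- apply(profile$counts, 2L, cumsum)
  out <- data.frame(position = at)
  out <- cbind(out, as.data.frame(cs[at, , drop = FALSE]))
  out$Kt <- out$As + out$Bs + out$Aa + out$Ba
  rownames(out) <- NULL
  attr(out, "step") <- step
  class(out) <- c("cumulative_series", "data.frame")
  out
}
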