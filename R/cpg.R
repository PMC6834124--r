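# Sliding-window CpG statistics and island calling.
#
# For a window of length N: GC% = 100 * (#C + #G) / N and
# Obs/Exp CpG = #CpG * N / (#C * #G), with #CpG the overlapping count of
# "CG" dimers. Windows with #C = 0 or #G = 0 take Obs/Exp = 0 by convention
# (they can never qualify as island windows). A window containing any N
# base is emitted with skipped = TRUE and excluded from island calling and
# summaries.

#' Per-window GC% and observed/expected CpG statistics
#'
#' Slides a window of \code{window} bp across the sequence at \code{step}-bp
#' intervals (defaults 200 and 1).
#'
#' @param seq A \code{\link{dna_seq}} (or DNA character scalar).
#' @param window Window length in bp (>= 2).
#' @param step Step between window starts in bp (>= 1).
#' @return A data.frame with one row per window: \code{start} (0-based),
#'   \code{end} (half-open), \code{gc_percent}, \code{obs_exp},
#'   \code{skipped}.
#' @export
window_stats <- function(seq, window = 200L, step = 1L) {
  if (!inherits(seq, "dna_seq")) seq <- dna_seq("seq", seq)
  window <- as.integer(window); step <- as.integer(step)
  stopifnot(window >= 2L, step >= 1L)
  n <- seq$length
  if (n < window)
    stop(sprintf("sequence '%s' (%d bp) shorter than window; minimum length is %d bp",
                 seq$id, n, window), call. = FALSE)
  d <- Biostrings::DNAString(seq$seq)
  freq <- Biostrings::letterFrequencyInSlidingView(d, window, c("C", "G", "N"))
  # overlapping CG dimer count per window, via cumulative dimer indicators
  ch <- strsplit(seq$seq, "")[[1]]
  dimer <- as.integer(ch[-n] == "C" & ch[-1] == "G")
  cum <- c(0L, cumsum(dimer))
  starts1 <- seq.int(1L, n - window + 1L, by = step)  # 1-based starts
  ncg <- cum[starts1 + window - 1L] - cum[starts1]
  nc <- freq[starts1, "C"]; ng <- freq[starts1, "G"]
  nn <- freq[starts1, "N"]
  obs_exp <- ifelse(nc > 0 & ng > 0, ncg * window / (nc * ng), 0)
  data.frame(start = starts1 - 1L, end = starts1 - 1L + window,
             gc_percent = 100 * (nc + ng) / window,
             obs_exp = obs_exp, skipped = nn > 0, row.names = NULL)
}

#' Call CpG islands from window statistics
#'
#' A window qualifies when its GC content is strictly greater than
#' \code{gc_min} percent AND its observed/expected CpG ratio is strictly
#' greater than \code{obs_exp_min}; overlapping or adjacent qualifying
#' window spans are merged into maximal island ranges (so every island is
#' at least one window long, over 200 bp at the default window).
#'
#' @param stats Output of \code{\link{window_stats}} for one sequence.
#' @param gc_min GC threshold in percent (default 50, strict).
#' @param obs_exp_min Obs/Exp threshold (default 0.6, strict).
#' @return A data.frame of islands: \code{start}, \code{end} (0-based
#'   half-open), \code{mean_gc}, \code{mean_obs_exp}, \code{n_windows}.
#' @export
call_islands <- function(stats, gc_min = 50, obs_exp_min = 0.6) {
  q <- !stats$skipped & stats$gc_percent > gc_min & stats$obs_exp > obs_exp_min
  empty <- data.frame(start = integer(0), end = integer(0),
                      mean_gc = numeric(0), mean_obs_exp = numeric(0),
                      n_windows = integer(0))
  if (!any(q)) return(empty)
  qs <- stats[q, , drop = FALSE]
  qs <- qs[order(qs$start), , drop = FALSE]
  # merge overlapping/adjacent window spans
  grp <- cumsum(c(1L, as.integer(qs$start[-1] > cummax(qs$end[-nrow(qs)]))))
  out <- do.call(rbind, lapply(split(qs, grp), function(g) {
    data.frame(start = min(g$start), end = max(g$end),
               mean_gc = mean(g$gc_percent), mean_obs_exp = mean(g$obs_exp),
               n_windows = nrow(g))
  }))
  rownames(out) <- NULL
  out
}

#' Per-gene CpG summary
#'
#' Minimum and maximum GC% and Obs/Exp over all non-skipped windows, plus
#' the island count: the per-promoter summary record.
#'
#' @param gene_id Gene identifier for the report row.
#' @param stats Output of \code{\link{window_stats}}.
#' @param islands Output of \code{\link{call_islands}}.
#' @return A one-row data.frame: gene_id, min_gc, max_gc, min_obs_exp,
#'   max_obs_exp, n_islands (statistics at full precision; round at the
#'   reporting layer).
#' @export
cpg_summary <- function(gene_id, stats, islands) {
  use <- stats[!stats$skipped, , drop = FALSE]
  if (!nrow(use)) stop("no usable (N-free) windows for ", gene_id, call. = FALSE)
  data.frame(gene_id = gene_id,
             min_gc = min(use$gc_percent), max_gc = max(use$gc_percent),
             min_obs_exp = min(use$obs_exp), max_obs_exp = max(use$obs_exp),
             n_islands = nrow(islands))
}

#' Write islands as BED
#'
#' @param islands Output of \code{\link{call_islands}}.
#' @param seq_id Chromosome/sequence name for column 1.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_islands_bed <- function(islands, seq_id, path) {
  if (nrow(islands)) {
    lines <- sprintf("%s\t%d\t%d\tCpG_island_%d\t%d\t.", seq_id,
                     islands$start, islands$end, seq_len(nrow(islands)),
                     round(islands$mean_obs_exp * 100))
  } else {
    lines <- character(0)
  }
  writeLines(lines, path)
  invisible(path)
}
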