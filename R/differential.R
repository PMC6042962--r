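# Differential occupancy between two conditions over a consensus peak set.
# This is a documented, fully specified stand-in for affinity-based
# differential binding tools: per-million scaling, pseudocount-1 log2 fold
# change, optional Fisher exact gate.

#' Build a consensus peak set from two conditions
#'
#' The union of both interval sets, merged so that overlapping or adjacent
#' intervals (gap `<= 0`) always coalesce; with `merge_gap > 0`, gaps
#' strictly below it also merge. Scores are not meaningful on a consensus
#' and are reported as `NA`.
#'
#' @param peaks_a,peaks_b [peak_set()]s.
#' @param merge_gap additional proximity merging (default 0: only
#'   overlapping/adjacent intervals merge).
#' @return A [peak_set()] with `NA` scores.
#' @export
build_consensus <- function(peaks_a, peaks_b, merge_gap = 0L) {
  validate_peak_set(peaks_a); validate_peak_set(peaks_b)
  both <- rbind(as.data.frame(peaks_a)[c("chrom", "start", "end")],
                as.data.frame(peaks_b)[c("chrom", "start", "end")])
  if (nrow(both) == 0) return(peak_set())
  both <- both[order(both$chrom, both$start), , drop = FALSE]
  ps <- structure(data.frame(both, name = paste0("peak_", seq_len(nrow(both))),
                             score = NA_real_, stringsAsFactors = FALSE),
                  class = c("peak_set", "data.frame"))
  out <- .sweep_merge(ps, function(gap) gap <= 0 || gap < merge_gap)
  out$score <- NA_real_
  out
}

#' Per-region summed signal, library-scaled
#'
#' Sums the per-base coverage over each region, then scales to the track's
#' library total (counts per million), so conditions sequenced to different
#' depths are comparable.
#'
#' @param regions a [peak_set()].
#' @param track a [coverage_track()].
#' @param per_million scale raw sums by `1e6 / total_signal` (default TRUE).
#' @return Numeric vector of per-region signals (one per row of `regions`).
#' @export
score_regions <- function(regions, track, per_million = TRUE) {
  validate_peak_set(regions)
  stopifnot(inherits(track, "coverage_track"))
  cl <- chrom_lengths(track)
  if (nrow(regions) == 0) return(numeric(0))
  if (any(!regions$chrom %in% names(cl)) ||
      any(regions$end > cl[regions$chrom])) {
    stop("region lies outside the coverage track")
  }
  raw <- vapply(seq_len(nrow(regions)), function(i) {
    sum(track$values[[regions$chrom[i]]][(regions$start[i] + 1L):regions$end[i]])
  }, numeric(1))
  if (!per_million) return(raw)
  if (track$total_signal <= 0) return(raw * 0)
  raw * 1e6 / track$total_signal
}

#' Call differential occupancy over consensus regions
#'
#' For each consensus region, computes per-million-scaled summed IP signal in
#' each condition and `log2fc = log2((b + 1) / (a + 1))`. Regions with
#' `log2fc >= lfc_threshold` are labelled `up` (higher in condition B),
#' `<= -lfc_threshold` `down`, otherwise `unchanged`. With `test = "fisher"`,
#' a 2x2 Fisher exact test on rounded raw counts (region count vs library
#' remainder, per condition) must additionally pass `alpha` for an up/down
#' label; this gate is approximate because scaled sums are rounded to counts.
#'
#' @param consensus a [peak_set()] of regions to test.
#' @param ip_a,ip_b IP [coverage_track()]s for conditions A and B.
#' @param lfc_threshold minimum `|log2fc|` for an up/down label.
#' @param test `"none"` or `"fisher"`.
#' @param alpha significance level for the Fisher gate.
#' @return Data frame with columns `chrom`, `start`, `end`, `signal_a`,
#'   `signal_b`, `log2fc`, `p_value`, `label`.
#' @export
differential_call <- function(consensus, ip_a, ip_b, lfc_threshold = 1,
                              test = c("none", "fisher"), alpha = 0.05) {
  test <- match.arg(test)
  validate_peak_set(consensus)
  if (nrow(consensus) == 0) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      signal_a = numeric(), signal_b = numeric(),
                      log2fc = numeric(), p_value = numeric(),
                      label = character(), stringsAsFactors = FALSE))
  }
  s_a <- score_regions(consensus, ip_a)
  s_b <- score_regions(consensus, ip_b)
  log2fc <- log2((s_b + 1) / (s_a + 1))
  p <- rep(NA_real_, nrow(consensus))
  if (test == "fisher") {
    raw_a <- score_regions(consensus, ip_a, per_million = FALSE)
    raw_b <- score_regions(consensus, ip_b, per_million = FALSE)
    tot_a <- ip_a$total_signal; tot_b <- ip_b$total_signal
    p <- vapply(seq_len(nrow(consensus)), function(i) {
      m <- matrix(round(c(raw_a[i], tot_a - raw_a[i],
                          raw_b[i], tot_b - raw_b[i])), nrow = 2)
      stats::fisher.test(m)$p.value
    }, numeric(1))
  }
  label <- ifelse(log2fc >= lfc_threshold, "up",
                  ifelse(log2fc <= -lfc_threshold, "down", "unchanged"))
  if (test == "fisher") label[label != "unchanged" & p >= alpha] <- "unchanged"
  data.frame(chrom = consensus$chrom, start = consensus$start,
             end = consensus$end, signal_a = s_a, signal_b = s_b,
             log2fc = log2fc, p_value = p, label = label,
             stringsAsFactors = FALSE)
}
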