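# Peak-to-gene assignment: closest transcription start site, after removing
# Pol III / tRNA / rRNA genes from the candidate set.

#' Filter out Pol III, tRNA and rRNA genes
#'
#' @param genes a [gene_table()].
#' @param exclude_polIII_tRNA_rRNA apply the filter (FALSE = identity).
#' @return The filtered [gene_table()]; warns if no genes remain.
#' @export
filter_genes <- function(genes, exclude_polIII_tRNA_rRNA = TRUE) {
  if (!exclude_polIII_tRNA_rRNA) return(genes)
  keep <- !(genes$polymerase == "PolIII" | genes$biotype %in% c("tRNA", "rRNA"))
  out <- genes[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0) warning("all genes removed by the Pol III/tRNA/rRNA filter")
  attr(out, "chrom_lengths") <- attr(genes, "chrom_lengths")
  class(out) <- class(genes)
  out
}

# Distance from an interval [start, end) to a TSS point: 0 if the TSS lies
# inside; otherwise the distance to the nearer boundary base (start or
# end - 1). Strand-agnostic, matching bedtools-closest semantics.
.tss_distance <- function(start, end, tss) {
  ifelse(tss >= start & tss < end, 0L,
         ifelse(tss < start, start - tss, tss - (end - 1L)))
}

#' Closest TSS to a single peak
#'
#' Finds the gene whose transcription start site minimises the interval
#' distance to the peak (0 when the TSS lies inside the peak). Ties are broken
#' deterministically by the lexicographically smallest `gene_id` and flagged.
#' A peak on a chromosome with no genes yields an unassigned record with
#' `distance = Inf`.
#'
#' @param peak one-row data frame (or list) with `chrom`, `start`, `end`.
#' @param genes a [gene_table()] of candidate genes.
#' @return One-row data frame: `chrom`, `start`, `end`, `gene_id`, `distance`,
#'   `tie`.
#' @export
closest_tss <- function(peak, genes) {
  cand <- genes[genes$chrom == peak$chrom, , drop = FALSE]
  if (nrow(cand) == 0) {
    return(data.frame(chrom = peak$chrom, start = peak$start, end = peak$end,
                      gene_id = NA_character_, distance = Inf, tie = FALSE,
                      stringsAsFactors = FALSE))
  }
  d <- .tss_distance(peak$start, peak$end, cand$tss)
  dmin <- min(d)
  winners <- sort(cand$gene_id[d == dmin])
  data.frame(chrom = peak$chrom, start = peak$start, end = peak$end,
             gene_id = winners[1], distance = as.numeric(dmin),
             tie = length(winners) > 1, stringsAsFactors = FALSE)
}

#' Assign every peak to its closest TSS
#'
#' Applies [filter_genes()] first (so a removed tRNA gene cannot absorb a
#' peak), then [closest_tss()] per peak. The distinct `gene_id`s of the
#' resulting assignments form the gene list handed to enrichment. The result
#' is invariant under the input order of `genes`.
#'
#' @param peaks a [peak_set()] (or data frame with `chrom`, `start`, `end`).
#' @param genes a [gene_table()].
#' @param exclude_non_polII remove Pol III / tRNA / rRNA genes before the
#'   search.
#' @return Data frame with one row per peak: `chrom`, `start`, `end`,
#'   `gene_id`, `distance`, `tie`.
#' @export
assign_peaks <- function(peaks, genes, exclude_non_polII = TRUE) {
  genes <- filter_genes(genes, exclude_non_polII)
  if (nrow(peaks) == 0) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      gene_id = character(), distance = numeric(),
                      tie = logical(), stringsAsFactors = FALSE))
  }
  out <- lapply(seq_len(nrow(peaks)), function(i) {
    closest_tss(peaks[i, , drop = FALSE], genes)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Distinct genes of an assignment table
#'
#' @param assignments output of [assign_peaks()].
#' @return Sorted character vector of assigned gene ids (unassigned records
#'   dropped).
#' @export
assigned_genes <- function(assignments) {
  sort(unique(assignments$gene_id[!is.na(assignments$gene_id)]))
}
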