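#' Per-base coverage track
#'
#' A coverage track holds one dense, non-negative numeric vector per
#' chromosome: element `i` of `values[[chrom]]` is the signal at the 0-based
#' position `i - 1`. Dense vectors keep the ratio, smoothing and profile code
#' simple; synthetic genomes are at most a few megabases so the memory cost is
#' negligible.
#'
#' @param values named list of per-chromosome numeric vectors (all finite,
#'   `>= 0`). Chromosomes are stored sorted by name.
#' @param sample_id label carried through to outputs.
#' @return An object of class `coverage_track` with fields `sample_id`,
#'   `values` and `total_signal` (the sum over all positions).
#' @examples
#' trk <- coverage_track(list(chrI = rep(2, 100)), "demo")
#' trk$total_signal
#' @export
coverage_track <- function(values, sample_id = "sample") {
  if (!is.list(values) || is.null(names(values)) || any(names(values) == "")) {
    stop("`values` must be a named list of per-chromosome numeric vectors")
  }
  values <- lapply(values, as.numeric)
  bad <- vapply(values, function(v) any(!is.finite(v)) || any(v < 0), logical(1))
  if (any(bad)) {
    stop("coverage values must be finite and non-negative (offending chromosome: ",
         names(values)[which(bad)[1]], ")")
  }
  values <- values[order(names(values))]
  structure(
    list(sample_id = as.character(sample_id),
         values = values,
         total_signal = sum(vapply(values, sum, numeric(1)))),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("<coverage_track> sample:", x$sample_id, "\n")
  cat("  chromosomes:", length(x$values),
      "| total length:", sum(chrom_lengths(x)),
      "| total signal:", format(x$total_signal), "\n")
  invisible(x)
}

#' Chromosome lengths of a coverage track
#'
#' @param track a [coverage_track()].
#' @return Named integer vector of per-chromosome lengths in bases.
#' @export
chrom_lengths <- function(track) {
  stopifnot(inherits(track, "coverage_track"))
  vapply(track$values, length, integer(1))
}

#' Peak set container
#'
#' An ordered, non-overlapping set of genomic intervals with scores. Intervals
#' use the 0-based half-open convention. The constructor sorts by
#' `(chrom, start)` and enforces disjointness within each chromosome.
#'
#' @param chrom,start,end,score parallel vectors (score may be `NA` for peaks
#'   whose score is undefined, e.g. consensus regions).
#' @param params optional list of calling parameters recorded as provenance.
#' @return A `data.frame` of class `peak_set` with columns `chrom`, `start`,
#'   `end`, `name`, `score` and attribute `source_params`.
#' @export
peak_set <- function(chrom = character(), start = integer(), end = integer(),
                     score = numeric(), params = NULL) {
  n <- length(chrom)
  if (length(score) == 0 && n > 0) score <- rep(NA_real_, n)
  stopifnot(length(start) == n, length(end) == n, length(score) == n)
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start),
                   end = as.integer(end),
                   name = if (n) paste0("peak_", seq_len(n)) else character(),
                   score = as.numeric(score),
                   stringsAsFactors = FALSE)
  if (n > 0) {
    df <- df[order(df$chrom, df$start), , drop = FALSE]
    df$name <- paste0("peak_", seq_len(n))
    rownames(df) <- NULL
  }
  out <- structure(df, class = c("peak_set", "data.frame"))
  attr(out, "source_params") <- params
  validate_peak_set(out)
  out
}

#' Validate peak-set invariants
#'
#' Checks that every interval is non-empty (`start < end`), that rows are
#' sorted by `(chrom, start)`, and that same-chromosome intervals are pairwise
#' disjoint. Used by every constructor and by the test suite.
#'
#' @param peaks object to validate.
#' @return `peaks`, invisibly; errors on violation.
#' @export
validate_peak_set <- function(peaks) {
  stopifnot(is.data.frame(peaks),
            all(c("chrom", "start", "end", "score") %in% names(peaks)))
  if (nrow(peaks) == 0) return(invisible(peaks))
  if (any(peaks$start < 0)) stop("peak start positions must be >= 0")
  if (any(peaks$start >= peaks$end)) stop("peaks must satisfy start < end")
  ord <- order(peaks$chrom, peaks$start)
  if (!identical(ord, seq_len(nrow(peaks)))) {
    stop("peak set is not sorted by (chrom, start)")
  }
  same <- peaks$chrom[-1] == peaks$chrom[-nrow(peaks)]
  if (any(same & peaks$start[-1] < peaks$end[-nrow(peaks)])) {
    stop("peak set contains overlapping intervals on one chromosome")
  }
  invisible(peaks)
}

#' @export
print.peak_set <- function(x, ...) {
  cat("<peak_set>", nrow(x), "peaks on",
      length(unique(x$chrom)), "chromosome(s)\n")
  if (nrow(x)) print.data.frame(utils::head(x, 10))
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more\n")
  invisible(x)
}

#' Gene table constructor
#'
#' Genes are represented as a data frame (one row per gene) rather than a list
#' of objects; this is the natural R idiom and vectorises the positional
#' computations. TSS and TES follow the strand: on `+` the TSS is `start`, on
#' `-` it is `end - 1` (the interval's last base).
#'
#' @param gene_id,chrom,start,end,strand,biotype,polymerase parallel vectors;
#'   `start`/`end` 0-based half-open; `strand` in `+`/`-`; `biotype` one of
#'   `protein_coding`, `tRNA`, `rRNA`, `other`; `polymerase` one of `PolII`,
#'   `PolIII`, `other`.
#' @param chrom_lengths optional named vector recorded as an attribute.
#' @return A `data.frame` of class `gene_table` with derived `tss` and `tes`
#'   columns.
#' @export
gene_table <- function(gene_id, chrom, start, end, strand,
                       biotype = "protein_coding", polymerase = "PolII",
                       chrom_lengths = NULL) {
  n <- length(gene_id)
  start <- as.integer(start); end <- as.integer(end)
  strand <- as.character(strand)
  if (any(!strand %in% c("+", "-"))) stop("gene strand must be '+' or '-'")
  if (any(start < 0) || any(start >= end)) {
    stop("gene intervals must satisfy 0 <= start < end")
  }
  biotype <- rep_len(as.character(biotype), n)
  polymerase <- rep_len(as.character(polymerase), n)
  bad_bt <- !biotype %in% c("protein_coding", "tRNA", "rRNA", "other")
  biotype[bad_bt] <- "other"
  bad_pol <- !polymerase %in% c("PolII", "PolIII", "other")
  polymerase[bad_pol] <- "other"
  df <- data.frame(gene_id = as.character(gene_id),
                   chrom = as.character(chrom),
                   start = start, end = end, strand = strand,
                   biotype = biotype, polymerase = polymerase,
                   tss = ifelse(strand == "+", start, end - 1L),
                   tes = ifelse(strand == "+", end - 1L, start),
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  out <- structure(df, class = c("gene_table", "data.frame"))
  attr(out, "chrom_lengths") <- chrom_lengths
  out
}

#' @export
print.gene_table <- function(x, ...) {
  cat("<gene_table>", nrow(x), "genes;",
      sum(x$polymerase == "PolII"), "Pol II\n")
  if (nrow(x)) print.data.frame(utils::head(x, 8))
  invisible(x)
}

#' Expression matrix with derived RPKM
#'
#' Bundles a gene-by-sample count matrix with gene lengths, per-sample library
#' sizes (column sums) and the derived RPKM matrix
#' (`count / (length_kb * library_millions)`).
#'
#' @param counts integer gene-by-sample matrix with row and column names.
#' @param gene_lengths named vector of gene lengths in bases (one per row).
#' @param group optional factor of sample group labels (one per column).
#' @return An object of class `expression_matrix` with fields `counts`,
#'   `gene_lengths`, `library_sizes`, `rpkm` and `group`.
#' @export
expression_matrix <- function(counts, gene_lengths, group = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must have gene row names and sample column names")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  gene_lengths <- gene_lengths[rownames(counts)]
  if (any(is.na(gene_lengths))) stop("gene_lengths missing for some genes")
  lib <- colSums(counts)
  structure(
    list(counts = counts,
         gene_lengths = gene_lengths,
         library_sizes = lib,
         rpkm = rpkm(counts, gene_lengths, lib),
         group = group),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix>", nrow(x$counts), "genes x",
      ncol(x$counts), "samples\n")
  cat("  library sizes:", paste(format(x$library_sizes), collapse = ", "), "\n")
  invisible(x)
}
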