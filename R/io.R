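# Readers and writers for the plain-text formats the pipeline touches.
# Internal coordinates are 0-based half-open everywhere; GTF (1-based
# inclusive) is converted on read and write.

#' Read a gene annotation (GTF/GFF or BED6+biotype)
#'
#' GTF/GFF parsing is delegated to [rtracklayer::import()]; attribute keys
#' `gene_id` and `gene_biotype` populate the gene table. A BED-style file
#' (detected by a `.bed` extension) is read as BED6 with an optional seventh
#' biotype column. Records without a `+`/`-` strand are rejected with a
#' warning naming them; unknown biotypes map to `"other"`. Header comments of
#' the form `##chrom-length <chrom> <len>` (written by
#' [write_gene_annotation()]) populate the `chrom_lengths` attribute.
#'
#' @param path annotation file.
#' @return A [gene_table()].
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  cl <- .parse_chrom_length_comments(lines)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) == 0) {
    warning("annotation file is empty: ", path)
    return(gene_table(character(), character(), integer(), integer(),
                      character(), chrom_lengths = cl))
  }
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    return(.read_annotation_bed(path, body, cl))
  }
  nf <- lengths(strsplit(body, "\t", fixed = TRUE))
  if (any(nf != 9)) {
    ln <- which(!grepl("^#", lines) & nzchar(lines))[which(nf != 9)[1]]
    stop("malformed GTF record (expected 9 tab-separated fields) at line ", ln,
         " of ", path)
  }
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  if ("type" %in% names(df) && any(df$type == "gene")) {
    df <- df[df$type == "gene", , drop = FALSE]
  }
  if (is.null(df$gene_id)) stop("GTF attributes lack gene_id: ", path)
  keep <- df$strand %in% c("+", "-")
  if (any(!keep)) {
    warning(sum(!keep), " record(s) without '+'/'-' strand rejected: ",
            paste(utils::head(df$gene_id[!keep], 5), collapse = ", "))
    df <- df[keep, , drop = FALSE]
  }
  biotype <- if (!is.null(df$gene_biotype)) df$gene_biotype else "other"
  gene_table(gene_id = df$gene_id,
             chrom = as.character(df$seqnames),
             start = df$start - 1L,       # 1-based inclusive -> 0-based
             end = df$end,
             strand = as.character(df$strand),
             biotype = biotype,
             polymerase = .polymerase_for_biotype(
               rep_len(as.character(biotype), nrow(df))),
             chrom_lengths = cl)
}

.read_annotation_bed <- function(path, body, cl) {
  nf <- lengths(strsplit(body, "\t", fixed = TRUE))
  if (any(nf < 6)) {
    stop("malformed BED record (need >= 6 fields) at data line ",
         which(nf < 6)[1], " of ", path)
  }
  tb <- utils::read.table(text = body, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  strand <- as.character(tb[[6]])
  keep <- strand %in% c("+", "-")
  if (any(!keep)) {
    warning(sum(!keep), " record(s) without '+'/'-' strand rejected")
    tb <- tb[keep, , drop = FALSE]
  }
  biotype <- if (ncol(tb) >= 7) as.character(tb[[7]]) else "protein_coding"
  gene_table(gene_id = as.character(tb[[4]]), chrom = as.character(tb[[1]]),
             start = tb[[2]], end = tb[[3]], strand = as.character(tb[[6]]),
             biotype = biotype,
             polymerase = .polymerase_for_biotype(biotype),
             chrom_lengths = cl)
}

# Canonical biotype -> polymerase class used when no explicit label exists:
# tRNA genes are Pol III transcripts; rRNA is (mostly) Pol I, recorded as
# "other"; anything not protein-coding defaults to "other".
.polymerase_for_biotype <- function(biotype) {
  ifelse(biotype == "protein_coding", "PolII",
         ifelse(biotype == "tRNA", "PolIII", "other"))
}

.parse_chrom_length_comments <- function(lines) {
  m <- grep("^##chrom-length\\s", lines, value = TRUE)
  if (length(m) == 0) return(NULL)
  parts <- strsplit(m, "\\s+")
  stats::setNames(vapply(parts, function(p) as.integer(p[3]), integer(1)),
                  vapply(parts, function(p) p[2], character(1)))
}

#' Write a gene annotation as GTF
#'
#' Emits one `gene` feature per row with `gene_id` and `gene_biotype`
#' attributes, converting to 1-based inclusive coordinates, plus
#' `##chrom-length` header comments so chromosome extents round-trip.
#'
#' @param genes a [gene_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(genes, path) {
  cl <- attr(genes, "chrom_lengths")
  header <- if (!is.null(cl)) {
    sprintf("##chrom-length %s %d", names(cl), as.integer(cl))
  } else character()
  recs <- sprintf(
    "%s\tchipfold\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; gene_biotype \"%s\";",
    genes$chrom, genes$start + 1L, genes$end, genes$strand,
    genes$gene_id, genes$biotype)
  writeLines(c(header, recs), path)
  invisible(path)
}

#' Read a bedGraph file into a dense coverage track
#'
#' Records are 0-based half-open and must not overlap; positions not covered
#' by any record are 0. `##chrom-length` header comments (written by
#' [write_bedgraph()]) fix chromosome extents; otherwise each chromosome ends
#' at its last covered base.
#'
#' @param path bedGraph file.
#' @param sample_id label for the resulting track (defaults to the file name).
#' @param chrom_lengths optional named vector overriding chromosome extents.
#' @return A [coverage_track()].
#' @export
read_bedgraph <- function(path, sample_id = basename(path),
                          chrom_lengths = NULL) {
  if (!file.exists(path)) stop("bedGraph file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (is.null(chrom_lengths)) chrom_lengths <- .parse_chrom_length_comments(lines)
  body <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(body) == 0) {
    if (is.null(chrom_lengths)) stop("bedGraph file has no records: ", path)
    return(coverage_track(lapply(chrom_lengths, numeric), sample_id))
  }
  tb <- utils::read.table(text = body, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "value"),
                          colClasses = c("character", "integer", "integer",
                                         "numeric"))
  if (any(is.na(tb$start) | is.na(tb$end) | is.na(tb$value))) {
    stop("malformed bedGraph record in ", path)
  }
  if (any(tb$value < 0)) stop("negative coverage values in ", path)
  if (any(tb$start < 0 | tb$start >= tb$end)) {
    stop("bedGraph intervals must satisfy 0 <= start < end in ", path)
  }
  tb <- tb[order(tb$chrom, tb$start), , drop = FALSE]
  same <- tb$chrom[-1] == tb$chrom[-nrow(tb)]
  if (nrow(tb) > 1 && any(same & tb$start[-1] < tb$end[-nrow(tb)])) {
    stop("overlapping bedGraph records in ", path)
  }
  chroms <- unique(tb$chrom)
  if (!is.null(chrom_lengths)) chroms <- union(chroms, names(chrom_lengths))
  values <- lapply(chroms, function(ch) {
    sub <- tb[tb$chrom == ch, , drop = FALSE]
    len <- if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths)) {
      chrom_lengths[[ch]]
    } else if (nrow(sub)) max(sub$end) else 0L
    if (nrow(sub) && max(sub$end) > len) {
      stop("bedGraph record beyond declared length of ", ch, " in ", path)
    }
    v <- numeric(len)
    for (i in seq_len(nrow(sub))) {
      v[(sub$start[i] + 1L):sub$end[i]] <- sub$value[i]
    }
    v
  })
  names(values) <- chroms
  coverage_track(values, sample_id)
}

#' Write a coverage track as bedGraph
#'
#' Runs of equal value are collapsed into single records; zero runs are
#' omitted (bedGraph semantics: uncovered means 0). `##chrom-length` comments
#' record chromosome extents so [read_bedgraph()] is an exact inverse.
#'
#' @param track a [coverage_track()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  cl <- chrom_lengths(track)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("##chrom-length %s %d", names(cl), cl), con)
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    if (!length(v)) next
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (any(keep)) {
      writeLines(sprintf("%s\t%d\t%d\t%s", ch, starts[keep], ends[keep],
                         formatC(r$values[keep], format = "g", digits = 15)),
                 con)
    }
  }
  invisible(path)
}

#' Write a peak set as BED6
#'
#' The score column is the mean fold change rounded to 3 decimals; strand is
#' reported as `.`. A header comment is always written, so an empty peak set
#' yields a non-empty, self-describing file.
#'
#' @param peaks a [peak_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  validate_peak_set(peaks)
  header <- "# chrom\tstart\tend\tname\tscore\tstrand"
  recs <- if (nrow(peaks)) {
    sprintf("%s\t%d\t%d\t%s\t%s\t.", peaks$chrom, peaks$start, peaks$end,
            peaks$name,
            ifelse(is.na(peaks$score), ".",
                   formatC(peaks$score, format = "f", digits = 3)))
  } else character()
  writeLines(c(header, recs), path)
  invisible(path)
}

#' Read a BED file as a peak set
#'
#' @param path BED6 file (comment lines ignored).
#' @param resort re-sort unsorted input instead of erroring.
#' @return A [peak_set()].
#' @export
read_bed <- function(path, resort = FALSE) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  body <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(body) == 0) return(peak_set())
  tb <- utils::read.table(text = body, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(tb) < 3) stop("BED file needs >= 3 columns: ", path)
  score <- if (ncol(tb) >= 5) suppressWarnings(as.numeric(tb[[5]])) else NA_real_
  ord <- order(tb[[1]], tb[[2]])
  if (!identical(ord, seq_len(nrow(tb)))) {
    if (!resort) stop("BED records are not sorted by (chrom, start); ",
                      "pass resort = TRUE to re-sort: ", path)
    tb <- tb[ord, , drop = FALSE]
    score <- score[ord]
  }
  peak_set(chrom = tb[[1]], start = tb[[2]], end = tb[[3]], score = score)
}

# Deterministic TSV writer shared by all table outputs.
write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv_file <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
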