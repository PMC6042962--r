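# Synthetic genomes, coverage pairs, count matrices and term maps with known
# planted truth. All generators are pure functions of (parameters, seed).

#' Generate a synthetic gene annotation
#'
#' Places `n_genes` non-overlapping genes with random strands on `n_chroms`
#' chromosomes of `chrom_length` bases each. A fraction `frac_non_polII` of
#' genes is labelled as non-Pol II (cycling through tRNA, rRNA and other
#' Pol III transcripts), mirroring the biotype filter applied before peak-to-
#' gene assignment. Deterministic given `seed`.
#'
#' @param n_chroms number of chromosomes (named `chr1`, `chr2`, ...).
#' @param chrom_length chromosome length in bases.
#' @param n_genes total number of genes.
#' @param frac_non_polII fraction of genes labelled tRNA/rRNA/Pol III.
#' @param seed integer RNG seed.
#' @param gene_length_range min/max gene length in bases.
#' @return A [gene_table()] with a `chrom_lengths` attribute.
#' @export
generate_genome <- function(n_chroms = 1, chrom_length = 500000L,
                            n_genes = 100, frac_non_polII = 0.1,
                            seed = 1, gene_length_range = c(500L, 2000L)) {
  stopifnot(n_chroms >= 1, chrom_length >= 1, n_genes >= 1,
            frac_non_polII >= 0, frac_non_polII <= 1)
  with_seed(seed, {
    chroms <- paste0("chr", seq_len(n_chroms))
    per <- diff(round(seq(0, n_genes, length.out = n_chroms + 1)))
    rows <- vector("list", n_chroms)
    for (ci in seq_len(n_chroms)) {
      k <- per[ci]
      if (k == 0) next
      len <- sample(gene_length_range[1]:gene_length_range[2], k, replace = TRUE)
      free <- chrom_length - sum(len)
      if (free < k) {
        stop("cannot pack ", k, " genes of total length ", sum(len),
             " into a ", chrom_length, "-base chromosome; ",
             "increase chrom_length or reduce n_genes")
      }
      # random gap allocation: k cut points in the free space
      cuts <- sort(sample.int(free + 1L, k, replace = TRUE) - 1L)
      start <- cuts + cumsum(c(0L, len[-k]))
      rows[[ci]] <- data.frame(chrom = chroms[ci], start = start,
                               end = start + len,
                               stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, rows)
    n <- nrow(df)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    biotype <- rep("protein_coding", n)
    polymerase <- rep("PolII", n)
    n_non <- round(frac_non_polII * n)
    if (n_non > 0) {
      idx <- sample.int(n, n_non)
      bt <- rep_len(c("tRNA", "rRNA", "other"), n_non)
      biotype[idx] <- bt
      polymerase[idx] <- ifelse(bt == "tRNA", "PolIII",
                                ifelse(bt == "rRNA", "other", "PolIII"))
    }
    gene_table(gene_id = sprintf("gene_%04d", seq_len(n)),
               chrom = df$chrom, start = df$start, end = df$end,
               strand = strand, biotype = biotype, polymerase = polymerase,
               chrom_lengths = stats::setNames(rep(as.integer(chrom_length),
                                                   n_chroms), chroms))
  })
}

#' Generate an IP/input coverage pair with planted enrichment
#'
#' The input track has expectation `background_level` at every base; the IP
#' track has expectation `background_level * fold` inside each planted region
#' and `background_level` elsewhere, then is globally scaled by `depth_ratio`
#' (modelling unequal sequencing depth, so the depth-normalisation step of the
#' peak caller is testable). With `noise = "none"` the tracks are exact
#' piecewise-constant expectations; with `noise = "poisson"` per-base counts
#' are drawn from the stated means.
#'
#' @param genes a [gene_table()] carrying a `chrom_lengths` attribute; defines
#'   the genome the tracks cover.
#' @param planted_regions data frame with columns `chrom`, `start`, `end`,
#'   `fold` (`fold > 1`); regions must lie inside the genome and not overlap.
#' @param background_level expected input coverage per base (`> 0`).
#' @param depth_ratio global IP depth multiplier.
#' @param noise `"none"` or `"poisson"`.
#' @param seed integer RNG seed (used only when `noise = "poisson"`).
#' @return A list with elements `ip` and `input` ([coverage_track()]s) and
#'   `truth` (list with `enriched_regions`).
#' @export
generate_coverage_pair <- function(genes, planted_regions,
                                   background_level = 50, depth_ratio = 1,
                                   noise = c("none", "poisson"), seed = 1) {
  noise <- match.arg(noise)
  stopifnot(background_level > 0, depth_ratio > 0)
  cl <- attr(genes, "chrom_lengths")
  if (is.null(cl)) stop("`genes` must carry a chrom_lengths attribute")
  pr <- as.data.frame(planted_regions)
  if (nrow(pr)) {
    stopifnot(all(c("chrom", "start", "end", "fold") %in% names(pr)))
    if (any(pr$fold <= 1)) stop("planted folds must be > 1")
    if (any(!pr$chrom %in% names(cl)) || any(pr$start < 0) ||
        any(pr$end > cl[pr$chrom])) {
      stop("planted regions must lie inside the genome")
    }
    pr <- pr[order(pr$chrom, pr$start), , drop = FALSE]
    same <- nrow(pr) > 1 & c(FALSE, pr$chrom[-1] == pr$chrom[-nrow(pr)])
    if (any(same & c(FALSE, pr$start[-1] < pr$end[-nrow(pr)])[seq_len(nrow(pr))])) {
      stop("planted regions overlap")
    }
  }
  input_mean <- lapply(cl, function(len) rep(background_level, len))
  ip_mean <- input_mean
  for (i in seq_len(nrow(pr))) {
    idx <- (pr$start[i] + 1L):pr$end[i]
    ip_mean[[pr$chrom[i]]][idx] <- background_level * pr$fold[i]
  }
  ip_mean <- lapply(ip_mean, function(v) v * depth_ratio)
  draw <- function(means, id) {
    vals <- if (noise == "none") means else lapply(means, function(m) {
      as.numeric(rpois(length(m), m))
    })
    coverage_track(vals, id)
  }
  with_seed(if (noise == "poisson") seed else NULL, {
    ip <- draw(ip_mean, "ip")
    input <- draw(input_mean, "input")
    list(ip = ip, input = input,
         truth = list(enriched_regions = pr))
  })
}

#' Generate a two-group RNA-seq count matrix with planted fold changes
#'
#' Counts are drawn from a negative binomial parameterised by mean `m` and
#' dispersion `phi` (variance `m + phi * m^2`); `phi = 0` degenerates to
#' Poisson. Group A has mean `baseline_mean`; group B has mean
#' `baseline_mean * 2^log2fc` for genes named in `planted_log2fc` (0
#' otherwise). Deterministic given `seed`.
#'
#' @param genes a [gene_table()] (gene lengths feed the RPKM computation).
#' @param n_samples_per_group samples per group.
#' @param baseline_mean scalar or per-gene named vector of group-A means.
#' @param planted_log2fc named numeric vector `gene_id -> log2 fold change`.
#' @param dispersion NB dispersion `phi >= 0`.
#' @param seed integer RNG seed.
#' @param group_names labels for the two groups (column prefixes).
#' @return A list with `expr` (an [expression_matrix()] whose `group` field
#'   holds the two-level factor) and `truth` (lists `de_up`, `de_down` of
#'   planted gene ids).
#' @export
generate_counts <- function(genes, n_samples_per_group = 3,
                            baseline_mean = 200, planted_log2fc = NULL,
                            dispersion = 0, seed = 1,
                            group_names = c("A", "B")) {
  stopifnot(dispersion >= 0, n_samples_per_group >= 1)
  ids <- genes$gene_id
  base <- if (length(baseline_mean) == 1) {
    stats::setNames(rep(baseline_mean, length(ids)), ids)
  } else baseline_mean[ids]
  if (any(is.na(base)) || any(base < 0)) {
    stop("baseline_mean must be non-negative and cover every gene")
  }
  lfc <- stats::setNames(rep(0, length(ids)), ids)
  if (!is.null(planted_log2fc)) {
    unknown <- setdiff(names(planted_log2fc), ids)
    if (length(unknown)) stop("planted_log2fc names not in gene set: ",
                              paste(unknown, collapse = ", "))
    lfc[names(planted_log2fc)] <- planted_log2fc
  }
  mean_a <- base
  mean_b <- base * 2^lfc
  n <- n_samples_per_group
  with_seed(seed, {
    draw <- function(mu) {
      if (dispersion == 0) rpois(length(mu), mu)
      else rnbinom(length(mu), size = 1 / dispersion, mu = mu)
    }
    cnt <- vapply(seq_len(2 * n), function(j) {
      draw(if (j <= n) mean_a else mean_b)
    }, numeric(length(ids)))
    rownames(cnt) <- ids
    colnames(cnt) <- c(paste0(group_names[1], "_", seq_len(n)),
                       paste0(group_names[2], "_", seq_len(n)))
    group <- factor(rep(group_names, each = n), levels = group_names)
    expr <- expression_matrix(cnt, stats::setNames(genes$end - genes$start, ids),
                              group = group)
    list(expr = expr,
         truth = list(de_up = names(lfc)[lfc > 0],
                      de_down = names(lfc)[lfc < 0]))
  })
}

#' Generate a gene-to-term annotation with one planted enriched term
#'
#' Random terms each annotate `genes_per_term` genes sampled uniformly; the
#' planted term's membership is reproduced exactly as given, so a significant
#' gene list equal to its members must rank it first in the downstream
#' hypergeometric test.
#'
#' @param genes a [gene_table()].
#' @param n_terms number of random background terms.
#' @param genes_per_term membership size of each background term.
#' @param planted_term `list(term = <id>, members = <gene ids>)` or `NULL`.
#' @param seed integer RNG seed.
#' @return Data frame with columns `gene_id`, `term_id`.
#' @export
generate_term_map <- function(genes, n_terms = 50, genes_per_term = 15,
                              planted_term = NULL, seed = 1) {
  ids <- genes$gene_id
  if (!is.null(planted_term)) {
    bad <- setdiff(planted_term$members, ids)
    if (length(bad)) stop("planted term members not in gene set: ",
                          paste(bad, collapse = ", "))
  }
  with_seed(seed, {
    rows <- lapply(seq_len(n_terms), function(t) {
      data.frame(gene_id = sample(ids, min(genes_per_term, length(ids))),
                 term_id = sprintf("TERM_%03d", t),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (!is.null(planted_term)) {
      out <- rbind(out, data.frame(gene_id = planted_term$members,
                                   term_id = planted_term$term,
                                   stringsAsFactors = FALSE))
    }
    rownames(out) <- NULL
    out
  })
}
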