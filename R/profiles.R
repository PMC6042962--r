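# Metagene profiles (TSS-anchored and transcript-scaled), RPKM, expression
# quantiles, the differential-expression stand-in and dependence scatters.

#' Centred moving-average smoothing
#'
#' Mean over a centred window of `window` bases; at the edges the window
#' shrinks to the available positions, so output length equals input length.
#' Missing values are ignored within each window (a window with no data
#' yields `NA`).
#'
#' @param signal numeric vector (may contain `NA`).
#' @param window odd window width in bases (`window = 1` is the identity).
#' @return Smoothed vector of the same length.
#' @export
smooth_mean <- function(signal, window = 101L) {
  window <- as.integer(window)
  if (window < 1 || window %% 2 == 0) stop("window must be odd and >= 1")
  if (window == 1 || length(signal) == 0) return(signal)
  h <- (window - 1L) %/% 2L
  n <- length(signal)
  miss <- is.na(signal)
  s <- signal; s[miss] <- 0
  cs <- c(0, cumsum(s))
  cn <- c(0, cumsum(!miss))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  tot <- cs[hi + 1L] - cs[lo]
  cnt <- cn[hi + 1L] - cn[lo]
  out <- ifelse(cnt > 0, tot / cnt, NA_real_)
  out
}

#' TSS-anchored per-gene profile
#'
#' Extracts the signal at `TSS - flank ... TSS + flank` in 5'→3' orientation
#' (the vector is reversed for minus-strand genes). Positions beyond the
#' chromosome ends are `NA`.
#'
#' @param track a [coverage_track()].
#' @param gene one-row [gene_table()] slice (needs `chrom`, `tss`, `strand`).
#' @param flank flank size in bases.
#' @return Numeric vector of length `2 * flank + 1`.
#' @export
anchored_profile <- function(track, gene, flank = 2000L) {
  v <- track$values[[gene$chrom]]
  if (is.null(v)) stop("gene chromosome absent from track: ", gene$chrom)
  pos <- (gene$tss - flank):(gene$tss + flank)      # 0-based genome positions
  out <- rep(NA_real_, length(pos))
  ok <- pos >= 0 & pos < length(v)
  out[ok] <- v[pos[ok] + 1L]
  if (gene$strand == "-") out <- rev(out)
  out
}

#' Transcript-scaled per-gene profile
#'
#' Flanks of `flank` bases are taken at base resolution; the gene body is
#' resampled to `body_points` values by linear interpolation
#' ([stats::approx()]) of the per-base signal at equally spaced fractional
#' positions, so genes of different lengths share one axis. A body whose
#' length equals `body_points` is returned unchanged. Orientation is 5'→3'.
#'
#' @param track a [coverage_track()].
#' @param gene one-row [gene_table()] slice.
#' @param flank flank size in bases.
#' @param body_points number of interpolated body positions.
#' @return Numeric vector of length `2 * flank + body_points`.
#' @export
scaled_profile <- function(track, gene, flank = 500L, body_points = 1000L) {
  v <- track$values[[gene$chrom]]
  if (is.null(v)) stop("gene chromosome absent from track: ", gene$chrom)
  L <- gene$end - gene$start
  if (L < 2) stop("gene body must be at least 2 bases for interpolation")
  grab <- function(pos) {
    out <- rep(NA_real_, length(pos))
    ok <- pos >= 0 & pos < length(v)
    out[ok] <- v[pos[ok] + 1L]
    out
  }
  left <- if (flank > 0) grab((gene$start - flank):(gene$start - 1L)) else numeric(0)
  body <- v[(gene$start + 1L):gene$end]
  right <- if (flank > 0) grab(gene$end:(gene$end + flank - 1L)) else numeric(0)
  body_rs <- stats::approx(seq_len(L), body,
                           xout = seq(1, L, length.out = body_points))$y
  out <- c(left, body_rs, right)
  if (gene$strand == "-") out <- rev(out)
  out
}

#' Positionwise average of per-gene profiles
#'
#' The mean at each position over all genes with data there; the number of
#' contributing genes is recorded per position.
#'
#' @param per_gene_matrix genes-in-rows matrix of aligned profiles (may
#'   contain `NA`).
#' @param positions optional coordinate axis (defaults to column index).
#' @return Data frame of class `metagene_profile` with columns `position`,
#'   `mean_signal`, `n_genes`.
#' @export
metagene_average <- function(per_gene_matrix, positions = NULL) {
  m <- as.matrix(per_gene_matrix)
  if (nrow(m) == 0) stop("metagene average needs at least one gene")
  if (is.null(positions)) positions <- seq_len(ncol(m))
  stopifnot(length(positions) == ncol(m))
  n_genes <- colSums(!is.na(m))
  mean_signal <- ifelse(n_genes > 0, colMeans(m, na.rm = TRUE), NA_real_)
  structure(data.frame(position = positions, mean_signal = mean_signal,
                       n_genes = n_genes),
            class = c("metagene_profile", "data.frame"))
}

#' Metagene profile of a coverage track over a gene set
#'
#' Builds per-gene profiles (TSS-anchored or transcript-scaled), smooths each
#' gene's vector with a centred `smooth_window` moving average, then averages
#' positionwise. Smoothing before averaging commutes with the reverse order
#' on complete data; gene-first is fixed here so that chromosome-edge missing
#' stretches are smoothed within, not across, genes.
#'
#' @param track a [coverage_track()].
#' @param genes a [gene_table()].
#' @param mode `"tss_anchored"` or `"transcript_scaled"`.
#' @param flank flank in bases (2000 for TSS mode, 500 for scaled mode by
#'   convention; pass explicitly to override).
#' @param body_points body grid size for scaled mode.
#' @param smooth_window odd moving-average width (1 = no smoothing).
#' @return A `metagene_profile` data frame; in TSS mode `position` is the
#'   base offset from the TSS, in scaled mode it is the output index with the
#'   body spanning `flank + 1 ... flank + body_points`.
#' @export
metagene_profile <- function(track, genes,
                             mode = c("tss_anchored", "transcript_scaled"),
                             flank = NULL, body_points = 1000L,
                             smooth_window = 101L) {
  mode <- match.arg(mode)
  if (nrow(genes) == 0) stop("metagene profile needs at least one gene")
  if (is.null(flank)) flank <- if (mode == "tss_anchored") 2000L else 500L
  prof <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, , drop = FALSE]
    p <- if (mode == "tss_anchored") anchored_profile(track, g, flank)
         else scaled_profile(track, g, flank, body_points)
    smooth_mean(p, smooth_window)
  })
  m <- do.call(rbind, prof)
  positions <- if (mode == "tss_anchored") seq(-flank, flank) else seq_len(ncol(m))
  out <- metagene_average(m, positions)
  attr(out, "mode") <- mode
  attr(out, "flank") <- flank
  attr(out, "smooth_window") <- smooth_window
  out
}

#' Reads per kilobase per million mapped reads
#'
#' `rpkm = count / (gene_length_kb * library_millions)`, elementwise over a
#' gene-by-sample matrix.
#'
#' @param counts gene-by-sample matrix (or vector).
#' @param gene_lengths per-gene lengths in bases (`> 0`).
#' @param library_sizes per-sample totals (`> 0`).
#' @return Matrix (or vector) of RPKM values.
#' @export
rpkm <- function(counts, gene_lengths, library_sizes) {
  if (any(gene_lengths <= 0)) stop("gene lengths must be > 0")
  if (any(library_sizes <= 0)) stop("library sizes must be > 0")
  if (is.matrix(counts)) {
    stopifnot(length(gene_lengths) == nrow(counts),
              length(library_sizes) == ncol(counts))
    counts / outer(gene_lengths / 1e3, library_sizes / 1e6)
  } else {
    counts / (gene_lengths / 1e3 * library_sizes / 1e6)
  }
}

#' Equal-sized expression quantile groups
#'
#' Sorts genes ascending by value (ties broken by name for determinism) and
#' splits them into `n_groups` contiguous groups whose sizes differ by at
#' most one; the first `n %% n_groups` groups take the extra gene. Group 1 is
#' the lowest-expression group.
#'
#' @param values named numeric vector (e.g. RPKM in one condition).
#' @param n_groups number of quantile groups (`>= 2`).
#' @return Named integer vector of group indices (1 = lowest) in the input
#'   order.
#' @export
quantile_groups <- function(values, n_groups = 5L) {
  n_groups <- as.integer(n_groups)
  if (n_groups < 2) stop("n_groups must be >= 2")
  if (any(!is.finite(values))) stop("values must be finite")
  n <- length(values)
  if (n < n_groups) stop("fewer genes (", n, ") than groups (", n_groups, ")")
  ids <- names(values)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  ord <- order(values, ids)
  base <- n %/% n_groups
  extra <- n %% n_groups
  sizes <- base + as.integer(seq_len(n_groups) <= extra)
  grp <- rep(seq_len(n_groups), times = sizes)
  out <- integer(n)
  out[ord] <- grp
  stats::setNames(out, ids)
}

#' Differential expression by exact conditional binomial test
#'
#' A fully specified stand-in for count-model DE testing: per gene, counts
#' are pooled within each of the two groups and the group-B pooled count is
#' tested against `Binomial(a + b, L_B / (L_A + L_B))` (two-sided exact
#' test), where `L_A`, `L_B` are the pooled library sizes — the conditional
#' test of equal rates with library-size offsets. Fold changes are computed
#' on per-million-scaled pooled counts with a pseudocount of 1. A gene is
#' called DE when the BH-adjusted p-value is below `alpha` and
#' `|log2fc| >= lfc_threshold` (defaults: 0.05 and 1, i.e. two-fold).
#'
#' @param expr an [expression_matrix()] whose `group` field has two levels,
#'   or a counts matrix (then `group_labels` is required).
#' @param group_labels factor of length `ncol(counts)` with exactly two
#'   levels (ignored when `expr` carries its own grouping).
#' @param lfc_threshold minimum `|log2fc|`.
#' @param alpha BH-adjusted significance level.
#' @return Data frame: `gene`, `log2fc`, `p_value`, `adj_p_value`, `de`.
#' @export
de_genes <- function(expr, group_labels = NULL, lfc_threshold = 1,
                     alpha = 0.05) {
  if (inherits(expr, "expression_matrix")) {
    counts <- expr$counts
    if (is.null(group_labels)) group_labels <- expr$group
  } else counts <- as.matrix(expr)
  group_labels <- as.factor(group_labels)
  if (nlevels(group_labels) != 2 || length(group_labels) != ncol(counts) ||
      any(table(group_labels) < 1)) {
    stop("group_labels must assign every sample to one of exactly two groups")
  }
  ga <- group_labels == levels(group_labels)[1]
  a <- rowSums(counts[, ga, drop = FALSE])
  b <- rowSums(counts[, !ga, drop = FALSE])
  L_a <- sum(counts[, ga, drop = FALSE])
  L_b <- sum(counts[, !ga, drop = FALSE])
  pr_b <- L_b / (L_a + L_b)
  p <- vapply(seq_along(a), function(i) {
    tot <- a[i] + b[i]
    if (tot == 0) return(1)
    stats::binom.test(round(b[i]), round(tot), p = pr_b)$p.value
  }, numeric(1))
  cpm_a <- a / L_a * 1e6
  cpm_b <- b / L_b * 1e6
  log2fc <- log2((cpm_b + 1) / (cpm_a + 1))
  adj <- bh_adjust(p)
  data.frame(gene = rownames(counts), log2fc = log2fc, p_value = p,
             adj_p_value = adj, de = adj < alpha & abs(log2fc) >= lfc_threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Condition-vs-mutant dependence scatter
#'
#' For each gene, `x` is the expression change upon the condition shift in
#' wild type, `y` the change in the mutant relative to wild type under the
#' shifted condition:
#' `x = log2((gly_wt + 1) / (glu_wt + 1))`,
#' `y = log2((gly_mut + 1) / (gly_wt + 1))`,
#' both on per-million-scaled values. The Pearson correlation of `(x, y)`
#' summarises whether the mutant reverts the condition response (a full
#' reversion gives `y = -x`, `r = -1`). Computable over any gene subset
#' (pathway lists).
#'
#' @param expr_wt_glu,expr_wt_gly,expr_mut_gly named count vectors over the
#'   same genes (wild type in glucose, wild type in glycerol, mutant in
#'   glycerol).
#' @param gene_subset optional character vector restricting the computation;
#'   genes missing from the data are an error.
#' @param library_sizes optional numeric vector of the three library totals
#'   (defaults to the sums of each vector).
#' @return List with `x`, `y` (named per gene), `r` and `genes`.
#' @export
dependence_scatter <- function(expr_wt_glu, expr_wt_gly, expr_mut_gly,
                               gene_subset = NULL, library_sizes = NULL) {
  ids <- names(expr_wt_glu)
  if (is.null(ids) || !identical(ids, names(expr_wt_gly)) ||
      !identical(ids, names(expr_mut_gly))) {
    stop("the three expression vectors must share identical gene names")
  }
  if (!is.null(gene_subset)) {
    missing <- setdiff(gene_subset, ids)
    if (length(missing)) {
      stop("subset genes absent from the data: ",
           paste(utils::head(missing, 10), collapse = ", "))
    }
    ids <- gene_subset
  }
  if (is.null(library_sizes)) {
    library_sizes <- c(sum(expr_wt_glu), sum(expr_wt_gly), sum(expr_mut_gly))
  }
  if (any(library_sizes <= 0)) stop("library sizes must be > 0")
  glu <- expr_wt_glu[ids] / library_sizes[1] * 1e6
  gly <- expr_wt_gly[ids] / library_sizes[2] * 1e6
  mut <- expr_mut_gly[ids] / library_sizes[3] * 1e6
  x <- log2((gly + 1) / (glu + 1))
  y <- log2((mut + 1) / (gly + 1))
  r <- tryCatch(pearson_correlation(x, y), warning = function(w) {
    warning(conditionMessage(w)); NA_real_
  })
  list(x = x, y = y, r = r, genes = ids)
}
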