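# Hypergeometric term enrichment with fold-enrichment scoring, plus the BH
# adjustment and Pearson correlation utilities used across the pipeline.

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the chance that a uniform
#' draw of `n` genes from a universe of `N`, of which `K` carry the term,
#' contains at least `k` carriers. Delegates to [stats::phyper()], which
#' accumulates in a numerically stable way.
#'
#' @param k observed carriers in the draw (`0 <= k <= min(n, K)`).
#' @param K carriers in the universe.
#' @param n draw size.
#' @param N universe size.
#' @return The upper-tail probability (exactly 1 when `k = 0`).
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(n, K)) {
    stop("hypergeometric bounds violated: need 0 <= k <= min(n, K), K,n <= N")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Fold enrichment of a term in a gene list
#'
#' The term's frequency in the significant list divided by its frequency in
#' the universe: `(k/n) / (K/N)`.
#'
#' @param k term genes in the list; @param n list size;
#' @param K term genes in the universe; @param N universe size.
#' @return The ratio; `NA` (with a warning) when `K = 0`.
#' @export
fold_enrichment <- function(k, n, K, N) {
  stopifnot(n > 0, N > 0)
  if (any(K == 0)) {
    warning("fold enrichment undefined for terms absent from the universe")
  }
  ifelse(K == 0, NA_real_, (k / n) / (K / N))
}

#' Hypergeometric term enrichment over a gene list
#'
#' One test per term annotating at least one universe gene. A term is
#' `included` when its p-value is below `p_cutoff` and at least `min_k` genes
#' from the significant list are annotated to it (defaults 0.05 and 2).
#' Results are sorted by fold enrichment, descending. Raw p-values drive
#' inclusion by default; `adjust = TRUE` switches the cutoff to BH-adjusted
#' p-values.
#'
#' @param gene_list significant genes (must be a subset of `universe`).
#' @param universe background gene set (typically the filtered Pol II genes).
#' @param term_map data frame with columns `gene_id`, `term_id`.
#' @param p_cutoff inclusion p-value cutoff.
#' @param min_k minimum annotated genes from the list.
#' @param adjust apply Benjamini-Hochberg before the cutoff.
#' @return Data frame with columns `term`, `k`, `n`, `K`, `N`, `p_value`,
#'   `adj_p_value`, `fold_enrichment`, `included`.
#' @export
term_enrichment <- function(gene_list, universe, term_map,
                            p_cutoff = 0.05, min_k = 2, adjust = FALSE) {
  gene_list <- unique(gene_list)
  universe <- unique(universe)
  offenders <- setdiff(gene_list, universe)
  if (length(offenders)) {
    stop("gene_list contains genes absent from the universe: ",
         paste(utils::head(offenders, 10), collapse = ", "))
  }
  tm <- term_map[term_map$gene_id %in% universe, , drop = FALSE]
  tm <- unique(tm[c("gene_id", "term_id")])
  N <- length(universe); n <- length(gene_list)
  terms <- sort(unique(tm$term_id))
  K <- vapply(terms, function(t) sum(tm$term_id == t), integer(1))
  k <- vapply(terms, function(t) {
    sum(tm$gene_id[tm$term_id == t] %in% gene_list)
  }, integer(1))
  p <- vapply(seq_along(terms), function(i) {
    hypergeom_upper_tail(k[i], K[i], n, N)
  }, numeric(1))
  adj <- bh_adjust(p)
  fe <- if (n > 0) fold_enrichment(k, n, K, N) else rep(NA_real_, length(terms))
  crit_p <- if (adjust) adj else p
  included <- crit_p < p_cutoff & k >= min_k
  out <- data.frame(term = terms, k = k, n = n, K = K, N = N,
                    p_value = p, adj_p_value = adj,
                    fold_enrichment = fe, included = included,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$fold_enrichment, out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: `adj_(i) = min_{j >= i}
#' (N p_(j) / j)`, capped at 1. Wraps [stats::p.adjust()] after validating the
#' input range.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Pearson correlation with the pipeline's missing-data contract
#'
#' Standard product-moment correlation; pairs with a missing value in either
#' vector are dropped. A zero-variance argument (after pair dropping) makes
#' the coefficient undefined: `NA` is returned with a warning rather than an
#' error, matching how figure-level statistics report it.
#'
#' @param x,y numeric vectors of equal length (`>= 2` complete pairs).
#' @return The correlation coefficient, or `NA` when undefined.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) stop("need at least two complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("zero variance: correlation undefined, reported as NA")
    return(NA_real_)
  }
  stats::cor(x, y)
}
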