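# Independent oracles used across the suite. These deliberately use naive
# formulations (loops, enumeration, direct formulas) so they share no code
# with the implementation paths they check.

# Exhaustive-search closest TSS: try every gene, track the minimum.
brute_closest_tss <- function(peak, genes) {
  best_d <- Inf; best_ids <- character()
  for (i in seq_len(nrow(genes))) {
    if (genes$chrom[i] != peak$chrom) next
    tss <- genes$tss[i]
    d <- if (tss >= peak$start && tss < peak$end) 0
         else min(abs(tss - peak$start), abs(tss - (peak$end - 1)))
    if (d < best_d) { best_d <- d; best_ids <- genes$gene_id[i] }
    else if (d == best_d) best_ids <- c(best_ids, genes$gene_id[i])
  }
  if (!length(best_ids)) return(list(gene_id = NA_character_, distance = Inf,
                                     tie = FALSE))
  list(gene_id = min(best_ids), distance = best_d,
       tie = length(unique(best_ids)) > 1)
}

# Direct step-up Benjamini-Hochberg formula.
bh_stepup_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(n)
  for (i in seq_len(n)) adj[i] <- min(1, min(n * ps[i:n] / (i:n)))
  out <- numeric(n)
  out[o] <- adj
  out
}

# Upper-tail hypergeometric by summing pmf terms over the support.
hyper_tail_support_sum <- function(k, K, n, N) {
  hi <- min(n, K)
  if (k > hi) return(0)
  j <- k:hi
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Upper-tail hypergeometric by literally enumerating every possible draw of
# n items from N (feasible only for small N).
hyper_tail_enumerate <- function(k, K, n, N) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)     # items 1..K carry the term
  mean(hits >= k)
}

# Repeated pairwise merging until stable: the fixed-point oracle for
# proximity merging (scores ignored).
merge_fixed_point_oracle <- function(df, gap) {
  repeat {
    df <- df[order(df$chrom, df$start), , drop = FALSE]
    merged_any <- FALSE
    i <- 1
    while (i < nrow(df)) {
      if (df$chrom[i] == df$chrom[i + 1] &&
          df$start[i + 1] - df$end[i] < gap) {
        df$end[i] <- max(df$end[i], df$end[i + 1])
        df <- df[-(i + 1), , drop = FALSE]
        merged_any <- TRUE
      } else i <- i + 1
    }
    if (!merged_any) return(df)
  }
}

# Random sorted disjoint peak set on one chromosome.
random_peak_set <- function(n, chrom_len = 100000L, seed = 1) {
  set.seed(seed)
  bounds <- sort(sample.int(chrom_len, 2 * n))
  peak_set(rep("chr1", n), bounds[seq(1, 2 * n, 2)], bounds[seq(2, 2 * n, 2)],
           score = round(runif(n, 1, 10), 3))
}

# Bases of [s1,e1) overlapping [s2,e2).
overlap_len <- function(s1, e1, s2, e2) max(0, min(e1, e2) - max(s1, s2))

# Total called bases falling outside any planted region (single chromosome).
bases_outside <- function(peaks, regions) {
  tot <- 0
  for (i in seq_len(nrow(peaks))) {
    inside <- 0
    for (j in seq_len(nrow(regions))) {
      inside <- inside + overlap_len(peaks$start[i], peaks$end[i],
                                     regions$start[j], regions$end[j])
    }
    tot <- tot + (peaks$end[i] - peaks$start[i]) - inside
  }
  tot
}

# Tiny genome helper used by coverage-level tests.
tiny_genome <- function(chrom_length = 100000L, n_genes = 10, seed = 1,
                        frac_non_polII = 0) {
  generate_genome(n_chroms = 1, chrom_length = chrom_length,
                  n_genes = n_genes, frac_non_polII = frac_non_polII,
                  seed = seed)
}
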