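# Orchestration of the two workflows (occupancy and expression) over the
# synthetic study conditions, plus the CFU viability utility. Every
# randomized stage receives a seed derived from the single top-level seed
# (seed + fixed per-stage offset), and the run log records parameters, seeds
# and per-stage record counts. Outputs are plain text and byte-identical
# across reruns with the same config.

#' Default occupancy-pipeline configuration
#'
#' Study conditions for the synthetic two-condition ChIP experiment: a 500 kb
#' single-chromosome genome with 100 genes (10% non-Pol II), Poisson
#' counting noise over a background of 50, ten fold-3 promoter regions
#' planted only in condition B (the nutrient-stress condition) and five
#' planted equally in both, and the published calling parameters (2-fold /
#' 50 bases / 400-base merge).
#'
#' @param out_dir output directory.
#' @param seed top-level integer seed.
#' @param overrides named list merged over the defaults (one level deep).
#' @return A configuration list.
#' @export
occupancy_config <- function(out_dir, seed = 1, overrides = list()) {
  cfg <- list(
    out_dir = out_dir, seed = as.integer(seed),
    genome = list(n_chroms = 1, chrom_length = 500000L, n_genes = 100,
                  frac_non_polII = 0.1),
    background_level = 50, depth_ratio = 1, noise = "poisson",
    n_condition_regions = 10, n_shared_regions = 5, planted_fold = 3,
    region_upstream = 100L, region_downstream = 400L,
    peak_params = peak_params(),
    lfc_threshold = 1, diff_test = "none", alpha = 0.05,
    enrichment = list(p_cutoff = 0.05, min_k = 2,
                      n_terms = 30, genes_per_term = 15),
    metagene = list(flank = 2000L, smooth_window = 101L)
  )
  utils::modifyList(cfg, overrides)
}

# Deterministic selection of planted promoter regions: Pol II genes whose
# promoter window fits in the genome, taken in TSS order, skipping any whose
# region would come within `spacing` bases of the previously selected one
# (so planted regions never merge with each other).
.select_promoter_regions <- function(genes, n, upstream, downstream,
                                     spacing = 1000L, skip = 0) {
  cl <- attr(genes, "chrom_lengths")
  cand <- filter_genes(genes, TRUE)
  cand <- cand[order(cand$chrom, cand$tss), , drop = FALSE]
  sel <- list(); last_chrom <- ""; last_end <- -Inf; skipped <- 0
  for (i in seq_len(nrow(cand))) {
    g <- cand[i, ]
    s <- g$tss - upstream; e <- g$tss + downstream
    if (s < 0 || e > cl[[g$chrom]]) next
    if (g$chrom == last_chrom && s - last_end < spacing) next
    if (skipped < skip) {
      # skipped candidates still claim their space, so a later call with a
      # larger skip selects regions disjoint from an earlier call's
      skipped <- skipped + 1
      last_chrom <- g$chrom; last_end <- e
      next
    }
    sel[[length(sel) + 1]] <- data.frame(chrom = g$chrom, start = s, end = e,
                                         gene_id = g$gene_id,
                                         stringsAsFactors = FALSE)
    last_chrom <- g$chrom; last_end <- e
    if (is.finite(n) && length(sel) == n) break
  }
  if (is.finite(n) && length(sel) < n) {
    stop("could not place ", n, " promoter regions; ",
         "use a larger genome or fewer regions")
  }
  do.call(rbind, sel)
}

#' Run the occupancy workflow
#'
#' Generates the synthetic genome and IP/input pairs for two conditions,
#' calls peaks per condition, builds the consensus, calls differential
#' occupancy, assigns up/down peaks to their closest TSS (Pol III/tRNA/rRNA
#' genes removed), runs term enrichment on the up gene list against a term
#' map with the planted term, and writes metagene profiles per condition.
#' All outputs are tab-delimited text under `config$out_dir`.
#'
#' @param config an [occupancy_config()].
#' @return Invisibly, a list with the intermediate objects and the planted
#'   truth.
#' @export
run_occupancy_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  g <- config$genome
  genes <- generate_genome(g$n_chroms, g$chrom_length, g$n_genes,
                           g$frac_non_polII, seed = config$seed)
  shared <- .select_promoter_regions(genes, config$n_shared_regions,
                                     config$region_upstream,
                                     config$region_downstream)
  cond <- .select_promoter_regions(genes, config$n_condition_regions,
                                   config$region_upstream,
                                   config$region_downstream,
                                   skip = config$n_shared_regions)
  fold <- config$planted_fold
  reg_a <- data.frame(shared[c("chrom", "start", "end")], fold = fold)
  reg_b <- rbind(reg_a, data.frame(cond[c("chrom", "start", "end")], fold = fold))
  pair_a <- generate_coverage_pair(genes, reg_a, config$background_level,
                                   config$depth_ratio, config$noise,
                                   seed = config$seed + 101L)
  pair_b <- generate_coverage_pair(genes, reg_b, config$background_level,
                                   config$depth_ratio, config$noise,
                                   seed = config$seed + 202L)
  peaks_a <- call_peaks(pair_a$ip, pair_a$input, config$peak_params)
  peaks_b <- call_peaks(pair_b$ip, pair_b$input, config$peak_params)
  write_bed(peaks_a, file.path(config$out_dir, "peaks_condition_a.bed"))
  write_bed(peaks_b, file.path(config$out_dir, "peaks_condition_b.bed"))

  consensus <- build_consensus(peaks_a, peaks_b)
  diff <- differential_call(consensus, pair_a$ip, pair_b$ip,
                            config$lfc_threshold, config$diff_test,
                            config$alpha)
  write_tsv_file(diff, file.path(config$out_dir, "differential.tsv"))

  to_peaks <- function(lab) {
    d <- diff[diff$label == lab, , drop = FALSE]
    peak_set(d$chrom, d$start, d$end, d$log2fc)
  }
  asg_up <- assign_peaks(to_peaks("up"), genes)
  asg_down <- assign_peaks(to_peaks("down"), genes)
  write_tsv_file(asg_up, file.path(config$out_dir, "assignments_up.tsv"))
  write_tsv_file(asg_down, file.path(config$out_dir, "assignments_down.tsv"))

  universe <- filter_genes(genes, TRUE)$gene_id
  term_map <- generate_term_map(genes,
                                n_terms = config$enrichment$n_terms,
                                genes_per_term = config$enrichment$genes_per_term,
                                planted_term = list(term = "TERM_PLANTED",
                                                    members = cond$gene_id),
                                seed = config$seed + 303L)
  up_genes <- intersect(assigned_genes(asg_up), universe)
  enr <- term_enrichment(up_genes, universe, term_map,
                         p_cutoff = config$enrichment$p_cutoff,
                         min_k = config$enrichment$min_k)
  write_tsv_file(enr, file.path(config$out_dir, "enrichment.tsv"))

  mg <- config$metagene
  polII <- filter_genes(genes, TRUE)
  mg_a <- metagene_profile(pair_a$ip, polII, "tss_anchored",
                           flank = mg$flank, smooth_window = mg$smooth_window)
  mg_b <- metagene_profile(pair_b$ip, polII, "tss_anchored",
                           flank = mg$flank, smooth_window = mg$smooth_window)
  write_tsv_file(mg_a, file.path(config$out_dir, "metagene_condition_a.tsv"))
  write_tsv_file(mg_b, file.path(config$out_dir, "metagene_condition_b.tsv"))

  log_lines <- c(
    "chipfold occupancy pipeline",
    paste0("seed: ", config$seed,
           " (coverage A: +101, coverage B: +202, term map: +303)"),
    paste0("genome: ", g$n_chroms, " x ", g$chrom_length, " bases, ",
           g$n_genes, " genes, frac_non_polII ", g$frac_non_polII),
    paste0("noise: ", config$noise, ", background ", config$background_level,
           ", depth_ratio ", config$depth_ratio),
    paste0("peak params: fold ", config$peak_params$fold_threshold,
           ", min_run ", config$peak_params$min_run,
           ", merge_gap ", config$peak_params$merge_gap),
    paste0("peaks condition A: ", nrow(peaks_a),
           "; condition B: ", nrow(peaks_b),
           "; consensus: ", nrow(consensus)),
    paste0("differential: up ", sum(diff$label == "up"),
           ", down ", sum(diff$label == "down"),
           ", unchanged ", sum(diff$label == "unchanged")),
    paste0("up gene list: ", length(up_genes),
           "; enriched terms included: ", sum(enr$included))
  )
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))

  invisible(list(genes = genes, peaks_a = peaks_a, peaks_b = peaks_b,
                 consensus = consensus, differential = diff,
                 assignments_up = asg_up, assignments_down = asg_down,
                 enrichment = enr, metagene_a = mg_a, metagene_b = mg_b,
                 truth = list(condition_regions = cond,
                              shared_regions = shared,
                              enriched_term = "TERM_PLANTED")))
}

#' Default expression-pipeline configuration
#'
#' Study conditions for the synthetic RNA-seq arm: the same 100-gene genome,
#' 3 samples per group, baseline mean 200, 15 genes planted up and 15 down
#' (|log2FC| = 2) upon the condition shift, a mutant that reverts 80% of the
#' condition response, and promoter occupancy scaled with expression rank so
#' the quantile-stratified metagene ordering is testable.
#'
#' @inheritParams occupancy_config
#' @export
expression_config <- function(out_dir, seed = 1, overrides = list()) {
  cfg <- list(
    out_dir = out_dir, seed = as.integer(seed),
    genome = list(n_chroms = 1, chrom_length = 500000L, n_genes = 100,
                  frac_non_polII = 0.1),
    n_samples_per_group = 3, baseline_mean = 200, dispersion = 0,
    n_up = 15, n_down = 15, planted_lfc = 2, mutant_reversion = 0.8,
    n_quantiles = 5,
    de = list(lfc_threshold = 1, alpha = 0.05),
    metagene = list(flank = 1000L, smooth_window = 101L),
    background_level = 50
  )
  utils::modifyList(cfg, overrides)
}

#' Run the expression workflow
#'
#' Generates two-group (condition) counts for wild type and a mutant that
#' partially reverts the condition response; computes RPKM, expression
#' quantile groups in the shifted condition, quantile-stratified metagene
#' profiles over a coverage track whose promoter enrichment grows with
#' expression, the differential-expression table, and the
#' condition-vs-mutant dependence scatter.
#'
#' @param config an [expression_config()].
#' @return Invisibly, a list of intermediates including the scatter
#'   correlation `r`.
#' @export
run_expression_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  g <- config$genome
  genes <- generate_genome(g$n_chroms, g$chrom_length, g$n_genes,
                           g$frac_non_polII, seed = config$seed)
  ids <- genes$gene_id
  polII_ids <- filter_genes(genes, TRUE)$gene_id
  up <- polII_ids[seq_len(config$n_up)]
  down <- polII_ids[config$n_up + seq_len(config$n_down)]
  cond_lfc <- stats::setNames(
    c(rep(config$planted_lfc, length(up)), rep(-config$planted_lfc, length(down))),
    c(up, down))
  wt <- generate_counts(genes, config$n_samples_per_group,
                        config$baseline_mean, cond_lfc, config$dispersion,
                        seed = config$seed + 11L,
                        group_names = c("glu_wt", "gly_wt"))
  full_lfc <- stats::setNames(rep(0, length(ids)), ids)
  full_lfc[names(cond_lfc)] <- cond_lfc
  gly_means <- stats::setNames(rep(config$baseline_mean, length(ids)) *
                                 2^full_lfc, ids)
  mut_lfc <- -config$mutant_reversion * cond_lfc
  mut <- generate_counts(genes, config$n_samples_per_group, gly_means,
                         mut_lfc, config$dispersion,
                         seed = config$seed + 22L,
                         group_names = c("gly_wt2", "gly_mut"))

  rpkm_tab <- data.frame(gene = rownames(wt$expr$rpkm), wt$expr$rpkm,
                         stringsAsFactors = FALSE, row.names = NULL)
  write_tsv_file(rpkm_tab, file.path(config$out_dir, "rpkm.tsv"))

  gly_cols <- wt$expr$group == "gly_wt"
  gly_rpkm <- rowMeans(wt$expr$rpkm[, gly_cols, drop = FALSE])[polII_ids]
  grp <- quantile_groups(gly_rpkm, config$n_quantiles)
  write_tsv_file(data.frame(gene = names(grp), quantile = grp,
                            rpkm_gly = gly_rpkm, row.names = NULL),
                 file.path(config$out_dir, "quantiles.tsv"))

  # promoter occupancy scaled with expression quantile (fold 1.2 ... 3.6)
  mg <- config$metagene
  # plant a promoter region for every Pol II gene whose window fits without
  # touching a previously placed one; quantile profiles are computed over
  # the genes that received a region
  reg <- .select_promoter_regions(genes, Inf, 200L, 300L, spacing = 1L)
  reg$fold <- 1.2 + 0.6 * (grp[reg$gene_id] - 1)
  pair <- generate_coverage_pair(genes, reg[c("chrom", "start", "end", "fold")],
                                 config$background_level, noise = "none")
  prof <- lapply(seq_len(config$n_quantiles), function(q) {
    sub <- genes[genes$gene_id %in% names(grp)[grp == q] &
                   genes$gene_id %in% reg$gene_id, , drop = FALSE]
    p <- metagene_profile(pair$ip, sub, "tss_anchored", flank = mg$flank,
                          smooth_window = mg$smooth_window)
    data.frame(quantile = q, p)
  })
  write_tsv_file(do.call(rbind, prof),
                 file.path(config$out_dir, "quantile_profiles.tsv"))

  de <- de_genes(wt$expr, lfc_threshold = config$de$lfc_threshold,
                 alpha = config$de$alpha)
  write_tsv_file(de, file.path(config$out_dir, "de.tsv"))

  glu_pooled <- rowSums(wt$expr$counts[, !gly_cols, drop = FALSE])
  gly_pooled <- rowSums(wt$expr$counts[, gly_cols, drop = FALSE])
  mut_pooled <- rowSums(mut$expr$counts[, mut$expr$group == "gly_mut",
                                        drop = FALSE])
  sc <- dependence_scatter(glu_pooled, gly_pooled, mut_pooled)
  write_tsv_file(data.frame(gene = sc$genes, x = sc$x, y = sc$y,
                            row.names = NULL),
                 file.path(config$out_dir, "scatter.tsv"))

  writeLines(c(
    "chipfold expression pipeline",
    paste0("seed: ", config$seed, " (WT counts: +11, mutant counts: +22)"),
    paste0("genes: ", length(ids), "; Pol II: ", length(polII_ids)),
    paste0("planted: ", length(up), " up / ", length(down),
           " down at |log2FC| ", config$planted_lfc,
           "; mutant reversion ", config$mutant_reversion),
    paste0("DE genes called: ", sum(de$de)),
    paste0("dependence scatter r: ", format(sc$r, digits = 6))
  ), file.path(config$out_dir, "run_log.txt"))

  invisible(list(genes = genes, wt = wt, mut = mut, quantiles = grp,
                 de = de, scatter = sc,
                 truth = list(de_up = up, de_down = down)))
}

#' Chronological-lifespan viability from colony counts
#'
#' Colony-forming-unit viability normalized to the reference day: each day's
#' percentage is `100 * count / count[reference_day]`, with the reference day
#' itself at 100%.
#'
#' @param colony_counts non-negative counts named by day number.
#' @param reference_day day whose count defines 100% (default 3).
#' @return Named numeric vector of per-day percentages.
#' @examples
#' cfu_viability(c(`3` = 200, `7` = 100, `10` = 30))
#' @export
cfu_viability <- function(colony_counts, reference_day = 3) {
  days <- names(colony_counts)
  if (is.null(days)) stop("colony_counts must be named by day")
  if (any(colony_counts < 0)) stop("colony counts must be >= 0")
  ref <- as.character(reference_day)
  if (!ref %in% days) stop("reference day ", ref, " absent from counts")
  if (colony_counts[[ref]] == 0) stop("reference-day colony count is zero")
  100 * colony_counts / colony_counts[[ref]]
}
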