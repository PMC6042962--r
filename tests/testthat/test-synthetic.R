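test_that("generate_genome packs disjoint genes with the requested biotype mix", {
  genes <- generate_genome(n_chroms = 1, chrom_length = 100000, n_genes = 20,
                           frac_non_polII = 0.1, seed = 0)
  expect_equal(nrow(genes), 20)
  expect_equal(sum(genes$polymerase != "PolII" |
                     genes$biotype %in% c("tRNA", "rRNA")), 2)
  ord <- genes[order(genes$chrom, genes$start), ]
  expect_true(all(ord$start[-1] >= ord$end[-nrow(ord)] |
                    ord$chrom[-1] != ord$chrom[-nrow(ord)]))
  # determinism and the all-Pol-II degenerate case
  expect_identical(genes, generate_genome(1, 100000, 20, 0.1, seed = 0))
  all_pol2 <- generate_genome(1, 100000, 20, 0, seed = 0)
  expect_true(all(all_pol2$polymerase == "PolII"))
  expect_true(all(all_pol2$biotype == "protein_coding"))
})

test_that("infeasible gene packing errors with advice", {
  expect_error(generate_genome(1, 2000, 50, 0, seed = 1), "chrom_length")
})

test_that("noise-free coverage pairs realise the planted fold exactly", {
  genes <- tiny_genome()
  pr <- data.frame(chrom = "chr1", start = 1000, end = 1500, fold = 3)
  sim <- generate_coverage_pair(genes, pr, background_level = 50,
                                depth_ratio = 1, noise = "none")
  ratio <- sim$ip$values$chr1 / sim$input$values$chr1
  expect_equal(ratio[1001:1500], rep(3, 500))
  expect_equal(ratio[-(1001:1500)], rep(1, 100000 - 500))

  # depth_ratio scales the raw per-base ratio everywhere
  sim2 <- generate_coverage_pair(genes, pr, 50, depth_ratio = 2, noise = "none")
  ratio2 <- sim2$ip$values$chr1 / sim2$input$values$chr1
  expect_equal(ratio2, 2 * ratio)
})

test_that("overlapping or out-of-genome planted regions are rejected", {
  genes <- tiny_genome()
  bad <- data.frame(chrom = "chr1", start = c(100, 300), end = c(500, 600),
                    fold = c(2, 3))
  expect_error(generate_coverage_pair(genes, bad, noise = "none"), "overlap")
  out <- data.frame(chrom = "chr1", start = 99900, end = 100500, fold = 3)
  expect_error(generate_coverage_pair(genes, out, noise = "none"),
               "inside the genome")
})

test_that("Poisson coverage reproduces the planted enrichment in expectation", {
  genes <- tiny_genome()
  pr <- data.frame(chrom = "chr1", start = 5000, end = 5500, fold = 3)
  sim <- generate_coverage_pair(genes, pr, background_level = 50,
                                noise = "poisson", seed = 4)
  idx <- 5001:5500
  obs <- mean((sim$ip$values$chr1[idx] + 1) / (sim$input$values$chr1[idx] + 1))
  expect_lt(abs(obs - 3) / 3, 0.1)
  # determinism under a fixed seed
  sim_b <- generate_coverage_pair(genes, pr, 50, noise = "poisson", seed = 4)
  expect_identical(sim_b$ip$values, sim$ip$values)
})

test_that("generate_counts hits its planted group means", {
  genes <- tiny_genome(n_genes = 20)
  lfc <- stats::setNames(1, genes$gene_id[1])
  sim <- generate_counts(genes, n_samples_per_group = 50, baseline_mean = 100,
                         planted_log2fc = lfc, dispersion = 0, seed = 5)
  cnt <- sim$expr$counts
  ga <- sim$expr$group == levels(sim$expr$group)[1]
  # null genes: both group means equal within Poisson error at n = 50
  null_a <- rowMeans(cnt[-1, ga]); null_b <- rowMeans(cnt[-1, !ga])
  expect_lt(max(abs(null_a - null_b)) / 100, 0.15)
  # the planted gene doubles
  expect_lt(abs(mean(cnt[1, !ga]) / mean(cnt[1, ga]) - 2) / 2, 0.1)
  expect_equal(sim$truth$de_up, genes$gene_id[1])
  expect_identical(sim$expr$counts,
                   generate_counts(genes, 50, 100, lfc, 0, seed = 5)$expr$counts)
})

test_that("expression matrices record library sizes and RPKM consistently", {
  genes <- tiny_genome(n_genes = 5)
  sim <- generate_counts(genes, 2, 100, seed = 1)
  em <- sim$expr
  expect_equal(em$library_sizes, colSums(em$counts))
  expect_equal(em$rpkm,
               em$counts / outer(em$gene_lengths / 1e3, em$library_sizes / 1e6))
})

test_that("term maps reproduce the planted term exactly and are seed-stable", {
  genes <- tiny_genome(n_genes = 50)
  members <- genes$gene_id[1:10]
  tm <- generate_term_map(genes, n_terms = 20, genes_per_term = 8,
                          planted_term = list(term = "T_P", members = members),
                          seed = 9)
  expect_setequal(tm$gene_id[tm$term_id == "T_P"], members)
  expect_identical(tm, generate_term_map(genes, 20, 8,
                                         list(term = "T_P", members = members),
                                         seed = 9))
  expect_error(generate_term_map(genes, 5, 3,
                                 list(term = "T", members = "nope"), seed = 1),
               "not in gene set")
})
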