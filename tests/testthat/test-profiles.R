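test_that("moving-average smoothing has the stated fixed points and edges", {
  expect_equal(smooth_mean(rep(4, 300), 101), rep(4, 300))
  v <- rnorm(50)
  expect_equal(smooth_mean(v, 1), v)
  # an impulse of height 101 spreads into a plateau of exactly 1
  imp <- rep(0, 501); imp[251] <- 101
  sm <- smooth_mean(imp, 101)
  expect_equal(sm[201:301], rep(1, 101))
  expect_equal(sum(sm > 0), 101)
  expect_error(smooth_mean(v, 100), "odd")
})

test_that("smoothing matches a naive windowed-mean loop, including NA handling", {
  set.seed(5)
  v <- rnorm(120)
  v[sample(120, 10)] <- NA
  w <- 21; h <- 10
  naive <- vapply(seq_along(v), function(i) {
    win <- v[max(1, i - h):min(length(v), i + h)]
    if (all(is.na(win))) NA_real_ else mean(win, na.rm = TRUE)
  }, numeric(1))
  expect_equal(smooth_mean(v, w), naive)
})

test_that("TSS-anchored profiles are oriented 5'->3' and NA off the chromosome", {
  # track value = genomic coordinate makes orientation visible
  trk <- coverage_track(list(c1 = as.numeric(0:9999)))
  gplus <- gene_table("g+", "c1", 5000, 6000, "+")[1, ]
  p <- anchored_profile(trk, gplus, flank = 100)
  expect_equal(p, as.numeric(4900:5100))
  gminus <- gene_table("g-", "c1", 4000, 5001, "-")[1, ]
  m <- anchored_profile(trk, gminus, flank = 100)
  expect_equal(m, as.numeric(5100:4900))   # descending: orientation flip
  # gene 100 bases from the chromosome start: first 1900 positions missing
  gedge <- gene_table("ge", "c1", 100, 1100, "+")[1, ]
  pe <- anchored_profile(trk, gedge, flank = 2000)
  expect_equal(sum(is.na(pe)), 1900)
  expect_true(all(is.na(pe[1:1900])))
})

test_that("transcript scaling is the identity at matching length and exact on ramps", {
  trk <- coverage_track(list(c1 = as.numeric(0:9999)))
  g <- gene_table("g", "c1", 2000, 3000, "+")[1, ]
  sp <- scaled_profile(trk, g, flank = 100, body_points = 1000)
  expect_equal(sp[101:1100], as.numeric(2000:2999))   # body length == grid
  expect_equal(sp[1:100], as.numeric(1900:1999))

  # constant body stays constant at any resampling
  cst <- coverage_track(list(c1 = rep(7, 10000)))
  expect_equal(scaled_profile(cst, g, 50, 333)[51:383], rep(7, 333))

  # a linear ramp resamples onto the new grid in closed form
  g2 <- gene_table("g2", "c1", 2000, 2500, "+")[1, ]
  sp2 <- scaled_profile(trk, g2, flank = 0, body_points = 200)
  expect_equal(sp2, 2000 + (seq(1, 500, length.out = 200) - 1))
})

test_that("metagene averaging equals a per-position loop and honours symmetry", {
  set.seed(31)
  m <- matrix(rnorm(50 * 40), nrow = 50)
  m[sample(length(m), 60)] <- NA
  prof <- metagene_average(m)
  naive_mean <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    if (all(is.na(col))) NA_real_ else mean(col, na.rm = TRUE)
  }, numeric(1))
  expect_equal(prof$mean_signal, naive_mean)
  expect_equal(prof$n_genes, colSums(!is.na(m)))

  p <- rnorm(30)
  expect_equal(metagene_average(rbind(p, -p))$mean_signal, rep(0, 30))
  expect_error(metagene_average(m[0, ]), "at least one gene")
})

test_that("identical genes reduce the metagene to the single smoothed profile", {
  set.seed(17)
  vals <- as.numeric(rpois(20000, 10))
  trk <- coverage_track(list(c1 = vals))
  genes <- gene_table(paste0("g", 1:5), "c1", rep(9000, 5), rep(10000, 5), "+")
  prof <- metagene_profile(trk, genes, "tss_anchored", flank = 500,
                           smooth_window = 101)
  single <- smooth_mean(anchored_profile(trk, genes[1, ], 500), 101)
  expect_equal(prof$mean_signal, single)
  expect_equal(prof$n_genes, rep(5, 1001))
})

test_that("RPKM follows its definition and scaling laws", {
  expect_equal(rpkm(10, 1000, 1e6), 10)
  expect_equal(rpkm(10, 1000, 2e6), 5)      # doubling depth halves RPKM
  expect_equal(rpkm(10, 2000, 1e6), 5)      # doubling length halves RPKM
  cnt <- matrix(c(10, 20, 30, 40), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  r <- rpkm(cnt, c(1000, 500), c(1e6, 2e6))
  expect_equal(r["a", "s1"], 10)
  expect_equal(r["b", "s2"], 40 / (0.5 * 2))
  expect_error(rpkm(10, 0, 1e6), "> 0")
})

test_that("quantile grouping is a deterministic balanced partition", {
  v <- stats::setNames(runif(10), paste0("g", 1:10))
  g5 <- quantile_groups(v, 5)
  expect_equal(as.vector(table(g5)), rep(2, 5))
  v11 <- stats::setNames(runif(11), paste0("g", 1:11))
  expect_equal(as.vector(table(quantile_groups(v11, 5))), c(3, 2, 2, 2, 2))
  # group 1 holds the lowest values
  expect_equal(sort(names(v)[g5 == 1]), sort(names(sort(v)[1:2])))
  # ties broken by name: stable under permutation of input order
  vt <- stats::setNames(rep(1, 6), paste0("g", 1:6))
  expect_equal(quantile_groups(vt, 3)[paste0("g", 1:6)],
               quantile_groups(vt[c(4, 2, 6, 1, 3, 5)], 3)[paste0("g", 1:6)])
  expect_error(quantile_groups(v[1:3], 5), "fewer genes")
})

test_that("the conditional binomial DE test is null-safe and recovers planted effects", {
  genes <- tiny_genome(n_genes = 40)
  sim <- generate_counts(genes, 3, 150, dispersion = 0, seed = 13)
  cnt <- sim$expr$counts
  # identical columns duplicated across groups: exact null, zero DE genes
  dup <- cbind(cnt[, 1:3], cnt[, 1:3])
  colnames(dup) <- paste0("s", 1:6)
  de0 <- de_genes(dup, factor(rep(c("A", "B"), each = 3)))
  expect_equal(sum(de0$de), 0)
  expect_equal(de0$log2fc, rep(0, nrow(dup)))

  lfc <- stats::setNames(rep(3, 5), genes$gene_id[1:5])
  sim2 <- generate_counts(genes, 3, 200, planted_log2fc = lfc,
                          dispersion = 0, seed = 14)
  de <- de_genes(sim2$expr)
  # all planted genes recovered; strong one-sided planting shifts the
  # library-size offsets, so a few null genes may also pass (documented
  # limitation of total-count normalisation)
  expect_true(all(de$de[de$gene %in% names(lfc)]))
  expect_gte(sum(de$de), 5)
  expect_error(de_genes(cnt, factor(rep("A", 6))), "two groups")
})

test_that("dependence scatter handles degenerate and anti-identity constructions", {
  ids <- paste0("g", 1:50)
  glu <- stats::setNames(rpois(50, 500) + 100, ids)
  gly <- stats::setNames(round(glu * 2^seq(-2, 2, length.out = 50)), ids)
  # mutant identical to WT in the shifted condition: y = 0, r undefined
  expect_warning(sc0 <- dependence_scatter(glu, gly, gly), "zero variance")
  expect_equal(unname(sc0$y), rep(0, 50))
  expect_true(is.na(sc0$r))
  # equal library sizes and mutant == unshifted WT: y = -x exactly, r = -1
  sc <- dependence_scatter(glu, gly, glu,
                           library_sizes = c(1e6, 1e6, 1e6))
  expect_equal(unname(sc$y), unname(-sc$x))
  expect_equal(sc$r, -1, tolerance = 1e-12)
  expect_error(dependence_scatter(glu, gly, glu, gene_subset = "ghost"),
               "absent")
})

test_that("a planted partial reversion yields the analytic correlation", {
  set.seed(41)
  n <- 500
  ids <- paste0("g", seq_len(n))
  x_true <- rnorm(n, sd = 1)
  e <- rnorm(n, sd = 0.5)
  glu <- stats::setNames(rep(2000, n), ids)
  gly <- stats::setNames(glu * 2^x_true, ids)
  mut <- stats::setNames(gly * 2^(-0.5 * x_true + e), ids)
  sc <- dependence_scatter(glu, gly, mut,
                           library_sizes = rep(sum(glu), 3))
  r_analytic <- -0.5 * stats::sd(x_true) /
    sqrt(0.25 * stats::var(x_true) + 0.25)
  expect_lt(abs(sc$r - r_analytic), 0.1)
  expect_lt(sc$r, 0)
})
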