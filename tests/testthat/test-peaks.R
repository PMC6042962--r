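test_that("depth normalization scales both tracks to the mean total", {
  ip <- coverage_track(list(chr1 = rep(4, 500000)))       # total 2e6
  input <- coverage_track(list(chr1 = rep(2, 500000)))    # total 1e6
  pair <- normalize_pair(ip, input)
  expect_equal(pair$ip$total_signal, 1.5e6)
  expect_equal(pair$input$total_signal, 1.5e6)
  # equal totals: identity
  pair2 <- normalize_pair(input, input)
  expect_equal(pair2$ip$values, input$values)
  expect_error(normalize_pair(ip, coverage_track(list(chr1 = rep(0, 500000)))),
               "zero total")
})

test_that("fold_change_track applies the pseudocount per base", {
  a <- coverage_track(list(c1 = c(5, 0, 2)))
  b <- coverage_track(list(c1 = c(1, 0, 2)))
  r <- fold_change_track(a, b, pseudocount = 1)
  expect_equal(r$values$c1, c(3, 1, 1))
  expect_error(fold_change_track(a, coverage_track(list(c2 = c(1, 1, 1)))),
               "same chromosomes")
})

test_that("raw peak calling keeps only sustained threshold runs", {
  base <- rep(1, 1000)
  expect_equal(nrow(call_raw_peaks(coverage_track(list(c1 = base)), 2, 50)), 0)

  v <- base; v[101:160] <- 2.5            # 60-base run
  pk <- call_raw_peaks(coverage_track(list(c1 = v)), 2, 50)
  expect_equal(nrow(pk), 1)
  expect_equal(c(pk$start, pk$end), c(100L, 160L))
  expect_equal(pk$score, 2.5)

  v49 <- base; v49[101:149] <- 3          # 49-base run: below min_run
  expect_equal(nrow(call_raw_peaks(coverage_track(list(c1 = v49)), 2, 50)), 0)
})

test_that("merging uses a strict gap inequality at the 400-base boundary", {
  near <- peak_set(c("c1", "c1"), c(100, 599), c(200, 700), c(2, 4))
  m <- merge_peaks(near, 400)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end), c(100L, 700L))
  # merged score is the length-weighted mean of member scores
  expect_equal(m$score, (2 * 100 + 4 * 101) / 201)

  at <- peak_set(c("c1", "c1"), c(100, 600), c(200, 700), c(2, 4))
  expect_equal(nrow(merge_peaks(at, 400)), 2)
})

test_that("chained peaks collapse to the pairwise fixed point and merging is idempotent", {
  starts <- seq(0, by = 400, length.out = 6)   # 100-base peaks 300 apart
  chain <- peak_set(rep("c1", 6), starts, starts + 100, rep(2, 6))
  m <- merge_peaks(chain, 400)
  oracle <- merge_fixed_point_oracle(as.data.frame(chain), 400)
  expect_equal(nrow(m), nrow(oracle))
  expect_equal(m$start, oracle$start)
  expect_equal(m$end, oracle$end)
  expect_equal(nrow(m), 1)

  for (seed in 1:5) {
    p <- random_peak_set(30, seed = seed)
    m1 <- merge_peaks(p, 500)
    expect_equal(as.data.frame(merge_peaks(m1, 500)), as.data.frame(m1))
    gaps <- m1$start[-1] - m1$end[-nrow(m1)]
    expect_true(all(gaps >= 500))
    orc <- merge_fixed_point_oracle(as.data.frame(p), 500)
    expect_equal(m1$start, orc$start)
    expect_equal(m1$end, orc$end)
  }
})

test_that("stricter thresholds never enlarge the called peak set", {
  genes <- tiny_genome()
  pr <- data.frame(chrom = "chr1", start = c(5000, 20000, 40000),
                   end = c(5600, 20300, 40900), fold = c(3, 2.5, 4))
  sim <- generate_coverage_pair(genes, pr, 50, noise = "poisson", seed = 2)
  covered <- function(pk) sum(pk$end - pk$start)
  base <- call_peaks(sim$ip, sim$input, peak_params())
  for (thr in c(2.5, 3, 3.5)) {
    pk <- call_peaks(sim$ip, sim$input, peak_params(fold_threshold = thr))
    expect_lte(covered(pk), covered(base))
  }
  for (mr in c(100, 200, 400)) {
    pk <- call_peaks(sim$ip, sim$input, peak_params(min_run = mr))
    expect_lte(covered(pk), covered(base))
  }
  n_base <- nrow(call_peaks(sim$ip, sim$input, peak_params(merge_gap = 0)))
  for (gp in c(200, 400, 2000)) {
    pk <- call_peaks(sim$ip, sim$input, peak_params(merge_gap = gp))
    expect_lte(nrow(pk), n_base)
  }
})

test_that("noise-free calling recovers planted regions base-for-base", {
  genes <- tiny_genome()
  pr <- data.frame(chrom = "chr1", start = c(10000, 50000),
                   end = c(10500, 50500), fold = c(3, 1.5))
  sim <- generate_coverage_pair(genes, pr, 50, noise = "none")
  pk <- call_peaks(sim$ip, sim$input)
  expect_equal(nrow(pk), 1)                 # fold 1.5 < threshold 2
  expect_equal(c(pk$start, pk$end), c(10000L, 10500L))

  # two fold-3 regions 300 bases apart merge into one spanning peak
  pr2 <- data.frame(chrom = "chr1", start = c(10000, 10800),
                    end = c(10500, 11300), fold = 3)
  sim2 <- generate_coverage_pair(genes, pr2, 50, noise = "none")
  pk2 <- call_peaks(sim2$ip, sim2$input)
  expect_equal(nrow(pk2), 1)
  expect_equal(c(pk2$start, pk2$end), c(10000L, 11300L))

  # a depth-imbalanced pair gives the same peaks after normalization
  sim3 <- generate_coverage_pair(genes, pr, 50, depth_ratio = 2, noise = "none")
  pk3 <- call_peaks(sim3$ip, sim3$input)
  expect_equal(as.data.frame(pk3)[c("start", "end")],
               as.data.frame(pk)[c("start", "end")])

  # empty signal: no peaks
  flat <- generate_coverage_pair(genes, pr[0, ], 50, noise = "none")
  expect_equal(nrow(call_peaks(flat$ip, flat$input)), 0)
})

test_that("called peak sets always satisfy the sortedness/disjointness invariant", {
  genes <- tiny_genome()
  pr <- data.frame(chrom = "chr1", start = c(3000, 30000), end = c(3500, 30700),
                   fold = c(3, 2.2))
  for (seed in 1:5) {
    sim <- generate_coverage_pair(genes, pr, 50, noise = "poisson", seed = seed)
    expect_no_error(validate_peak_set(call_peaks(sim$ip, sim$input)))
  }
})
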