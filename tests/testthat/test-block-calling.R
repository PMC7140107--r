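test_that("genome tiling covers each chromosome exactly once", {
  g <- genome_model("chr1", 12000)
  expect_equal(tile_genome(g, 5000)[, c("start", "end")],
               data.frame(start = c(0, 5000, 10000),
                          end = c(5000, 10000, 12000)))
  expect_equal(nrow(tile_genome(genome_model("chr1", 5000), 5000)), 1)
  g2 <- genome_model(c("chr1", "chr2"), c(23456, 7890))
  tl <- tile_genome(g2, 5000)
  expect_equal(interval_bases(tl, g2), genome_size(g2))
  expect_equal(sum(tl$end - tl$start), genome_size(g2))  # no overlap
})

test_that("tile differential is null for identical groups", {
  set.seed(9)
  g <- genome_model("chr1", 20000)
  vals <- matrix(runif(40 * 4, 0.6, 0.9), 40, 4)
  m <- make_methylome("chr1", sort(sample.int(19999, 40)), vals, vals)
  ts <- tile_differential(m, paste0("r", 1:4), paste0("c", 1:4), g)
  expect_true(all(abs(ts$delta) < 1e-12))
  expect_true(all(ts$p >= 0.99))
})

test_that("a planted hypomethylated tile is detected with q below 0.05", {
  set.seed(21)
  g <- genome_model("chr1", 50000)
  pos <- sort(sample.int(49999, 120))
  ref <- matrix(rnorm(120 * 4, 0.8, 0.02), 120, 4)
  case <- matrix(rnorm(120 * 4, 0.8, 0.02), 120, 4)
  planted <- pos >= 20000 & pos < 25000
  case[planted, ] <- rnorm(sum(planted) * 4, 0.4, 0.02)
  m <- make_methylome("chr1", pos, ref, case)
  ts <- tile_differential(m, paste0("r", 1:4), paste0("c", 1:4), g)
  hit <- ts[ts$start == 20000, ]
  expect_equal(hit$delta, -0.4, tolerance = 0.05)
  expect_lt(hit$q, 0.05)
  # q is Benjamini-Hochberg over emitted tiles: check against the step-up
  # formula computed by hand
  ord <- order(ts$p)
  k <- length(ts$p)
  bh <- rev(cummin(rev(ts$p[ord] * k / seq_len(k))))
  expect_equal(ts$q[ord], pmin(1, bh))
})

test_that("small groups require delta-only mode", {
  g <- genome_model("chr1", 10000)
  m <- make_methylome("chr1", c(100, 200), matrix(0.8, 2, 1),
                      matrix(0.4, 2, 1))
  expect_error(tile_differential(m, "r1", "c1", g), "delta-only")
  ts <- tile_differential(m, "r1", "c1", g, test = "none")
  expect_equal(ts$delta, -0.4)
  expect_true(is.na(ts$p))
  bl <- call_hypo_blocks(ts, block_config(min_block_cpgs = 1, use_fdr = FALSE))
  expect_equal(nrow(bl), 1)
  expect_error(call_hypo_blocks(ts, block_config(min_block_cpgs = 1)),
               "use_fdr")
})

test_that("block assembly merges by gap and filters by CpG count", {
  # two near tiles merge across their gap; a distant light tile is dropped
  ts <- data.frame(chrom = "chr1",
                   start = c(0, 5000, 300000),
                   end = c(5000, 10000, 305000),
                   n_cpgs = c(3, 4, 4),
                   mean_ref = 0.8, mean_case = 0.4,
                   delta = c(-0.40, -0.36, -0.50),
                   p = c(0.001, 0.004, 0.0001),
                   q = c(0.01, 0.04, 0.001))
  bl <- call_hypo_blocks(ts, block_config())
  expect_equal(nrow(bl), 1)
  expect_equal(bl[, c("start", "end", "n_cpgs", "n_tiles")],
               data.frame(start = 0, end = 10000, n_cpgs = 7, n_tiles = 2L))
  expect_equal(bl$mean_delta, (3 * -0.40 + 4 * -0.36) / 7)

  # no passing tile -> empty set, not an error
  ts$delta <- -0.1
  expect_equal(nrow(call_hypo_blocks(ts)), 0)
  expect_equal(nrow(call_hypo_blocks(ts[0, ])), 0)
})

test_that("threshold relaxation and merge gap behave monotonically", {
  set.seed(13)
  n <- 200
  ts <- data.frame(chrom = "chr1",
                   start = sort(sample.int(1e6, n)) * 10,
                   n_cpgs = sample.int(10, n, replace = TRUE),
                   mean_ref = 0.8,
                   delta = runif(n, -0.6, 0.1),
                   q = runif(n)^2)
  ts$end <- ts$start + 5000
  ts$mean_case <- ts$mean_ref + ts$delta
  ts$p <- ts$q / 2
  kept <- function(fdr, dlt) sum(ts$q <= fdr & ts$delta <= -dlt)
  expect_true(kept(0.10, 0.35) >= kept(0.05, 0.35))
  expect_true(kept(0.05, 0.25) >= kept(0.05, 0.35))
  cfgs <- lapply(c(1e4, 1e5, 1e6), function(gap) {
    call_hypo_blocks(ts, block_config(merge_gap = gap, min_block_cpgs = 1))
  })
  n_blocks <- vapply(cfgs, nrow, 1L)
  bases <- vapply(cfgs, function(b) sum(b$end - b$start), 1)
  expect_true(all(diff(n_blocks) <= 0))
  expect_true(all(diff(bases) >= 0))
})

test_that("a planted 600-kb region is recovered as one block", {
  cfg <- sim_config(seed = 301, n_chrom = 1, chrom_length = 5e6,
                    block_fraction = 0.12, block_length_min = 6e5,
                    block_length_max = 6e5)
  mt <- simulate_methylome(cfg)
  expect_equal(nrow(mt$truth), 1)
  ts <- tile_differential(mt$methylome, mt$samples$ref, mt$samples$case,
                          mt$genome)
  bl <- call_hypo_blocks(ts)
  expect_equal(nrow(bl), 1)
  expect_gte(jaccard_index(bl[, 1:3], mt$truth), 0.8)
})
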