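test_that("feature-in-block counting matches a per-feature scan", {
  g <- genome_model("chr1", 1e5)
  blocks <- intervals("chr1", c(10000, 50000), c(20000, 70000))
  inside <- intervals("chr1", seq(11000, 19000, 1000),
                      seq(11000, 19000, 1000) + 100)
  expect_equal(count_in_blocks(inside, blocks),
               list(n_total = 9L, n_in = 9L))
  expect_equal(count_in_blocks(inside, blocks[0, ])$n_in, 0L)

  set.seed(17)
  feats <- random_intervals(500, g, max_len = 500)
  cnt <- count_in_blocks(feats, blocks)
  mid <- floor((feats$start + feats$end) / 2)
  oracle <- sum((mid >= 10000 & mid < 20000) | (mid >= 50000 & mid < 70000))
  expect_equal(cnt$n_in, oracle)
  # any-overlap mode counts at least as many features as midpoint mode
  expect_gte(count_in_blocks(feats, blocks, mode = "any")$n_in, cnt$n_in)
})

test_that("fold enrichment is exact arithmetic on the inputs", {
  fe <- fold_enrichment(18264, 49328, 0.29)
  expect_equal(fe$fold * 0.29 * 49328, 18264)
  expect_equal(fold_enrichment(290, 1000, 0.29)$fold, 1.0)
  expect_error(fold_enrichment(0, 0, 0.29), "n_total = 0")
})

test_that("projection test reproduces exact binomial tails", {
  g <- genome_model("chr1", 1000)
  blocks <- intervals("chr1", 0, 500)  # p0 = 0.5
  feats <- intervals("chr1", seq(0, 450, 50), seq(0, 450, 50) + 10)
  res <- projection_test(feats, blocks, g)
  expect_equal(res$k, 10)
  expect_equal(res$p0, 0.5)
  expect_equal(res$p, 2 * 0.5^10)
  # degenerate coverage: consistent observation gives p = 1
  whole <- intervals("chr1", 0, 1000)
  expect_equal(projection_test(feats, whole, g)$p, 1)
})

test_that("jaccard permutation test statistic and tails behave", {
  g <- genome_model("chr1", 1e6)
  q <- intervals("chr1", c(0, 300), c(100, 500))
  expect_equal(jaccard_index(intervals("chr1", 0, 100),
                             intervals("chr1", 50, 150)), 1 / 3)
  expect_equal(jaccard_index(q, q), 1)
  cfg <- permutation_config(n_permutations = 199, seed = 5)
  self <- jaccard_test(q, q, g, cfg)
  expect_equal(self$j_obs, 1)
  expect_equal(self$perm_p, 1 / 200)
  expect_equal(self$direction, "Direct")
  # reproducible under the same seed
  again <- jaccard_test(q, q, g, cfg)
  expect_identical(self, again)
  # disjoint sparse sets on a huge genome: J = 0, depletion direction needs
  # a reference dense enough that random relocation usually hits it
  dense_ref <- intervals("chr1", seq(0, 9e5, 1e4), seq(0, 9e5, 1e4) + 9000)
  far_q <- intervals("chr1", seq(9000, 899009, 1e4), seq(9000, 899009, 1e4) + 999)
  res <- jaccard_test(far_q, dense_ref, g, cfg)
  expect_equal(res$j_obs, 0)
  expect_equal(res$direction, "Indirect")
  expect_error(jaccard_test(q[0, ], q, g, cfg), "non-empty")
})

test_that("the permutation null matches manual relocation on two chromosomes", {
  g <- genome_model(c("chr1", "chr2"), c(1e6, 6e5))
  ref <- normalize_intervals(rbind(
    intervals("chr1", seq(0, 9) * 1e5, seq(0, 9) * 1e5 + 4e4),
    intervals("chr2", seq(0, 5) * 1e5, seq(0, 5) * 1e5 + 4e4)), g)
  set.seed(55)
  query <- rbind(random_intervals(60, genome_model("chr1", 1e6 - 3000), 3000),
                 {
                   q2 <- random_intervals(40, genome_model("chr2", 6e5 - 3000),
                                          3000)
                   q2$chrom <- "chr2"; q2
                 })
  jp <- hypoblocks:::jaccard_null(query[, c("chrom", "start", "end")], ref, g,
                                  300, seed = 8)
  # manual oracle: relocate each interval uniformly within its chromosome and
  # recompute J with the GRanges-backed index
  set.seed(8)
  qlen <- query$end - query$start
  clen <- c(chr1 = 1e6, chr2 = 6e5)[query$chrom]
  man <- replicate(300, {
    s <- floor(runif(nrow(query)) * (clen - qlen + 1))
    jaccard_index(intervals(query$chrom, s, s + qlen), ref)
  })
  expect_equal(mean(jp), mean(man), tolerance = 0.03)
  expect_equal(sd(jp), sd(man), tolerance = 0.25)
})

test_that("enrichment table recovers planted track enrichment", {
  cfg <- sim_config(seed = 88, n_chrom = 2, chrom_length = 5e6,
                    block_fraction = 0.2,
                    tracks = list(
                      list(name = "planted2x", n = 10000, length = 200,
                           enrichment = 2),
                      list(name = "flat", n = 5000, length = 200,
                           enrichment = 1)))
  g <- sim_genome(cfg)
  mt <- simulate_methylome(cfg)
  tr <- simulate_tracks(cfg, mt$truth, g)
  tab <- enrich_table(mt$truth, tr, g,
                      cfg = permutation_config(200, seed = 2))
  p2 <- tab[tab$feature == "planted2x", ]
  expect_equal(p2$fold, 2, tolerance = 0.15 / 2)
  expect_equal(p2$direction, "Direct")
  expect_lt(p2$p, 0.05)
  flat <- tab[tab$feature == "flat", ]
  expect_equal(flat$fold, 1, tolerance = 0.1)
  # the exact identity fold * genome_fraction * n_total = n_in
  expect_equal(tab$fold * tab$genome_fraction * tab$n_total, tab$n_in)
})

test_that("uniform tracks are rarely called significant", {
  g <- genome_model("chr1", 2e6)
  blocks <- intervals("chr1", c(2e5, 9e5, 15e5), c(4e5, 11e5, 17e5))
  rejections <- 0
  for (s in 1:20) {
    set.seed(400 + s)
    pos <- floor(runif(500) * (2e6 - 100))
    feats <- intervals("chr1", pos, pos + 100)
    if (projection_test(feats, blocks, g)$p < 0.05) rejections <- rejections + 1
  }
  expect_lte(rejections, 3)  # >= 90% of seeds non-significant under the null
})
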