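test_that("all generators are deterministic under the seed", {
  cfg <- sim_config(seed = 11, n_chrom = 1, chrom_length = 2e6,
                    tracks = list(list(name = "t", n = 200, length = 500,
                                       enrichment = 2)),
                    expression = list(n_genes = 50, base_mean = 8, base_sd = 1,
                                      noise_sd = 0.3, inblock_sd_multiplier = 2,
                                      group_effects = c(MKI67 = 1),
                                      signature = list(genes = "CIN25_01",
                                                       shift_mean = 0.5,
                                                       shift_sd = 0.1)))
  a <- simulate_methylome(cfg); b <- simulate_methylome(cfg)
  expect_identical(a, b)
  expect_identical(simulate_tracks(cfg, a$truth, a$genome),
                   simulate_tracks(cfg, a$truth, a$genome))
  expect_identical(simulate_cna(cfg, a$truth, a$genome),
                   simulate_cna(cfg, a$truth, a$genome))
  expect_identical(simulate_expression(cfg, a$truth, a$genome),
                   simulate_expression(cfg, a$truth, a$genome))
  # a different seed changes the data
  expect_false(identical(a$methylome,
                         simulate_methylome(sim_config(
                           seed = 12, n_chrom = 1, chrom_length = 2e6))$methylome))
})

test_that("a zero planted delta leaves the groups indistinguishable", {
  cfg <- sim_config(seed = 21, n_chrom = 1, chrom_length = 2e6,
                    delta_min = 0, delta_max = 0)
  mt <- simulate_methylome(cfg)
  ref_mean <- rowMeans(mt$methylome[, mt$samples$ref])
  case_mean <- rowMeans(mt$methylome[, mt$samples$case])
  expect_lt(abs(mean(case_mean) - mean(ref_mean)), 0.01)
})

test_that("planted block coverage matches the requested genome fraction", {
  for (s in 1:5) {
    cfg <- sim_config(seed = 30 + s, n_chrom = 2, chrom_length = 25e6,
                      block_fraction = 0.15)
    mt <- simulate_methylome(cfg)
    expect_equal(coverage_fraction(mt$truth, mt$genome), 0.15,
                 tolerance = 0.02 / 0.15)
  }
})

test_that("track placement matches the requested enrichment factor", {
  cfg <- sim_config(seed = 41, n_chrom = 2, chrom_length = 1e7,
                    block_fraction = 0.15,
                    tracks = list(
                      list(name = "f3", n = 10000, length = 300,
                           enrichment = 3),
                      list(name = "f1", n = 10000, length = 300,
                           enrichment = 1),
                      list(name = "none", n = 0, length = 300,
                           enrichment = 1)))
  g <- sim_genome(cfg)
  mt <- simulate_methylome(cfg)
  tr <- simulate_tracks(cfg, mt$truth, g)
  cvg <- coverage_fraction(mt$truth, g)
  fold <- function(x) {
    cnt <- count_in_blocks(x, mt$truth)
    (cnt$n_in / cnt$n_total) / cvg
  }
  expect_equal(fold(tr$f3), 3, tolerance = 0.15)
  expect_equal(fold(tr$f1), 1, tolerance = 0.15)
  expect_equal(nrow(tr$none), 0)
})

test_that("unit CNA concentration gives equal in/out densities", {
  ratios <- numeric(5)
  for (s in 1:5) {
    cfg <- sim_config(seed = 50 + s, n_chrom = 2, chrom_length = 1e7,
                      cna = list(altered_fraction_ref = 0.15,
                                 altered_fraction_case = 0.15,
                                 segment_length = 5e4, concentration = 1))
    g <- sim_genome(cfg)
    mt <- simulate_methylome(cfg)
    segs <- simulate_cna(cfg, mt$truth, g)
    ratios[s] <- cna_block_overlap(segs, mt$truth, g)$density_ratio
  }
  expect_equal(mean(ratios), 1, tolerance = 0.15)
})

test_that("expression generator plants in-block variability and effects", {
  cfg <- sim_config(seed = 61, n_chrom = 2, chrom_length = 1e7,
                    block_fraction = 0.2,
                    expression = list(n_genes = 2000, base_mean = 8,
                                      base_sd = 1, noise_sd = 0.3,
                                      inblock_sd_multiplier = 2,
                                      group_effects = c(MKI67 = 1.5),
                                      signature = list(
                                        genes = sprintf("CIN25_%02d", 1:25),
                                        shift_mean = 0.8, shift_sd = 0.1)))
  g <- sim_genome(cfg)
  mt <- simulate_methylome(cfg)
  xp <- simulate_expression(cfg, mt$truth, g)
  mid <- interval_midpoints(xp$coords)
  in_block <- mid$pos >= 0 &
    sapply(seq_len(nrow(xp$coords)), function(i) {
      any(mt$truth$chrom == mid$chrom[i] & mt$truth$start <= mid$pos[i] &
            mt$truth$end > mid$pos[i])
    })
  case <- xp$expr[, grep("^case_", colnames(xp$expr))]
  sds <- apply(case - rowMeans(case), 1, sd)
  expect_equal(median(sds[in_block]) / median(sds[!in_block]), 2,
               tolerance = 0.2)
  expect_gt(mean(xp$expr["MKI67", grep("^case_", colnames(xp$expr))]) -
              mean(xp$expr["MKI67", grep("^ref_", colnames(xp$expr))]), 1)
})
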