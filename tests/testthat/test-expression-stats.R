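test_that("zero prior reduces the regularized t to the pooled t-test", {
  set.seed(71)
  m <- matrix(rnorm(300 * 8, 8, 1), 300, 8,
              dimnames = list(sprintf("g%03d", 1:300),
                              c(paste0("r", 1:4), paste0("c", 1:4))))
  rt <- regularized_t(m, paste0("r", 1:4), paste0("c", 1:4), prior_df = 0)
  oracle_t <- oracle_p <- numeric(300)
  for (i in 1:300) {
    tt <- t.test(m[i, 5:8], m[i, 1:4], var.equal = TRUE)
    oracle_t[i] <- unname(tt$statistic)
    oracle_p[i] <- tt$p.value
  }
  expect_equal(rt$t_reg, oracle_t, tolerance = 1e-10)
  expect_equal(rt$p, oracle_p, tolerance = 1e-10)
  expect_equal(rt$df, rep(6, 300))
})

test_that("regularized t handles degenerate genes and null data", {
  m <- rbind(flat = c(5, 5, 5, 5, 5, 5),
             diff = c(5, 5, 5, 7, 7, 7))
  colnames(m) <- c(paste0("r", 1:3), paste0("c", 1:3))
  expect_warning(
    rt <- regularized_t(m, paste0("r", 1:3), paste0("c", 1:3),
                        window = 3, prior_df = 0),
    "zero regularized variance")
  expect_true(is.na(rt$t_reg[rt$gene == "flat"]))
  # identical group means -> t = 0
  m2 <- matrix(rnorm(40, 8, 0.5), 10, 4,
               dimnames = list(paste0("g", 1:10), c("r1", "r2", "c1", "c2")))
  m2[, c("c1", "c2")] <- m2[, c("r1", "r2")]
  rt2 <- regularized_t(m2, c("r1", "r2"), c("c1", "c2"), window = 5)
  expect_true(all(rt2$t_reg == 0))

  # type-I calibration at alpha = 0.05 on a null simulation
  set.seed(72)
  null <- matrix(rnorm(5000 * 6, 8, 1), 5000, 6,
                 dimnames = list(sprintf("n%04d", 1:5000),
                                 c(paste0("r", 1:3), paste0("c", 1:3))))
  rtn <- regularized_t(null, paste0("r", 1:3), paste0("c", 1:3))
  rate <- mean(rtn$p < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("DEG shares reproduce printed percentages exactly", {
  expect_equal(deg_share(1696, 958)$pct, 56)
  expect_equal(deg_share(752, 357)$pct, 47)
  expect_equal(deg_share(100, 0)$pct, 0)
  expect_error(deg_share(0, 0), "n_deg = 0")
  # rounding is invertible for the printed pairs
  for (pair in list(c(1696, 958), c(752, 357))) {
    expect_equal(round(deg_share(pair[1], pair[2])$pct_exact *
                         pair[1] / 100), pair[2])
  }
})

test_that("proliferation-normalized ratios compare groups correctly", {
  m <- matrix(8, 2, 4, dimnames = list(c("DNMT1", "MKI67"), paste0("s", 1:4)))
  expect_equal(unname(proliferation_normalize(m, "DNMT1", "MKI67")$ratios),
               rep(0, 4))
  m["DNMT1", ] <- 9
  expect_equal(unname(proliferation_normalize(m, "DNMT1", "MKI67")$ratios),
               rep(1, 4))
  expect_error(proliferation_normalize(m, "DNMT3B", "MKI67"), "DNMT3B")

  # marker elevated in the case group with a flat gene: case ratios drop
  set.seed(73)
  samples <- c(paste0("r", 1:10), paste0("c", 1:10))
  mm <- rbind(DNMT1 = rnorm(20, 8, 0.2),
              MKI67 = c(rnorm(10, 8, 0.2), rnorm(10, 9.5, 0.2)))
  colnames(mm) <- samples
  res <- proliferation_normalize(mm, "DNMT1", "MKI67",
                                 paste0("r", 1:10), paste0("c", 1:10))
  expect_lt(res$median_case, res$median_ref)
  expect_lt(res$p, 0.05)
})

test_that("MAD is the raw median absolute deviation with its invariances", {
  mad1 <- function(x) median(abs(x - median(x)))
  expect_equal(mad1(c(1, 2, 3, 4, 100)), 1)
  expect_equal(mad1(rep(5, 6)), 0)
  set.seed(74)
  x <- rnorm(31)
  expect_equal(mad1(x + 17), mad1(x))
  expect_equal(mad1(3 * x), 3 * mad1(x))

  g <- genome_model("chr1", 1e6)
  blocks <- intervals("chr1", 0, 5e5)
  coords <- data.frame(chrom = "chr1",
                       start = c(1e5, 7e5), end = c(1e5, 7e5) + 1e4,
                       name = c("gin", "gout"))
  m <- rbind(gin = c(1, 2, 3, 4, 100), gout = rep(5, 5))
  colnames(m) <- paste0("c", 1:5)
  res <- mad_in_blocks(m, coords, blocks, paste0("c", 1:5))
  expect_equal(res$per_gene$mad[res$per_gene$gene == "gin"], 1)
  expect_equal(res$per_gene$in_block, c(TRUE, FALSE))
  expect_error(mad_in_blocks(m, coords, intervals("chr1", 9e5, 1e6),
                             paste0("c", 1:5)), "inside blocks")
})

test_that("doubled in-block noise is recovered by the MAD comparison", {
  set.seed(75)
  n <- 200
  mads_in <- matrix(rnorm(n * 10, 8, 0.6), n, 10)   # in-block: sd 0.6
  mads_out <- matrix(rnorm(n * 10, 8, 0.3), n, 10)  # out-block: sd 0.3
  m <- rbind(mads_in, mads_out)
  rownames(m) <- sprintf("g%03d", 1:(2 * n))
  colnames(m) <- paste0("c", 1:10)
  coords <- data.frame(chrom = "chr1",
                       start = c(seq(0, 199) * 1000,       # inside [0, 2e5)
                                 5e5 + seq(0, 199) * 1000),
                       name = rownames(m))
  coords$end <- coords$start + 500
  blocks <- intervals("chr1", 0, 2.5e5)
  res <- mad_in_blocks(m, coords, blocks, paste0("c", 1:10))
  expect_gt(res$median_in, res$median_out)
  expect_lt(res$p, 0.01)
  paired <- mad_in_blocks(m, coords, blocks, paste0("c", 1:10),
                          test = "paired")
  expect_lt(paired$p, 0.01)
})

test_that("instability signature scoring averages planted fold changes", {
  set.seed(76)
  sig <- sprintf("CIN25_%02d", 1:25)
  genes <- c(sig, sprintf("g%03d", 1:100))
  samples <- c(paste0("r", 1:10), paste0("c", 1:10))
  base <- rnorm(length(genes), 8, 1)
  m <- base + matrix(rnorm(length(genes) * 20, 0, 0.3), length(genes), 20)
  dimnames(m) <- list(genes, samples)
  same <- cin_score(m, sig, paste0("r", 1:10), paste0("c", 1:10))
  expect_equal(same$score, 0, tolerance = 0.15)
  m[sig, paste0("c", 1:10)] <- m[sig, paste0("c", 1:10)] + 1
  shifted <- cin_score(m, sig, paste0("r", 1:10), paste0("c", 1:10))
  expect_equal(shifted$score, 1, tolerance = 0.15)
  expect_warning(cin_score(m, c(sig, "NOSUCH"), paste0("r", 1:10),
                           paste0("c", 1:10)), "NOSUCH")
  expect_error(cin_score(m, "NOSUCH", paste0("r", 1:10), paste0("c", 1:10)),
               "none of the signature genes")
})

test_that("repeat-family expression/methylation summary counts quadrants", {
  one <- re_expression_summary(data.frame(family = "LINE1", dexpr = 1),
                               data.frame(family = "LINE1", dmeth = -20))
  expect_equal(one$n_up_hypo, 1)
  zero <- re_expression_summary(data.frame(family = c("a", "b"), dexpr = 0),
                                data.frame(family = c("a", "b"), dmeth = 0))
  expect_equal(zero$n_up_hypo, 0)
  set.seed(77)
  dm <- rnorm(30, -10, 5)
  tab <- re_expression_summary(
    data.frame(family = paste0("f", 1:30), dexpr = -0.1 * dm + rnorm(30, 0, 0.2)),
    data.frame(family = paste0("f", 1:30), dmeth = dm))
  expect_lt(tab$spearman_rho, 0)
  expect_error(re_expression_summary(data.frame(family = "a", dexpr = 1),
                                     data.frame(family = "b", dmeth = 1)),
               "no repeat families shared")
})
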