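#' Simulation configuration with planted ground truth
#'
#' Every generator draws from one mandatory seed, so identical configurations
#' produce identical data. Defaults emulate the study conditions the analysis
#' assumes: a reference epithelium group and a globally hypomethylated tumor
#' group whose methylomes differ by multi-hundred-kb blocks of 35-50%
#' methylation decrease covering ~15% of the genome, feature tracks with
#' configurable in-block enrichment, CNA segments concentrated in blocks, and
#' expression with proliferation-marker effects and inflated in-block
#' variability.
#'
#' @param seed integer RNG seed (mandatory).
#' @param n_chrom,chrom_length genome shape (equal-length chromosomes).
#' @param cpg_spacing mean bp between CpG sites (exponential spacing).
#' @param baseline_beta,beta_sd mean methylation fraction of unaffected CpGs
#'   and the per-CpG truncated-normal noise sd.
#' @param samples_per_group samples in each of the reference and case groups.
#' @param block_fraction genome fraction planted as hypomethylated blocks.
#' @param block_length_min,block_length_max planted block lengths, bp.
#' @param block_separation minimum bp between planted blocks (keeps planted
#'   blocks distinct under the caller's merge gap).
#' @param delta_min,delta_max planted per-block methylation decrease range.
#' @param tracks list of feature-track specs, each a list with `name`, `n`,
#'   `length`, `enrichment` (fold concentration of feature midpoints inside
#'   blocks; 1 = uniform).
#' @param cna list: `altered_fraction_ref`, `altered_fraction_case` (target
#'   per-sample genome fraction altered), `segment_length`, `concentration`
#'   (in-block density over out-of-block density).
#' @param expression list: `n_genes`, `base_mean`, `base_sd`, `noise_sd`,
#'   `inblock_sd_multiplier` (case-sample noise multiplier inside blocks),
#'   `group_effects` (named vector of case-group log2 shifts, e.g. the
#'   proliferation markers), `signature` (list `genes`, `shift_mean`,
#'   `shift_sd` for a planted instability-signature shift).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_chrom = 2, chrom_length = 25e6,
                       cpg_spacing = 500,
                       baseline_beta = 0.8, beta_sd = 0.05,
                       samples_per_group = 4,
                       block_fraction = 0.15,
                       block_length_min = 3e5, block_length_max = 9e5,
                       block_separation = 6e5,
                       delta_min = 0.35, delta_max = 0.5,
                       tracks = list(
                         list(name = "LAD", n = 2000, length = 20000,
                              enrichment = 2),
                         list(name = "uniform", n = 2000, length = 1000,
                              enrichment = 1)),
                       cna = list(altered_fraction_ref = 0.08,
                                  altered_fraction_case = 0.25,
                                  segment_length = 2e5, concentration = 3),
                       expression = list(
                         n_genes = 1000, base_mean = 8, base_sd = 1,
                         noise_sd = 0.3, inblock_sd_multiplier = 2,
                         group_effects = c(MKI67 = 1.5, PLK1 = 1.2,
                                           BUB1 = 1.0, DNMT1 = 0,
                                           DNMT3A = 0, UHRF1 = 0),
                         signature = list(genes = sprintf("CIN25_%02d", 1:25),
                                          shift_mean = 0.8, shift_sd = 0.1))) {
  if (missing(seed)) stop("sim_config requires an explicit seed")
  stopifnot(n_chrom >= 1, chrom_length > 0, cpg_spacing > 0,
            baseline_beta >= 0, baseline_beta <= 1, beta_sd >= 0,
            samples_per_group >= 1,
            block_fraction >= 0, block_fraction < 1,
            delta_min >= 0, delta_max <= 1, delta_min <= delta_max)
  structure(as.list(environment()), class = "sim_config")
}

#' @rdname sim_config
#' @param cfg a `sim_config`.
#' @export
sim_genome <- function(cfg) {
  genome_model(paste0("chr", seq_len(cfg$n_chrom)),
               rep(cfg$chrom_length, cfg$n_chrom))
}

sim_samples <- function(cfg) {
  list(ref = sprintf("ref_%d", seq_len(cfg$samples_per_group)),
       case = sprintf("case_%d", seq_len(cfg$samples_per_group)))
}

# plant non-overlapping blocks covering ~block_fraction of the genome
sim_truth_blocks <- function(cfg, genome) {
  target <- cfg$block_fraction * genome_size(genome)
  placed <- data.frame(chrom = character(), start = numeric(), end = numeric())
  covered <- 0
  tries <- 0
  while (covered < target && tries < 10000) {
    tries <- tries + 1
    len <- stats::runif(1, cfg$block_length_min, cfg$block_length_max)
    if (covered + len > target + cfg$block_length_min / 2) {
      len <- max(cfg$block_length_min, target - covered)
    }
    ci <- sample.int(nrow(genome), 1, prob = genome$length)
    if (genome$length[ci] <= len) next
    start <- floor(stats::runif(1, 0, genome$length[ci] - len))
    cs <- max(0, start - cfg$block_separation)
    ce <- min(genome$length[ci], start + len + cfg$block_separation)
    if (any(placed$chrom == genome$chrom[ci] &
              placed$start < ce & placed$end > cs)) next
    placed <- rbind(placed, data.frame(chrom = genome$chrom[ci], start = start,
                                       end = start + len))
    covered <- covered + len
  }
  normalize_intervals(placed, genome)
}

#' Simulate a per-CpG methylome with planted hypomethylated blocks
#'
#' Reference samples fluctuate around the baseline everywhere; case samples
#' are decreased by a per-block delta (uniform in `[delta_min, delta_max]`)
#' inside the planted blocks. Noise is truncated normal on \[0, 1\].
#'
#' @param cfg a [sim_config()].
#' @return List: `methylome` (`data.frame`), `truth` (planted block interval
#'   `data.frame`), `genome`, `samples` (list `ref`, `case`), `block_delta`
#'   (per planted block).
#' @export
simulate_methylome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  genome <- sim_genome(cfg)
  samples <- sim_samples(cfg)
  withr_seed(cfg$seed, {
    truth <- sim_truth_blocks(cfg, genome)
    block_delta <- if (nrow(truth)) {
      stats::runif(nrow(truth), cfg$delta_min, cfg$delta_max)
    } else numeric()
    pos_list <- lapply(seq_len(nrow(genome)), function(i) {
      n_approx <- ceiling(genome$length[i] / cfg$cpg_spacing * 1.3) + 10
      gaps <- pmax(1, round(stats::rexp(n_approx, 1 / cfg$cpg_spacing)))
      p <- cumsum(gaps)
      p <- p[p < genome$length[i]]
      data.frame(chrom = genome$chrom[i], pos = unique(p))
    })
    sites <- do.call(rbind, pos_list)
    n_sites <- nrow(sites)
    # per-CpG planted decrease for case samples
    delta_site <- numeric(n_sites)
    if (nrow(truth)) {
      for (b in seq_len(nrow(truth))) {
        hit <- sites$chrom == truth$chrom[b] & sites$pos >= truth$start[b] &
          sites$pos < truth$end[b]
        delta_site[hit] <- block_delta[b]
      }
    }
    meth <- sites
    for (s in samples$ref) {
      meth[[s]] <- clamp01(cfg$baseline_beta +
                             stats::rnorm(n_sites, 0, cfg$beta_sd))
    }
    for (s in samples$case) {
      meth[[s]] <- clamp01(cfg$baseline_beta - delta_site +
                             stats::rnorm(n_sites, 0, cfg$beta_sd))
    }
    list(methylome = meth, truth = truth, genome = genome, samples = samples,
         block_delta = block_delta)
  })
}

clamp01 <- function(x) pmin(1, pmax(0, x))

# pick a uniformly random position within a set of intervals (length-weighted)
sample_positions <- function(set, n) {
  if (n == 0 || nrow(set) == 0) return(data.frame(chrom = character(),
                                                  pos = numeric()))
  w <- set$end - set$start
  i <- sample.int(nrow(set), n, replace = TRUE, prob = w)
  data.frame(chrom = set$chrom[i],
             pos = floor(set$start[i] + stats::runif(n) * w[i]))
}

#' Simulate feature tracks with planted in-block enrichment
#'
#' Each feature's midpoint lands inside the truth blocks with probability
#' `min(1, enrichment * c)` where `c` is the blocks' genome coverage, so the
#' expected midpoint fold enrichment equals the requested factor (factor 1 is
#' uniform placement).
#'
#' @param cfg a [sim_config()].
#' @param truth planted block interval `data.frame`.
#' @param genome a `genome_model`.
#' @return Named list of interval `data.frame`s.
#' @export
simulate_tracks <- function(cfg, truth, genome) {
  stopifnot(inherits(cfg, "sim_config"))
  cvg <- coverage_fraction(truth, genome)
  comp <- interval_complement(truth, genome)
  withr_seed(cfg$seed + 1L, {
    out <- lapply(cfg$tracks, function(tr) {
      if (tr$n == 0) return(intervals(character(), numeric(), numeric()))
      p_in <- if (cvg > 0) min(1, tr$enrichment * cvg) else 0
      n_in <- stats::rbinom(1, tr$n, p_in)
      mids <- rbind(sample_positions(truth, n_in),
                    sample_positions(comp, tr$n - n_in))
      half <- tr$length / 2
      len <- .chrom_lengths(mids$chrom, genome)
      start <- pmax(0, floor(mids$pos - half))
      end <- pmin(len, start + tr$length)
      start <- pmax(0, end - tr$length)
      iv <- intervals(mids$chrom, start, end)
      iv[order(iv$chrom, iv$start), , drop = FALSE]
    })
    names(out) <- vapply(cfg$tracks, `[[`, "", "name")
    out
  })
}

#' Simulate per-sample CNA segments concentrated in blocks
#'
#' Each sample receives segments totalling its group's target altered
#' fraction; a segment falls wholly inside the block compartment with
#' probability `k*c / (k*c + (1 - c))` (`k` = concentration, `c` = block
#' coverage), which makes the expected in/out per-bp density ratio equal `k`.
#'
#' @inheritParams simulate_tracks
#' @return Segment `data.frame` (`sample`, `chrom`, `start`, `end`, `call`).
#' @export
simulate_cna <- function(cfg, truth, genome) {
  stopifnot(inherits(cfg, "sim_config"))
  samples <- sim_samples(cfg)
  cvg <- coverage_fraction(truth, genome)
  comp <- interval_complement(truth, genome)
  k <- cfg$cna$concentration
  p_in <- if (cvg > 0) (k * cvg) / (k * cvg + (1 - cvg)) else 0
  gs <- genome_size(genome)
  seg_len <- cfg$cna$segment_length
  withr_seed(cfg$seed + 2L, {
    # non-overlapping candidate slots of seg_len within a compartment, with a
    # random sub-slot offset per compartment interval (segment callers emit
    # non-overlapping segments; slot sampling keeps realized densities at
    # their targets instead of saturating under self-overlap)
    slots_of <- function(set) {
      pieces <- lapply(seq_len(nrow(set)), function(i) {
        w <- set$end[i] - set$start[i]
        k <- floor(w / seg_len)
        if (k == 0) return(NULL)
        off <- floor(stats::runif(1, 0, w - k * seg_len + 1))
        data.frame(chrom = set$chrom[i],
                   start = set$start[i] + off + (0:(k - 1)) * seg_len,
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, pieces)
    }
    place <- function(sample_id, frac) {
      n_seg <- max(1, round(frac * gs / seg_len))
      n_in <- stats::rbinom(1, n_seg, p_in)
      pick <- function(slots, n) {
        if (is.null(slots) || n == 0) return(NULL)
        slots[sample.int(nrow(slots), min(n, nrow(slots))), , drop = FALSE]
      }
      sel <- rbind(pick(slots_of(truth), n_in),
                   pick(slots_of(comp), n_seg - n_in))
      data.frame(sample = sample_id, chrom = sel$chrom, start = sel$start,
                 end = sel$start + seg_len,
                 call = ifelse(stats::runif(nrow(sel)) < 0.5, "gain", "loss"),
                 stringsAsFactors = FALSE)
    }
    out <- rbind(
      do.call(rbind, lapply(samples$ref, place,
                            frac = cfg$cna$altered_fraction_ref)),
      do.call(rbind, lapply(samples$case, place,
                            frac = cfg$cna$altered_fraction_case)))
    out <- out[order(out$sample, out$chrom, out$start), ]
    rownames(out) <- NULL
    out
  })
}

#' Simulate a log2 expression matrix with planted effects
#'
#' Gene baselines are normal around `base_mean`; case samples add the named
#' `group_effects` shifts and the planted signature shifts; per-sample noise
#' sd is multiplied by `inblock_sd_multiplier` for case samples of genes whose
#' midpoint lies in a planted block (the variability inflation the block
#' analysis is meant to recover).
#'
#' @inheritParams simulate_tracks
#' @return List: `expr` (matrix), `coords` (interval `data.frame` with
#'   `name`), `samples`, `signature_shifts` (named planted shifts).
#' @export
simulate_expression <- function(cfg, truth, genome) {
  stopifnot(inherits(cfg, "sim_config"))
  samples <- sim_samples(cfg)
  ex <- cfg$expression
  special <- c(names(ex$group_effects), ex$signature$genes)
  n_bulk <- ex$n_genes
  genes <- c(sprintf("gene_%05d", seq_len(n_bulk)), special)
  withr_seed(cfg$seed + 3L, {
    mids <- sample_positions(intervals(genome$chrom, 0, genome$length),
                             length(genes))
    len <- .chrom_lengths(mids$chrom, genome)
    start <- pmax(0, mids$pos - 5000)
    end <- pmin(len, start + 10000)
    coords <- data.frame(chrom = mids$chrom, start = start, end = end,
                         name = genes, stringsAsFactors = FALSE)
    in_block <- .points_in_set(mids$chrom, mids$pos,
                               normalize_intervals(truth))
    shift <- stats::setNames(rep(0, length(genes)), genes)
    shift[names(ex$group_effects)] <- ex$group_effects
    sig_shift <- stats::rnorm(length(ex$signature$genes),
                              ex$signature$shift_mean, ex$signature$shift_sd)
    shift[ex$signature$genes] <- sig_shift
    base <- stats::rnorm(length(genes), ex$base_mean, ex$base_sd)
    all_samples <- c(samples$ref, samples$case)
    expr <- matrix(0, length(genes), length(all_samples),
                   dimnames = list(genes, all_samples))
    for (s in samples$ref) {
      expr[, s] <- base + stats::rnorm(length(genes), 0, ex$noise_sd)
    }
    sd_case <- ex$noise_sd * ifelse(in_block, ex$inblock_sd_multiplier, 1)
    for (s in samples$case) {
      expr[, s] <- base + shift + stats::rnorm(length(genes), 0, sd_case)
    }
    list(expr = expr, coords = coords, samples = samples,
         signature_shifts = stats::setNames(sig_shift, ex$signature$genes))
  })
}
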