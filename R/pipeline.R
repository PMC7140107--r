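#' Run the full synthetic-or-supplied analysis pipeline
#'
#' Orchestrates simulate -> block calling -> feature enrichment -> CNA ->
#' expression in dependency order, writing each stage's outputs under
#' `outdir` and returning (and writing) a JSON run report. All randomness
#' flows from the single top-level `seed`, expanded per stage, so a rerun
#' with the same configuration produces a byte-identical report. A failing
#' stage stops the run with the stage named; earlier stage outputs stay on
#' disk.
#'
#' @param config a configuration list, or the path to a YAML/JSON file with
#'   the same structure: `seed` (integer, required); `simulate` (list of
#'   [sim_config()] overrides, or `FALSE` to analyse supplied inputs, in
#'   which case `input` must give `methylome`, `genome`, `ref_samples`,
#'   `case_samples` and optionally `tracks`, `segments`, `expression`,
#'   `genes`); `blocks` ([block_config()] overrides); `enrichment`
#'   (`n_permutations`, `tests`); `expression` (`window`, `prior_df`,
#'   `deg_p`).
#' @param outdir output directory (created if needed).
#' @return The run report, invisibly (also written to
#'   `file.path(outdir, "report.json")`).
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) config <- read_run_config(config)
  validate_run_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  report <- list(tool = "hypoblocks",
                 version = as.character(utils::packageVersion("hypoblocks")),
                 seed = config$seed, config = config, stages = list())

  stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # -- stage 1: simulate (or load) -----------------------------------------
  sim_on <- !isFALSE(config$simulate)
  dat <- stage("simulate", function() {
    if (sim_on) {
      cfg <- do.call(sim_config, c(list(seed = config$seed),
                                   config$simulate %||% list()))
      mt <- simulate_methylome(cfg)
      tracks <- simulate_tracks(cfg, mt$truth, mt$genome)
      segments <- simulate_cna(cfg, mt$truth, mt$genome)
      xp <- simulate_expression(cfg, mt$truth, mt$genome)
      write_methylome(mt$methylome, file.path(outdir, "methylome.tsv"))
      write_genome(mt$genome, file.path(outdir, "genome.tsv"))
      dir.create(file.path(outdir, "truth"), showWarnings = FALSE)
      write_bed(mt$truth, file.path(outdir, "truth", "blocks.bed"))
      for (nm in names(tracks)) {
        write_bed(tracks[[nm]], file.path(outdir, paste0("track_", nm, ".bed")))
      }
      write_segments(segments, file.path(outdir, "segments.tsv"))
      write_expression(xp$expr, file.path(outdir, "expression.tsv"))
      write_bed(xp$coords, file.path(outdir, "genes.bed"))
      list(methylome = mt$methylome, genome = mt$genome,
           ref = mt$samples$ref, case = mt$samples$case, truth = mt$truth,
           tracks = tracks, segments = segments, expr = xp$expr,
           coords = xp$coords,
           signature = cfg$expression$signature$genes)
    } else {
      inp <- config$input
      genome <- read_genome(inp$genome)
      tracks <- if (!is.null(inp$tracks)) {
        stats::setNames(lapply(inp$tracks, read_bed, genome = genome),
                        names(inp$tracks))
      }
      list(methylome = read_methylome(inp$methylome, genome), genome = genome,
           ref = inp$ref_samples, case = inp$case_samples, truth = NULL,
           tracks = tracks,
           segments = if (!is.null(inp$segments))
             read_segments(inp$segments, genome),
           expr = if (!is.null(inp$expression)) read_expression(inp$expression),
           coords = if (!is.null(inp$genes)) read_bed(inp$genes, genome),
           signature = inp$signature_genes)
    }
  })
  report$stages$simulate <- list(
    simulated = sim_on, n_cpgs = nrow(dat$methylome),
    n_samples = length(dat$ref) + length(dat$case),
    truth_blocks = if (!is.null(dat$truth)) nrow(dat$truth))

  # -- stage 2: block calling ----------------------------------------------
  bcfg <- do.call(block_config, config$blocks %||% list())
  blocks <- stage("blocks", function() {
    ts <- tile_differential(dat$methylome, dat$ref, dat$case, dat$genome,
                            tile_size = bcfg$tile_size,
                            min_tile_cpgs = bcfg$min_tile_cpgs)
    utils::write.table(ts, file.path(outdir, "tiles.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    bl <- call_hypo_blocks(ts, bcfg)
    out <- bl
    if (nrow(out)) {
      out$name <- sprintf("block_%d", seq_len(nrow(out)))
      out$score <- round(-100 * out$mean_delta)
    }
    write_bed(out, file.path(outdir, "blocks.bed"))
    bl
  })
  bs <- summarize_blocks(blocks, dat$genome)
  report$stages$blocks <- list(n_blocks = bs$n_blocks,
                               total_bases = bs$total_bases,
                               pct_genome = 100 * bs$genome_fraction)

  # -- stage 3: feature enrichment -----------------------------------------
  if (!is.null(dat$tracks) && nrow(blocks) > 0) {
    ecfg <- config$enrichment %||% list()
    enr <- stage("enrichment", function() {
      tab <- enrich_table(blocks, dat$tracks, dat$genome,
                          tests = ecfg$tests,
                          cfg = permutation_config(
                            n_permutations = ecfg$n_permutations %||% 200,
                            seed = config$seed + 10L))
      utils::write.table(tab, file.path(outdir, "enrichment.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      tab
    })
    report$stages$enrichment <- lapply(seq_len(nrow(enr)), function(i) {
      as.list(enr[i, c("feature", "n_total", "n_in", "pct_in_blocks",
                       "fold", "direction", "p")])
    })
  }

  # -- stage 4: CNA ---------------------------------------------------------
  if (!is.null(dat$segments) && nrow(blocks) > 0) {
    cna <- stage("cna", function() {
      idx <- cna_index(dat$segments, dat$genome)
      grp <- stats::setNames(
        ifelse(idx$sample %in% dat$ref, "ref", "case"), idx$sample)
      cmp <- cna_compare_groups(idx, grp, ref = "ref", case = "case")
      ov <- cna_block_overlap(
        dat$segments[dat$segments$sample %in% dat$case, , drop = FALSE],
        blocks, dat$genome)
      utils::write.table(idx, file.path(outdir, "cna_index.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      list(median_index = as.list(cmp$medians), mw_p = cmp$p,
           density_in = ov$density_in, density_out = ov$density_out,
           density_ratio = ov$density_ratio, overlap_p = ov$p)
    })
    report$stages$cna <- cna
  }

  # -- stage 5: expression --------------------------------------------------
  if (!is.null(dat$expr)) {
    xcfg <- config$expression %||% list()
    xp <- stage("expression", function() {
      rt <- regularized_t(dat$expr, dat$ref, dat$case,
                          window = xcfg$window %||% 101,
                          prior_df = xcfg$prior_df %||% 10)
      utils::write.table(rt, file.path(outdir, "differential_expression.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      deg_p <- xcfg$deg_p %||% 0.01
      deg <- rt[!is.na(rt$p) & rt$p < deg_p, , drop = FALSE]
      share <- if (nrow(deg)) deg_share(nrow(deg), sum(deg$mean_diff > 0))
      pn <- if (all(c("DNMT1", "MKI67") %in% rownames(dat$expr))) {
        proliferation_normalize(dat$expr, "DNMT1", "MKI67", dat$ref, dat$case)
      }
      mad <- if (!is.null(dat$coords) && nrow(blocks) > 0) {
        mad_in_blocks(dat$expr, dat$coords, blocks, dat$case)
      }
      cin <- if (!is.null(dat$signature)) {
        cin_score(dat$expr, dat$signature, dat$ref, dat$case,
                  window = xcfg$window %||% 101,
                  prior_df = xcfg$prior_df %||% 10)
      }
      list(n_deg = if (is.null(share)) 0 else share$n_deg,
           pct_up = if (is.null(share)) NULL else share$pct,
           dnmt1_mki67_p = if (is.null(pn)) NULL else pn$p,
           mad_median_in = if (is.null(mad)) NULL else mad$median_in,
           mad_median_out = if (is.null(mad)) NULL else mad$median_out,
           mad_p = if (is.null(mad)) NULL else mad$p,
           cin_score = if (is.null(cin)) NULL else cin$score)
    })
    report$stages$expression <- xp
  }

  write_report(report, file.path(outdir, "report.json"))
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname run_pipeline
#' @param path YAML or JSON configuration file.
#' @export
read_run_config <- function(path) {
  if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

# all schema violations reported at once
validate_run_config <- function(config) {
  errs <- character()
  if (is.null(config$seed) || !is.numeric(config$seed)) {
    errs <- c(errs, "config$seed (integer) is required")
  }
  if (isFALSE(config$simulate)) {
    inp <- config$input
    if (is.null(inp)) {
      errs <- c(errs, "simulate is disabled and no input section is given")
    } else {
      for (f in c("methylome", "genome", "ref_samples", "case_samples")) {
        if (is.null(inp[[f]])) {
          errs <- c(errs, sprintf("input$%s is required when simulate is disabled", f))
        }
      }
    }
  }
  if (length(errs)) stop("invalid run configuration:\n  - ",
                         paste(errs, collapse = "\n  - "), call. = FALSE)
  invisible(config)
}

write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, null = "null")
  invisible(path)
}
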