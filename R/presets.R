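# Scenario presets bundling the two model systems: a Dcm-methylated
# bacterial genome read in 2 x 38 mode and a mammalian-like CpG-island
# genome read in 2 x 150 mode, each carrying a 10 kb fully unmethylated
# spike-in emulating the 1% unmethylated lambda DNA conversion control.

.PRESETS <- list(
  ecoli_dcm = list(
    genome_name = "ecoli_synthetic", genome_length = 100000L,
    gc_fraction = 0.51, cpg_enrichment = 1.0,
    spike_name = "lambda_synthetic", spike_length = 10000L,
    spike_gc = 0.50, read_length = 38L,
    methylome = "dcm"),
  ecoli_dcm_minus = list(
    genome_name = "ecoli_synthetic", genome_length = 100000L,
    gc_fraction = 0.51, cpg_enrichment = 1.0,
    spike_name = "lambda_synthetic", spike_length = 10000L,
    spike_gc = 0.50, read_length = 38L,
    methylome = "dcm_minus"),
  mammalian_k562_like = list(
    genome_name = "chrS", genome_length = 1000000L,
    gc_fraction = 0.41, cpg_enrichment = 0.25,
    spike_name = "lambda_synthetic", spike_length = 10000L,
    spike_gc = 0.50, read_length = 150L,
    methylome = "mammalian")
)

#' Names of the bundled scenario presets
#' @return character vector.
#' @export
scenario_presets <- function() names(.PRESETS)

#' Build the genome and methylome of a scenario preset
#'
#' `ecoli_dcm` is a 100 kb bacterial-like genome with every CCWGG site
#' methylated at level 1 (Dcm model); `ecoli_dcm_minus` is the same genome
#' fully unmethylated (the dcm- negative-control strain);
#' `mammalian_k562_like` is a 1 Mb CpG-depleted genome with CpG islands and
#' a bimodal CpG methylome. All presets add a 10 kb unmethylated spike-in.
#'
#' @param preset one of [scenario_presets()].
#' @param seed integer seed.
#' @param genome_length optional override of the main-sequence length.
#' @param params [methylome_model_params()] for the mammalian preset.
#' @return list with `genome`, `methylome`, `cgi` (RegionSet or NULL),
#'   `read_length`, `preset`.
#' @export
build_scenario <- function(preset = scenario_presets(), seed = 1L,
                           genome_length = NULL,
                           params = methylome_model_params()) {
  preset <- match.arg(preset)
  p <- .PRESETS[[preset]]
  glen <- if (is.null(genome_length)) p$genome_length else
    as.integer(genome_length)
  spec <- data.frame(
    name = c(p$genome_name, p$spike_name),
    length = c(glen, p$spike_length),
    gc_fraction = c(p$gc_fraction, p$spike_gc),
    cpg_enrichment = c(p$cpg_enrichment, 1.0))
  genome <- generate_genome(spec, seed = seed, spike_in_name = p$spike_name)
  cgi <- NULL
  methylome <- switch(p$methylome,
    dcm = dcm_methylome(genome, level = 1.0),
    dcm_minus = dcm_minus_methylome(genome),
    mammalian = {
      mm <- mammalian_methylome(genome, params, seed = seed)
      cgi <- mm$cgi
      mm$methylome
    })
  list(genome = genome, methylome = methylome, cgi = cgi,
       read_length = p$read_length, preset = preset)
}

#' Read pairs needed to reach a target mean cytosine depth
#'
#' Estimates the informative (post-trim) bases contributed per read pair by
#' averaging the trimmed mate spans over the fragment-length and
#' priming-position ranges, then sizes the run so that the mean per-cytosine
#' coverage of the call table reaches `depth`. Cytosine coverage is
#' strand-specific (a forward-strand C is only observed from OT templates),
#' so it runs at half the raw base depth. The estimate treats priming
#' positions as uniform, which is exact for WGBS and a good approximation
#' for ABBS.
#'
#' @param genome a `GenomeSet`.
#' @param config a [sim_config()] (read length, fragment range, spike
#'   fraction are used).
#' @param depth target mean depth (x).
#' @param policy a [trim_policy()].
#' @return integer number of read pairs.
#' @export
pairs_for_depth <- function(genome, config, depth, policy = trim_policy()) {
  rl <- config$read_length; pl <- 6L
  i1s <- max(pl, policy$ignore_r1_start)
  i1e <- rl - 1L - policy$ignore_r1_end
  i2s <- policy$ignore_r2_start
  i2e <- rl - 1L - policy$ignore_r2_end
  per_pair <- numeric(0)
  for (L in seq(config$frag_min, config$frag_max, by = 5L)) {
    a_lo <- max(config$min_extension, rl - 6L)
    a_hi <- L - 6L
    if (a_hi < a_lo) next
    a <- a_lo:a_hi
    t1hi <- pmin(a - 1L - (i1s - pl), L - 1L)
    t1lo <- pmax(a - 1L - (i1e - pl), 0L)
    n1 <- pmax(t1hi - t1lo + 1L, 0L)
    t2lo <- i2s; t2hi <- min(i2e, L - 1L)
    n2 <- max(t2hi - t2lo + 1L, 0L)
    ov <- pmax(pmin(t1hi, t2hi) - pmax(t1lo, t2lo) + 1L, 0L)
    per_pair <- c(per_pair, n1 + n2 - if (policy$no_overlap) ov else 0L)
  }
  if (!length(per_pair)) stop("no valid pair geometry", call. = FALSE)
  main <- setdiff(names(genome$sequences), genome$spike_in_name)
  main_len <- sum(nchar(genome$sequences[main]))
  eff <- mean(per_pair) * (1 - config$spike_in_read_fraction) / 2
  as.integer(ceiling(depth * main_len / eff))
}

#' Run a full scenario end to end
#'
#' Generates the preset genome and methylome, simulates matched ABBS and
#' WGBS libraries, calls cytosines for both, and computes the summary
#' statistics: conversion efficiency, called 5mC sites, methylated- vs
#' unmethylated-bin coverage enrichment, ABBS/WGBS level correlation, and
#' the read-1 position-6 G fraction. Writes FASTQ/truth/bedGraph files plus
#' a JSON-lines report and a manifest, all reproducible from the seed.
#'
#' @param preset one of [scenario_presets()].
#' @param n_read_pairs pairs per protocol.
#' @param seed integer root seed.
#' @param outdir output directory (created if missing).
#' @param genome_length optional main-genome length override.
#' @param stats_cfg a [stats_config()].
#' @param ... passed to [sim_config()] (e.g. `p_specific`).
#' @return invisibly, the report as a named list.
#' @export
run_scenario <- function(preset, n_read_pairs, seed = 1L, outdir,
                         genome_length = NULL,
                         stats_cfg = stats_config(), ...) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sc <- build_scenario(preset, seed = seed, genome_length = genome_length)
  write_fasta(sc$genome, file.path(outdir, "genome.fa"))
  write_methylome(sc$methylome, file.path(outdir, "methylome.tsv"))
  if (!is.null(sc$cgi)) write_bed(sc$cgi, file.path(outdir, "cgi.bed"))
  policy <- trim_policy()
  report <- list(preset = preset, seed = seed, n_read_pairs = n_read_pairs,
                 read_length = sc$read_length)
  tabs <- list(); pair_tabs <- list()
  for (protocol in c("ABBS", "WGBS")) {
    cfg <- sim_config(protocol = protocol, n_read_pairs = n_read_pairs,
                      read_length = sc$read_length,
                      seed = derive_seed(seed, match(protocol, c("ABBS", "WGBS"))),
                      ...)
    prefix <- file.path(outdir, tolower(protocol))
    res <- simulate_run(sc$genome, sc$methylome, cfg, prefix)
    pairs <- read_run(prefix)
    tab <- call_cytosines(pairs, sc$genome, policy)
    write_bedgraph(tab, paste0(prefix, ".cov.bedgraph"))
    write_cx_report(tab, paste0(prefix, ".CX_report.txt"))
    tabs[[protocol]] <- tab
    pair_tabs[[protocol]] <- pairs
    sites <- call_methylated_sites(tab, stats_cfg)
    track <- bin_coverage(pairs, sc$genome, stats_cfg$bin_size_small)
    track <- classify_bins(track, sites, stats_cfg$overlap_min)
    main_track <- track[seqnames != sc$genome$spike_in_name]
    enr <- if (any(main_track$is_methylated) && any(!main_track$is_methylated))
      mean(main_track[is_methylated == TRUE, read_count]) /
        max(mean(main_track[is_methylated == FALSE, read_count]), 1e-9)
    else NA_real_
    comp <- read_position_composition(pairs$r1)
    report[[protocol]] <- list(
      conversion_efficiency_percent =
        tryCatch(conversion_efficiency(tab, sc$genome$spike_in_name),
                 error = function(e) NA_real_),
      n_called_5mc_sites = nrow(sites),
      specific_products = attr(pairs, "report")$specific %||%
        sum(pairs$specific),
      meth_bin_enrichment = enr,
      read1_pos6_G_fraction = comp$G[6L])
  }
  report$abbs_wgbs_correlation <- tryCatch(
    methylation_correlation(tabs$ABBS, tabs$WGBS, stats_cfg, mode = "all")$r,
    error = function(e) NA_real_)
  ## JSON-lines report + manifest
  rep_path <- file.path(outdir, "report.jsonl")
  con <- file(rep_path, "w")
  for (nm in names(report))
    writeLines(jsonlite::toJSON(setNames(list(report[[nm]]), nm),
                                auto_unbox = TRUE, digits = NA), con)
  close(con)
  manifest <- list(preset = preset, seed = seed,
                   child_seeds = list(ABBS = derive_seed(seed, 1L),
                                      WGBS = derive_seed(seed, 2L)),
                   n_read_pairs = n_read_pairs,
                   package_version =
                     as.character(utils::packageVersion("abbskit")),
                   genome_md5 = unname(tools::md5sum(file.path(outdir,
                                                               "genome.fa"))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
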