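#' Wet-lab simulation configuration
#'
#' Bundles every tunable of the ABBS/WGBS library simulator. Defaults mirror
#' the published protocol: fragments of 200-300 nt, conversion efficiency
#' 0.996 (above the 99.5% QC floor), a 1% unmethylated spike-in read share,
#' the 5'-NNNNN-PPG-3' ABBS primer geometry and 2 x 38 / 2 x 150 read modes.
#'
#' @param protocol `"ABBS"` or `"WGBS"`.
#' @param n_read_pairs number of read pairs to emit.
#' @param read_length bases per read (38 or 150 typical).
#' @param frag_min,frag_max fragment length range in bases.
#' @param conversion_efficiency probability an unmethylated C is converted
#'   to T.
#' @param inappropriate_conversion probability a methylated C is wrongly
#'   converted.
#' @param p_anneal_match probability each primer N base complements its
#'   template base (the remainder are uniform random).
#' @param p_specific probability a fragment carrying at least one eligible
#'   anchor is specifically primed (ABBS only).
#' @param min_extension minimum template bases 5' of the anchor.
#' @param spike_in_read_fraction fraction of fragments drawn from the
#'   spike-in sequence.
#' @param seq_error_rate per-base substitution error rate in reads.
#' @param seed integer root seed; all stages derive child streams from it.
#' @return a list of class `SimConfig`.
#' @export
sim_config <- function(protocol = c("ABBS", "WGBS"), n_read_pairs = 1000L,
                       read_length = 38L, frag_min = 200L, frag_max = 300L,
                       conversion_efficiency = 0.996,
                       inappropriate_conversion = 0,
                       p_anneal_match = 0.9, p_specific = 0.8,
                       min_extension = 30L, spike_in_read_fraction = 0.01,
                       seq_error_rate = 0, seed = 1L) {
  protocol <- match.arg(toupper(protocol[1]), c("ABBS", "WGBS"))
  n_read_pairs <- .assert_count(n_read_pairs, "n_read_pairs", 0L)
  read_length <- .assert_count(read_length, "read_length", 1L)
  frag_min <- .assert_count(frag_min, "frag_min", 1L)
  frag_max <- .assert_count(frag_max, "frag_max", 1L)
  min_extension <- .assert_count(min_extension, "min_extension", 0L)
  .assert_fraction(conversion_efficiency, "conversion_efficiency")
  .assert_fraction(inappropriate_conversion, "inappropriate_conversion")
  .assert_fraction(p_anneal_match, "p_anneal_match")
  .assert_fraction(p_specific, "p_specific")
  .assert_fraction(spike_in_read_fraction, "spike_in_read_fraction")
  .assert_fraction(seq_error_rate, "seq_error_rate")
  if (frag_min > frag_max)
    stop("frag_min must be <= frag_max", call. = FALSE)
  if (read_length < 7L)
    stop("read_length must be >= primer length + 1 (7)", call. = FALSE)
  structure(list(protocol = protocol, n_read_pairs = n_read_pairs,
                 read_length = read_length, frag_min = frag_min,
                 frag_max = frag_max,
                 conversion_efficiency = conversion_efficiency,
                 inappropriate_conversion = inappropriate_conversion,
                 p_anneal_match = p_anneal_match, p_specific = p_specific,
                 min_extension = min_extension,
                 spike_in_read_fraction = spike_in_read_fraction,
                 seq_error_rate = seq_error_rate, seed = as.integer(seed)),
            class = "SimConfig")
}

#' Read-trimming policy for methylation calling
#'
#' Mirrors the Bismark methylation-extractor settings used downstream of
#' PBAT-style libraries: ignore 7 bases from the 5' end of each mate (which
#' covers the 6 primer-derived bases of read 1 plus one buffer base), 5 bases
#' from each 3' end, and count mate-overlapping positions once (read 1 wins).
#'
#' @param ignore_r1_start,ignore_r2_start bases trimmed from the 5' ends.
#' @param ignore_r1_end,ignore_r2_end bases trimmed from the 3' ends.
#' @param no_overlap logical; count overlapping mate positions once.
#' @return a list of class `TrimPolicy`.
#' @export
trim_policy <- function(ignore_r1_start = 7L, ignore_r2_start = 7L,
                        ignore_r1_end = 5L, ignore_r2_end = 5L,
                        no_overlap = TRUE) {
  for (v in c(ignore_r1_start, ignore_r2_start, ignore_r1_end, ignore_r2_end))
    .assert_count(v, "trim", 0L)
  structure(list(ignore_r1_start = as.integer(ignore_r1_start),
                 ignore_r2_start = as.integer(ignore_r2_start),
                 ignore_r1_end = as.integer(ignore_r1_end),
                 ignore_r2_end = as.integer(ignore_r2_end),
                 no_overlap = isTRUE(no_overlap)),
            class = "TrimPolicy")
}

#' Quantification thresholds and binning parameters
#'
#' All threshold comparisons downstream are strict (`>`), mirroring the awk
#' filters of the original analysis: a cytosine is methylated when its level
#' is above 50%, and high-confidence when its coverage is above 25 reads.
#'
#' @param meth_call_threshold methylation-call threshold in percent (strict).
#' @param coverage_cutoff coverage cutoff in reads (strict).
#' @param bin_size_small,bin_size_large bin widths in bases for coverage
#'   tracks (10 bp and 10 kb analyses).
#' @param intermediate_range percent range (open interval) defining
#'   intermediate-methylation sites.
#' @param resample_bin_width width in percent of the homogeneous-resampling
#'   bins tiling \[0, 100\].
#' @param resample_per_bin cytosines drawn per bin in homogeneous resampling.
#' @param overlap_min minimum base overlap for interval intersections.
#' @return a list of class `StatsConfig`.
#' @export
stats_config <- function(meth_call_threshold = 50, coverage_cutoff = 25L,
                         bin_size_small = 10L, bin_size_large = 10000L,
                         intermediate_range = c(20, 80),
                         resample_bin_width = 5, resample_per_bin = 5000L,
                         overlap_min = 1L) {
  stopifnot(meth_call_threshold > 0, coverage_cutoff > 0,
            bin_size_small >= 1, bin_size_large >= 1,
            length(intermediate_range) == 2L,
            intermediate_range[1] < intermediate_range[2],
            resample_per_bin >= 1, overlap_min >= 1)
  if (100 %% resample_bin_width != 0)
    stop("resample_bin_width must tile [0, 100]", call. = FALSE)
  structure(list(meth_call_threshold = meth_call_threshold,
                 coverage_cutoff = as.integer(coverage_cutoff),
                 bin_size_small = as.integer(bin_size_small),
                 bin_size_large = as.integer(bin_size_large),
                 intermediate_range = as.numeric(intermediate_range),
                 resample_bin_width = as.numeric(resample_bin_width),
                 resample_per_bin = as.integer(resample_per_bin),
                 overlap_min = as.integer(overlap_min)),
            class = "StatsConfig")
}

#' Validate and normalize a YAML simulation config
#'
#' Reads a YAML file of [sim_config()] fields, fills defaults for missing
#' keys and reports every violation at once. An empty file yields the full
#' default configuration.
#'
#' @param path YAML file path.
#' @return a normalized `SimConfig`.
#' @export
validate_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a YAML mapping", call. = FALSE)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  problems <- character(0)
  if (length(unknown))
    problems <- c(problems, sprintf("unknown field(s): %s",
                                    paste(unknown, collapse = ", ")))
  raw <- raw[intersect(names(raw), known)]
  cfg <- tryCatch(do.call(sim_config, raw), error = function(e) e)
  if (inherits(cfg, "error")) problems <- c(problems, conditionMessage(cfg))
  # collect per-field violations explicitly so users see them all at once
  check <- function(name, ok, msg) {
    if (name %in% names(raw) && !isTRUE(ok(raw[[name]]))) msg else NULL
  }
  frac_fields <- c("conversion_efficiency", "inappropriate_conversion",
                   "p_anneal_match", "p_specific", "spike_in_read_fraction",
                   "seq_error_rate")
  for (f in frac_fields)
    problems <- c(problems, check(f, function(x)
      is.numeric(x) && x >= 0 && x <= 1, sprintf("%s must be in [0, 1]", f)))
  if (all(c("frag_min", "frag_max") %in% names(raw)) &&
      raw$frag_min > raw$frag_max)
    problems <- c(problems, "frag_min must be <= frag_max")
  problems <- unique(problems[nzchar(problems)])
  if (length(problems))
    stop(paste0("invalid config:\n  - ", paste(problems, collapse = "\n  - ")),
         call. = FALSE)
  cfg
}
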