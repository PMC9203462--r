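# Quantification layer: conversion QC, strict-threshold site calling, bin
# coverage and classification, motif meta-profiles, read-position
# statistics, subsampling sensitivity, correlation procedures and region
# overlaps. All threshold comparisons are strict (>), mirroring the awk
# filters used on Bismark output ($4 > 50, $5 > coverage).

#' Bisulfite conversion efficiency from the unmethylated spike-in
#'
#' 100 x sum(unmethylated) / sum(total) over all cytosine observations of
#' the spike-in sequence, all contexts. The spike-in is fully unmethylated,
#' so every methylated call there is a conversion failure.
#'
#' @param table a `CytosineCallTable`.
#' @param spike_name name of the spike-in sequence.
#' @return conversion efficiency in percent.
#' @export
conversion_efficiency <- function(table, spike_name) {
  dt <- data.table::as.data.table(table)[seqnames == spike_name]
  tot <- sum(dt$n_meth + dt$n_unmeth)
  if (tot == 0) stop("no spike-in coverage", call. = FALSE)
  100 * sum(dt$n_unmeth) / tot
}

#' Call methylated cytosines under strict thresholds
#'
#' A site is called methylated when its coverage is strictly above
#' `coverage_cutoff` and its methylation level strictly above
#' `meth_call_threshold` percent.
#'
#' @param table a `CytosineCallTable`.
#' @param config a [stats_config()].
#' @return a [region_set()] of 1-base stranded intervals at the called
#'   cytosines.
#' @export
call_methylated_sites <- function(table, config = stats_config()) {
  dt <- call_levels(table)
  dt <- dt[coverage > config$coverage_cutoff &
             level_percent > config$meth_call_threshold]
  region_set(data.frame(seqnames = dt$seqnames, start = dt$pos,
                        end = dt$pos + 1L, strand = dt$strand),
             label = "methylated_sites")
}

# aligned genomic spans of a pair table: per pair up to two intervals
# (0-based half-open), from the post-primer read-1 span and the read-2 span
.pair_spans <- function(pairs) {
  rl <- nchar(pairs$r1[1L])
  pl <- pairs$primer_len[1L]
  ot <- pairs$template_strand == "OT"
  Lf <- pairs$frag_end - pairs$frag_start
  a <- ifelse(ot, pairs$prime_pos - pairs$frag_start,
              pairs$frag_end - 1L - pairs$prime_pos)
  # template-offset intervals [lo, hi] inclusive
  lo1 <- pmax(a + pl - rl, 0L); hi1 <- pmin(a - 1L, Lf - 1L)
  lo2 <- rep(0L, nrow(pairs)); hi2 <- pmin(rl, Lf) - 1L
  has1 <- hi1 >= lo1
  # merge when touching/overlapping (read 2 interval starts at 0)
  merged <- has1 & (lo1 <= hi2 + 1L)
  ulo <- ifelse(merged, pmin(lo1, lo2), lo2)
  uhi <- ifelse(merged, pmax(hi1, hi2), hi2)
  to_g <- function(lo, hi, idx) {
    glo <- ifelse(ot[idx], pairs$frag_start[idx] + lo,
                  pairs$frag_end[idx] - 1L - hi)
    ghi <- ifelse(ot[idx], pairs$frag_start[idx] + hi,
                  pairs$frag_end[idx] - 1L - lo)
    list(lo = glo, hi = ghi)
  }
  all_idx <- seq_len(nrow(pairs))
  g1 <- to_g(ulo, uhi, all_idx)
  spans <- data.table::data.table(seqnames = pairs$seqnames,
                                  lo = g1$lo, hi = g1$hi, pair = all_idx)
  extra <- which(has1 & !merged)
  if (length(extra)) {
    g2 <- to_g(lo1[extra], hi1[extra], extra)
    spans <- rbind(spans, data.table::data.table(
      seqnames = pairs$seqnames[extra], lo = g2$lo, hi = g2$hi,
      pair = extra))
  }
  spans
}

#' Fixed-width bin coverage of a simulated run
#'
#' A read pair increments every bin its aligned read bases overlap (primer
#' bases excluded; a pair counts once per bin). Bins tile each sequence;
#' trailing bins may be short and RPKM normalization uses their true width:
#' count / (kb width x million pairs).
#'
#' @param pairs pair table from [simulate_pairs()] / [read_run()].
#' @param genome a `GenomeSet`.
#' @param bin_size bin width in bases.
#' @param normalize `"raw"` or `"rpkm"`.
#' @return a `BinCoverageTrack`: data.table with `seqnames`, `bin_start`,
#'   `bin_width`, `read_count`, `normalized_value`, `is_methylated` (NA
#'   until [classify_bins()]).
#' @export
bin_coverage <- function(pairs, genome, bin_size = 10L,
                         normalize = c("raw", "rpkm")) {
  normalize <- match.arg(normalize)
  stopifnot(inherits(genome, "GenomeSet"), bin_size >= 1L)
  pairs <- data.table::as.data.table(pairs)
  lens <- seq_lengths(genome)
  nbins <- as.integer(ceiling(lens / bin_size))
  bin_off <- c(0L, cumsum(nbins))[seq_along(nbins)]
  names(bin_off) <- names(lens)
  counts <- integer(sum(nbins))
  if (nrow(pairs)) {
    spans <- .pair_spans(pairs)
    spans[, blo := lo %/% bin_size]
    spans[, bhi := hi %/% bin_size]
    # a pair with two disjoint spans can still share a boundary bin: a pair
    # increments a bin once, so shift the second span past the first's bins
    data.table::setorderv(spans, c("pair", "lo"))
    spans[, prev_bhi := data.table::shift(bhi), by = pair]
    spans[!is.na(prev_bhi) & blo <= prev_bhi, blo := prev_bhi + 1L]
    spans <- spans[blo <= bhi]
    gb <- unname(bin_off[spans$seqnames])
    expand <- sequence(spans$bhi - spans$blo + 1L,
                       from = gb + spans$blo + 1L, by = 1L)
    counts <- tabulate(expand, nbins = sum(nbins))
  }
  track <- data.table::data.table(
    seqnames = rep(names(lens), nbins),
    bin_start = unlist(lapply(nbins, function(k)
      (seq_len(k) - 1L) * bin_size), use.names = FALSE),
    bin_width = unlist(lapply(seq_along(nbins), function(i) {
      w <- rep(bin_size, nbins[i])
      w[nbins[i]] <- lens[i] - (nbins[i] - 1L) * bin_size
      w
    }), use.names = FALSE),
    read_count = counts)
  if (normalize == "rpkm") {
    npairs <- max(nrow(pairs), 1L)
    track[, normalized_value :=
            read_count / ((bin_width / 1000) * (npairs / 1e6))]
  } else {
    track[, normalized_value := as.numeric(read_count)]
  }
  track[, is_methylated := NA]
  data.table::setattr(track, "class",
                      c("BinCoverageTrack", class(data.table::data.table())))
  track[]
}

#' Flag bins overlapping called methylated sites
#'
#' A bin is methylated iff it overlaps at least one called site by at least
#' `overlap_min` bases (half-open interval arithmetic).
#'
#' @param track a `BinCoverageTrack`.
#' @param sites a `RegionSet` from [call_methylated_sites()].
#' @param overlap_min minimum base overlap.
#' @return the track with `is_methylated` set.
#' @export
classify_bins <- function(track, sites, overlap_min = 1L) {
  track <- data.table::copy(data.table::as.data.table(track))
  sdf <- as.data.frame(sites)
  track[, is_methylated := .overlaps_any(
    seqnames, bin_start, bin_start + bin_width,
    sdf$seqnames, sdf$start, sdf$end, min_overlap = overlap_min)]
  data.table::setattr(track, "class",
                      c("BinCoverageTrack", class(data.table::data.table())))
  track[]
}

#' Per-base read coverage
#'
#' Depth of aligned read bases (primer block excluded) at every position,
#' one numeric vector per sequence. Input to [motif_metaprofile()].
#'
#' @param pairs pair table.
#' @param genome a `GenomeSet`.
#' @return named list of numeric vectors.
#' @export
base_coverage <- function(pairs, genome) {
  lens <- seq_lengths(genome)
  gi <- .genome_index(genome)
  cov <- numeric(sum(lens))
  pairs <- data.table::as.data.table(pairs)
  if (nrow(pairs)) {
    spans <- .pair_spans(pairs)
    glo <- unname(gi$off[spans$seqnames]) + spans$lo
    n <- spans$hi - spans$lo + 1L
    expand <- sequence(n, from = glo + 1L, by = 1L)
    cov <- tabulate(expand, nbins = sum(lens))
  }
  split(cov, rep(names(lens), lens))[names(lens)]
}

.as_base_coverage <- function(coverage, genome) {
  if (is.list(coverage) && !is.data.frame(coverage)) return(coverage)
  track <- data.table::as.data.table(coverage)
  lens <- seq_lengths(genome)
  out <- lapply(names(lens), function(nm) {
    tr <- track[seqnames == nm]
    rep(tr$read_count, tr$bin_width)
  })
  setNames(out, names(lens))
}

#' Coverage meta-profile around motif occurrences
#'
#' Aligns per-base coverage on the midpoints of motif occurrences
#' (orientation-normalized: minus-strand occurrences are flipped), columns
#' running from -flank to +flank; occurrences truncated by sequence ends are
#' dropped. The mean profile is the column mean.
#'
#' @param coverage named list of per-base coverage vectors
#'   ([base_coverage()]) or a `BinCoverageTrack`.
#' @param occurrences a `RegionSet` (e.g. [find_motif_occurrences()]).
#' @param flank flanking bases on each side.
#' @param genome `GenomeSet`, required when `coverage` is a track.
#' @return list with `matrix` (occurrences x offsets), `mean_profile` and
#'   `offsets`.
#' @export
motif_metaprofile <- function(coverage, occurrences, flank = 100L,
                              genome = NULL) {
  stopifnot(flank >= 1L)
  occ <- as.data.frame(occurrences)
  if (nrow(occ) == 0L) stop("empty occurrence set", call. = FALSE)
  if (!is.null(genome)) coverage <- .as_base_coverage(coverage, genome)
  rows <- list()
  for (i in seq_len(nrow(occ))) {
    v <- coverage[[occ$seqnames[i]]]
    if (is.null(v)) next
    mid <- (occ$start[i] + occ$end[i]) %/% 2L
    lo <- mid - flank; hi <- mid + flank
    if (lo < 0L || hi >= length(v)) next
    prof <- v[(lo:hi) + 1L]
    if (!is.null(occ$strand) && occ$strand[i] == "-") prof <- rev(prof)
    rows[[length(rows) + 1L]] <- prof
  }
  if (!length(rows)) stop("no occurrence fits within the sequences",
                          call. = FALSE)
  mat <- do.call(rbind, rows)
  colnames(mat) <- as.character(-flank:flank)
  list(matrix = mat, mean_profile = colMeans(mat), offsets = -flank:flank)
}

#' Per-position base composition of reads
#'
#' Fraction of A/C/G/T at each read position; reveals the fixed PPG anchor
#' (G at position 6 of ABBS read 1) and the cytosine enrichment immediately
#' before it.
#'
#' @param reads character vector of read sequences, or a FASTQ path.
#' @return data.table with `position` (1-based) and columns `A`, `C`, `G`,
#'   `T`.
#' @export
read_position_composition <- function(reads) {
  if (length(reads) == 1L && file.exists(reads))
    reads <- as.character(Biostrings::readDNAStringSet(reads, format = "fastq"))
  if (!length(reads)) stop("no reads", call. = FALSE)
  rl <- nchar(reads[1L])
  stopifnot(all(nchar(reads) == rl))
  cat_raw <- charToRaw(paste0(reads, collapse = ""))
  posv <- rep(seq_len(rl), times = length(reads))
  base_i <- match(cat_raw, .RAW_BASES)
  code <- (posv - 1L) * 4L + base_i
  cnt <- tabulate(code, nbins = rl * 4L)
  mat <- matrix(cnt, ncol = 4L, byrow = TRUE) / length(reads)
  data.table::data.table(position = seq_len(rl), A = mat[, 1], C = mat[, 2],
                         G = mat[, 3], T = mat[, 4])
}

#' Per-position 5mC prevalence in read 1
#'
#' At each read-1 position past the primer block, the fraction of cytosine
#' observations that read methylated. Deliberately untrimmed: this statistic
#' is positional.
#'
#' @param pairs pair table.
#' @param genome a `GenomeSet`.
#' @return data.table with `position` (1-based), `n_meth`, `n_unmeth`,
#'   `prevalence`.
#' @export
read_position_methylation <- function(pairs, genome) {
  pairs <- data.table::as.data.table(pairs)
  stopifnot(nrow(pairs) > 0L)
  gi <- .genome_index(genome)
  rl <- nchar(pairs$r1[1L])
  pl <- pairs$primer_len[1L]
  np <- nrow(pairs)
  ot <- pairs$template_strand == "OT"
  Lf <- pairs$frag_end - pairs$frag_start
  a <- ifelse(ot, pairs$prime_pos - pairs$frag_start,
              pairs$frag_end - 1L - pairs$prime_pos)
  off <- unname(gi$off[pairs$seqnames])
  k <- rl - pl
  p <- rep(seq_len(np), each = k)
  iv <- rep(pl:(rl - 1L), times = np)
  r1cat <- charToRaw(paste0(pairs$r1, collapse = ""))
  obs <- .comp_raw(r1cat[(p - 1L) * rl + iv + 1L])
  t <- a[p] - 1L - (iv - pl)
  ok <- t >= 0L & t < Lf[p]
  g <- ifelse(ot[p], pairs$frag_start[p] + t, pairs$frag_end[p] - 1L - t)
  gb <- gi$blob[(off[p] + g)[ok] + 1L]
  is_tc <- ifelse(ot[p][ok], gb == .RAW_C, gb == .RAW_G)
  obs_ok <- obs[ok]
  keep <- is_tc & (obs_ok == .RAW_C | obs_ok == .RAW_T)
  dt <- data.table::data.table(position = iv[ok][keep] + 1L,
                               m = obs_ok[keep] == .RAW_C)
  res <- dt[, list(n_meth = sum(m), n_unmeth = sum(!m)), by = position]
  data.table::setorderv(res, "position")
  res[, prevalence := n_meth / (n_meth + n_unmeth)]
  res[]
}

#' Subsample read pairs without replacement
#'
#' Draws exactly `round(fraction * n)` pairs, deterministically for a given
#' seed.
#'
#' @param pairs pair table.
#' @param fraction fraction in (0, 1].
#' @param seed integer seed.
#' @return the subsampled pair table (original order preserved).
#' @export
subsample_pairs <- function(pairs, fraction, seed = 1L) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]", call. = FALSE)
  pairs <- data.table::as.data.table(pairs)
  n <- nrow(pairs)
  k <- as.integer(round(fraction * n))
  if (k >= n) return(pairs)
  set.seed(derive_seed(seed, 31L))
  pairs[sort(sample.int(n, k))]
}

#' Called-site counts at varying total read counts
#'
#' For each requested read count: subsample that many pairs, call cytosines,
#' call methylated sites under the strict thresholds, and report the count.
#' The expected curve is monotone non-decreasing in read count.
#'
#' @param pairs pair table.
#' @param genome a `GenomeSet`.
#' @param read_counts integer vector of total pair counts (each at most
#'   `nrow(pairs)`).
#' @param config a [stats_config()].
#' @param policy a [trim_policy()].
#' @param seed integer seed.
#' @return data.table with `read_count` and `n_sites`.
#' @export
sensitivity_curve <- function(pairs, genome, read_counts,
                              config = stats_config(),
                              policy = trim_policy(), seed = 1L) {
  pairs <- data.table::as.data.table(pairs)
  if (any(read_counts > nrow(pairs)))
    stop("read_counts exceed available pairs", call. = FALSE)
  n_sites <- integer(length(read_counts))
  for (i in seq_along(read_counts)) {
    k <- as.integer(read_counts[i])
    if (k == 0L) { n_sites[i] <- 0L; next }
    set.seed(derive_seed(seed, 37L + i))
    sub <- pairs[sort(sample.int(nrow(pairs), k))]
    tab <- call_cytosines(sub, genome, policy)
    n_sites[i] <- nrow(call_methylated_sites(tab, config))
  }
  data.table::data.table(read_count = as.integer(read_counts),
                         n_sites = n_sites)
}

#' Pearson correlation with a two-tailed test
#'
#' @param x,y numeric vectors of equal length >= 3 with non-zero variance.
#' @return list with `r`, `p` (two-tailed) and `n`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need equal-length vectors with n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate (zero-variance) input", call. = FALSE)
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Correlation of methylation levels between two call tables
#'
#' Joins the two tables on (sequence, position, strand), keeps sites with
#' coverage strictly above the cutoff in BOTH, and correlates percent
#' levels. `mode = "all"` uses every joined site; `"intermediate"` keeps
#' sites whose level on the binning axis lies strictly inside
#' `intermediate_range`; `"homogeneous"` bins sites by the binning-axis
#' level into `100 / resample_bin_width` equal-width bins over \[0, 100\]
#' and draws an equal number per bin without replacement before
#' correlating, removing the leverage of the bimodal extremes.
#'
#' @param table_a,table_b `CytosineCallTable`s (a = ABBS, b = WGBS by
#'   convention).
#' @param config a [stats_config()].
#' @param mode `"all"`, `"intermediate"` or `"homogeneous"`.
#' @param n_per_bin sites per bin in homogeneous mode; `NULL` uses the
#'   largest equal count every bin can supply. An explicit value errors if
#'   any bin holds fewer sites.
#' @param seed integer seed for the homogeneous resampling.
#' @param bin_axis `"b"` (default; the WGBS/X axis) or `"a"`: which table's
#'   level drives the intermediate filter and the homogeneous binning.
#' @return list with `r`, `p`, `n_sites` and (homogeneous mode)
#'   `n_per_bin`.
#' @export
methylation_correlation <- function(table_a, table_b,
                                    config = stats_config(),
                                    mode = c("all", "intermediate",
                                             "homogeneous"),
                                    n_per_bin = NULL, seed = 1L,
                                    bin_axis = c("b", "a")) {
  mode <- match.arg(mode)
  bin_axis <- match.arg(bin_axis)
  a <- call_levels(table_a)[, list(seqnames, pos, strand,
                                   cov_a = coverage, lev_a = level_percent)]
  b <- call_levels(table_b)[, list(seqnames, pos, strand,
                                   cov_b = coverage, lev_b = level_percent)]
  j <- merge(a, b, by = c("seqnames", "pos", "strand"))
  j <- j[cov_a > config$coverage_cutoff & cov_b > config$coverage_cutoff]
  if (nrow(j) == 0L) stop("empty join after coverage filter", call. = FALSE)
  axis <- if (bin_axis == "b") j$lev_b else j$lev_a
  if (mode == "intermediate") {
    keep <- axis > config$intermediate_range[1] &
      axis < config$intermediate_range[2]
    j <- j[keep]
    if (nrow(j) < 3L) stop("too few intermediate sites", call. = FALSE)
    res <- pearson(j$lev_a, j$lev_b)
    return(list(r = res$r, p = res$p, n_sites = res$n, mode = mode))
  }
  if (mode == "homogeneous") {
    width <- config$resample_bin_width
    nbins <- as.integer(100 / width)
    bin <- pmax(1L, pmin(nbins, as.integer(ceiling(axis / width))))
    counts <- tabulate(bin, nbins = nbins)
    if (is.null(n_per_bin)) {
      n_use <- min(counts)
      if (n_use == 0L)
        stop("a resampling bin holds no sites", call. = FALSE)
    } else {
      n_use <- as.integer(n_per_bin)
      if (any(counts < n_use))
        stop(sprintf("bin(s) with fewer than %d sites (min %d)",
                     n_use, min(counts)), call. = FALSE)
    }
    set.seed(derive_seed(seed, 41L))
    idx <- unlist(lapply(seq_len(nbins), function(bb) {
      w <- which(bin == bb)
      w[sample.int(length(w), n_use)]
    }), use.names = FALSE)
    res <- pearson(j$lev_a[idx], j$lev_b[idx])
    return(list(r = res$r, p = res$p, n_sites = res$n, n_per_bin = n_use,
                mode = mode))
  }
  res <- pearson(j$lev_a, j$lev_b)
  list(r = res$r, p = res$p, n_sites = res$n, mode = mode)
}

#' Fractions of sites inside and outside a region set
#'
#' A site (1-base interval at the cytosine position; strand ignored) is
#' "inside" iff it overlaps any region by at least `overlap_min` bases.
#' The two fractions sum to 1.
#'
#' @param sites a `RegionSet` of called sites.
#' @param regions a `RegionSet` (e.g. CpG islands or RRBS targets).
#' @param overlap_min minimum base overlap.
#' @return list with `fraction_in` and `fraction_out`.
#' @export
region_overlap_fractions <- function(sites, regions, overlap_min = 1L) {
  sdf <- as.data.frame(sites)
  if (nrow(sdf) == 0L) stop("empty site set", call. = FALSE)
  rdf <- as.data.frame(regions)
  inside <- .overlaps_any(sdf$seqnames, sdf$start, sdf$end,
                          rdf$seqnames, rdf$start, rdf$end,
                          min_overlap = overlap_min)
  list(fraction_in = mean(inside), fraction_out = mean(!inside))
}
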