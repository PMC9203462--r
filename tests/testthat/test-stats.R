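test_that("conversion efficiency is the unmethylated fraction of spike observations", {
  g <- genome_set(c(chr = "ACGT", lam = "ACGT"), spike_in_name = "lam")
  tab <- abbskit:::.finish_call_table(
    data.table::data.table(site_key = c(1L * 2L, (4L + 1L) * 2L),
                           n_meth = c(5L, 4L), n_unmeth = c(5L, 996L)),
    g, 1010, 0)
  expect_equal(conversion_efficiency(tab, "lam"), 99.6)
  tab2 <- abbskit:::.finish_call_table(
    data.table::data.table(site_key = (4L + 1L) * 2L,
                           n_meth = 0L, n_unmeth = 50L), g, 50, 0)
  expect_equal(conversion_efficiency(tab2, "lam"), 100)
  expect_error(conversion_efficiency(tab, "missing"), "no spike-in coverage")
})

test_that("site calling applies strict thresholds at both boundaries", {
  g <- genome_set(c(c = paste(rep("AC", 50), collapse = "")))
  mk <- function(n_meth, n_unmeth, pos)
    data.table::data.table(site_key = pos * 2L,
                           n_meth = as.integer(n_meth),
                           n_unmeth = as.integer(n_unmeth))
  tab <- abbskit:::.finish_call_table(data.table::rbindlist(list(
    mk(18, 12, 1L),    # 60% at coverage 30 -> called
    mk(13, 13, 3L),    # exactly 50% -> NOT called (strict >)
    mk(20, 5, 5L),     # 80% but coverage exactly 25 -> NOT called (strict >)
    mk(26, 0, 7L))),   # 100% at 26 -> called
    g, 107, 0)
  sites <- call_methylated_sites(tab, stats_config())
  expect_equal(as.data.frame(sites)$start, c(1L, 7L))
})

test_that("bin coverage counts pair incidences and conserves them", {
  g <- genome_set(c(c = paste(rep("ACGT", 5000), collapse = "")))
  pairs <- data.table::data.table(
    read_id = "p1", r1 = strrep("A", 38), r2 = strrep("A", 38),
    seqnames = "c", frag_start = 1000L, frag_end = 1250L,
    template_strand = "OT", protocol = "WGBS", anchor_pos = -1L,
    prime_pos = 1100L, primer_len = 6L, specific = FALSE)
  tr <- bin_coverage(pairs, g, 10000L)
  expect_equal(tr$read_count, c(1L, 0L))   # everything inside the first bin
  # fine bins: read 2 covers [1000,1038), read 1 covers [1068,1100): the
  # pair increments each overlapped 10 bp bin exactly once
  tr10 <- bin_coverage(pairs, g, 10L)
  hit <- tr10[tr10$read_count > 0]
  expect_true(all(hit$read_count == 1L))
  expect_equal(hit$bin_start,
               c(seq(1000L, 1030L, 10L), seq(1060L, 1090L, 10L)))
  # rpkm normalization uses true width and million-pair scaling
  trr <- bin_coverage(pairs, g, 10000L, normalize = "rpkm")
  expect_equal(trr$normalized_value[1], 1 / (10 * (1 / 1e6)))
})

test_that("bin classification respects half-open boundaries", {
  g <- genome_set(c(c = paste(rep("AC", 60), collapse = "")))
  track <- bin_coverage(data.table::data.table(), g, 10L)
  sites <- region_set(data.frame(seqnames = "c", start = 10L, end = 11L,
                                 strand = "+"))
  cl <- classify_bins(track, sites)
  expect_true(cl$is_methylated[cl$bin_start == 10L])
  expect_false(any(cl$is_methylated[cl$bin_start != 10L]))
  # empty site set -> all unmethylated
  cl0 <- classify_bins(track, region_set(data.frame()))
  expect_false(any(cl0$is_methylated))
})

test_that("ABBS concentrates coverage on methylated bins, WGBS does not", {
  sc <- build_scenario("ecoli_dcm", seed = 7, genome_length = 40000L)
  cfg0 <- sim_config(n_read_pairs = 10L, read_length = 38L, seed = 1)
  np <- pairs_for_depth(sc$genome, cfg0, 35)
  ratio <- list()
  for (proto in c("ABBS", "WGBS")) {
    cfg <- sim_config(protocol = proto, n_read_pairs = np, read_length = 38,
                      seed = 41)
    pairs <- simulate_pairs(sc$genome, sc$methylome, cfg)
    tab <- call_cytosines(pairs, sc$genome)
    sites <- call_methylated_sites(tab, stats_config())
    tr <- classify_bins(bin_coverage(pairs, sc$genome, 10L), sites)
    tr <- tr[tr$seqnames == "ecoli_synthetic"]
    ratio[[proto]] <- mean(tr$read_count[tr$is_methylated]) /
      mean(tr$read_count[!tr$is_methylated])
  }
  expect_gt(ratio$ABBS, ratio$WGBS)       # enrichment property
  expect_gt(ratio$ABBS, 1.2)
  expect_lt(abs(ratio$WGBS - 1), 0.2)     # WGBS spreads evenly
})

test_that("meta-profile peaks at the Dcm motif and nowhere else", {
  sc <- build_scenario("ecoli_dcm", seed = 7, genome_length = 40000L)
  scm <- build_scenario("ecoli_dcm_minus", seed = 7, genome_length = 40000L)
  keep_main <- function(occ) {
    df <- as.data.frame(occ)
    region_set(df[df$seqnames == "ecoli_synthetic", ], attr(occ, "label"))
  }
  occ_dcm <- keep_main(find_motif_occurrences(sc$genome, "CCWGG"))
  occ_ctl <- keep_main(find_motif_occurrences(sc$genome, "AASTT"))
  peak_ratio <- function(genome, methylome, proto) {
    cfg <- sim_config(protocol = proto, n_read_pairs = 25000,
                      read_length = 38, seed = 42)
    pairs <- simulate_pairs(genome, methylome, cfg)
    cov <- base_coverage(pairs, genome)
    sapply(list(dcm = occ_dcm, ctl = occ_ctl), function(occ) {
      mp <- motif_metaprofile(cov, occ, flank = 100)
      mean(mp$mean_profile[abs(mp$offsets) <= 38]) /
        mean(mp$mean_profile[abs(mp$offsets) > 60])
    })
  }
  r_abbs <- peak_ratio(sc$genome, sc$methylome, "ABBS")
  expect_gt(r_abbs[["dcm"]], 1.3)           # reads accumulate at CCWGG
  expect_lt(abs(r_abbs[["ctl"]] - 1), 0.15) # flat at the control motif
  r_wgbs <- peak_ratio(sc$genome, sc$methylome, "WGBS")
  expect_lt(abs(r_wgbs[["dcm"]] - 1), 0.15) # WGBS flat at CCWGG
  r_minus <- peak_ratio(scm$genome, scm$methylome, "ABBS")
  expect_lt(abs(r_minus[["dcm"]] - 1), 0.15) # dcm-: no accumulation
  # uniform coverage -> flat profile, exactly
  flat <- motif_metaprofile(list(ecoli_synthetic =
                                   rep(5, 40000)), occ_dcm, flank = 50)
  expect_true(all(flat$mean_profile == 5))
})

test_that("read position composition exposes the fixed PPG anchor", {
  g <- fixture_dcm_genome(30000L)
  m <- dcm_methylome(g)
  cfg <- sim_config(protocol = "ABBS", n_read_pairs = 3000, read_length = 38,
                    seq_error_rate = 0, seed = 43)
  pairs <- simulate_pairs(g, m, cfg)
  comp <- read_position_composition(pairs$r1)
  expect_equal(comp$G[6], 1.0)            # PPG anchor at the 6th position
  cfgw <- sim_config(protocol = "WGBS", n_read_pairs = 3000,
                     read_length = 38, seq_error_rate = 0, seed = 43)
  pw <- simulate_pairs(g, m, cfgw)
  compw <- read_position_composition(pw$r1)
  expect_true(all(compw$G < 1.0))         # randomized hexamer: no fixed base
  expect_equal(unname(rowSums(as.matrix(comp[, c("A", "C", "G", "T")]))),
               rep(1, 38))
})

test_that("read-1 methylation prevalence is positional and unbiased", {
  g <- genome_set(c(chr = paste(rep("ACGT", 2000), collapse = "")))
  m <- fixture_binary_cpg_methylome(g)   # every CpG at level 1
  cfg <- sim_config(protocol = "WGBS", n_read_pairs = 2000, read_length = 38,
                    conversion_efficiency = 1, seed = 44,
                    spike_in_read_fraction = 0)
  pairs <- simulate_pairs(g, m, cfg)
  pm <- read_position_methylation(pairs, g)
  # in this genome every C is a CpG C, so prevalence is 1 at all positions
  expect_true(all(pm$prevalence[pm$n_meth + pm$n_unmeth > 50] > 0.999))
  # WGBS prevalence has no positional trend on a mixed methylome
  sc <- fixture_mammalian(60000L)
  cfg2 <- sim_config(protocol = "WGBS", n_read_pairs = 20000,
                     read_length = 38, seed = 45)
  p2 <- simulate_pairs(sc$genome, sc$methylome, cfg2)
  pm2 <- read_position_methylation(p2, sc$genome)
  fit <- stats::lm(prevalence ~ position, data = pm2[pm2$position > 6])
  ci <- stats::confint(fit)["position", ]
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("subsampling is exact, deterministic and seed-sensitive", {
  pairs <- data.table::data.table(read_id = sprintf("r%04d", 1:1000),
                                  x = 1:1000)
  s1 <- subsample_pairs(pairs, 0.5, seed = 1)
  expect_equal(nrow(s1), 500L)
  expect_identical(as.data.frame(subsample_pairs(pairs, 0.5, seed = 1)),
                   as.data.frame(s1))
  s2 <- subsample_pairs(pairs, 0.5, seed = 2)
  expect_false(identical(s1$read_id, s2$read_id))
  ov <- length(intersect(s1$read_id, s2$read_id))
  expect_gt(ov, 170); expect_lt(ov, 330)  # hypergeometric around 250
  expect_identical(as.data.frame(subsample_pairs(pairs, 1, seed = 1)),
                   as.data.frame(pairs))
  expect_error(subsample_pairs(pairs, 0), "fraction")
})

test_that("sensitivity curves start at zero and increase with reads", {
  sc <- build_scenario("ecoli_dcm", seed = 7, genome_length = 40000L)
  cfg <- sim_config(protocol = "ABBS",
                    n_read_pairs = pairs_for_depth(
                      sc$genome, sim_config(read_length = 38L), 60),
                    read_length = 38, seed = 46)
  pairs <- simulate_pairs(sc$genome, sc$methylome, cfg)
  curve <- sensitivity_curve(pairs, sc$genome,
                             c(0L, nrow(pairs) %/% 4L, nrow(pairs)),
                             seed = 5)
  expect_equal(curve$n_sites[1], 0L)
  expect_true(all(diff(curve$n_sites) >= 0))
  expect_gt(curve$n_sites[3], curve$n_sites[2])
  expect_error(sensitivity_curve(pairs, sc$genome, nrow(pairs) + 1L),
               "exceed")
})

test_that("pearson matches the closed form and a brute-force oracle", {
  expect_equal(pearson(c(1, 2, 3), c(1, 2, 4))$r, 0.9819805061, tolerance = 1e-9)
  expect_equal(pearson(1:10, 1:10)$r, 1.0)
  expect_equal(pearson(1:10, -(1:10))$r, -1.0)
  # two-pass textbook formula as independent oracle
  brute <- function(x, y) {
    mx <- sum(x) / length(x); my <- sum(y) / length(y)
    sum((x - mx) * (y - my)) /
      sqrt(sum((x - mx)^2) * sum((y - my)^2))
  }
  set.seed(8)
  for (k in 1:5) {
    x <- rnorm(200); y <- 0.3 * x + rnorm(200)
    expect_lt(abs(pearson(x, y)$r - brute(x, y)), 1e-12)
  }
  expect_error(pearson(c(1, 1, 1), c(1, 2, 3)), "degenerate")
  expect_error(pearson(1:2, 1:2), "n >= 3")
})

test_that("methylation_correlation joins, filters and resamples as specified", {
  g <- genome_set(c(c = paste(rep("AC", 4000), collapse = "")))
  set.seed(9)
  pos <- seq(1L, 7999L, by = 2L)          # every C on the + strand
  lev <- runif(length(pos))
  mk_tab <- function(noise) {
    n <- 60L
    meth <- rbinom(length(pos), n, pmin(pmax(lev + noise, 0), 1))
    abbskit:::.finish_call_table(
      data.table::data.table(site_key = pos * 2L, n_meth = meth,
                             n_unmeth = n - meth), g, length(pos) * n, 0)
  }
  ta <- mk_tab(0); tb <- mk_tab(0.0)
  same <- methylation_correlation(ta, ta, mode = "all")
  expect_equal(same$r, 1.0)
  expect_equal(methylation_correlation(ta, ta, mode = "homogeneous",
                                       n_per_bin = 20L, seed = 1)$r, 1.0)
  r_all <- methylation_correlation(ta, tb, mode = "all")
  expect_gt(r_all$r, 0.9)
  # homogeneous draws exactly n_per_bin from each of the twenty bins
  hom <- methylation_correlation(ta, tb, mode = "homogeneous",
                                 n_per_bin = 30L, seed = 2)
  expect_equal(hom$n_sites, 20L * 30L)
  expect_equal(hom$n_per_bin, 30L)
  # over-demanding n_per_bin errors
  expect_error(methylation_correlation(ta, tb, mode = "homogeneous",
                                       n_per_bin = 10000L), "fewer")
  # intermediate mode restricts to the open (20, 80) band on the B axis
  imd <- methylation_correlation(ta, tb, mode = "intermediate")
  lvb <- call_levels(tb)
  expect_lte(imd$n_sites, sum(lvb$level_percent > 20 & lvb$level_percent < 80))
  # empty join errors
  thin <- abbskit:::.finish_call_table(
    data.table::data.table(site_key = 1L * 2L, n_meth = 1L, n_unmeth = 1L),
    g, 2, 0)
  expect_error(methylation_correlation(ta, thin), "empty join")
})

test_that("region overlap fractions use >= 1 bp overlap and sum to one", {
  sites <- region_set(data.frame(seqnames = "c", start = c(5L, 20L),
                                 end = c(6L, 21L), strand = "+"))
  regions <- region_set(data.frame(seqnames = "c", start = 0L, end = 10L))
  ov <- region_overlap_fractions(sites, regions)
  expect_equal(ov$fraction_in, 0.5)
  expect_equal(ov$fraction_in + ov$fraction_out, 1.0)
  # site at the region end (half-open): outside
  abut <- region_set(data.frame(seqnames = "c", start = 10L, end = 11L,
                                strand = "+"))
  expect_equal(region_overlap_fractions(abut, regions)$fraction_in, 0)
  expect_error(region_overlap_fractions(region_set(data.frame()), regions),
               "empty site set")
})
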