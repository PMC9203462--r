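# Caller: brute-force oracle equivalence, trimming geometry, conservation,
# context classification, estimator consistency, bedGraph strictness.

test_that("observations match a brute-force re-simulation of base pairing", {
  g <- fixture_dcm_genome(20000L)
  m <- dcm_methylome(g)
  policy <- trim_policy()
  for (proto in c("ABBS", "WGBS")) {
    cfg <- sim_config(protocol = proto, n_read_pairs = 12, read_length = 38,
                      seed = 31)
    pairs <- simulate_pairs(g, m, cfg)
    for (i in seq_len(nrow(pairs))) {
      got <- observations_from_pair(pairs[i], g, policy)
      want <- brute_force_observations(pairs[i], g, policy)
      expect_equal(nrow(got), nrow(want))
      if (nrow(got)) {
        o1 <- got[order(got$pos, got$strand), c("pos", "strand", "observed")]
        o2 <- want[order(want$pos, want$strand), ]
        rownames(o1) <- rownames(o2) <- NULL
        expect_equal(o1, o2)
      }
    }
  }
})

test_that("call_cytosines aggregates exactly the per-pair observations", {
  g <- fixture_dcm_genome(20000L)
  m <- dcm_methylome(g)
  cfg <- sim_config(protocol = "ABBS", n_read_pairs = 300, read_length = 38,
                    seed = 32)
  pairs <- simulate_pairs(g, m, cfg)
  policy <- trim_policy()
  tab <- call_cytosines(pairs, g, policy)
  per_pair <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i)
    observations_from_pair(pairs[i], g, policy)))
  agg <- stats::aggregate(cbind(n_meth = observed == "METH",
                                n_unmeth = observed == "UNMETH")
                          ~ seqnames + pos + strand, data = per_pair, FUN = sum)
  agg <- agg[order(agg$seqnames, agg$pos, agg$strand), ]
  tdf <- as.data.frame(tab)[, c("seqnames", "pos", "strand",
                                "n_meth", "n_unmeth")]
  rownames(agg) <- rownames(tdf) <- NULL
  agg$n_meth <- as.integer(agg$n_meth); agg$n_unmeth <- as.integer(agg$n_unmeth)
  expect_equal(tdf, agg)
  # conservation: table total equals retained observation count
  expect_equal(sum(tab$n_meth + tab$n_unmeth), attr(tab, "report")$n_obs)
  expect_equal(sum(tab$n_meth + tab$n_unmeth), nrow(per_pair))
})

test_that("trimming excludes the primer block and bounds informative bases", {
  g <- fixture_dcm_genome(20000L)
  m <- dcm_methylome(g)
  cfg <- sim_config(protocol = "ABBS", n_read_pairs = 200, read_length = 38,
                    conversion_efficiency = 1, p_anneal_match = 1, seed = 33)
  pairs <- simulate_pairs(g, m, cfg)
  policy <- trim_policy()
  for (i in seq_len(20)) {
    obs <- observations_from_pair(pairs[i], g, policy)
    # 2 x 38 with trims 7/5: at most 26 informative positions per mate
    expect_lte(nrow(obs), 2 * (38 - 7 - 5))
    # no observation outside the fragment
    expect_true(all(obs$pos >= pairs$frag_start[i] &
                      obs$pos < pairs$frag_end[i]))
    # the anchor itself is excluded from read 1 (it sits at position 6,
    # inside the trim); it can only ever enter via the distal end of read 2,
    # i.e. when its template offset is exactly read_length - 6
    if (pairs$specific[i]) {
      a_off <- ifelse(pairs$template_strand[i] == "OT",
                      pairs$anchor_pos[i] - pairs$frag_start[i],
                      pairs$frag_end[i] - 1L - pairs$anchor_pos[i])
      if (a_off > 38 - 6) expect_false(pairs$anchor_pos[i] %in% obs$pos)
    }
  }
})

test_that("cytosine context follows the strand-aware CpG/CHG/CHH rule", {
  g <- genome_set(c(c = "ACGTACAGTACATT"))
  expect_equal(classify_context(g, "c", 1, "+"), "CpG")
  expect_equal(classify_context(g, "c", 5, "+"), "CHG")   # C,A,G
  expect_equal(classify_context(g, "c", 10, "+"), "CHH")  # C,A,T
  expect_equal(classify_context(g, "c", 2, "-"), "CpG")   # G preceded by C
  g2 <- genome_set(c(c = "CCG"))
  expect_equal(classify_context(g2, "c", 0, "+"), "CHG")  # C,C,G
  # sequence edge: insufficient downstream bases defaults to CHH
  g3 <- genome_set(c(c = "AAC"))
  expect_equal(classify_context(g3, "c", 2, "+"), "CHH")
  expect_error(classify_context(g, "c", 0, "+"), "not a cytosine")
})

test_that("WGBS levels recover the true methylome within binomial error", {
  g <- generate_genome(data.frame(name = c("chr", "lam"),
                                  length = c(8000, 2000), gc_fraction = 0.45,
                                  cpg_enrichment = c(1, 1)), seed = 13,
                       spike_in_name = "lam")
  subj <- Biostrings::DNAString(g$sequences[["chr"]])
  cg <- Biostrings::start(Biostrings::matchPattern("CG", subj)) - 1L
  set.seed(7)
  lev <- runif(length(cg))
  m <- methylome_profile(data.frame(seqnames = "chr", pos = c(cg, cg + 1L),
                                    strand = rep(c("+", "-"), each = length(cg)),
                                    level = rep(lev, 2)), g)
  cfg <- sim_config(protocol = "WGBS", n_read_pairs = 10L, read_length = 38,
                    conversion_efficiency = 1, seed = 34)
  np <- pairs_for_depth(g, cfg, 200)
  cfg <- sim_config(protocol = "WGBS", n_read_pairs = np, read_length = 38,
                    conversion_efficiency = 1, seed = 34)
  tab <- call_levels(call_cytosines(simulate_pairs(g, m, cfg), g))
  j <- merge(as.data.frame(tab[tab$strand == "+" & tab$seqnames == "chr"]),
             data.frame(pos = cg, true = 100 * lev), by = "pos")
  j <- j[j$coverage >= 100, ]
  expect_gt(nrow(j), 50)
  se <- 100 * sqrt(pmax(j$true / 100 * (1 - j$true / 100), 1e-4) / j$coverage)
  frac_in <- mean(abs(j$level_percent - j$true) < 3 * se)
  expect_gt(frac_in, 0.95)
  # unmethylated spike reads at the conversion-failure floor
  lam <- tab[tab$seqnames == "lam"]
  expect_lt(100 * sum(lam$n_meth) / sum(lam$coverage), 0.2)
})

test_that("bedGraph output applies strict coverage filtering and round-trips", {
  g <- genome_set(c(c = "ACGTTACGGA"))
  tab <- abbskit:::.finish_call_table(
    data.table::data.table(site_key = c(1L * 2L, 6L * 2L, 7L * 2L + 1L),
                           n_meth = c(10L, 26L, 2L),
                           n_unmeth = c(15L, 0L, 0L)), g, 53, 0)
  path <- tempfile(fileext = ".bedgraph")
  write_bedgraph(tab, path, min_coverage = 25L)
  kept <- read.delim(path, header = FALSE)
  expect_equal(kept$V2, 6L)               # 25/25 excluded, 26/0 kept, 2/0 excluded
  expect_equal(kept$V4, 100)
  # round-trip with no filter is lossless
  write_bedgraph(tab, path, min_coverage = 0L)
  tab2 <- read_bedgraph(path, g)
  expect_equal(as.data.frame(tab2), as.data.frame(tab))
  # CX report carries all six columns
  cx <- tempfile(fileext = ".txt")
  write_cx_report(tab, cx)
  cxdf <- read.delim(cx, header = FALSE)
  expect_equal(ncol(cxdf), 6L)
  expect_equal(sum(cxdf$V4), sum(tab$n_meth))
})
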