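# Small deterministic fixtures shared across test files. Everything is
# generated in code; no binary data.

# genome with a known Dcm landscape plus an unmethylated spike-in
fixture_dcm_genome <- function(main_len = 50000L, seed = 3L) {
  generate_genome(
    data.frame(name = c("chr", "lam"),
               length = c(main_len, 10000L),
               gc_fraction = c(0.51, 0.5),
               cpg_enrichment = c(1, 1)),
    seed = seed, spike_in_name = "lam")
}

# small mammalian-like scenario for medium-cost tests
fixture_mammalian <- function(len = 100000L, seed = 11L) {
  build_scenario("mammalian_k562_like", seed = seed, genome_length = len)
}

# fully methylated (level exactly 1) CpG methylome: deterministic
# realization, used by reconstruction oracles
fixture_binary_cpg_methylome <- function(genome) {
  ent <- list()
  for (nm in setdiff(names(genome$sequences), genome$spike_in_name)) {
    subj <- Biostrings::DNAString(genome$sequences[[nm]])
    cg <- Biostrings::start(Biostrings::matchPattern("CG", subj)) - 1L
    if (length(cg))
      ent[[nm]] <- data.frame(seqnames = nm, pos = c(cg, cg + 1L),
                              strand = rep(c("+", "-"), each = length(cg)),
                              level = 1)
  }
  methylome_profile(do.call(rbind, ent), genome)
}

revcomp_chr <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

comp_chr <- function(s)
  as.character(Biostrings::complement(Biostrings::DNAString(s)))

# brute-force, loop-based re-simulation of the read-pair geometry from a
# truth record under deterministic settings (p_anneal_match = 1,
# conversion_efficiency = 1, binary methylome, no errors). Independent of
# the package's byte-level engine: string operations only.
brute_force_reads <- function(pair_row, genome, methylome, read_length) {
  p <- as.list(as.data.frame(pair_row)[1L, ])
  slice <- substr(genome$sequences[[p$seqnames]], p$frag_start + 1L,
                  p$frag_end)
  tmpl <- if (p$template_strand == "OT") slice else revcomp_chr(slice)
  conv <- vapply(seq_len(nchar(tmpl)), function(k) {
    b <- substr(tmpl, k, k)
    if (b != "C") return(b)
    g <- if (p$template_strand == "OT") p$frag_start + (k - 1L)
         else p$frag_end - k
    strand2 <- if (p$template_strand == "OT") "+" else "-"
    m <- methylome[methylome$seqnames == p$seqnames &
                     methylome$pos == g & methylome$strand == strand2, ]
    if (nrow(m) && m$level[1] == 1) "C" else "T"
  }, character(1))
  conv <- paste(conv, collapse = "")
  a <- if (p$template_strand == "OT") p$prime_pos - p$frag_start
       else p$frag_end - 1L - p$prime_pos
  if (p$protocol == "WGBS") {
    primer <- paste(vapply(1:6, function(i)
      comp_chr(substr(conv, a + 7L - i, a + 7L - i)), character(1)),
      collapse = "")
  } else {
    primer <- paste0(paste(vapply(1:5, function(i)
      comp_chr(substr(conv, a + 7L - i, a + 7L - i)), character(1)),
      collapse = ""), "G")
  }
  synth <- paste0(primer, revcomp_chr(substr(conv, 1L, a)))
  list(r1 = substr(synth, 1L, read_length),
       r2 = substr(revcomp_chr(synth), 1L, read_length),
       converted = conv, a = a)
}

# brute-force observation extractor: explicit loops over read positions,
# written independently of observations_from_pair()
brute_force_observations <- function(pair_row, genome, policy) {
  p <- as.list(as.data.frame(pair_row)[1L, ])
  rl <- nchar(p$r1)
  L <- p$frag_end - p$frag_start
  ot <- p$template_strand == "OT"
  a <- if (ot) p$prime_pos - p$frag_start else p$frag_end - 1L - p$prime_pos
  seqc <- genome$sequences[[p$seqnames]]
  out <- data.frame(pos = integer(0), strand = character(0),
                    observed = character(0))
  seen <- integer(0)
  for (i in seq(max(p$primer_len, policy$ignore_r1_start),
                rl - 1L - policy$ignore_r1_end)) {
    t <- a - 1L - (i - p$primer_len)
    if (t < 0L || t >= L) next
    seen <- c(seen, t)
    g <- if (ot) p$frag_start + t else p$frag_end - 1L - t
    ref <- substr(seqc, g + 1L, g + 1L)
    if ((ot && ref != "C") || (!ot && ref != "G")) next
    obs_base <- comp_chr(substr(p$r1, i + 1L, i + 1L))
    if (obs_base == "C")
      out <- rbind(out, data.frame(pos = g, strand = if (ot) "+" else "-",
                                   observed = "METH"))
    else if (obs_base == "T")
      out <- rbind(out, data.frame(pos = g, strand = if (ot) "+" else "-",
                                   observed = "UNMETH"))
  }
  for (j in seq(policy$ignore_r2_start, rl - 1L - policy$ignore_r2_end)) {
    if (j >= L) next
    if (policy$no_overlap && j %in% seen) next
    g <- if (ot) p$frag_start + j else p$frag_end - 1L - j
    ref <- substr(seqc, g + 1L, g + 1L)
    if ((ot && ref != "C") || (!ot && ref != "G")) next
    obs_base <- substr(p$r2, j + 1L, j + 1L)
    if (obs_base == "C")
      out <- rbind(out, data.frame(pos = g, strand = if (ot) "+" else "-",
                                   observed = "METH"))
    else if (obs_base == "T")
      out <- rbind(out, data.frame(pos = g, strand = if (ot) "+" else "-",
                                   observed = "UNMETH"))
  }
  out
}
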