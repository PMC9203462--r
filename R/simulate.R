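# Per-molecule simulation of the ABBS/WGBS wet-lab chain: bisulfite
# conversion of a realized molecule, anchored or random priming, and
# paired-end read generation. These functions define the molecule-level
# contracts; simulate_pairs() is the vectorized engine used for large runs.

#' Realize one molecule and bisulfite-convert it
#'
#' Draws the methylation state of every cytosine of the template strand
#' (methylated with probability equal to its methylome level; absent entries
#' mean 0), then applies bisulfite chemistry: an unmethylated C is converted
#' to T with probability `conversion_efficiency` (otherwise it is a
#' conversion failure and stays C); a methylated C stays C with probability
#' `1 - inappropriate_conversion`. Non-C bases are unchanged. OB fragments
#' are built from the reverse complement of the genomic slice before
#' conversion, since after denaturation the two strands are independent
#' templates.
#'
#' @param genome a `GenomeSet`.
#' @param methylome a `MethylomeProfile`.
#' @param seq_name sequence name.
#' @param start,end 0-based half-open fragment interval.
#' @param template_strand `"OT"` (original top) or `"OB"` (original bottom).
#' @param config a [sim_config()].
#' @return a `ConvertedFragment`: list with the fragment coordinates, the
#'   converted template sequence (5'->3' of the template strand), the
#'   template offsets of all original cytosines (`c_offsets`), their realized
#'   methylation (`realized_meth`), and the offsets where a C remains
#'   (`retained_c_offsets`).
#' @export
realize_and_convert <- function(genome, methylome, seq_name, start, end,
                                template_strand = c("OT", "OB"), config) {
  stopifnot(inherits(genome, "GenomeSet"), inherits(config, "SimConfig"))
  template_strand <- match.arg(template_strand)
  L <- nchar(genome$sequences[[seq_name]])
  if (is.null(L) || start < 0L || end > L || start >= end)
    stop("interval out of bounds", call. = FALSE)
  slice <- substr(genome$sequences[[seq_name]], start + 1L, end)
  tmpl <- if (template_strand == "OT") slice else .revcomp_chr(slice)
  traw <- charToRaw(tmpl)
  t_off <- which(traw == .RAW_C) - 1L
  n <- end - start
  gpos <- if (template_strand == "OT") start + t_off else end - 1L - t_off
  strand <- if (template_strand == "OT") "+" else "-"
  lev <- numeric(length(t_off))
  if (length(t_off) && nrow(methylome)) {
    lut <- data.table::data.table(seqnames = seq_name, pos = gpos,
                                  strand = strand)
    hit <- methylome[lut, on = c("seqnames", "pos", "strand"), x.level]
    lev <- ifelse(is.na(hit), 0, hit)
  }
  realized <- runif(length(t_off)) < lev
  u <- runif(length(t_off))
  retained <- ifelse(realized,
                     u >= config$inappropriate_conversion,
                     u >= config$conversion_efficiency)
  traw[t_off[!retained] + 1L] <- .RAW_T
  structure(list(seq_name = seq_name, start = as.integer(start),
                 end = as.integer(end), template_strand = template_strand,
                 converted_seq = rawToChar(traw),
                 c_offsets = t_off, realized_meth = realized,
                 retained_c_offsets = t_off[retained]),
            class = "ConvertedFragment")
}

#' Draw fragment intervals and template strands
#'
#' Fragment length is uniform on `[frag_min, frag_max]`, the start is uniform
#' over the positions where the fragment fits, and the template strand is
#' OT/OB with probability 1/2 each, emulating sonication of denatured DNA to
#' 200-300 nt.
#'
#' @param seq_length length of the sequence being fragmented.
#' @param n_fragments number of fragments to draw.
#' @param config a [sim_config()].
#' @return data.frame with columns `start`, `end` (0-based half-open) and
#'   `template_strand`.
#' @export
fragmentize <- function(seq_length, n_fragments, config) {
  stopifnot(inherits(config, "SimConfig"))
  if (seq_length < config$frag_max)
    stop("sequence shorter than frag_max", call. = FALSE)
  n_fragments <- .assert_count(n_fragments, "n_fragments", 0L)
  if (n_fragments == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      template_strand = character(0)))
  len <- config$frag_min +
    floor(runif(n_fragments) * (config$frag_max - config$frag_min + 1L))
  start <- floor(runif(n_fragments) * (seq_length - len + 1L))
  data.frame(start = as.integer(start), end = as.integer(start + len),
             template_strand = c("OT", "OB")[1L + (runif(n_fragments) < 0.5)])
}

.random_bases <- function(n) rawToChar(.RAW_BASES[sample.int(4L, n, replace = TRUE)])

# primer N bases pairing template offsets: N_i pairs offset a + 6 - i
# (ABBS: N_1..N_5 pair a+5..a+1, the anchor G pairs a; WGBS: N_1..N_6 pair
# a+5..a), matched to the complement of the converted template base with
# probability p_anneal_match, else uniform.
.primer_n_block <- function(conv_raw, a, k, p_anneal) {
  offs <- a + 6L - seq_len(k)   # template offsets paired by N_1..N_k
  matched <- .comp_raw(conv_raw[offs + 1L])
  miss <- runif(k) >= p_anneal
  if (any(miss))
    matched[miss] <- .RAW_BASES[sample.int(4L, sum(miss), replace = TRUE)]
  matched
}

#' Prime a converted fragment with the ABBS anchored primer
#'
#' Eligible anchors are retained-C offsets `a` with `a >= min_extension`
#' (room to extend) and `a + 5 <= length - 1` (the five N bases lie on
#' template). If at least one anchor is eligible and a Bernoulli
#' `p_specific` succeeds, one anchor is chosen uniformly and the primer's
#' five N bases pair template offsets `a+5 .. a+1` under the
#' `p_anneal_match` model, with the PPG anchor (read as G) pairing the
#' retained C; otherwise the fragment falls back to nonspecific priming
#' (same geometry as WGBS, five random N plus the fixed anchor G). The
#' synthesized strand is the primer followed by the reverse complement of
#' the template 5' of the anchor.
#'
#' @param fragment a `ConvertedFragment`.
#' @param config a [sim_config()].
#' @return a `PrimedProduct`, or `NULL` when no position satisfies the
#'   geometric constraints at all.
#' @export
prime_abbs <- function(fragment, config) {
  stopifnot(inherits(fragment, "ConvertedFragment"),
            inherits(config, "SimConfig"))
  L <- nchar(fragment$converted_seq)
  a_max <- L - 6L
  if (a_max < config$min_extension) return(NULL)
  conv_raw <- charToRaw(fragment$converted_seq)
  eligible <- fragment$retained_c_offsets
  eligible <- eligible[eligible >= config$min_extension & eligible <= a_max]
  specific <- length(eligible) >= 1L && runif(1L) < config$p_specific
  if (specific) {
    a <- eligible[sample.int(length(eligible), 1L)]
    n_block <- .primer_n_block(conv_raw, a, 5L, config$p_anneal_match)
  } else {
    a <- config$min_extension +
      floor(runif(1L) * (a_max - config$min_extension + 1L))
    a <- as.integer(a)
    n_block <- charToRaw(.random_bases(5L))
  }
  primer <- rawToChar(n_block)
  synthesized <- paste0(primer, "G",
                        .revcomp_chr(substr(fragment$converted_seq, 1L, a)))
  structure(list(fragment = fragment,
                 anchor_offset = if (specific) a else -1L,
                 prime_offset = as.integer(a),
                 primer_bases = primer, synthesized_seq = synthesized,
                 specific = specific, protocol = "ABBS"),
            class = "PrimedProduct")
}

#' Prime a converted fragment with a WGBS random hexamer
#'
#' Anchor-free: the priming position is uniform over the eligible range and
#' the six N bases pair template offsets `a+5 .. a` under the same
#' `p_anneal_match` model.
#'
#' @param fragment a `ConvertedFragment`.
#' @param config a [sim_config()].
#' @return a `PrimedProduct` with `specific = FALSE`.
#' @export
prime_wgbs <- function(fragment, config) {
  stopifnot(inherits(fragment, "ConvertedFragment"),
            inherits(config, "SimConfig"))
  L <- nchar(fragment$converted_seq)
  if (L <= config$min_extension + 6L)
    stop("fragment too short for priming", call. = FALSE)
  a_max <- L - 6L
  a <- as.integer(config$min_extension +
                    floor(runif(1L) * (a_max - config$min_extension + 1L)))
  conv_raw <- charToRaw(fragment$converted_seq)
  primer <- rawToChar(.primer_n_block(conv_raw, a, 6L, config$p_anneal_match))
  synthesized <- paste0(primer,
                        .revcomp_chr(substr(fragment$converted_seq, 1L, a)))
  structure(list(fragment = fragment, anchor_offset = -1L,
                 prime_offset = a, primer_bases = primer,
                 synthesized_seq = synthesized, specific = FALSE,
                 protocol = "WGBS"),
            class = "PrimedProduct")
}

.apply_seq_errors <- function(seq_chr, rate) {
  if (rate <= 0) return(seq_chr)
  r <- charToRaw(seq_chr)
  hit <- which(runif(length(r)) < rate)
  if (length(hit)) {
    cur <- match(r[hit], .RAW_BASES)
    shift <- sample.int(3L, length(hit), replace = TRUE)
    r[hit] <- .RAW_BASES[1L + (cur - 1L + shift) %% 4L]
  }
  rawToChar(r)
}

#' Turn a primed product into a paired-end read
#'
#' Read 1 is the first `read_length` bases of the synthesized strand (primer
#' end first, PBAT orientation: read 1 is the complement of the converted
#' template); read 2 is the first `read_length` bases of its reverse
#' complement. Products whose synthesized strand is shorter than
#' `read_length` are discarded.
#'
#' @param product a `PrimedProduct`.
#' @param config a [sim_config()].
#' @param read_id identifier stored in the truth tag.
#' @return a `ReadPair` (list with `r1_seq`, `r2_seq`, `r1_qual`, `r2_qual`
#'   and a `truth` record), or `NULL` when the product is too short.
#' @export
make_read_pair <- function(product, config, read_id = "read") {
  stopifnot(inherits(product, "PrimedProduct"),
            inherits(config, "SimConfig"))
  rl <- config$read_length
  synth <- product$synthesized_seq
  if (nchar(synth) < rl) return(NULL)
  r1 <- substr(synth, 1L, rl)
  r2 <- substr(.revcomp_chr(synth), 1L, rl)
  r1 <- .apply_seq_errors(r1, config$seq_error_rate)
  r2 <- .apply_seq_errors(r2, config$seq_error_rate)
  frag <- product$fragment
  g <- if (frag$template_strand == "OT") frag$start + product$prime_offset
       else frag$end - 1L - product$prime_offset
  structure(list(read_id = read_id, r1_seq = r1, r2_seq = r2,
                 r1_qual = strrep("I", rl), r2_qual = strrep("I", rl),
                 truth = list(read_id = read_id, seqnames = frag$seq_name,
                              frag_start = frag$start, frag_end = frag$end,
                              template_strand = frag$template_strand,
                              protocol = product$protocol,
                              anchor_pos = if (product$specific) g else -1L,
                              prime_pos = g, primer_len = 6L,
                              specific = product$specific)),
            class = "ReadPair")
}
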