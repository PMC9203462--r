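# Truth-based alignment and per-cytosine methylation extraction: the in-repo
# analog of a bisulfite aligner plus methylation extractor. Read 1 index i
# (0-based, past the primer block) maps to template offset
# a - 1 - (i - primer_len); read 2 index j maps to template offset j, where
# a is the priming offset recorded in the truth sidecar. Observed template
# base C => methylated, T => unmethylated, anything else is discarded.

#' Per-cytosine observations from one read pair
#'
#' Reference (molecule-level) implementation of the read-to-genome mapping;
#' [call_cytosines()] applies the same rules vectorized. Bases inside the
#' trim windows (which cover the primer block) yield no observations, and
#' with `no_overlap` template offsets covered by both mates are counted once
#' with read 1 taking precedence.
#'
#' @param pair a `ReadPair` from [make_read_pair()], or a single-row pair
#'   table from [simulate_pairs()].
#' @param genome the `GenomeSet` the pair was simulated from.
#' @param policy a [trim_policy()].
#' @return data.frame with columns `seqnames`, `pos` (0-based forward),
#'   `strand`, `observed` (`"METH"`/`"UNMETH"`).
#' @export
observations_from_pair <- function(pair, genome, policy = trim_policy()) {
  stopifnot(inherits(genome, "GenomeSet"), inherits(policy, "TrimPolicy"))
  if (inherits(pair, "ReadPair")) {
    tr <- pair$truth; r1 <- pair$r1_seq; r2 <- pair$r2_seq
  } else {
    pair <- as.list(as.data.frame(pair)[1L, ])
    tr <- pair; r1 <- pair$r1; r2 <- pair$r2
  }
  rl <- nchar(r1)
  if (nchar(r2) != rl) stop("mate length mismatch", call. = FALSE)
  L <- tr$frag_end - tr$frag_start
  ot <- tr$template_strand == "OT"
  a <- if (ot) tr$prime_pos - tr$frag_start else tr$frag_end - 1L - tr$prime_pos
  pl <- tr$primer_len
  seq_raw <- charToRaw(genome$sequences[[tr$seqnames]])
  obs <- list()
  add_obs <- function(t, base) {
    g <- if (ot) tr$frag_start + t else tr$frag_end - 1L - t
    strand <- if (ot) "+" else "-"
    gb <- seq_raw[g + 1L]
    is_tc <- (ot && gb == .RAW_C) || (!ot && gb == .RAW_G)
    if (!is_tc) return(NULL)
    if (base == .RAW_C) data.frame(seqnames = tr$seqnames, pos = g,
                                   strand = strand, observed = "METH")
    else if (base == .RAW_T) data.frame(seqnames = tr$seqnames, pos = g,
                                        strand = strand, observed = "UNMETH")
    else NULL
  }
  r1_raw <- charToRaw(r1); r2_raw <- charToRaw(r2)
  i1s <- max(pl, policy$ignore_r1_start)
  i1e <- rl - 1L - policy$ignore_r1_end
  t1_seen <- integer(0)
  if (i1s <= i1e) {
    for (i in i1s:i1e) {
      t <- a - 1L - (i - pl)
      if (t < 0L || t >= L) next
      t1_seen <- c(t1_seen, t)
      obs[[length(obs) + 1L]] <- add_obs(t, .comp_raw(r1_raw[i + 1L]))
    }
  }
  i2s <- policy$ignore_r2_start
  i2e <- rl - 1L - policy$ignore_r2_end
  if (i2s <= i2e) {
    for (j in i2s:i2e) {
      t <- j
      if (t >= L) next
      if (policy$no_overlap && t %in% t1_seen) next
      obs[[length(obs) + 1L]] <- add_obs(t, r2_raw[j + 1L])
    }
  }
  if (!length(obs))
    return(data.frame(seqnames = character(0), pos = integer(0),
                      strand = character(0), observed = character(0)))
  do.call(rbind, obs)
}

#' Aggregate read pairs into a per-cytosine call table
#'
#' Applies the trim policy, maps every informative read base to its forward
#' genomic coordinate, keeps observations landing on genuine cytosines of
#' the template strand, classifies C as methylated and T as unmethylated
#' (other bases, i.e. sequencing errors, are discarded but counted), and
#' aggregates counts per (sequence, position, strand) with CpG/CHG/CHH
#' context.
#'
#' @param pairs pair table from [simulate_pairs()] / [read_run()].
#' @param genome the `GenomeSet` the pairs were simulated from.
#' @param policy a [trim_policy()].
#' @param chunk_size pairs processed per internal chunk.
#' @return a `CytosineCallTable`: keyed `data.table` with columns
#'   `seqnames`, `pos`, `strand`, `context`, `n_meth`, `n_unmeth`; attribute
#'   `report` carries observation counts.
#' @export
call_cytosines <- function(pairs, genome, policy = trim_policy(),
                           chunk_size = 25000L) {
  stopifnot(inherits(genome, "GenomeSet"), inherits(policy, "TrimPolicy"))
  pairs <- data.table::as.data.table(pairs)
  gi <- .genome_index(genome)
  if (nrow(pairs) == 0L)
    return(.finish_call_table(data.table::data.table(), genome, 0, 0))
  rl <- nchar(pairs$r1[1L])
  pl <- pairs$primer_len[1L]
  if (any(pairs$primer_len != pl)) stop("mixed primer lengths", call. = FALSE)
  i1s <- max(pl, policy$ignore_r1_start)
  i1e <- rl - 1L - policy$ignore_r1_end
  i2s <- policy$ignore_r2_start
  i2e <- rl - 1L - policy$ignore_r2_end
  if (i1s > i1e && i2s > i2e)
    stop("trim policy leaves no informative bases", call. = FALSE)
  aggs <- list()
  n_obs <- 0; n_discarded <- 0
  for (rows in .chunk_indices(nrow(pairs), chunk_size)) {
    ch <- pairs[rows]
    np <- nrow(ch)
    if (any(nchar(ch$r1) != rl) || any(nchar(ch$r2) != rl))
      stop("read length mismatch within run", call. = FALSE)
    ot <- ch$template_strand == "OT"
    Lf <- ch$frag_end - ch$frag_start
    a <- ifelse(ot, ch$prime_pos - ch$frag_start,
                ch$frag_end - 1L - ch$prime_pos)
    off <- unname(gi$off[ch$seqnames])
    key <- integer(0); methv <- logical(0)
    t1lo <- rep(1L, np); t1hi <- rep(0L, np)   # empty window by default
    if (i1s <= i1e) {
      k1 <- i1e - i1s + 1L
      p1 <- rep(seq_len(np), each = k1)
      iv <- rep(i1s:i1e, times = np)
      r1cat <- charToRaw(paste0(ch$r1, collapse = ""))
      base1 <- .comp_raw(r1cat[(p1 - 1L) * rl + iv + 1L])
      t1 <- a[p1] - 1L - (iv - pl)
      ok <- t1 >= 0L & t1 < Lf[p1]
      res <- .obs_to_sites(t1[ok], base1[ok], p1[ok], ot, ch$frag_start,
                           ch$frag_end, off, gi)
      key <- c(key, res$site_key); methv <- c(methv, res$meth)
      n_discarded <- n_discarded + res$n_bad
      t1hi <- pmin(a - 1L - (i1s - pl), Lf - 1L)
      t1lo <- pmax(a - 1L - (i1e - pl), 0L)
      none <- t1hi < 0L | t1lo > t1hi
      t1lo[none] <- 1L; t1hi[none] <- 0L
    }
    if (i2s <= i2e) {
      k2 <- i2e - i2s + 1L
      p2 <- rep(seq_len(np), each = k2)
      jv <- rep(i2s:i2e, times = np)
      r2cat <- charToRaw(paste0(ch$r2, collapse = ""))
      base2 <- r2cat[(p2 - 1L) * rl + jv + 1L]
      t2 <- jv
      ok <- t2 < Lf[p2]
      if (policy$no_overlap)
        ok <- ok & !(t2 >= t1lo[p2] & t2 <= t1hi[p2])
      res <- .obs_to_sites(t2[ok], base2[ok], p2[ok], ot, ch$frag_start,
                           ch$frag_end, off, gi)
      key <- c(key, res$site_key); methv <- c(methv, res$meth)
      n_discarded <- n_discarded + res$n_bad
    }
    n_obs <- n_obs + length(key)
    dt <- data.table::data.table(site_key = key, m = methv)
    aggs[[length(aggs) + 1L]] <-
      dt[, list(n_meth = sum(m), n_unmeth = sum(!m)), by = site_key]
  }
  agg <- data.table::rbindlist(aggs)
  agg <- agg[, list(n_meth = sum(n_meth), n_unmeth = sum(n_unmeth)),
             by = site_key]
  .finish_call_table(agg, genome, n_obs, n_discarded)
}

# map observations to encoded site keys, keeping only genuine template
# cytosines with an unambiguous C/T readout
.obs_to_sites <- function(t, base, p, ot, fs, fe, off, gi) {
  otp <- ot[p]
  g <- ifelse(otp, fs[p] + t, fe[p] - 1L - t)
  gidx <- off[p] + g                       # 0-based global coordinate
  gb <- gi$blob[gidx + 1L]
  is_tc <- (otp & gb == .RAW_C) | (!otp & gb == .RAW_G)
  is_c <- base == .RAW_C
  is_t <- base == .RAW_T
  keep <- is_tc & (is_c | is_t)
  list(site_key = gidx[keep] * 2L + !otp[keep], meth = is_c[keep],
       n_bad = sum(is_tc & !(is_c | is_t)))
}

.finish_call_table <- function(agg, genome, n_obs, n_discarded) {
  gi <- .genome_index(genome)
  if (nrow(agg) == 0L) {
    tab <- data.table::data.table(seqnames = character(0), pos = integer(0),
                                  strand = character(0), context = character(0),
                                  n_meth = integer(0), n_unmeth = integer(0))
  } else {
    gidx <- agg$site_key %/% 2L
    minus <- agg$site_key %% 2L == 1L
    bnd <- c(unname(gi$off), length(gi$blob))
    seq_i <- findInterval(gidx, bnd[-length(bnd)])
    seqnames <- names(gi$off)[seq_i]
    pos <- gidx - unname(gi$off)[seq_i]
    strand <- ifelse(minus, "-", "+")
    tab <- data.table::data.table(seqnames = seqnames, pos = as.integer(pos),
                                  strand = strand,
                                  context = classify_context(genome, seqnames,
                                                             pos, strand),
                                  n_meth = as.integer(agg$n_meth),
                                  n_unmeth = as.integer(agg$n_unmeth))
    data.table::setorderv(tab, c("seqnames", "pos", "strand"))
  }
  data.table::setkeyv(tab, c("seqnames", "pos", "strand"))
  data.table::setattr(tab, "class",
                      c("CytosineCallTable", class(data.table::data.table())))
  data.table::setattr(tab, "report",
                      list(n_obs = n_obs, n_discarded_base = n_discarded))
  tab[]
}

#' Classify cytosine context (CpG / CHG / CHH)
#'
#' Strand-aware: for a `+` cytosine the next base downstream is at `pos + 1`;
#' for a `-` cytosine (a G on the forward strand) it is at `pos - 1` read as
#' the complement. Next base G gives CpG, else next-next base G gives CHG,
#' else CHH; cytosines too close to the sequence edge default to CHH.
#'
#' @param genome a `GenomeSet`.
#' @param seqnames,pos,strand parallel vectors identifying cytosines
#'   (0-based forward coordinates).
#' @return character vector of contexts.
#' @export
classify_context <- function(genome, seqnames, pos, strand) {
  stopifnot(inherits(genome, "GenomeSet"))
  gi <- .genome_index(genome)
  n <- length(pos)
  seqnames <- rep_len(as.character(seqnames), n)
  strand <- rep_len(as.character(strand), n)
  off <- unname(gi$off[seqnames])
  len <- unname(gi$len[seqnames])
  base0 <- gi$blob[off + pos + 1L]
  plus <- strand == "+"
  if (!all(ifelse(plus, base0 == .RAW_C, base0 == .RAW_G)))
    stop("position is not a cytosine of the given strand", call. = FALSE)
  d1 <- ifelse(plus, pos + 1L, pos - 1L)
  d2 <- ifelse(plus, pos + 2L, pos - 2L)
  in1 <- d1 >= 0L & d1 < len
  in2 <- d2 >= 0L & d2 < len
  b1 <- rep(as.raw(0L), n); b2 <- rep(as.raw(0L), n)
  b1[in1] <- gi$blob[(off + d1)[in1] + 1L]
  b2[in2] <- gi$blob[(off + d2)[in2] + 1L]
  want1 <- ifelse(plus, b1 == .RAW_G, b1 == .RAW_C)  # complement-strand G
  want2 <- ifelse(plus, b2 == .RAW_G, b2 == .RAW_C)
  ifelse(in1 & want1, "CpG", ifelse(in2 & want2, "CHG", "CHH"))
}

#' Coverage-filtered bedGraph-style output
#'
#' Writes rows with coverage strictly above `min_coverage` as zero-based
#' bedGraph: seqnames, start, start+1, methylation percent, methylated
#' count, unmethylated count, sorted by position.
#'
#' @param table a `CytosineCallTable`.
#' @param path output path.
#' @param min_coverage strict coverage cutoff (`coverage > min_coverage`).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(table, path, min_coverage = 0L) {
  dt <- data.table::as.data.table(table)
  dt <- dt[(n_meth + n_unmeth) > min_coverage]
  out <- dt[, list(seqnames, start = pos, end = pos + 1L,
                   level_percent = 100 * n_meth / (n_meth + n_unmeth),
                   n_meth, n_unmeth)]
  data.table::setorderv(out, c("seqnames", "start"))
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph-style cytosine file back into a call table
#' @param path file written by [write_bedgraph()].
#' @param genome the matching `GenomeSet` (used to recover strand and
#'   context).
#' @return a `CytosineCallTable`.
#' @export
read_bedgraph <- function(path, genome) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          col.names = c("seqnames", "start", "end",
                                        "level_percent", "n_meth", "n_unmeth"))
  if (nrow(dt) == 0L) return(.finish_call_table(data.table::data.table(),
                                                genome, 0, 0))
  gi <- .genome_index(genome)
  base <- gi$blob[unname(gi$off[dt$seqnames]) + dt$start + 1L]
  strand <- ifelse(base == .RAW_C, "+", "-")
  key <- (unname(gi$off[dt$seqnames]) + dt$start) * 2L + (strand == "-")
  agg <- data.table::data.table(site_key = key, n_meth = dt$n_meth,
                                n_unmeth = dt$n_unmeth)
  .finish_call_table(agg, genome, sum(dt$n_meth + dt$n_unmeth), 0)
}

#' Write a CX-style cytosine report
#'
#' Tab-delimited: seqnames, pos (0-based), strand, methylated count,
#' unmethylated count, context.
#'
#' @param table a `CytosineCallTable`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cx_report <- function(table, path) {
  dt <- data.table::as.data.table(table)
  out <- dt[, list(seqnames, pos, strand, n_meth, n_unmeth, context)]
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Derived percent methylation of a call table
#' @param table a `CytosineCallTable`.
#' @return the table with added columns `coverage` and `level_percent`.
#' @export
call_levels <- function(table) {
  dt <- data.table::as.data.table(table)
  dt[, coverage := n_meth + n_unmeth]
  dt[, level_percent := ifelse(coverage > 0, 100 * n_meth / coverage, NA_real_)]
  dt[]
}
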