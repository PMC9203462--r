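# Vectorized library simulator. Implements the same molecule-level contracts
# as realize_and_convert() / prime_abbs() / prime_wgbs() / make_read_pair()
# but operates on whole batches of fragments as flat raw byte vectors, which
# keeps multi-hundred-thousand-pair runs to seconds. Each pipeline stage
# draws from its own child RNG stream derived from the root seed, so stages
# are individually reproducible.

.STAGE_FRAG <- 1L; .STAGE_REALIZE <- 2L; .STAGE_PRIME <- 3L; .STAGE_ERROR <- 4L

#' Simulate an ABBS or WGBS run in memory
#'
#' Draws fragments (a `spike_in_read_fraction` share from the spike-in
#' sequence, the rest from the main genome in proportion to sequence
#' length), realizes and bisulfite-converts each molecule, primes it
#' (anchored with fallback to nonspecific for ABBS; random hexamer for
#' WGBS), and emits exactly `n_read_pairs` paired-end reads with their truth
#' records. Products whose synthesized strand is shorter than the read
#' length are discarded and resampled; discard counts are reported.
#'
#' @param genome a `GenomeSet`.
#' @param methylome a `MethylomeProfile` for `genome`.
#' @param config a [sim_config()].
#' @param chunk_size fragments generated per internal batch.
#' @return a `data.table` with one row per read pair: `read_id`, `r1`, `r2`
#'   and the truth columns `seqnames`, `frag_start`, `frag_end`,
#'   `template_strand`, `protocol`, `anchor_pos` (0-based genomic position
#'   of the PPG anchor, -1 for nonspecific products), `prime_pos` (0-based
#'   genomic position of the primer 3'-terminal template base, always set),
#'   `primer_len`, `specific`. The run report (stage counts) is attached as
#'   attribute `report`.
#' @export
simulate_pairs <- function(genome, methylome, config, chunk_size = 50000L) {
  stopifnot(inherits(genome, "GenomeSet"), inherits(config, "SimConfig"))
  if (config$spike_in_read_fraction > 0 && is.null(genome$spike_in_name))
    stop("genome lacks a spike-in while spike_in_read_fraction > 0",
         call. = FALSE)
  la <- .level_arrays(genome, methylome)
  gi <- la$index
  main <- setdiff(names(genome$sequences), genome$spike_in_name)
  main_len <- gi$len[main]
  usable <- main_len >= config$frag_max
  if (!any(usable)) stop("no main sequence is at least frag_max long",
                         call. = FALSE)
  main <- main[usable]; main_len <- main_len[usable]
  spike <- genome$spike_in_name
  if (!is.null(spike) && gi$len[spike] < config$frag_max) spike <- NULL
  rl <- config$read_length
  n_target <- config$n_read_pairs
  out <- list()
  n_done <- 0L; n_gen <- 0L
  rep_counts <- c(fragments = 0L, specific = 0L, nonspecific = 0L,
                  discarded_short = 0L, no_geometry = 0L, spike_fragments = 0L)
  keep_rate <- 0.9
  batch <- 0L
  while (n_done < n_target) {
    batch <- batch + 1L
    if (batch > 10000L) stop("simulation failed to accumulate reads")
    need <- n_target - n_done
    m <- min(as.integer(ceiling(need / keep_rate * 1.15) + 16L),
             as.integer(chunk_size))

    ## stage 1: fragment sampling -------------------------------------------
    set.seed(derive_seed(config$seed, 10L * batch + .STAGE_FRAG))
    is_spike <- if (!is.null(spike))
      runif(m) < config$spike_in_read_fraction else rep(FALSE, m)
    cum <- cumsum(as.numeric(main_len))
    pickm <- findInterval(runif(m) * cum[length(cum)], cum) + 1L
    seq_nm <- ifelse(is_spike, spike, main[pickm])
    seq_L <- gi$len[seq_nm]
    lens <- config$frag_min +
      as.integer(floor(runif(m) * (config$frag_max - config$frag_min + 1L)))
    s <- as.integer(floor(runif(m) * (seq_L - lens + 1L)))
    ot <- runif(m) < 0.5

    ## stage 2: realization + bisulfite conversion --------------------------
    set.seed(derive_seed(config$seed, 10L * batch + .STAGE_REALIZE))
    g0 <- unname(gi$off[seq_nm] + s)          # 0-based global fragment start
    from <- ifelse(ot, g0 + 1L, g0 + lens)
    idx <- sequence(lens, from = from, by = ifelse(ot, 1L, -1L))
    tmpl <- gi$blob[idx]
    fid <- rep.int(seq_len(m), lens)
    ob_base <- rep.int(!ot, lens)
    tmpl[ob_base] <- .comp_raw(tmpl[ob_base])
    t_off <- sequence(lens) - 1L
    ci <- which(tmpl == .RAW_C)
    iC <- idx[ci]; obC <- ob_base[ci]
    lev <- numeric(length(ci))
    lev[!obC] <- la$plus[iC[!obC]]
    lev[obC] <- la$minus[iC[obC]]
    realized <- runif(length(ci)) < lev
    u2 <- runif(length(ci))
    retained <- ifelse(realized, u2 >= config$inappropriate_conversion,
                       u2 >= config$conversion_efficiency)
    conv <- tmpl
    conv[ci[!retained]] <- .RAW_T

    ## stage 3: priming -----------------------------------------------------
    set.seed(derive_seed(config$seed, 10L * batch + .STAGE_PRIME))
    p0 <- cumsum(lens) - lens                 # 0-based chunk offset per frag
    a_max <- lens - 6L
    feasible <- a_max >= config$min_extension
    specific <- rep(FALSE, m)
    a <- rep(-1L, m)
    if (config$protocol == "ABBS") {
      cand <- ci[retained]
      keepc <- t_off[cand] >= config$min_extension &
        t_off[cand] <= a_max[fid[cand]]
      cand <- cand[keepc]
      if (length(cand)) {
        dtc <- data.table::data.table(f = fid[cand], t = t_off[cand],
                                      r = runif(length(cand)))
        pick <- dtc[dtc[, .I[which.max(r)], by = f]$V1]
        spec_draw <- runif(m) < config$p_specific
        specific[pick$f] <- spec_draw[pick$f]
        a[pick$f] <- pick$t
      }
      a[!specific] <- -1L
    }
    ns <- feasible & !specific
    if (any(ns))
      a[ns] <- as.integer(config$min_extension +
        floor(runif(sum(ns)) * (a_max[ns] - config$min_extension + 1L)))
    kept <- feasible & (a + 6L >= rl)
    km <- which(kept)
    nk <- length(km)
    rep_counts["fragments"] <- rep_counts["fragments"] + m
    rep_counts["no_geometry"] <- rep_counts["no_geometry"] + sum(!feasible)
    rep_counts["discarded_short"] <- rep_counts["discarded_short"] +
      sum(feasible & !kept)
    n_gen <- n_gen + m
    if (nk == 0L) { keep_rate <- max(0.02, n_done / max(n_gen, 1)); next }
    rep_counts["specific"] <- rep_counts["specific"] + sum(specific[km])
    rep_counts["nonspecific"] <- rep_counts["nonspecific"] + sum(!specific[km])
    rep_counts["spike_fragments"] <- rep_counts["spike_fragments"] +
      sum(is_spike[km])

    ak <- a[km]; p0k <- p0[km]; spk <- specific[km]
    ## primer block: 6 columns (5 N + anchor G for ABBS; 6 N for WGBS)
    prim <- matrix(.RAW_A, nrow = nk, ncol = 6L)
    n_cols <- if (config$protocol == "ABBS") 5L else 6L
    for (i in seq_len(n_cols)) {
      matched <- .comp_raw(conv[p0k + ak + 7L - i])
      miss <- runif(nk) >= config$p_anneal_match
      if (config$protocol == "ABBS") miss <- miss | !spk  # nonspecific N random
      nmiss <- sum(miss)
      if (nmiss) matched[miss] <- .RAW_BASES[sample.int(4L, nmiss, TRUE)]
      prim[, i] <- matched
    }
    if (config$protocol == "ABBS") prim[, 6L] <- .RAW_G

    ## read 1: primer block then complement of template walking 5'-ward
    r1raw <- raw(nk * rl)
    row0 <- (seq_len(nk) - 1L) * rl
    for (i in 1:6) r1raw[row0 + i] <- prim[, i]
    tail_len <- rl - 6L
    pos1 <- rep(row0, each = tail_len) + rep(7:rl, times = nk)
    ci_tail <- sequence(rep(tail_len, nk), from = p0k + ak, by = -1L)
    r1raw[pos1] <- .comp_raw(conv[ci_tail])
    ## read 2: converted template sense; positions past the priming site are
    ## the reverse complement of the primer block
    ci2 <- sequence(rep(rl, nk), from = p0k + 1L, by = 1L)
    r2raw <- conv[ci2]
    for (d in 0:5) {
      rows <- which(ak + d <= rl - 1L)
      if (length(rows))
        r2raw[row0[rows] + ak[rows] + d + 1L] <- .comp_raw(prim[rows, 6L - d])
    }

    ## stage 4: sequencing errors -------------------------------------------
    if (config$seq_error_rate > 0) {
      set.seed(derive_seed(config$seed, 10L * batch + .STAGE_ERROR))
      for (nmv in c("r1raw", "r2raw")) {
        v <- get(nmv)
        hit <- which(runif(length(v)) < config$seq_error_rate)
        if (length(hit)) {
          cur <- match(v[hit], .RAW_BASES)
          v[hit] <- .RAW_BASES[1L + (cur - 1L +
            sample.int(3L, length(hit), TRUE)) %% 4L]
          assign(nmv, v)
        }
      }
    }

    g_prime <- ifelse(ot[km], s[km] + ak, s[km] + lens[km] - 1L - ak)
    out[[length(out) + 1L]] <- data.table::data.table(
      r1 = .split_fixed(rawToChar(r1raw), rl, nk),
      r2 = .split_fixed(rawToChar(r2raw), rl, nk),
      seqnames = seq_nm[km],
      frag_start = s[km], frag_end = s[km] + lens[km],
      template_strand = ifelse(ot[km], "OT", "OB"),
      protocol = config$protocol,
      anchor_pos = as.integer(ifelse(spk, g_prime, -1L)),
      prime_pos = as.integer(g_prime),
      primer_len = 6L,
      specific = spk)
    n_done <- n_done + nk
    keep_rate <- max(0.02, min(0.99, n_done / n_gen))
  }
  pairs <- data.table::rbindlist(out)
  pairs <- pairs[seq_len(n_target)]
  run_id <- sprintf("%s_s%d", tolower(config$protocol), config$seed)
  pairs[, read_id := sprintf("%s:%07d", run_id, .I)]
  data.table::setcolorder(pairs, c("read_id"))
  report <- as.list(rep_counts)
  report$n_read_pairs <- n_target
  report$protocol <- config$protocol
  report$seed <- config$seed
  report$read_length <- rl
  data.table::setattr(pairs, "report", report)
  pairs[]
}

.write_fastq <- function(ids, seqs, qual, path, gzip = FALSE) {
  con <- if (gzip) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", qual)), con)
  invisible(path)
}

#' Run the simulator and write FASTQ plus truth sidecar
#'
#' Writes `<prefix>_R1.fastq`, `<prefix>_R2.fastq` (mate suffixes /1, /2),
#' the tab-delimited truth sidecar `<prefix>_truth.tsv` and a JSON run
#' report `<prefix>_report.json`.
#'
#' @param genome a `GenomeSet`.
#' @param methylome a `MethylomeProfile`.
#' @param config a [sim_config()].
#' @param out_prefix output path prefix.
#' @param gzip compress the FASTQ files.
#' @return invisibly, a list with the file paths and the run report.
#' @export
simulate_run <- function(genome, methylome, config, out_prefix,
                         gzip = FALSE) {
  pairs <- simulate_pairs(genome, methylome, config)
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  p1 <- paste0(out_prefix, "_R1", ext)
  p2 <- paste0(out_prefix, "_R2", ext)
  pt <- paste0(out_prefix, "_truth.tsv")
  pr <- paste0(out_prefix, "_report.json")
  qual <- strrep("I", config$read_length)
  .write_fastq(paste0(pairs$read_id, "/1"), pairs$r1, qual, p1, gzip)
  .write_fastq(paste0(pairs$read_id, "/2"), pairs$r2, qual, p2, gzip)
  truth <- pairs[, list(read_id, seqnames, frag_start, frag_end,
                        template_strand, protocol, anchor_pos, prime_pos,
                        primer_len, specific = as.integer(specific))]
  data.table::fwrite(truth, pt, sep = "\t")
  report <- attr(pairs, "report")
  jsonlite::write_json(report, pr, auto_unbox = TRUE, digits = NA)
  invisible(list(fastq1 = p1, fastq2 = p2, truth = pt, report_path = pr,
                 report = report))
}

#' Read a simulated run back into a pair table
#'
#' Joins the two FASTQ files with the truth sidecar by read id, recovering
#' the table emitted by [simulate_pairs()].
#'
#' @param prefix the `out_prefix` used by [simulate_run()].
#' @param gzip whether the FASTQ files were gzip-compressed.
#' @return a pair `data.table` (see [simulate_pairs()]).
#' @export
read_run <- function(prefix, gzip = FALSE) {
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  f1 <- Biostrings::readDNAStringSet(paste0(prefix, "_R1", ext),
                                     format = "fastq")
  f2 <- Biostrings::readDNAStringSet(paste0(prefix, "_R2", ext),
                                     format = "fastq")
  ids <- sub("/1$", "", sub("\\s.*$", "", names(f1)))
  ids2 <- sub("/2$", "", sub("\\s.*$", "", names(f2)))
  if (!identical(ids, ids2)) stop("mate FASTQ files do not match",
                                  call. = FALSE)
  truth <- data.table::fread(paste0(prefix, "_truth.tsv"), sep = "\t")
  reads <- data.table::data.table(read_id = ids,
                                  r1 = as.character(f1),
                                  r2 = as.character(f2))
  pairs <- merge(reads, truth, by = "read_id", sort = FALSE)
  if (nrow(pairs) != nrow(reads))
    stop("truth sidecar does not cover all reads", call. = FALSE)
  pairs[, specific := as.logical(specific)]
  pairs[]
}
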