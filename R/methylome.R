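#' MethylomeProfile: per-cytosine, per-strand true methylation levels
#'
#' Ground-truth methylation for a genome: one row per annotated cytosine,
#' with `level` the probability that the cytosine is methylated in any given
#' molecule. Cytosines without an entry have level 0. A minus-strand cytosine
#' is stored at the forward coordinate of its G, matching bedGraph/BED
#' zero-based conventions.
#'
#' @param entries data.frame/data.table with columns `seqnames`, `pos`
#'   (0-based), `strand` (`+`/`-`), `level` in \[0, 1\].
#' @param genome optional `GenomeSet`; when supplied, entries are validated
#'   to sit on genuine cytosines of their strand (`+` requires C at `pos`,
#'   `-` requires G) and spike-in entries are required to have level 0.
#' @return an object of class `MethylomeProfile` (a keyed data.table).
#' @export
methylome_profile <- function(entries, genome = NULL) {
  dt <- data.table::as.data.table(entries)
  if (nrow(dt) == 0L) {
    dt <- data.table::data.table(seqnames = character(0), pos = integer(0),
                                 strand = character(0), level = numeric(0))
  } else {
    stopifnot(all(c("seqnames", "pos", "strand", "level") %in% names(dt)))
    dt <- dt[, list(seqnames = as.character(seqnames), pos = as.integer(pos),
                    strand = as.character(strand), level = as.numeric(level))]
    if (any(dt$level < 0 | dt$level > 1))
      stop("levels must be in [0, 1]", call. = FALSE)
    if (!all(dt$strand %in% c("+", "-")))
      stop("strand must be '+' or '-'", call. = FALSE)
    if (anyDuplicated(dt, by = c("seqnames", "pos", "strand")))
      stop("duplicate (seqnames, pos, strand) entries", call. = FALSE)
    if (!is.null(genome)) .validate_methylome(dt, genome)
  }
  data.table::setkeyv(dt, c("seqnames", "pos", "strand"))
  data.table::setattr(dt, "class", c("MethylomeProfile", class(data.table::data.table())))
  dt[]
}

.validate_methylome <- function(dt, genome) {
  stopifnot(inherits(genome, "GenomeSet"))
  lens <- seq_lengths(genome)
  if (!all(dt$seqnames %in% names(lens)))
    stop("methylome refers to unknown sequence(s)", call. = FALSE)
  if (any(dt$pos < 0L) || any(dt$pos >= lens[dt$seqnames]))
    stop("methylome position outside sequence", call. = FALSE)
  gi <- .genome_index(genome)
  base <- gi$blob[gi$off[dt$seqnames] + dt$pos + 1L]
  ok <- (dt$strand == "+" & base == .RAW_C) | (dt$strand == "-" & base == .RAW_G)
  if (!all(ok))
    stop("methylome entry not on a cytosine of its strand", call. = FALSE)
  if (!is.null(genome$spike_in_name)) {
    sp <- dt$seqnames == genome$spike_in_name
    if (any(sp & dt$level != 0))
      stop("spike-in entries must all have level 0", call. = FALSE)
  }
  invisible(TRUE)
}

#' Dcm methylome: CCWGG second-cytosine methylation
#'
#' The Escherichia coli Dcm methyltransferase methylates the second cytosine
#' of CCWGG (W = A or T) on both strands. For every forward-strand occurrence
#' an entry is placed at the second C (strand `+`); for every occurrence read
#' on the reverse complement, at the corresponding forward coordinate
#' (strand `-`). The spike-in sequence, if any, is excluded.
#'
#' @param genome a `GenomeSet`.
#' @param level methylation level applied to every Dcm site (default 1.0,
#'   the fully methylated bacterial model).
#' @return a [methylome_profile()].
#' @examples
#' dcm_methylome(genome_set(c(chr = "CCAGG")))
#' @export
dcm_methylome <- function(genome, level = 1.0) {
  .assert_fraction(level, "level")
  occ <- find_motif_occurrences(genome, "CCWGG")
  occ <- as.data.frame(occ)
  if (!is.null(genome$spike_in_name))
    occ <- occ[occ$seqnames != genome$spike_in_name, , drop = FALSE]
  if (nrow(occ) == 0L) return(methylome_profile(data.frame(), genome))
  # forward match [s, s+5): mC at s+1 on '+'; reverse-strand match: the motif
  # second C sits at forward coordinate s+3 (a G on the forward strand)
  pos <- ifelse(occ$strand == "+", occ$start + 1L, occ$start + 3L)
  methylome_profile(data.frame(seqnames = occ$seqnames, pos = pos,
                               strand = occ$strand, level = level),
                    genome)
}

#' Empty methylome for the dcm- negative-control strain
#'
#' All cytosines unmethylated: the profile has zero entries. Under ABBS with
#' full conversion this genome yields no specifically anchored reads.
#'
#' @param genome a `GenomeSet`.
#' @return an empty [methylome_profile()].
#' @export
dcm_minus_methylome <- function(genome) {
  methylome_profile(data.frame(), genome)
}

#' Parameters of the mammalian-like methylome model
#'
#' @param dcm_level Dcm site level used by the bacterial model (default 1).
#' @param cgi_count number of CpG islands to place.
#' @param cgi_length_mean mean CGI length in bases.
#' @param hypo_beta `c(alpha, beta)` of the Beta distribution for
#'   hypomethylated (CGI) CpG levels.
#' @param hyper_beta `c(alpha, beta)` for hypermethylated background CpGs.
#' @param hyper_fraction fraction of non-CGI CpGs drawn from `hyper_beta`.
#' @param noncpg_level level given to non-CpG cytosines (default 0; bisulfite
#'   studies of somatic mammalian cells detect few occurrences of non-CpG
#'   methylation).
#' @return a list of class `MethylomeModelParams`.
#' @export
methylome_model_params <- function(dcm_level = 1.0, cgi_count = 10L,
                                   cgi_length_mean = 1000L,
                                   hypo_beta = c(1, 10),
                                   hyper_beta = c(10, 1),
                                   hyper_fraction = 0.8,
                                   noncpg_level = 0) {
  .assert_fraction(dcm_level, "dcm_level")
  .assert_fraction(hyper_fraction, "hyper_fraction")
  .assert_fraction(noncpg_level, "noncpg_level")
  .assert_count(cgi_count, "cgi_count", min = 0L)
  .assert_count(cgi_length_mean, "cgi_length_mean", min = 1L)
  if (length(hypo_beta) != 2L || any(hypo_beta <= 0) ||
      length(hyper_beta) != 2L || any(hyper_beta <= 0))
    stop("beta parameters must be two positive numbers", call. = FALSE)
  structure(list(dcm_level = dcm_level, cgi_count = as.integer(cgi_count),
                 cgi_length_mean = as.integer(cgi_length_mean),
                 hypo_beta = as.numeric(hypo_beta),
                 hyper_beta = as.numeric(hyper_beta),
                 hyper_fraction = hyper_fraction,
                 noncpg_level = noncpg_level),
            class = "MethylomeModelParams")
}

# deterministic CGI placement: tile candidate windows, rank by CpG count
# (above-median preferred), ties broken leftmost, greedy non-overlap.
.place_cgis <- function(seq_chr, n_cgi, cgi_len) {
  L <- nchar(seq_chr)
  if (n_cgi == 0L || cgi_len >= L) return(integer(0))
  step <- cgi_len
  starts <- seq.int(0L, L - cgi_len, by = step)
  subj <- Biostrings::DNAString(seq_chr)
  cg <- Biostrings::start(Biostrings::matchPattern("CG", subj)) - 1L
  counts <- vapply(starts, function(s)
    sum(cg >= s & cg < s + cgi_len), integer(1))
  ord <- order(-counts, starts)
  med <- stats::median(counts)
  ord <- c(ord[counts[ord] >= med], ord[counts[ord] < med])
  chosen <- integer(0)
  for (i in ord) {
    s <- starts[i]
    if (!length(chosen) || all(abs(chosen - s) >= cgi_len)) {
      chosen <- c(chosen, s)
      if (length(chosen) >= n_cgi) break
    }
  }
  sort(chosen)
}

#' Mammalian-like methylome: bimodal CpG methylation with CpG islands
#'
#' Places `cgi_count` non-overlapping CpG islands at CpG-dense windows and
#' assigns every CpG dyad (both strands, identical level) a level drawn from
#' `hypo_beta` inside CGIs, and from `hyper_beta` with probability
#' `hyper_fraction` (else `hypo_beta`) outside, producing the bimodal level
#' distribution typical of somatic mammalian methylomes. Non-CpG cytosines
#' receive `noncpg_level` (entries are materialized only when it is > 0).
#' The spike-in sequence remains fully unmethylated.
#'
#' @param genome a `GenomeSet`.
#' @param params a [methylome_model_params()].
#' @param seed integer seed.
#' @return list with elements `methylome` (a [methylome_profile()]) and
#'   `cgi` (a [region_set()] of the placed islands).
#' @export
mammalian_methylome <- function(genome, params = methylome_model_params(),
                                seed = 1L) {
  stopifnot(inherits(genome, "GenomeSet"),
            inherits(params, "MethylomeModelParams"))
  main <- setdiff(names(genome$sequences), genome$spike_in_name)
  if (params$cgi_count * params$cgi_length_mean >= sum(nchar(genome$sequences[main])))
    stop("cgi_count * cgi_length_mean must be smaller than the genome",
         call. = FALSE)
  set.seed(derive_seed(seed, 7L))
  ent <- list(); cgis <- list()
  for (nm in main) {
    s <- genome$sequences[[nm]]
    cgi_starts <- .place_cgis(s, params$cgi_count, params$cgi_length_mean)
    if (length(cgi_starts))
      cgis[[nm]] <- data.frame(seqnames = nm, start = cgi_starts,
                               end = cgi_starts + params$cgi_length_mean,
                               strand = "*")
    subj <- Biostrings::DNAString(s)
    cg <- Biostrings::start(Biostrings::matchPattern("CG", subj)) - 1L
    if (length(cg)) {
      in_cgi <- rep(FALSE, length(cg))
      for (st in cgi_starts)
        in_cgi <- in_cgi | (cg >= st & cg < st + params$cgi_length_mean)
      lev <- numeric(length(cg))
      lev[in_cgi] <- rbeta(sum(in_cgi), params$hypo_beta[1], params$hypo_beta[2])
      n_out <- sum(!in_cgi)
      if (n_out) {
        hyper <- runif(n_out) < params$hyper_fraction
        lv <- numeric(n_out)
        lv[hyper] <- rbeta(sum(hyper), params$hyper_beta[1], params$hyper_beta[2])
        lv[!hyper] <- rbeta(sum(!hyper), params$hypo_beta[1], params$hypo_beta[2])
        lev[!in_cgi] <- lv
      }
      # both strands of the dyad carry the same level
      ent[[length(ent) + 1L]] <- data.frame(
        seqnames = nm, pos = c(cg, cg + 1L),
        strand = rep(c("+", "-"), each = length(cg)),
        level = rep(lev, 2L))
    }
    if (params$noncpg_level > 0) {
      gi_raw <- charToRaw(s)
      cpos <- which(gi_raw == .RAW_C) - 1L
      gpos <- which(gi_raw == .RAW_G) - 1L
      non_c <- setdiff(cpos, cg)        # C not followed by G
      non_g <- setdiff(gpos, cg + 1L)   # G not preceded by C
      ent[[length(ent) + 1L]] <- data.frame(
        seqnames = nm, pos = c(non_c, non_g),
        strand = rep(c("+", "-"), c(length(non_c), length(non_g))),
        level = params$noncpg_level)
    }
  }
  entries <- if (length(ent)) do.call(rbind, ent) else data.frame()
  cgi_df <- if (length(cgis)) do.call(rbind, cgis) else data.frame()
  list(methylome = methylome_profile(entries, genome),
       cgi = region_set(cgi_df, label = "CGI", seq_lengths = seq_lengths(genome)))
}

#' Write a MethylomeProfile as tab-delimited text
#'
#' Columns: seqnames, pos (0-based), strand, level.
#' @param methylome a `MethylomeProfile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_methylome <- function(methylome, path) {
  stopifnot(inherits(methylome, "MethylomeProfile"))
  data.table::fwrite(as.data.frame(methylome), path, sep = "\t")
  invisible(path)
}

#' Read a MethylomeProfile from tab-delimited text
#' @param path input path (as written by [write_methylome()]).
#' @param genome optional `GenomeSet` for validation.
#' @return a [methylome_profile()].
#' @export
read_methylome <- function(path, genome = NULL) {
  dt <- data.table::fread(path, sep = "\t")
  methylome_profile(dt, genome)
}

# per-sequence level lookup arrays (forward-position indexed, one per strand)
.level_arrays <- function(genome, methylome) {
  gi <- .genome_index(genome)
  tot <- length(gi$blob)
  lvp <- numeric(tot); lvm <- numeric(tot)
  if (nrow(methylome)) {
    idx <- gi$off[methylome$seqnames] + methylome$pos + 1L
    plus <- methylome$strand == "+"
    lvp[idx[plus]] <- methylome$level[plus]
    lvm[idx[!plus]] <- methylome$level[!plus]
  }
  list(plus = lvp, minus = lvm, index = gi)
}
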