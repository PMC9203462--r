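#' GenomeSet: named DNA sequences with an optional spike-in control
#'
#' A `GenomeSet` holds the simulation reference: one or more DNA sequences
#' over the strict alphabet A/C/G/T, with at most one sequence flagged as the
#' unmethylated conversion-control spike-in (the in-silico analog of the 1%
#' unmethylated lambda DNA spiked into bisulfite libraries).
#'
#' @param sequences named character vector of DNA sequences (A/C/G/T only).
#' @param spike_in_name optional name of the sequence acting as the
#'   unmethylated conversion control; must refer to an existing sequence.
#' @return an object of class `GenomeSet`: a list with elements `sequences`
#'   and `spike_in_name`.
#' @examples
#' g <- genome_set(c(chr1 = "ACGTACGT"), spike_in_name = NULL)
#' total_length(g)
#' @export
genome_set <- function(sequences, spike_in_name = NULL) {
  if (length(sequences) == 0L)
    stop("GenomeSet requires at least one sequence", call. = FALSE)
  if (is.null(names(sequences)) || anyNA(names(sequences)) ||
      any(names(sequences) == "") || anyDuplicated(names(sequences)))
    stop("sequences must have unique non-empty names", call. = FALSE)
  sequences <- vapply(sequences, as.character, character(1))
  if (any(nchar(sequences) == 0L))
    stop("all sequences must be non-empty", call. = FALSE)
  if (any(grepl("[^ACGT]", sequences)))
    stop("sequences must use the alphabet {A,C,G,T} only", call. = FALSE)
  if (!is.null(spike_in_name)) {
    stopifnot(is.character(spike_in_name), length(spike_in_name) == 1L)
    if (!spike_in_name %in% names(sequences))
      stop("spike_in_name does not refer to an existing sequence", call. = FALSE)
  }
  structure(list(sequences = sequences, spike_in_name = spike_in_name),
            class = "GenomeSet")
}

#' @export
print.GenomeSet <- function(x, ...) {
  cat(sprintf("GenomeSet: %d sequence(s), %s bases total\n",
              length(x$sequences), format(total_length(x), big.mark = ",")))
  for (nm in names(x$sequences)) {
    tag <- if (!is.null(x$spike_in_name) && nm == x$spike_in_name)
      " [spike-in]" else ""
    cat(sprintf("  %s: %s bp%s\n", nm,
                format(nchar(x$sequences[[nm]]), big.mark = ","), tag))
  }
  invisible(x)
}

#' Total number of bases in a GenomeSet
#' @param genome a `GenomeSet`.
#' @return integer total length over all sequences.
#' @export
total_length <- function(genome) {
  stopifnot(inherits(genome, "GenomeSet"))
  sum(nchar(genome$sequences))
}

#' Lengths of the sequences in a GenomeSet
#' @param genome a `GenomeSet`.
#' @return named integer vector of per-sequence lengths.
#' @export
seq_lengths <- function(genome) {
  stopifnot(inherits(genome, "GenomeSet"))
  setNames(nchar(genome$sequences), names(genome$sequences))
}

# Concatenated byte view of a genome: blob (raw), 0-based per-sequence
# offsets and lengths. Used by the vectorized simulator and caller.
.genome_index <- function(genome) {
  lens <- nchar(genome$sequences)
  off <- c(0L, cumsum(as.integer(lens)))[seq_along(lens)]
  names(off) <- names(genome$sequences)
  list(blob = charToRaw(paste0(genome$sequences, collapse = "")),
       off = off, len = setNames(as.integer(lens), names(genome$sequences)))
}

# Dinucleotide joint distribution with margins fixed at the target base
# frequencies and the CG cell fixed at cpg_enrichment * fC * fG; the free
# cells are balanced by iterative proportional fitting. The transition matrix
# P(b | a) = J[a, b] / f[a] then has stationary distribution f, so the
# emitted sequence has base composition f and CpG dinucleotide frequency
# cpg_enrichment times the product of its base frequencies.
.dinuc_transition <- function(gc_fraction, cpg_enrichment) {
  f <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  J <- outer(f, f)
  if (f[["C"]] > 0 && f[["G"]] > 0 && cpg_enrichment != 1) {
    target_cg <- cpg_enrichment * f[["C"]] * f[["G"]]
    if (target_cg >= min(f[["C"]], f[["G"]]))
      stop("cpg_enrichment too large for this GC fraction", call. = FALSE)
    for (iter in 1:200) {
      J["C", "G"] <- target_cg
      rs <- rowSums(J)
      for (a in names(f)) {
        free <- rep(TRUE, 4L); names(free) <- names(f)
        if (a == "C") free["G"] <- FALSE
        scale <- (f[[a]] - sum(J[a, !free])) / sum(J[a, free])
        J[a, free] <- J[a, free] * scale
      }
      cs <- colSums(J)
      for (b in names(f)) {
        free <- rep(TRUE, 4L); names(free) <- names(f)
        if (b == "G") free["C"] <- FALSE
        scale <- (f[[b]] - sum(J[!free, b])) / sum(J[free, b])
        J[free, b] <- J[free, b] * scale
      }
      if (max(abs(rowSums(J) - f)) < 1e-12 && max(abs(colSums(J) - f)) < 1e-12)
        break
    }
    J["C", "G"] <- target_cg
  }
  P <- J / pmax(rowSums(J), .Machine$double.eps)
  # rows with zero stationary mass (gc 0 or 1) fall back to iid draws from f
  zero <- rowSums(J) <= 0
  if (any(zero)) P[zero, ] <- matrix(f, sum(zero), 4L, byrow = TRUE)
  list(f = f, P = P)
}

.markov_sequence <- function(n, f, P) {
  cum <- t(apply(P, 1L, cumsum))
  t1 <- cum[, 1L]; t2 <- cum[, 2L]; t3 <- cum[, 3L]
  x <- integer(n)
  u <- runif(n)
  cf <- cumsum(f)
  x[1L] <- 1L + (u[1L] > cf[1L]) + (u[1L] > cf[2L]) + (u[1L] > cf[3L])
  if (n > 1L) {
    for (i in 2:n) {
      p <- x[i - 1L]
      r <- u[i]
      x[i] <- 1L + (r > t1[p]) + (r > t2[p]) + (r > t3[p])
    }
  }
  rawToChar(.RAW_BASES[x])
}

#' Generate a synthetic genome
#'
#' Emits one first-order Markov sequence per row of `spec`. The chain is
#' parameterized so that the stationary base composition matches
#' `gc_fraction` and the CpG dinucleotide frequency equals `cpg_enrichment`
#' times the product of the base frequencies (values below 1 deplete CpG, as
#' in mammalian genomes; values above 1 enrich it, as inside CpG islands).
#'
#' @param spec data.frame with columns `name`, `length`, `gc_fraction` and
#'   optionally `cpg_enrichment` (default 1).
#' @param seed integer seed; output is reproducible for a fixed seed.
#' @param spike_in_name optional name (among `spec$name`) to flag as the
#'   unmethylated spike-in control.
#' @return a [genome_set()].
#' @examples
#' g <- generate_genome(data.frame(name = "chr1", length = 1000,
#'                                 gc_fraction = 0.5), seed = 1)
#' @export
generate_genome <- function(spec, seed, spike_in_name = NULL) {
  if (is.null(spec) || nrow(as.data.frame(spec)) == 0L)
    stop("empty genome spec", call. = FALSE)
  spec <- as.data.frame(spec, stringsAsFactors = FALSE)
  if (!all(c("name", "length", "gc_fraction") %in% names(spec)))
    stop("spec needs columns name, length, gc_fraction", call. = FALSE)
  if (is.null(spec$cpg_enrichment)) spec$cpg_enrichment <- 1
  if (any(spec$length < 1)) stop("sequence lengths must be >= 1", call. = FALSE)
  if (any(spec$gc_fraction < 0 | spec$gc_fraction > 1))
    stop("gc_fraction must be in [0, 1]", call. = FALSE)
  seqs <- character(nrow(spec))
  for (i in seq_len(nrow(spec))) {
    set.seed(derive_seed(seed, 101L * i))
    mod <- .dinuc_transition(spec$gc_fraction[i], spec$cpg_enrichment[i])
    seqs[i] <- .markov_sequence(as.integer(spec$length[i]), mod$f, mod$P)
  }
  names(seqs) <- spec$name
  genome_set(seqs, spike_in_name = spike_in_name)
}

#' Write a GenomeSet to FASTA
#' @param genome a `GenomeSet`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "GenomeSet"))
  x <- Biostrings::DNAStringSet(genome$sequences)
  Biostrings::writeXStringSet(x, filepath = path, width = 60L)
  invisible(path)
}

#' Read a GenomeSet from FASTA
#' @param path FASTA file path.
#' @param spike_in_name optional sequence name to flag as spike-in.
#' @return a [genome_set()].
#' @export
read_fasta <- function(path, spike_in_name = NULL) {
  x <- Biostrings::readDNAStringSet(path)
  nms <- sub("\\s.*$", "", names(x))
  genome_set(setNames(as.character(x), nms), spike_in_name = spike_in_name)
}
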