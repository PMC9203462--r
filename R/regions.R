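#' RegionSet: 0-based half-open genomic intervals
#'
#' A thin container for interval annotations (CpG islands, RRBS target
#' stand-ins, motif occurrences, called methylated sites). Coordinates are
#' 0-based half-open on forward-strand coordinates, as in BED.
#'
#' @param df data.frame with columns `seqnames`, `start`, `end` and
#'   optionally `strand` (`+`/`-`; defaults to `*`).
#' @param label free-text label for the set (used as BED track name).
#' @param seq_lengths optional named integer vector used to validate that
#'   intervals lie within their sequences.
#' @return an object of class `RegionSet`: a data.frame sorted by
#'   (seqnames, start) with attribute `label`.
#' @export
region_set <- function(df, label = "", seq_lengths = NULL) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    df <- data.frame(seqnames = character(0), start = integer(0),
                     end = integer(0), strand = character(0))
  } else {
    stopifnot(all(c("seqnames", "start", "end") %in% names(df)))
    if (is.null(df$strand)) df$strand <- "*"
    df <- df[, c("seqnames", "start", "end", "strand")]
    df$start <- as.integer(df$start); df$end <- as.integer(df$end)
    if (any(df$start < 0L) || any(df$start >= df$end))
      stop("intervals must satisfy 0 <= start < end", call. = FALSE)
    if (!is.null(seq_lengths)) {
      lim <- seq_lengths[df$seqnames]
      if (anyNA(lim) || any(df$end > lim))
        stop("interval outside its sequence", call. = FALSE)
    }
    df <- df[order(df$seqnames, df$start, df$end), , drop = FALSE]
    rownames(df) <- NULL
  }
  structure(df, class = c("RegionSet", "data.frame"), label = label)
}

#' @export
print.RegionSet <- function(x, ...) {
  cat(sprintf("RegionSet '%s': %d interval(s)\n", attr(x, "label"), nrow(x)))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 10L))
  invisible(x)
}

#' Find occurrences of an IUPAC motif on both strands
#'
#' Reports every match of `motif` on the forward strand and every match of
#' its reverse complement (= minus-strand occurrences), in forward 0-based
#' half-open coordinates. Overlapping matches are all reported. Used for the
#' Dcm motif CCWGG and the unmethylated control motif AASTT.
#'
#' @param genome a `GenomeSet`.
#' @param motif non-empty IUPAC string (e.g. `"CCWGG"`).
#' @return a [region_set()] with a `strand` column (`+` forward match,
#'   `-` reverse-strand match).
#' @examples
#' g <- genome_set(c(chr = "ACCAGGT"))
#' find_motif_occurrences(g, "CCWGG")
#' @export
find_motif_occurrences <- function(genome, motif) {
  stopifnot(inherits(genome, "GenomeSet"))
  if (!is.character(motif) || length(motif) != 1L || nchar(motif) == 0L)
    stop("motif must be a non-empty string", call. = FALSE)
  motif <- toupper(motif)
  bad <- setdiff(strsplit(motif, "")[[1]], names(Biostrings::IUPAC_CODE_MAP))
  if (length(bad))
    stop(sprintf("invalid IUPAC code(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  fwd <- Biostrings::DNAString(motif)
  rev <- Biostrings::reverseComplement(fwd)
  out <- list()
  for (nm in names(genome$sequences)) {
    subj <- Biostrings::DNAString(genome$sequences[[nm]])
    if (nchar(motif) > length(subj)) next
    mf <- Biostrings::matchPattern(fwd, subj, fixed = FALSE)
    if (length(mf))
      out[[length(out) + 1L]] <- data.frame(
        seqnames = nm, start = Biostrings::start(mf) - 1L,
        end = Biostrings::end(mf), strand = "+")
    mr <- Biostrings::matchPattern(rev, subj, fixed = FALSE)
    if (length(mr))
      out[[length(out) + 1L]] <- data.frame(
        seqnames = nm, start = Biostrings::start(mr) - 1L,
        end = Biostrings::end(mr), strand = "-")
  }
  df <- if (length(out)) do.call(rbind, out) else
    data.frame(seqnames = character(0), start = integer(0),
               end = integer(0), strand = character(0))
  region_set(df, label = sprintf("motif_%s", motif),
             seq_lengths = seq_lengths(genome))
}

#' Write a RegionSet as BED3(+strand)
#' @param regions a `RegionSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  stopifnot(inherits(regions, "RegionSet"))
  con <- file(path, "w")
  on.exit(close(con))
  lab <- attr(regions, "label")
  if (!is.null(lab) && nzchar(lab))
    writeLines(sprintf("track name=\"%s\"", lab), con)
  if (nrow(regions)) {
    df <- as.data.frame(regions)
    has_strand <- any(df$strand %in% c("+", "-"))
    cols <- if (has_strand)
      data.frame(df$seqnames, df$start, df$end, ".", 0L, df$strand) else
      data.frame(df$seqnames, df$start, df$end)
    write.table(cols, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a BED3/BED6 file into a RegionSet
#' @param path BED path (a leading `track` line is honored as the label).
#' @return a [region_set()].
#' @export
read_bed <- function(path) {
  first <- readLines(path, n = 1L)
  label <- ""
  skip <- 0L
  if (length(first) && grepl("^track", first)) {
    skip <- 1L
    m <- regmatches(first, regexec("name=\"?([^\"]*)\"?", first))[[1]]
    if (length(m) == 2L) label <- m[2]
  }
  df <- tryCatch(read.delim(path, header = FALSE, skip = skip,
                            stringsAsFactors = FALSE),
                 error = function(e) NULL)
  if (is.null(df) || nrow(df) == 0L) return(region_set(data.frame(), label))
  out <- data.frame(seqnames = df[[1]], start = df[[2]], end = df[[3]])
  if (ncol(df) >= 6L) out$strand <- df[[6]]
  region_set(out, label = label)
}

# minimum-overlap interval hits: returns logical, one per query row, TRUE if
# the query interval overlaps any subject interval by >= min_overlap bases.
.overlaps_any <- function(q_seq, q_start, q_end, s_seq, s_start, s_end,
                          min_overlap = 1L) {
  hit <- logical(length(q_seq))
  if (!length(q_seq) || !length(s_seq)) return(hit)
  for (nm in unique(q_seq)) {
    qi <- which(q_seq == nm)
    si <- which(s_seq == nm)
    if (!length(si)) next
    qr <- IRanges::IRanges(start = q_start[qi] + 1L, end = q_end[qi])
    sr <- IRanges::IRanges(start = s_start[si] + 1L, end = s_end[si])
    ov <- IRanges::overlapsAny(qr, sr, minoverlap = min_overlap)
    hit[qi] <- ov
  }
  hit
}
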