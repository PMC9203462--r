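# Low-level byte helpers shared by the simulator and the caller.
# Sequences are manipulated as raw vectors of ASCII bytes (A=65, C=67, G=71,
# T=84); coordinates are 0-based half-open externally, 1-based internally.

.BASES <- c("A", "C", "G", "T")
.RAW_A <- as.raw(65L)
.RAW_C <- as.raw(67L)
.RAW_G <- as.raw(71L)
.RAW_T <- as.raw(84L)
.RAW_BASES <- as.raw(c(65L, 67L, 71L, 84L))

# 256-entry complement lookup table (index = byte value + 1)
.comp_table <- local({
  tab <- as.raw(seq_len(256L) - 1L)
  tab[66:90] <- as.raw(66:90 - 1L) # identity for A..Z placeholder, fixed below
  tab <- as.raw(seq_len(256L) - 1L)
  tab[65L + 1L] <- .RAW_T
  tab[84L + 1L] <- .RAW_A
  tab[67L + 1L] <- .RAW_G
  tab[71L + 1L] <- .RAW_C
  tab
})

.comp_raw <- function(x) .comp_table[as.integer(x) + 1L]

.revcomp_chr <- function(x) {
  vapply(x, function(s) rawToChar(rev(.comp_raw(charToRaw(s)))), character(1),
         USE.NAMES = FALSE)
}

.chunk_indices <- function(n, chunk_size) {
  if (n == 0L) return(list())
  starts <- seq.int(1L, n, by = chunk_size)
  lapply(starts, function(s) s:min(s + chunk_size - 1L, n))
}

#' Derive a child seed from a root seed
#'
#' Deterministic integer mixing used to give each pipeline stage (and each
#' batch within a stage) its own reproducible RNG stream while exposing a
#' single root seed to the user. Values stay below 2^31.
#'
#' @param seed integer root seed.
#' @param stage integer stage tag.
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(stage))
  as.integer((abs(seed) * 48271 + stage * 16807 + 12345) %% 2147483629)
}

.assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single value in [0, 1]", name), call. = FALSE)
  invisible(x)
}

.assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  invisible(as.integer(x))
}

# substring a concatenated fixed-width raw/char blob into per-record strings
.split_fixed <- function(big_string, width, n) {
  if (n == 0L) return(character(0))
  starts <- (seq_len(n) - 1L) * width + 1L
  substring(big_string, starts, starts + width - 1L)
}
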