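# Internal helpers shared across modules. All coordinates in the package are
# 0-based half-open (BED convention); conversion from 1-based records happens
# exactly once, in the parsers that accept them.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_oriturn <- function(...) stop(..., call. = FALSE)

#' Random DNA sequence
#'
#' Draws `n` bases i.i.d. from the given base probabilities. Used by the
#' synthetic-genome generator; fast enough for multi-megabase chromosomes.
#'
#' @param n number of bases.
#' @param probs length-4 numeric, probabilities for A, C, G, T (normalized
#'   internally).
#' @return a single character string of length `n`.
#' @keywords internal
#' @noRd
random_dna <- function(n, probs = rep(0.25, 4)) {
  if (n == 0L) return("")
  probs <- probs / sum(probs)
  idx <- sample.int(4L, n, replace = TRUE, prob = probs)
  rawToChar(charToRaw("ACGT")[idx])
}

# Split a string into a character vector of single bases.
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

reverse_complement <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# data.frame(start, end) of 0-based half-open intervals -> IRanges
df_to_iranges <- function(df) {
  IRanges::IRanges(start = df$start + 1L, end = df$end)
}

iranges_to_df <- function(ir) {
  data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

# Any-overlap indicator for query intervals against subject intervals, both
# data.frames with chrom/start/end. >= 1 bp overlap counts.
overlaps_any <- function(query, subject) {
  hit <- logical(nrow(query))
  if (nrow(query) == 0L || nrow(subject) == 0L) return(hit)
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    si <- which(subject$chrom == ch)
    if (length(si) == 0L) next
    q <- df_to_iranges(query[qi, , drop = FALSE])
    s <- df_to_iranges(subject[si, , drop = FALSE])
    hit[qi] <- IRanges::overlapsAny(q, s)
  }
  hit
}

# Merge sorted, possibly overlapping intervals (data.frame start/end).
reduce_intervals <- function(df) {
  if (nrow(df) == 0L) return(df)
  iranges_to_df(IRanges::reduce(df_to_iranges(df)))
}

# Total mappable bp of `intervals` (start/end data.frame) inside [from, to).
mappable_bp_between <- function(intervals, from, to) {
  if (nrow(intervals) == 0L) return(0L)
  s <- pmax(intervals$start, from)
  e <- pmin(intervals$end, to)
  sum(pmax(0L, e - s))
}

# Draw one integer position uniformly from a set of half-open intervals,
# vectorized over n draws. Intervals given as data.frame(start, end).
sample_positions_in_intervals <- function(intervals, n) {
  widths <- intervals$end - intervals$start
  if (sum(widths) == 0L || n == 0L) return(integer(0))
  cw <- cumsum(as.numeric(widths))
  u <- runif(n, 0, cw[length(cw)])
  i <- findInterval(u, c(0, cw), rightmost.closed = TRUE)
  i[i > length(widths)] <- length(widths)
  offset <- floor(u - c(0, cw)[i])
  as.integer(intervals$start[i] + offset)
}

# Deterministic child seed derived from a base seed and a stage tag; kept
# well below .Machine$integer.max.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483563)
}

# Count occurrences of a literal motif in a string, overlapping matches
# included (lookahead scan).
count_motif <- function(seqs, motif) {
  pat <- paste0("(?=", motif, ")")
  vapply(seqs, function(s) {
    m <- gregexpr(pat, s, perl = TRUE)[[1L]]
    if (m[1L] == -1L) 0L else length(m)
  }, integer(1), USE.NAMES = FALSE)
}
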