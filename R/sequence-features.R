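# Sequence signatures anchored on SNS peaks: nucleotide content, GC/AT
# strand skew with its inversion point, and G-quadruplex motif scanning.

#' Anchored profile container
#'
#' @param offsets bp (or bin midpoints) relative to the anchor; negative is
#'   upstream.
#' @param values per-offset statistic.
#' @param n_anchors number of anchors contributing.
#' @param bin_size bin width in bp.
#' @return data.frame of class `anchored_profile` with columns `offset` and
#'   `value`; attributes `n_anchors` and `bin_size`.
#' @export
anchored_profile <- function(offsets, values, n_anchors, bin_size = 1L) {
  if (is.unsorted(offsets, strictly = TRUE))
    stop_oriturn("offsets must be strictly increasing")
  structure(data.frame(offset = offsets, value = values),
            n_anchors = n_anchors, bin_size = bin_size,
            class = c("anchored_profile", "data.frame"))
}

# Extract fixed-width windows centred on anchor peaks as a DNAStringSet,
# dropping anchors whose window is clipped by a chromosome end.
anchor_windows <- function(peaks, genome, halfwidth) {
  keep <- peaks$peak - halfwidth >= 0 &
    peaks$peak + halfwidth < as.numeric(genome$chrom_lengths[peaks$chrom])
  pk <- peaks[keep, , drop = FALSE]
  if (nrow(pk) == 0L) stop_oriturn("all anchors clipped by chromosome ends")
  win <- vapply(seq_len(nrow(pk)), function(i)
    get_seq(genome, pk$chrom[i], pk$peak[i] - halfwidth,
            pk$peak[i] + halfwidth + 1L), character(1))
  Biostrings::DNAStringSet(win)
}

#' Average nucleotide content around SNS peaks
#'
#' For each offset in `[-halfwidth, halfwidth]`, the fraction of anchors
#' whose base at that offset is A, C, G or T (N bases excluded from the
#' denominator). The four profiles sum to 1 at every offset.
#'
#' @param peaks [origin_set()] (or data.frame) with `chrom` and `peak`.
#' @param genome a [genome_ref()].
#' @param halfwidth half-width of the profiled window in bp.
#' @return named list of four [anchored_profile()]s (`A`, `C`, `G`, `T`).
#' @export
nucleotide_profile <- function(peaks, genome, halfwidth = 250L) {
  win <- anchor_windows(peaks, genome, halfwidth)
  cm <- Biostrings::consensusMatrix(win, baseOnly = TRUE)
  acgt <- cm[c("A", "C", "G", "T"), , drop = FALSE]
  denom <- colSums(acgt)
  offsets <- seq(-halfwidth, halfwidth)
  stats::setNames(lapply(c("A", "C", "G", "T"), function(b)
    anchored_profile(offsets, as.numeric(acgt[b, ] / denom), length(win))),
    c("A", "C", "G", "T"))
}

#' GC and AT skew profiles around SNS peaks
#'
#' Base counts are pooled over anchors per offset bin; the skews are
#' S_GC = (G-C)/(G+C) and S_AT = (A-T)/(A+T). Bins without informative bases
#' are reported as `NA`. Anchors are not orientation-flipped (origins are
#' unoriented).
#'
#' @param peaks anchors with `chrom` and `peak`.
#' @param genome a [genome_ref()].
#' @param halfwidth half-width in bp.
#' @param bin bin width in bp.
#' @return list with [anchored_profile()]s `S_GC` and `S_AT`; offsets are
#'   bin midpoints.
#' @export
skew_profile <- function(peaks, genome, halfwidth = 2500L, bin = 25L) {
  if (bin < 1L) stop_oriturn("bin must be >= 1")
  win <- anchor_windows(peaks, genome, halfwidth)
  width <- 2L * halfwidth + 1L
  starts <- seq(1L, width, by = bin)
  ends <- starts + bin - 1L
  full <- ends <= width          # partial trailing bin dropped
  starts <- starts[full]
  ends <- ends[full]
  cnt <- vapply(seq_along(starts), function(j) {
    sub <- Biostrings::subseq(win, starts[j], ends[j])
    colSums(Biostrings::letterFrequency(sub, c("A", "C", "G", "T")))
  }, numeric(4))
  offsets <- (starts + ends) / 2 - (halfwidth + 1L)
  a <- cnt[1, ]; c_ <- cnt[2, ]; g <- cnt[3, ]; t <- cnt[4, ]
  sgc <- ifelse(g + c_ > 0, (g - c_) / (g + c_), NA_real_)
  sat <- ifelse(a + t > 0, (a - t) / (a + t), NA_real_)
  list(S_GC = anchored_profile(offsets, sgc, length(win), bin),
       S_AT = anchored_profile(offsets, sat, length(win), bin))
}

#' Locate the skew inversion point
#'
#' Finds the sign change of the binned skew nearest offset zero, linearly
#' interpolated between the flanking bins, together with the offsets of the
#' positive and negative extrema.
#'
#' @param profile an [anchored_profile()] (e.g. `S_GC` from
#'   [skew_profile()]).
#' @return list with `inversion` (interpolated offset), `max_offset`
#'   (positive extremum) and `min_offset` (negative extremum).
#' @export
find_skew_inversion <- function(profile) {
  v <- profile$value
  o <- profile$offset
  ok <- !is.na(v)
  v <- v[ok]; o <- o[ok]
  if (sum(v > 0) < 2L || sum(v < 0) < 2L)
    stop_oriturn("monotone profile: no sign change with >= 2 bins per sign")
  flip <- which(sign(v[-1]) * sign(v[-length(v)]) < 0)
  if (length(flip) == 0L) stop_oriturn("monotone profile: no sign change")
  mid <- (o[flip] + o[flip + 1L]) / 2
  k <- flip[which.min(abs(mid))]
  # linear interpolation of the zero crossing between bins k and k+1
  x0 <- o[k] - v[k] * (o[k + 1L] - o[k]) / (v[k + 1L] - v[k])
  list(inversion = x0,
       max_offset = o[which.max(v)],
       min_offset = o[which.min(v)])
}

# Exhaustive scanner core shared by scan_g4 and its test oracle is NOT used
# here; this is the production regex scanner. Leftmost non-overlapping
# greedy matches of G3 N1-7 G3 N1-7 G3 N1-7 G3; N bases never match.
g4_regex <- "G{3}[ACGT]{1,7}G{3}[ACGT]{1,7}G{3}[ACGT]{1,7}G{3}"

scan_g4_strand <- function(seq) {
  m <- gregexpr(g4_regex, seq, perl = TRUE)[[1L]]
  if (m[1L] == -1L)
    return(data.frame(start = integer(0), length = integer(0)))
  data.frame(start = as.integer(m) - 1L,
             length = attr(m, "match.length"))
}

#' Scan for G-quadruplex motifs
#'
#' Detects the motif G3 N1-7 G3 N1-7 G3 N1-7 G3 on both strands (minus
#' strand = matches on the reverse complement, mapped back to plus-strand
#' coordinates). Matching is leftmost non-overlapping per strand; ambiguous
#' N bases never match. Each hit is summarized by its midpoint,
#' `start + floor(length/2)` in genome coordinates.
#'
#' @param genome a [genome_ref()].
#' @param intervals optional data.frame of intervals to restrict scanning
#'   (coordinates reported genome-wide).
#' @return data.frame of class `g4_hits`: `chrom`, `start`, `end`, `strand`,
#'   `length`, `midpoint`.
#' @export
scan_g4 <- function(genome, intervals = NULL) {
  regions <- if (is.null(intervals)) {
    data.frame(chrom = genome$chrom_names, start = 0L,
               end = as.integer(genome$chrom_lengths[genome$chrom_names]))
  } else intervals
  out <- NULL
  for (i in seq_len(nrow(regions))) {
    ch <- regions$chrom[i]
    s0 <- regions$start[i]
    sq <- get_seq(genome, ch, s0, regions$end[i])
    plus <- scan_g4_strand(sq)
    if (nrow(plus) > 0)
      out <- rbind(out, data.frame(chrom = ch, start = s0 + plus$start,
                                   length = plus$length, strand = "+"))
    rc <- reverse_complement(sq)
    minus <- scan_g4_strand(rc)
    if (nrow(minus) > 0) {
      L <- nchar(sq)
      out <- rbind(out, data.frame(
        chrom = ch,
        start = s0 + L - (minus$start + minus$length),
        length = minus$length, strand = "-"))
    }
  }
  if (is.null(out))
    out <- data.frame(chrom = character(0), start = integer(0),
                      length = integer(0), strand = character(0))
  out$end <- out$start + out$length
  out$midpoint <- out$start + out$length %/% 2L
  out <- out[order(out$chrom, out$start, out$strand),
             c("chrom", "start", "end", "strand", "length", "midpoint")]
  rownames(out) <- NULL
  class(out) <- c("g4_hits", "data.frame")
  out
}

#' Write G4 hits as BED6
#'
#' The midpoint is written as a 1-bp interval with the match length as
#' score and the strand in column 6.
#'
#' @param hits a [scan_g4()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_g4_bed <- function(hits, path) {
  writeLines(paste(hits$chrom, hits$midpoint, hits$midpoint + 1L, "G4",
                   hits$length, hits$strand, sep = "\t"), path)
  invisible(path)
}

#' G4 motif density profile around SNS peaks
#'
#' Counts hit midpoints per offset bin, summed (not averaged) over anchors.
#'
#' @param peaks anchors with `chrom` and `peak`.
#' @param hits a [scan_g4()] result on the same genome.
#' @param halfwidth half-width in bp.
#' @param bin bin width in bp.
#' @return an [anchored_profile()]; offsets are bin midpoints.
#' @export
g4_density_profile <- function(peaks, hits, halfwidth = 250L, bin = 5L) {
  edges <- seq(-halfwidth, halfwidth, by = bin)
  counts <- numeric(length(edges) - 1L)
  for (ch in unique(peaks$chrom)) {
    mid <- sort(hits$midpoint[hits$chrom == ch])
    if (length(mid) == 0L) next
    for (p in peaks$peak[peaks$chrom == ch]) {
      d <- mid[mid >= p - halfwidth & mid < p + halfwidth] - p
      if (length(d))
        counts <- counts + tabulate(findInterval(d, edges),
                                    nbins = length(counts))
    }
  }
  anchored_profile(edges[-length(edges)] + bin / 2, counts,
                   nrow(peaks), bin)
}
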