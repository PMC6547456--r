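#' Genome reference container
#'
#' Bundles chromosome sequences, lengths and a mappability mask under a single
#' coordinate authority. All coordinates in the package are 0-based half-open.
#'
#' @param seqs named character vector of upper-case chromosome sequences
#'   (alphabet A, C, G, T, N).
#' @param mappable named list (one entry per chromosome) of
#'   `data.frame(start, end)` half-open mappable intervals; defaults to fully
#'   mappable chromosomes.
#' @return an object of class `genome_ref` with elements `chrom_names`,
#'   `chrom_lengths`, `seqs` and `mappable`.
#' @export
genome_ref <- function(seqs, mappable = NULL) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop_oriturn("chromosome sequences must have unique names")
  seqs <- vapply(seqs, toupper, character(1))
  bad <- vapply(seqs, function(s) grepl("[^ACGTN]", s), logical(1))
  if (any(bad))
    stop_oriturn("non-IUPAC character in sequence of: ",
                 paste(names(seqs)[bad], collapse = ", "))
  lens <- vapply(seqs, nchar, integer(1))
  if (is.null(mappable)) {
    mappable <- lapply(lens, function(L) data.frame(start = 0L, end = L))
  }
  mappable <- mappable[names(seqs)]
  names(mappable) <- names(seqs)
  for (ch in names(seqs)) {
    m <- mappable[[ch]]
    if (is.null(m)) m <- data.frame(start = integer(0), end = integer(0))
    m <- m[order(m$start), , drop = FALSE]
    if (nrow(m) > 0) {
      if (any(m$start < 0L) || any(m$end > lens[[ch]]))
        stop_oriturn("mappable interval outside [0, chrom_length) on ", ch)
      if (any(m$start >= m$end))
        stop_oriturn("empty or inverted mappable interval on ", ch)
      if (nrow(m) > 1 && any(m$start[-1] < m$end[-nrow(m)]))
        m <- reduce_intervals(m)
    }
    rownames(m) <- NULL
    mappable[[ch]] <- m[, c("start", "end")]
  }
  structure(
    list(chrom_names = names(seqs), chrom_lengths = lens,
         seqs = seqs, mappable = mappable),
    class = "genome_ref")
}

#' @export
print.genome_ref <- function(x, ...) {
  cat("<genome_ref> ", length(x$chrom_names), " chromosome(s), ",
      format(sum(as.numeric(x$chrom_lengths)), big.mark = ","), " bp total, ",
      format(mappable_length(x), big.mark = ","), " bp mappable\n", sep = "")
  invisible(x)
}

#' Total mappable length of a genome
#' @param genome a [genome_ref()].
#' @return mappable base pairs (numeric scalar).
#' @export
mappable_length <- function(genome) {
  sum(vapply(genome$mappable,
             function(m) sum(as.numeric(m$end - m$start)), numeric(1)))
}

#' Extract sequence of a genomic interval
#' @param genome a [genome_ref()].
#' @param chrom chromosome name.
#' @param start,end 0-based half-open coordinates.
#' @return character scalar.
#' @export
get_seq <- function(genome, chrom, start, end) {
  if (!chrom %in% genome$chrom_names)
    stop_oriturn("unknown chromosome: ", chrom)
  L <- genome$chrom_lengths[[chrom]]
  if (start < 0 || end > L || start >= end)
    stop_oriturn("interval [", start, ",", end, ") out of range on ", chrom)
  substr(genome$seqs[[chrom]], start + 1L, end)
}

#' SNS read-position track
#'
#' Per-chromosome sorted 0-based 5' read positions plus the total mapped-read
#' count. Fragment length is not modeled: a read is its 5' position.
#'
#' @param positions named list of integer vectors of 0-based positions.
#' @param genome optional [genome_ref()] used to validate positions.
#' @return object of class `read_track` with `positions` (sorted) and
#'   `total_reads`.
#' @export
read_track <- function(positions, genome = NULL) {
  positions <- lapply(positions, function(p) sort(as.integer(p)))
  if (!is.null(genome)) {
    for (ch in names(positions)) {
      if (!ch %in% genome$chrom_names)
        stop_oriturn("track chromosome not in genome: ", ch)
      L <- genome$chrom_lengths[[ch]]
      p <- positions[[ch]]
      if (length(p) && (p[1] < 0L || p[length(p)] >= L))
        stop_oriturn("read position outside [0, chrom_length) on ", ch)
    }
  }
  structure(list(positions = positions,
                 total_reads = sum(lengths(positions))),
            class = "read_track")
}

#' @export
print.read_track <- function(x, ...) {
  cat("<read_track> ", format(x$total_reads, big.mark = ","), " reads on ",
      length(x$positions), " chromosome(s)\n", sep = "")
  invisible(x)
}

#' Convert 1-based inclusive coordinates to 0-based half-open
#'
#' The single conversion point for records from 1-based sources (GFF, EPD
#' promoter tables, and the like): start shifts by -1, end is unchanged.
#'
#' @param start,end 1-based inclusive coordinates.
#' @return list with 0-based half-open `start` and `end`.
#' @export
from_one_based <- function(start, end) {
  if (any(start < 1L) || any(end < start))
    stop_oriturn("invalid 1-based inclusive interval")
  list(start = as.integer(start) - 1L, end = as.integer(end))
}

#' Read a BED file of intervals
#'
#' Accepts BED3/BED4/BED5: chrom, start, end, then optional name and score.
#' The score column is mapped onto `rpkm`. Coordinates are taken as 0-based
#' half-open, unchanged.
#'
#' @param path file path.
#' @return data.frame with columns `chrom`, `start`, `end` and, when present,
#'   `label` and `rpkm`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop_oriturn("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3L))
    stop_oriturn("malformed BED line ", which(ncol < 3L)[1],
                 ": fewer than 3 tab-separated columns")
  start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  if (anyNA(start) || anyNA(end))
    stop_oriturn("malformed BED line ",
                 which(is.na(start) | is.na(end))[1],
                 ": non-integer coordinate")
  if (any(start >= end))
    stop_oriturn("invalid interval at line ", which(start >= end)[1],
                 ": start must be < end")
  if (any(start < 0L))
    stop_oriturn("invalid interval at line ", which(start < 0L)[1],
                 ": negative start")
  out <- data.frame(chrom = vapply(fields, `[`, "", 1L),
                    start = start, end = end)
  if (all(ncol >= 4L)) out$label <- vapply(fields, `[`, "", 4L)
  if (all(ncol >= 5L))
    out$rpkm <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 5L)))
  out
}

#' Write intervals as BED
#'
#' Writes BED3, BED4 (with `label`) or BED5 (with `label` and `rpkm`);
#' coordinates are written unchanged so `read_bed(write_bed(x))` round-trips
#' bit-exactly.
#'
#' @param x data.frame with `chrom`, `start`, `end` and optional `label`,
#'   `rpkm`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  cols <- list(x$chrom, x$start, x$end)
  if (!is.null(x$label)) {
    cols <- c(cols, list(x$label))
    if (!is.null(x$rpkm)) cols <- c(cols, list(format(x$rpkm, digits = 15)))
  }
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTA genome, with optional mappability mask
#'
#' Sequences are upper-cased for storage. Soft-masked (lower-case) bases are
#' kept in the sequence but excluded from the mappable intervals when no mask
#' file is given; when `mask_path` is given, the mask BED defines mappability
#' and case is ignored.
#'
#' @param path FASTA path (unique headers required).
#' @param mask_path optional BED of mappable intervals.
#' @return a [genome_ref()].
#' @export
read_fasta <- function(path, mask_path = NULL) {
  dss <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(dss))
  if (anyDuplicated(nm))
    stop_oriturn("duplicate FASTA header: ", nm[duplicated(nm)][1])
  raw <- as.character(dss)
  names(raw) <- nm
  if (any(grepl("[^ACGTNacgtn]", raw)))
    stop_oriturn("non-IUPAC character in FASTA record")
  if (is.null(mask_path)) {
    mappable <- lapply(raw, function(s) {
      soft <- charToRaw(s) >= charToRaw("a")  # lower-case = soft-masked
      r <- rle(!soft)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths
      data.frame(start = starts[r$values], end = ends[r$values])
    })
  } else {
    bed <- read_bed(mask_path)
    mappable <- lapply(nm, function(ch) {
      b <- bed[bed$chrom == ch, c("start", "end"), drop = FALSE]
      reduce_intervals(b[order(b$start), , drop = FALSE])
    })
    names(mappable) <- nm
  }
  genome_ref(vapply(raw, toupper, character(1)), mappable)
}

#' Write a genome as FASTA (plus optional mask BED)
#'
#' Mappability is encoded in the companion mask BED, not as soft-masking.
#'
#' @param genome a [genome_ref()].
#' @param path FASTA output path.
#' @param mask_path optional BED output path for the mappable intervals.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, mask_path = NULL, width = 70L) {
  dss <- Biostrings::DNAStringSet(genome$seqs)
  Biostrings::writeXStringSet(dss, path, width = width)
  if (!is.null(mask_path)) {
    beds <- do.call(rbind, lapply(genome$chrom_names, function(ch) {
      m <- genome$mappable[[ch]]
      if (nrow(m) == 0L) return(NULL)
      data.frame(chrom = ch, start = m$start, end = m$end)
    }))
    write_bed(beds, mask_path)
  }
  invisible(path)
}

#' Read a variant table
#'
#' Tab-separated columns `chrom`, `pos` (0-based), `ancestral`, `derived`,
#' optional `daf`. Rows whose ancestral and derived alleles differ in length
#' are indels; `daf` may be missing throughout (species where rare and common
#' variants cannot be distinguished).
#'
#' @param path TSV path with a header line.
#' @return data.frame of class `variant_table` with columns `chrom`, `pos`,
#'   `ancestral`, `derived`, `daf`, `kind`.
#' @export
read_variant_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = c(chrom = "character",
                                  ancestral = "character",
                                  derived = "character"),
                   stringsAsFactors = FALSE)
  if (!all(c("chrom", "pos", "ancestral", "derived") %in% names(df)))
    stop_oriturn("variant table must have chrom, pos, ancestral, derived")
  if (is.null(df$daf)) df$daf <- NA_real_
  variant_table(df)
}

#' Construct/validate a variant table
#' @param df data.frame with `chrom`, `pos`, `ancestral`, `derived` and
#'   optional `daf`.
#' @return validated `variant_table` data.frame (adds `kind`: snp or indel).
#' @export
variant_table <- function(df) {
  if (is.null(df$daf)) df$daf <- NA_real_
  if (nrow(df) > 0) {
    if (any(df$ancestral == df$derived))
      stop_oriturn("variant with ancestral == derived at row ",
                   which(df$ancestral == df$derived)[1])
    bad <- !is.na(df$daf) & (df$daf < 0 | df$daf > 1)
    if (any(bad)) stop_oriturn("daf outside [0,1] at row ", which(bad)[1])
  }
  df$kind <- ifelse(nchar(df$ancestral) == 1L & nchar(df$derived) == 1L,
                    "snp", "indel")
  df <- df[, c("chrom", "pos", "ancestral", "derived", "daf", "kind")]
  class(df) <- c("variant_table", "data.frame")
  df
}

#' Write a variant table as TSV
#' @param x a `variant_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(x, path) {
  write.table(x[, c("chrom", "pos", "ancestral", "derived", "daf")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a homology (conserved-segment) map
#'
#' Tab-separated columns `chrom_a`, `start_a`, `end_a`, `chrom_b`, `start_b`,
#' `end_b`, `orientation` (+/-). Segments are ungapped and co-linear: both
#' sides must have equal length, and A-side segments must not overlap.
#'
#' @param path TSV path with a header line.
#' @return data.frame of class `homology_map`.
#' @export
read_homology_map <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE,
                   colClasses = c(chrom_a = "character",
                                  chrom_b = "character",
                                  orientation = "character"))
  homology_map(df)
}

#' Construct/validate a homology map
#' @param df data.frame with `chrom_a`, `start_a`, `end_a`, `chrom_b`,
#'   `start_b`, `end_b`, `orientation`.
#' @return validated `homology_map` data.frame.
#' @export
homology_map <- function(df) {
  need <- c("chrom_a", "start_a", "end_a", "chrom_b", "start_b", "end_b",
            "orientation")
  if (!all(need %in% names(df)))
    stop_oriturn("homology map needs columns: ", paste(need, collapse = ", "))
  if (nrow(df) > 0) {
    if (!all(df$orientation %in% c("+", "-")))
      stop_oriturn("orientation must be '+' or '-'")
    mism <- (df$end_a - df$start_a) != (df$end_b - df$start_b)
    if (any(mism))
      stop_oriturn("segment pair with unequal lengths at row ",
                   which(mism)[1])
    for (ch in unique(df$chrom_a)) {
      a <- df[df$chrom_a == ch, , drop = FALSE]
      a <- a[order(a$start_a), , drop = FALSE]
      if (nrow(a) > 1 && any(a$start_a[-1] < a$end_a[-nrow(a)]))
        stop_oriturn("overlapping A-side segments on ", ch)
    }
  }
  df <- df[, need]
  class(df) <- c("homology_map", "data.frame")
  df
}

#' Write a homology map as TSV
#' @param x a `homology_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_homology_map <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a bedGraph score track
#' @param path bedGraph path (chrom, start, end, value; no header).
#' @return data.frame with `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "value"),
                   colClasses = c("character", "integer", "integer",
                                  "numeric"))
  if (nrow(df) > 0 && any(df$start >= df$end))
    stop_oriturn("invalid bedGraph interval: start must be < end")
  df
}

#' Write a bedGraph score track
#' @param x data.frame with `chrom`, `start`, `end`, `value`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(x, path) {
  writeLines(paste(x$chrom, x$start, x$end,
                   format(x$value, digits = 15, trim = TRUE), sep = "\t"),
             path)
  invisible(path)
}

#' Read a track of read 5' positions from BED
#'
#' Each BED interval contributes one read at its start coordinate.
#'
#' @param path BED path.
#' @param genome optional [genome_ref()] for validation.
#' @return a [read_track()].
#' @export
read_reads_bed <- function(path, genome = NULL) {
  bed <- read_bed(path)
  read_track(split(bed$start, bed$chrom), genome)
}

#' Write a read track as BED3
#' @param track a [read_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reads_bed <- function(track, path) {
  df <- do.call(rbind, lapply(names(track$positions), function(ch) {
    p <- track$positions[[ch]]
    if (length(p) == 0L) return(NULL)
    data.frame(chrom = ch, start = p, end = p + 1L)
  }))
  if (is.null(df)) df <- data.frame(chrom = character(0), start = integer(0),
                                    end = integer(0))
  write_bed(df, path)
}

#' Construct an origin set
#'
#' @param df data.frame with `chrom`, `start`, `end` and optional `peak`,
#'   `rpkm`, `label`.
#' @return validated data.frame of class `origin_set`.
#' @export
origin_set <- function(df) {
  if (is.null(df$peak)) df$peak <- rep(NA_integer_, nrow(df))
  if (is.null(df$rpkm)) df$rpkm <- rep(NA_real_, nrow(df))
  if (is.null(df$label)) df$label <- rep(NA_character_, nrow(df))
  if (nrow(df) > 0) {
    if (any(df$start >= df$end)) stop_oriturn("origin with start >= end")
    pk <- !is.na(df$peak)
    if (any(df$peak[pk] < df$start[pk] | df$peak[pk] >= df$end[pk]))
      stop_oriturn("peak outside [start, end)")
    if (any(!is.na(df$rpkm) & df$rpkm < 0)) stop_oriturn("negative rpkm")
  }
  df <- df[, c("chrom", "start", "end", "peak", "rpkm", "label")]
  rownames(df) <- NULL
  class(df) <- c("origin_set", "data.frame")
  df
}

#' Write origins as BED-like TSV (BED5 + peak column)
#' @param x an [origin_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_origins <- function(x, path) {
  out <- data.frame(chrom = x$chrom, start = x$start, end = x$end,
                    label = ifelse(is.na(x$label), ".", x$label),
                    rpkm = format(x$rpkm, digits = 15, trim = TRUE),
                    peak = x$peak)
  writeLines(c("#chrom\tstart\tend\tlabel\trpkm\tpeak",
               do.call(paste, c(out, sep = "\t"))), path)
  invisible(path)
}

#' Read origins written by [write_origins()]
#' @param path TSV path.
#' @return an [origin_set()].
#' @export
read_origins <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                   col.names = c("chrom", "start", "end", "label", "rpkm",
                                 "peak"),
                   colClasses = c("character", "integer", "integer",
                                  "character", "numeric", "integer"))
  df$label[df$label == "."] <- NA_character_
  origin_set(df)
}
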